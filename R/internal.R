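# Internal helpers shared across modules. Images are plain numeric matrices
# (gray, H x W) or H x W x 3 arrays; pixels are addressed in R's column-major
# order so pixel k corresponds to index k of as.vector(channel). All
# user-facing coordinates are 0-based (row, col) with the origin at the
# top-left pixel center.

.n_channels <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) < 2L) {
    stop("image must be a matrix or a height x width x 3 array", call. = FALSE)
  }
  if (length(d) == 2L) return(1L)
  if (length(d) == 3L && d[3L] == 3L) return(3L)
  stop("image must have 1 (gray) or 3 (color) channels, got dim ",
       paste(d, collapse = "x"), call. = FALSE)
}

.check_image <- function(image) {
  nc <- .n_channels(image)
  if (!all(is.finite(image))) {
    stop("image contains non-finite values", call. = FALSE)
  }
  invisible(nc)
}

.image_dim <- function(image) {
  d <- dim(image)
  c(height = d[1L], width = d[2L])
}

.get_channel <- function(image, ch) {
  if (length(dim(image)) == 2L) image else image[, , ch]
}

# Matrix shifted by (dr, dc): out[r, c] = m[r + dr, c + dc] where defined,
# 0 elsewhere; `mask` marks the defined entries. Used to accumulate
# 8-neighborhood sums without loops over pixels.
.shift_pad <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  msk <- matrix(FALSE, h, w)
  r_lo <- max(1L, 1L - dr); r_hi <- min(h, h - dr)
  c_lo <- max(1L, 1L - dc); c_hi <- min(w, w - dc)
  if (r_lo <= r_hi && c_lo <= c_hi) {
    rs <- r_lo:r_hi; cs <- c_lo:c_hi
    out[rs, cs] <- m[rs + dr, cs + dc]
    msk[rs, cs] <- TRUE
  }
  list(values = out, mask = msk)
}

.NBR_OFFSETS <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

# Per-pixel 8-neighborhood statistics: count of existing neighbors (shared
# across channels) and, per channel, the sum and sum of squares of neighbor
# values. gamma_ik then evaluates as
#   sum_ch [ sumsq_ch - 2 v_ich * sum_ch + count * v_ich^2 ].
.nbr_stats <- function(image) {
  nc <- .n_channels(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  count <- matrix(0, h, w)
  sums <- vector("list", nc)
  sumsq <- vector("list", nc)
  for (ch in seq_len(nc)) {
    sums[[ch]] <- matrix(0, h, w)
    sumsq[[ch]] <- matrix(0, h, w)
  }
  for (o in seq_len(nrow(.NBR_OFFSETS))) {
    dr <- .NBR_OFFSETS[o, 1L]; dc <- .NBR_OFFSETS[o, 2L]
    for (ch in seq_len(nc)) {
      s <- .shift_pad(.get_channel(image, ch), dr, dc)
      sums[[ch]] <- sums[[ch]] + s$values
      sumsq[[ch]] <- sumsq[[ch]] + s$values^2
      if (ch == 1L) count <- count + s$mask
    }
  }
  list(count = count, sum = sums, sumsq = sumsq)
}

# Evaluate an expression with a locally seeded RNG, restoring (or removing)
# the global .Random.seed afterwards so generators never perturb user code.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.check_labels <- function(labels, what = "labels") {
  if (!is.matrix(labels)) stop(what, " must be an integer matrix", call. = FALSE)
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels))) {
    stop(what, " must contain nonnegative integers", call. = FALSE)
  }
  invisible(labels)
}
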