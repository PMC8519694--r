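# Initialization: regular-grid seeding and the minimum-gradient seed move
# that keeps initial centers off region boundaries.

#' Place initial cluster seeds on a regular grid
#'
#' Partitions an M x N image into near-square cells of side
#' \eqn{S = \sqrt{MN/k}} (\eqn{\lceil M/S\rceil \times \lceil N/S\rceil}
#' cells, distributed as evenly as integer sizes allow) and returns each
#' cell's center pixel with its intensity. The actual seed count equals the
#' number of grid cells and may differ slightly from `k` when `S` does not
#' divide the image sides.
#'
#' @param image Gray matrix or H x W x 3 array.
#' @param k Requested superpixel count, `1 <= k <= M*N`.
#' @return A data.frame of class `seed_set` with 0-based integer columns
#'   `row`, `col` and one intensity column per channel (`value` for gray,
#'   `value1..value3` for color).
#' @export
#' @examples
#' grid_seeds(matrix(0, 10, 10), k = 1) # single seed at (4, 4)
grid_seeds <- function(image, k) {
  nc <- .check_image(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (length(k) != 1L || !is.finite(k) || k < 1 || k > h * w || k != round(k)) {
    stop("k must be an integer in [1, M*N]", call. = FALSE)
  }
  s <- sqrt(h * w / k)
  n_r <- ceiling(h / s)
  n_c <- ceiling(w / s)
  # near-even integer cell sizes; remainder pixels go to the leading cells
  # (k <= M*N implies S >= 1, hence n_r <= M and no cell is empty)
  rcut <- c(0L, cumsum(.cell_sizes(h, n_r)))
  ccut <- c(0L, cumsum(.cell_sizes(w, n_c)))
  rows <- integer(0); cols <- integer(0)
  for (i in seq_len(n_r)) {
    r0 <- rcut[i]; r1 <- rcut[i + 1L]        # 0-based [r0, r1)
    rc <- (r0 + r1 - 1L) %/% 2L
    for (j in seq_len(n_c)) {
      c0 <- ccut[j]; c1 <- ccut[j + 1L]
      rows <- c(rows, rc)
      cols <- c(cols, (c0 + c1 - 1L) %/% 2L)
    }
  }
  .seed_set(image, rows, cols, nc)
}

.cell_sizes <- function(len, n_cells) {
  base <- len %/% n_cells
  rem <- len %% n_cells
  as.integer(c(rep(base + 1L, rem), rep(base, n_cells - rem)))
}

.seed_set <- function(image, rows, cols, nc) {
  out <- data.frame(row = as.integer(rows), col = as.integer(cols))
  for (ch in seq_len(nc)) {
    chan <- .get_channel(image, ch)
    val <- chan[cbind(rows + 1L, cols + 1L)]
    out[[if (nc == 1L) "value" else paste0("value", ch)]] <- val
  }
  class(out) <- c("seed_set", "data.frame")
  out
}

# Squared-central-difference gradient magnitude at every pixel, summed over
# channels; one-sided differences at the image border.
.gradient_image <- function(image) {
  nc <- .n_channels(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  g <- matrix(0, h, w)
  for (ch in seq_len(nc)) {
    m <- .get_channel(image, ch)
    up <- m[c(1L, seq_len(h - 1L)), , drop = FALSE]
    dn <- m[c(seq_len(h)[-1L], h), , drop = FALSE]
    lf <- m[, c(1L, seq_len(w - 1L)), drop = FALSE]
    rt <- m[, c(seq_len(w)[-1L], w), drop = FALSE]
    g <- g + (dn - up)^2 + (rt - lf)^2
  }
  g
}

#' Move each seed to the lowest-gradient pixel of its 3 x 3 window
#'
#' For every seed the 3 x 3 window around it (clipped at the image border)
#' is searched and the seed moves to the pixel with the smallest gradient
#' magnitude \eqn{G = \|I(r+1,c) - I(r-1,c)\|^2 + \|I(r,c+1) - I(r,c-1)\|^2}
#' (one-sided differences at the border, summed over channels for color).
#' Ties are broken by the lowest row-major index, which makes the move
#' deterministic.
#'
#' @param image Gray matrix or H x W x 3 array.
#' @param seeds A `seed_set` from [grid_seeds()].
#' @return A `seed_set` with updated positions and intensities.
#' @export
perturb_seeds <- function(image, seeds) {
  nc <- .check_image(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (any(seeds$row < 0L | seeds$row >= h | seeds$col < 0L | seeds$col >= w)) {
    stop("seeds outside the image", call. = FALSE)
  }
  g <- .gradient_image(image)
  rows <- seeds$row; cols <- seeds$col
  for (s in seq_along(rows)) {
    rr <- max(0L, rows[s] - 1L):min(h - 1L, rows[s] + 1L)
    cc <- max(0L, cols[s] - 1L):min(w - 1L, cols[s] + 1L)
    best <- c(rows[s], cols[s]); bestg <- Inf
    for (r in rr) for (c in cc) {       # row-major scan => first minimum wins
      gv <- g[r + 1L, c + 1L]
      if (gv < bestg) { bestg <- gv; best <- c(r, c) }
    }
    rows[s] <- best[1L]; cols[s] <- best[2L]
  }
  .seed_set(image, rows, cols, nc)
}
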