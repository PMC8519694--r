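# The SMBFT iteration: alternating closed-form minimization of the
# regularized objective over memberships, intensity centers and coordinate
# centers, followed by hard label extraction.

#' Closed-form membership update
#'
#' Given the current cluster state, computes the membership matrix that
#' minimizes the objective under the per-pixel sum-to-one constraint:
#' \deqn{u_{ik} = 1 \Big/ \sum_j \left[ E_{ik} / E_{jk} \right]^{1/(p-1)}}{
#'   u_ik = 1 / sum_j (E_ik / E_jk)^(1/(p-1))}
#' with effective distance \eqn{E_{ik} = D_{ik} + (\beta/N_R)\gamma_{ik}}.
#' If some \eqn{E_{ik}} is exactly 0 (the pixel coincides with a center in
#' value and position), the pixel is assigned crisply to the lowest-index
#' zero-distance cluster.
#'
#' @param image Gray matrix or H x W x 3 array.
#' @param state Cluster state (`v`, `x`, `y`; see [smbft_objective()]).
#' @param config An [smbft_config()].
#' @return Membership matrix, clusters x pixels, columns summing to 1.
#' @export
update_membership <- function(image, state, config) {
  .check_image(image)
  E <- .effective_distance(image, state, config)
  if (config$windowed) {
    E <- .window_mask(E, image, state, config)
  }
  .membership_from_distance(E, config$p)
}

.membership_from_distance <- function(E, p) {
  cc <- nrow(E); n <- ncol(E)
  zero_cols <- which(colSums(E == 0) > 0)
  # scale by the column minimum before the negative power so very small
  # distances cannot overflow
  emin <- do.call(pmin, c(asplit(E, 1L), list(na.rm = FALSE)))
  emin[emin <= 0] <- 1
  W <- sweep(E, 2L, emin, "/")^(-1 / (p - 1))
  u <- sweep(W, 2L, colSums(W), "/")
  if (length(zero_cols) > 0L) {
    u[, zero_cols] <- 0
    first_zero <- apply(E[, zero_cols, drop = FALSE] == 0, 2L, which.max)
    u[cbind(first_zero, zero_cols)] <- 1
  }
  u
}

# Restrict each pixel to clusters whose coordinate centers lie within twice
# the initialization grid side (in both axes); pixels with no candidate
# cluster keep the full set.
.window_mask <- function(E, image, state, config) {
  h <- dim(image)[1L]; w <- dim(image)[2L]
  s <- sqrt(h * w / config$k)
  rows0 <- rep.int(seq_len(h) - 1, w)
  cols0 <- rep(seq_len(w) - 1, each = h)
  cc <- nrow(E); n <- ncol(E)
  far <- abs(matrix(rows0, cc, n, byrow = TRUE) - state$x) > 2 * s |
         abs(matrix(cols0, cc, n, byrow = TRUE) - state$y) > 2 * s
  keep_all <- colSums(!far) == 0L
  far[, keep_all] <- FALSE
  E[far] <- Inf
  E
}

#' Closed-form intensity-center update
#'
#' Computes, per channel, the stationary point of the objective in the
#' cluster intensity centers:
#' \deqn{v_i = \frac{\sum_k u_{ik}^p \left[ y_k + (\beta/N_R)\sum_{r\in N_k}
#'   y_r \right]}{\sum_k u_{ik}^p \left[ 1 + (\beta/N_R)\, n_k \right]}}{
#'   v_i = sum_k u_ik^p (y_k + (beta/N_R) sum_r y_r) /
#'         sum_k u_ik^p (1 + (beta/N_R) n_k)}
#' where \eqn{n_k} is the number of existing 8-neighbors of pixel \eqn{k}
#' (8 in the interior, fewer on the border). On interior pixels the
#' denominator factor reduces to the familiar \eqn{(1+\beta)}; keeping the
#' actual neighbor count at the border makes the update the exact block
#' minimizer, which guarantees the objective never increases.
#'
#' @param image Gray matrix or H x W x 3 array.
#' @param u Membership matrix, clusters x pixels.
#' @param config An [smbft_config()].
#' @param previous Optional previous intensity-center matrix; a cluster with
#'   zero total membership weight keeps its previous center (with a warning)
#'   instead of failing.
#' @return Matrix of intensity centers, clusters x channels.
#' @export
update_intensity_centers <- function(image, u, config, previous = NULL) {
  nc <- .check_image(image)
  n <- prod(dim(image)[1:2])
  .check_membership(u, n)
  nb <- .nbr_stats(image)
  coef <- config$beta / config$n_r
  W <- u^config$p
  den <- as.vector(W %*% (1 + coef * as.vector(nb$count)))
  v <- matrix(NA_real_, nrow(u), nc)
  for (ch in seq_len(nc)) {
    y <- as.vector(.get_channel(image, ch))
    num <- as.vector(W %*% (y + coef * as.vector(nb$sum[[ch]])))
    v[, ch] <- num / den
  }
  bad <- den == 0
  if (any(bad)) {
    if (is.null(previous)) {
      stop("degenerate cluster: zero membership weight and no previous center",
           call. = FALSE)
    }
    warning(sum(bad), " degenerate cluster(s) kept their previous center",
            call. = FALSE)
    prev <- if (is.null(dim(previous))) matrix(previous, ncol = 1L) else previous
    v[bad, ] <- prev[bad, , drop = FALSE]
  }
  v
}

#' Closed-form coordinate-center update
#'
#' Membership-weighted centroid of pixel coordinates:
#' \eqn{X_i = \sum_k u_{ik}^p X_k / \sum_k u_{ik}^p} and likewise
#' \eqn{Y_i}; real-valued, 0-based.
#'
#' @param u Membership matrix, clusters x pixels.
#' @param config An [smbft_config()].
#' @param coords Two-column matrix of 0-based `(row, col)` pixel coordinates,
#'   one row per membership column.
#' @return List with numeric vectors `x` (rows) and `y` (cols).
#' @export
update_coordinate_centers <- function(u, config, coords) {
  if (nrow(coords) != ncol(u)) {
    stop("coords must have one row per membership column", call. = FALSE)
  }
  W <- u^config$p
  ws <- rowSums(W)
  if (any(ws == 0)) {
    stop("degenerate cluster: zero membership weight", call. = FALSE)
  }
  list(x = as.vector(W %*% coords[, 1L]) / ws,
       y = as.vector(W %*% coords[, 2L]) / ws)
}

.pixel_coords <- function(h, w) {
  cbind(row = rep.int(seq_len(h) - 1, w), col = rep(seq_len(w) - 1, each = h))
}

#' Run the SMBFT superpixel clustering
#'
#' Seeds clusters on a regular grid ([grid_seeds()]), nudges each seed to
#' the lowest-gradient pixel of its 3 x 3 window ([perturb_seeds()]), then
#' alternates [update_membership()], [update_intensity_centers()] and
#' [update_coordinate_centers()] until the largest intensity-center change
#' drops below `config$tol` or `config$max_iter` iterations have run. Hard
#' labels are the per-pixel membership argmax (ties to the lowest cluster
#' index). The algorithm has no random state: identical inputs give
#' identical outputs.
#'
#' Connectivity enforcement and small-region merging are a separate step;
#' see [postprocess_labels()] or the [superpixels()] wrapper.
#'
#' @param image Gray matrix or H x W x 3 array on its native intensity
#'   scale.
#' @param config An [smbft_config()].
#' @return An object of class `smbft_fit`: list with `labels` (H x W
#'   integer matrix of 0-based cluster ids), `u` (membership matrix),
#'   `state` (`v`, `x`, `y`), `trace` (per-iteration `objective` and
#'   `center_shift`, `iterations`, `converged`), `seeds` and `config`.
#' @export
#' @examples
#' img <- cbind(matrix(50, 16, 8), matrix(200, 16, 8))
#' fit <- run_smbft(img, smbft_config(k = 2, alpha = 1, beta = 0))
#' table(fit$labels)
run_smbft <- function(image, config) {
  .check_image(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (h < 1L || w < 1L) stop("image is empty", call. = FALSE)
  seeds <- perturb_seeds(image, grid_seeds(image, config$k))
  nc <- .n_channels(image)
  vcols <- if (nc == 1L) "value" else paste0("value", seq_len(nc))
  state <- list(v = as.matrix(seeds[, vcols, drop = FALSE]),
                x = as.numeric(seeds$row), y = as.numeric(seeds$col))
  dimnames(state$v) <- NULL
  coords <- .pixel_coords(h, w)
  nb <- .nbr_stats(image)

  if (config$max_iter == 0L) {
    # nearest-seed assignment by the combined intensity/coordinate distance
    E <- .effective_distance(image, state,
                             smbft_config(config$k, alpha = config$alpha,
                                          beta = 0, n_r = config$n_r,
                                          p = config$p, tol = config$tol,
                                          max_iter = 0L), nb)
    lab <- max.col(-t(E), ties.method = "first") - 1L
    u <- matrix(0, nrow(state$v), h * w)
    u[cbind(lab + 1L, seq_len(h * w))] <- 1
    trace <- list(objective = numeric(0), center_shift = numeric(0),
                  iterations = 0L, converged = FALSE)
    return(.smbft_fit(matrix(as.integer(lab), h, w), u, state, trace,
                      seeds, config))
  }

  obj <- numeric(0); shifts <- numeric(0)
  converged <- FALSE
  E <- .effective_distance(image, state, config, nb)
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    u <- if (config$windowed) {
      .membership_from_distance(.window_mask(E, image, state, config), config$p)
    } else {
      .membership_from_distance(E, config$p)
    }
    v_new <- update_intensity_centers(image, u, config, previous = state$v)
    shift <- max(abs(v_new - state$v))
    cen <- update_coordinate_centers(u, config, coords)
    state <- list(v = v_new, x = cen$x, y = cen$y)
    E <- .effective_distance(image, state, config, nb)
    obj <- c(obj, sum(u^config$p * E))
    shifts <- c(shifts, shift)
    if (shift < config$tol) { converged <- TRUE; break }
  }
  lab <- max.col(t(u), ties.method = "first") - 1L
  trace <- list(objective = obj, center_shift = shifts,
                iterations = iter, converged = converged)
  .smbft_fit(matrix(as.integer(lab), h, w), u, state, trace, seeds, config)
}

.smbft_fit <- function(labels, u, state, trace, seeds, config) {
  structure(list(labels = labels, u = u, state = state, trace = trace,
                 seeds = seeds, config = config),
            class = "smbft_fit")
}

#' @export
print.smbft_fit <- function(x, ...) {
  cat(sprintf("SMBFT fit: %d clusters on a %d x %d image\n",
              nrow(x$state$v), nrow(x$labels), ncol(x$labels)))
  cat(sprintf("  %d iteration(s), %s (final center shift %.3g)\n",
              x$trace$iterations,
              if (x$trace$converged) "converged" else "iteration cap reached",
              if (length(x$trace$center_shift) > 0)
                x$trace$center_shift[length(x$trace$center_shift)] else NA))
  if (length(x$trace$objective) > 0) {
    cat(sprintf("  objective %.6g -> %.6g\n",
                x$trace$objective[1], x$trace$objective[length(x$trace$objective)]))
  }
  invisible(x)
}

#' Segment an image into superpixels (high-level wrapper)
#'
#' Runs [run_smbft()] (or its Lab-space color variant for 3-channel sRGB
#' input) and applies the postprocessing chain: connectivity enforcement
#' and small-region merging.
#'
#' @param image Gray matrix (native intensity scale) or H x W x 3 sRGB
#'   array on the 0-255 scale.
#' @param k Requested superpixel count.
#' @param config Optional [smbft_config()]; if supplied, `k` and `...` are
#'   ignored.
#' @param ... Further arguments passed to [smbft_config()].
#' @return List with `labels` (postprocessed 0-based label matrix) and
#'   `fit` (the underlying `smbft_fit`).
#' @export
superpixels <- function(image, k, config = NULL, ...) {
  if (is.null(config)) config <- smbft_config(k, ...)
  nc <- .n_channels(image)
  fit <- if (nc == 3L) run_smbft_color(image, config) else run_smbft(image, config)
  list(labels = postprocess_labels(fit$labels, image, config), fit = fit)
}
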