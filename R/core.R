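# Core model: configuration, the per-pixel distance and neighborhood penalty
# terms, and the regularized fuzzy c-means objective that the clustering
# iteration minimizes.

#' Configuration for SMBFT superpixel clustering
#'
#' Bundles the tunable parameters of the spatially regularized fuzzy c-means
#' objective
#' \deqn{J = \sum_i \sum_k u_{ik}^p \left[ \|y_k - v_i\|^2
#'   + \alpha \left((X_k - X_i)^2 + (Y_k - Y_i)^2\right)
#'   + \frac{\beta}{N_R} \sum_{r \in N_k} \|y_r - v_i\|^2 \right]}{
#'   J = sum_ik u_ik^p [ ||y_k - v_i||^2 + alpha ((X_k-X_i)^2 + (Y_k-Y_i)^2)
#'   + (beta/N_R) sum_{r in N_k} ||y_r - v_i||^2 ]}
#' where \eqn{u_{ik}} is the fuzzy membership of pixel \eqn{k} in cluster
#' \eqn{i}, \eqn{v_i} the cluster intensity center, \eqn{(X_i, Y_i)} its
#' coordinate center, and \eqn{N_k} the 8-neighborhood of pixel \eqn{k}.
#'
#' @param k Requested number of superpixels (the effective count after grid
#'   initialization may differ slightly; see [grid_seeds()]).
#' @param alpha Weight of the coordinate-distance term (>= 0). Controls
#'   compactness; useful values are roughly 1-10, smaller for larger `k`.
#' @param beta Weight of the 8-neighborhood noise-regularization term (>= 0).
#' @param n_r Nominal neighborhood size used as the normalizer of the
#'   neighborhood term; 8 for the 8-neighborhood. Border pixels have fewer
#'   neighbors but `n_r` stays fixed, so they receive a slightly smaller
#'   penalty.
#' @param p Fuzzifier exponent (> 1); larger values give softer memberships.
#' @param tol Convergence threshold on the largest absolute change of any
#'   cluster intensity center, on the raster's native intensity scale.
#' @param max_iter Iteration cap (>= 0). `max_iter = 0` yields the
#'   nearest-seed assignment.
#' @param windowed If `TRUE`, each pixel only competes among clusters whose
#'   coordinate centers lie within twice the initialization grid side; this
#'   is faster but changes results, so it is off by default.
#' @param min_size Minimum superpixel size for [merge_small_superpixels()];
#'   `NULL` means the automatic default `floor(S^2/4)` with `S` the
#'   initialization grid side.
#'
#' @return An object of class `smbft_config`.
#' @export
#' @examples
#' smbft_config(k = 100, alpha = 2, beta = 1)
smbft_config <- function(k, alpha = 2, beta = 1, n_r = 8L, p = 2,
                         tol = 1e-3, max_iter = 100L, windowed = FALSE,
                         min_size = NULL) {
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (!is.finite(n_r) || n_r < 1) stop("n_r must be >= 1", call. = FALSE)
  if (!is.finite(p) || p <= 1) stop("p must be > 1", call. = FALSE)
  if (!is.finite(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (!is.finite(max_iter) || max_iter < 0 || max_iter != round(max_iter)) {
    stop("max_iter must be a nonnegative integer", call. = FALSE)
  }
  if (!is.null(min_size) &&
      (!is.finite(min_size) || min_size < 0 || min_size != round(min_size))) {
    stop("min_size must be NULL or a nonnegative integer", call. = FALSE)
  }
  structure(
    list(k = as.integer(k), alpha = alpha, beta = beta, n_r = as.integer(n_r),
         p = p, tol = tol, max_iter = as.integer(max_iter),
         windowed = isTRUE(windowed),
         min_size = if (is.null(min_size)) NULL else as.integer(min_size)),
    class = "smbft_config"
  )
}

#' @export
print.smbft_config <- function(x, ...) {
  cat("SMBFT configuration\n")
  cat(sprintf("  k = %d, alpha = %g, beta = %g, N_R = %d, p = %g\n",
              x$k, x$alpha, x$beta, x$n_r, x$p))
  cat(sprintf("  tol = %g, max_iter = %d, windowed = %s, min_size = %s\n",
              x$tol, x$max_iter, x$windowed,
              if (is.null(x$min_size)) "auto" else x$min_size))
  invisible(x)
}

#' Combined intensity and coordinate distance between a pixel and a center
#'
#' Computes \eqn{\|y_k - v_i\|^2 + \alpha[(X_k - X_i)^2 + (Y_k - Y_i)^2]},
#' the distance term of the SMBFT objective. For multi-channel values the
#' intensity part is the sum of squared per-channel differences.
#'
#' @param pixel_value,center_value Numeric scalars or equal-length vectors
#'   (one entry per channel).
#' @param pixel_coord,center_coord Length-2 numeric `(row, col)` coordinates
#'   (0-based).
#' @param alpha Coordinate weight (>= 0).
#' @return A nonnegative scalar.
#' @export
#' @examples
#' pixel_distance(10, 7, c(0, 0), c(1, 2), alpha = 2) # 9 + 2 * (1 + 4) = 19
pixel_distance <- function(pixel_value, center_value, pixel_coord,
                           center_coord, alpha) {
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (length(pixel_value) != length(center_value)) {
    stop("pixel_value and center_value must have the same length", call. = FALSE)
  }
  sum((pixel_value - center_value)^2) +
    alpha * sum((pixel_coord[1:2] - center_coord[1:2])^2)
}

#' Neighborhood penalty of a pixel against a cluster center
#'
#' Sums \eqn{\|y_r - v_i\|^2} over the 8-neighbors of a pixel that exist
#' within the image (border pixels have fewer). The normalizer \eqn{N_R}
#' of the objective is applied by the caller and stays fixed regardless of
#' how many neighbors exist.
#'
#' @param image Gray matrix or H x W x 3 array.
#' @param pixel_coord Length-2 `(row, col)` 0-based coordinate inside the
#'   image.
#' @param center_value Cluster intensity center; scalar or one value per
#'   channel.
#' @return A nonnegative scalar.
#' @export
neighborhood_penalty <- function(image, pixel_coord, center_value) {
  nc <- .check_image(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  r <- pixel_coord[1L] + 1L; c <- pixel_coord[2L] + 1L
  if (r < 1L || r > h || c < 1L || c > w) {
    stop("pixel_coord outside the image", call. = FALSE)
  }
  if (length(center_value) != nc) {
    stop("center_value must have one entry per channel", call. = FALSE)
  }
  total <- 0
  for (o in seq_len(nrow(.NBR_OFFSETS))) {
    rr <- r + .NBR_OFFSETS[o, 1L]; cc <- c + .NBR_OFFSETS[o, 2L]
    if (rr < 1L || rr > h || cc < 1L || cc > w) next
    for (ch in seq_len(nc)) {
      total <- total + (.get_channel(image, ch)[rr, cc] - center_value[ch])^2
    }
  }
  total
}

# Effective distance matrix E (c x N):
#   E_ik = D_ik + (beta/N_R) * gamma_ik
# with D the intensity + alpha-weighted coordinate distance and gamma the
# 8-neighborhood penalty of pixel k against center v_i. Pixels are in
# column-major order. `nb` may carry precomputed .nbr_stats(image).
.effective_distance <- function(image, state, config, nb = NULL) {
  nc <- .n_channels(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  n <- h * w
  v <- state$v
  if (is.null(dim(v))) v <- matrix(v, ncol = 1L)
  cc <- nrow(v)
  if (is.null(nb)) nb <- .nbr_stats(image)
  coef <- config$beta / config$n_r

  # coordinate part: alpha * ((X_k - X_i)^2 + (Y_k - Y_i)^2), 0-based coords
  rows0 <- rep.int(seq_len(h) - 1, w)
  cols0 <- rep(seq_len(w) - 1, each = h)
  E <- config$alpha *
    ((matrix(rows0, cc, n, byrow = TRUE) - state$x)^2 +
     (matrix(cols0, cc, n, byrow = TRUE) - state$y)^2)

  cnt <- matrix(as.vector(nb$count), cc, n, byrow = TRUE)
  for (ch in seq_len(nc)) {
    y <- as.vector(.get_channel(image, ch))
    ym <- matrix(y, cc, n, byrow = TRUE)
    E <- E + (ym - v[, ch])^2
    if (coef > 0) {
      B <- matrix(as.vector(nb$sum[[ch]]), cc, n, byrow = TRUE)
      A <- matrix(as.vector(nb$sumsq[[ch]]), cc, n, byrow = TRUE)
      E <- E + coef * (A - 2 * v[, ch] * B + cnt * v[, ch]^2)
    }
  }
  # guard tiny negative values from cancellation in the gamma expansion
  E[E < 0] <- 0
  E
}

#' SMBFT objective function
#'
#' Evaluates the regularized fuzzy c-means objective (see [smbft_config()])
#' for a given membership matrix and cluster state. Used for monitoring:
#' the alternating closed-form updates of [run_smbft()] never increase it.
#'
#' @param image Gray matrix or H x W x 3 array.
#' @param u Membership matrix, clusters x pixels (pixels in column-major
#'   order); every column must sum to 1.
#' @param state Cluster state: list with `v` (intensity centers, clusters x
#'   channels), `x`, `y` (coordinate centers, 0-based row / col).
#' @param config An [smbft_config()].
#' @return The scalar objective value.
#' @export
smbft_objective <- function(image, u, state, config) {
  .check_image(image)
  .check_membership(u, prod(dim(image)[1:2]))
  E <- .effective_distance(image, state, config)
  sum(u^config$p * E)
}

.check_membership <- function(u, n_pixels, tol = 1e-9) {
  if (!is.matrix(u)) stop("u must be a clusters x pixels matrix", call. = FALSE)
  if (ncol(u) != n_pixels) {
    stop("u has ", ncol(u), " columns but the image has ", n_pixels,
         " pixels", call. = FALSE)
  }
  cs <- colSums(u)
  if (any(abs(cs - 1) > tol) || any(u < -tol) || any(u > 1 + tol)) {
    stop("membership columns must lie in [0,1] and sum to 1", call. = FALSE)
  }
  invisible(u)
}
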