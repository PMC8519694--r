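# Phantom generator: piecewise-constant multi-region templates with
# optional boundary blur, a smooth multiplicative bias field, and additive
# Gaussian noise, each with the exact ground-truth labeling. Emulates the
# conditions of simulated brain-MR experiments (noise levels around 0-7%,
# bias-field amplitudes 0 or 40%) at desk scale.

#' Specify a synthetic phantom
#'
#' @param shape Length-2 integer `(height, width)`.
#' @param template Region layout: `"stripes"` (equal vertical stripes, one
#'   per intensity), `"blobs"` (nested concentric rectangles) or `"brain"`
#'   (elliptical head with nested tissue-like regions: background, a
#'   gray-matter-like ring, a white-matter-like core when 3 intensities are
#'   given).
#' @param intensities Distinct region intensities on the 0-255 scale,
#'   outermost/leftmost region first.
#' @param noise_pct Additive Gaussian noise level: the noise standard
#'   deviation is `noise_pct/100` times the template intensity range
#'   (max - min over region intensities).
#' @param bias_pct Amplitude of the smooth multiplicative bias field in
#'   percent; the field spans `1 - bias_pct/100` to `1 + bias_pct/100`.
#' @param blur_sigma Gaussian boundary-softening width in pixels (0 = hard
#'   edges).
#' @param rng_seed Integer seed; the generated image is fully determined by
#'   the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L),
                         template = c("stripes", "blobs", "brain"),
                         intensities = c(20, 120, 200),
                         noise_pct = 0, bias_pct = 0, blur_sigma = 0,
                         rng_seed = 1L) {
  template <- match.arg(template)
  if (length(shape) != 2L || any(shape < 2) || any(shape != round(shape))) {
    stop("shape must be two integers >= 2", call. = FALSE)
  }
  if (length(intensities) < 2L || anyDuplicated(intensities)) {
    stop("intensities must be >= 2 distinct values", call. = FALSE)
  }
  if (noise_pct < 0 || bias_pct < 0 || blur_sigma < 0) {
    stop("noise_pct, bias_pct and blur_sigma must be >= 0", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), template = template,
                 intensities = intensities, noise_pct = noise_pct,
                 bias_pct = bias_pct, blur_sigma = blur_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# 0-based region template; independent of noise/bias/seed
.phantom_template <- function(spec) {
  h <- spec$shape[1L]; w <- spec$shape[2L]
  n <- length(spec$intensities)
  if (spec$template == "stripes") {
    col_region <- rep(seq_len(n) - 1L, times = .cell_sizes(w, n))
    matrix(rep(col_region, each = h), h, w)
  } else if (spec$template == "blobs") {
    # nested rectangles: normalized Chebyshev distance from the border
    r <- matrix(rep.int(seq_len(h) - 1, w), h, w)
    c <- matrix(rep(seq_len(w) - 1, each = h), h, w)
    m <- pmin(r / (h - 1), 1 - r / (h - 1), c / (w - 1), 1 - c / (w - 1)) * 2
    reg <- pmin(floor(m * n), n - 1L)
    matrix(as.integer(reg), h, w)
  } else {
    # brain-like: nested ellipses centered in the frame; outermost ellipse
    # spans ~90% of the frame, inner regions shrink geometrically
    r <- matrix(rep.int(seq_len(h) - 1, w), h, w)
    c <- matrix(rep(seq_len(w) - 1, each = h), h, w)
    rn <- (r - (h - 1) / 2) / ((h - 1) / 2)
    cn <- (c - (w - 1) / 2) / ((w - 1) / 2)
    d2 <- rn^2 + cn^2
    reg <- matrix(0L, h, w)
    radii <- 0.9 * (0.62^(seq_len(n - 1L) - 1L))
    for (j in seq_len(n - 1L)) reg[d2 <= radii[j]^2] <- j
    reg
  }
}

# separable Gaussian blur, kernel truncated at 3 sigma, edge replication
.gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-rad:rad, sd = sigma)
  kern <- kern / sum(kern)
  pad_conv <- function(x) { # along rows of a matrix
    h <- nrow(x)
    xp <- x[c(rep(1L, rad), seq_len(h), rep(h, rad)), , drop = FALSE]
    out <- matrix(0, h, ncol(x))
    for (j in seq_along(kern)) {
      out <- out + kern[j] * xp[(j - 1L) + seq_len(h), , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(m))))
}

.bias_field <- function(h, w, bias_pct) {
  if (bias_pct <= 0) return(matrix(1, h, w))
  a <- bias_pct / 100
  rr <- cos(pi * (seq_len(h) - 1) / (h - 1))
  cc <- cos(pi * (seq_len(w) - 1) / (w - 1))
  1 + a * outer(rr, cc)
}

#' Generate a grayscale phantom with ground truth
#'
#' Renders the piecewise-constant template, optionally softens region
#' boundaries with a Gaussian blur, multiplies by a smooth low-frequency
#' bias field (product of half-period cosine ramps, amplitude
#' `1 +/- bias_pct/100`), adds Gaussian noise with standard deviation
#' `noise_pct/100` of the template intensity range, and clamps to
#' \[0, 255\]. The ground truth is the template labeling and does not
#' depend on noise, bias or seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (numeric matrix, 0-255 scale) and `gt`
#'   (integer matrix of 0-based region ids).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32), noise_pct = 5))
#' table(ph$gt)
generate_phantom <- function(spec) {
  gt <- .phantom_template(spec)
  img <- matrix(spec$intensities[gt + 1L], nrow(gt), ncol(gt))
  img <- .gaussian_blur(img, spec$blur_sigma)
  img <- img * .bias_field(nrow(img), ncol(img), spec$bias_pct)
  if (spec$noise_pct > 0) {
    sdev <- spec$noise_pct / 100 * diff(range(spec$intensities))
    noise <- .with_seed(spec$rng_seed,
                        matrix(stats::rnorm(length(img), sd = sdev),
                               nrow(img), ncol(img)))
    img <- img + noise
  }
  img[img < 0] <- 0
  img[img > 255] <- 255
  list(image = img, gt = gt)
}

#' Generate an sRGB color phantom with ground truth
#'
#' Same corruption chain as [generate_phantom()], applied per channel; the
#' noise standard deviation uses the range of the template color
#' components and independent draws per channel.
#'
#' @param spec A [phantom_spec()]; its `intensities` field only determines
#'   the number of regions when `colors` is given.
#' @param colors Regions x 3 matrix of sRGB colors on the 0-255 scale, one
#'   row per region.
#' @return List with `image` (H x W x 3 sRGB array) and `gt` (integer
#'   matrix of 0-based region ids).
#' @export
generate_color_phantom <- function(spec, colors) {
  colors <- as.matrix(colors)
  if (ncol(colors) != 3L || nrow(colors) != length(spec$intensities)) {
    stop("colors must be a regions x 3 sRGB matrix matching the spec",
         call. = FALSE)
  }
  gt <- .phantom_template(spec)
  h <- nrow(gt); w <- ncol(gt)
  img <- array(0, c(h, w, 3L))
  sdev <- spec$noise_pct / 100 * diff(range(colors))
  noise <- if (spec$noise_pct > 0) {
    .with_seed(spec$rng_seed, array(stats::rnorm(h * w * 3L, sd = sdev),
                                    c(h, w, 3L)))
  } else {
    array(0, c(h, w, 3L))
  }
  bias <- .bias_field(h, w, spec$bias_pct)
  for (ch in 1:3) {
    m <- matrix(colors[gt + 1L, ch], h, w)
    m <- .gaussian_blur(m, spec$blur_sigma) * bias + noise[, , ch]
    img[, , ch] <- m
  }
  img[img < 0] <- 0
  img[img > 255] <- 255
  list(image = img, gt = gt)
}
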