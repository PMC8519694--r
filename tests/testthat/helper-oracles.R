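# Independent oracles used throughout the suite. Each one is a deliberately
# naive re-derivation (explicit loops, generic optimizers) kept free of the
# package's vectorized code paths.

# --- neighborhood / objective --------------------------------------------

oracle_channels <- function(image) if (length(dim(image)) == 2L) 1L else dim(image)[3L]

oracle_chan <- function(image, ch) if (length(dim(image)) == 2L) image else image[, , ch]

# sum of squared differences to center over existing 8-neighbors
oracle_gamma <- function(image, r0, c0, center) {
  h <- dim(image)[1L]; w <- dim(image)[2L]
  total <- 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r0 + dr; cc <- c0 + dc
    if (rr < 0 || rr >= h || cc < 0 || cc >= w) next
    for (ch in seq_len(oracle_channels(image))) {
      total <- total + (oracle_chan(image, ch)[rr + 1, cc + 1] - center[ch])^2
    }
  }
  total
}

# term-by-term evaluation of the objective: intensity + coordinate +
# neighborhood parts summed with explicit loops over clusters and pixels
oracle_objective <- function(image, u, state, config) {
  h <- dim(image)[1L]; w <- dim(image)[2L]
  nc <- oracle_channels(image)
  v <- if (is.null(dim(state$v))) matrix(state$v, ncol = 1) else state$v
  total <- 0
  for (i in seq_len(nrow(v))) {
    k <- 0L
    for (c0 in seq_len(w) - 1L) for (r0 in seq_len(h) - 1L) {
      k <- k + 1L # column-major pixel order
      dint <- 0
      for (ch in seq_len(nc)) {
        dint <- dint + (oracle_chan(image, ch)[r0 + 1, c0 + 1] - v[i, ch])^2
      }
      dcoord <- (r0 - state$x[i])^2 + (c0 - state$y[i])^2
      gam <- oracle_gamma(image, r0, c0, v[i, ])
      total <- total + u[i, k]^config$p *
        (dint + config$alpha * dcoord + (config$beta / config$n_r) * gam)
    }
  }
  total
}

# effective distance E_ik for small instances, via the same naive loops
oracle_effective_distance <- function(image, state, config) {
  h <- dim(image)[1L]; w <- dim(image)[2L]
  nc <- oracle_channels(image)
  v <- if (is.null(dim(state$v))) matrix(state$v, ncol = 1) else state$v
  E <- matrix(0, nrow(v), h * w)
  for (i in seq_len(nrow(v))) {
    k <- 0L
    for (c0 in seq_len(w) - 1L) for (r0 in seq_len(h) - 1L) {
      k <- k + 1L
      dint <- 0
      for (ch in seq_len(nc)) {
        dint <- dint + (oracle_chan(image, ch)[r0 + 1, c0 + 1] - v[i, ch])^2
      }
      E[i, k] <- dint + config$alpha * ((r0 - state$x[i])^2 + (c0 - state$y[i])^2) +
        (config$beta / config$n_r) * oracle_gamma(image, r0, c0, v[i, ])
    }
  }
  E
}

# numerical constrained minimizer of sum_i u_i^p E_i over the simplex,
# via a softmax reparameterization and Nelder-Mead restarts
oracle_simplex_membership <- function(E_col, p) {
  cc <- length(E_col)
  obj <- function(z) {
    u <- exp(z - max(z)); u <- u / sum(u)
    sum(u^p * E_col)
  }
  best <- NULL; bestval <- Inf
  for (start in list(rep(0, cc), log(1 / pmax(E_col, 1e-12)))) {
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (fit$value < bestval) { bestval <- fit$value; best <- fit$par }
  }
  u <- exp(best - max(best)); u / sum(u)
}

# classical FCM updates (membership and centers) from the textbook formulas
oracle_fcm_membership <- function(D, p) {
  u <- matrix(0, nrow(D), ncol(D))
  for (k in seq_len(ncol(D))) {
    for (i in seq_len(nrow(D))) {
      u[i, k] <- 1 / sum((D[i, k] / D[, k])^(1 / (p - 1)))
    }
  }
  u
}

oracle_fcm_centers <- function(y, u, p) {
  vapply(seq_len(nrow(u)), function(i) sum(u[i, ]^p * y) / sum(u[i, ]^p),
         numeric(1))
}

# --- labels / metrics -----------------------------------------------------

# connected components via union-find over same-label 4-adjacent pairs
oracle_component_count <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  parent <- seq_len(h * w)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (r in seq_len(h)) for (c in seq_len(w)) {
    idx <- (c - 1L) * h + r
    if (r < h && labels[r + 1L, c] == labels[r, c]) union(idx, idx + 1L)
    if (c < w && labels[r, c + 1L] == labels[r, c]) union(idx, idx + h)
  }
  length(unique(vapply(seq_len(h * w), find, integer(1))))
}

# UE by exhaustive pixel-set enumeration
oracle_ue <- function(labels, gt) {
  total <- 0
  for (i in unique(as.vector(gt))) {
    Ri <- which(gt == i)
    for (k in unique(as.vector(labels))) {
      Sk <- which(labels == k)
      if (length(intersect(Sk, Ri)) > 0) {
        total <- total + length(setdiff(Sk, Ri))
      }
    }
  }
  total / length(gt)
}

oracle_boundary <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  out <- NULL
  for (r in seq_len(h)) for (c in seq_len(w)) {
    differs <- (r > 1 && labels[r - 1, c] != labels[r, c]) ||
      (r < h && labels[r + 1, c] != labels[r, c]) ||
      (c > 1 && labels[r, c - 1] != labels[r, c]) ||
      (c < w && labels[r, c + 1] != labels[r, c])
    if (differs) out <- rbind(out, c(r, c))
  }
  out
}

# BR by exhaustive nearest-neighbor search over boundary sets
oracle_br <- function(labels, gt, eps) {
  dR <- oracle_boundary(gt)
  dS <- oracle_boundary(labels)
  if (is.null(dR)) stop("no ground-truth boundary")
  hit <- 0
  for (j in seq_len(nrow(dR))) {
    if (is.null(dS)) break
    dmin <- min(sqrt((dS[, 1] - dR[j, 1])^2 + (dS[, 2] - dR[j, 2])^2))
    if (dmin < eps) hit <- hit + 1
  }
  hit / nrow(dR)
}

# --- shared fixtures ------------------------------------------------------

# labels taking each pixel as its own superpixel
singleton_labels <- function(h, w) matrix(seq_len(h * w) - 1L, h, w)

# random label map with a handful of region ids
random_label_map <- function(h, w, n_labels, seed) {
  set.seed(seed)
  matrix(sample.int(n_labels, h * w, replace = TRUE) - 1L, h, w)
}

# feasible random membership matrix (columns on the simplex)
random_membership <- function(n_clusters, n_pixels, seed) {
  set.seed(seed)
  u <- matrix(stats::runif(n_clusters * n_pixels), n_clusters, n_pixels)
  sweep(u, 2, colSums(u), "/")
}

# independent restatement of the CIE sRGB (D65) -> L*a*b* formulas
oracle_lab <- function(rgb255) {
  s <- rgb255 / 255
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  M <- rbind(c(0.4124564, 0.3575761, 0.1804375),
             c(0.2126729, 0.7151522, 0.0721750),
             c(0.0193339, 0.1191920, 0.9503041))
  xyz <- as.vector(M %*% lin) / c(0.95047, 1, 1.08883)
  f <- ifelse(xyz > (6 / 29)^3, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  c(L = 116 * f[2] - 16, a = 500 * (f[1] - f[2]), b = 200 * (f[2] - f[3]))
}
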