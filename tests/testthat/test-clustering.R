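test_that("membership update matches closed form on degenerate cases", {
  img <- matrix(c(1, 2, 3, 4), 2, 2)
  cfg <- smbft_config(k = 1, alpha = 1, beta = 1)

  # single cluster: normalization forces u = 1 everywhere
  st1 <- list(v = matrix(2.5, 1, 1), x = 0.5, y = 0.5)
  expect_equal(update_membership(img, st1, cfg), matrix(1, 1, 4))

  # two clusters with mirror-symmetric centers: equal effective distances
  # at the symmetric pixels give u = 0.5
  img2 <- matrix(5, 2, 2)
  st2 <- list(v = matrix(c(5, 5), 2, 1), x = c(0, 1), y = c(0, 1))
  u2 <- update_membership(img2, st2, smbft_config(k = 2, alpha = 1, beta = 0))
  # pixels (0,1) and (1,0) are equidistant from both centers
  expect_equal(u2[, 2], c(0.5, 0.5)) # pixel (1,0) in column-major order
  expect_equal(u2[, 3], c(0.5, 0.5)) # pixel (0,1)
  expect_equal(colSums(u2), rep(1, 4))
})

test_that("membership update minimizes the constrained objective (oracle)", {
  # p=2 with effective distances (1, 3) must give (0.75, 0.25); build a
  # 1x1 image where alpha produces exactly those distances
  img <- matrix(0, 1, 1)
  cfg <- smbft_config(k = 2, alpha = 1, beta = 0)
  st <- list(v = matrix(c(0, 0), 2, 1), x = c(1, 0), y = c(0, sqrt(3)))
  u <- update_membership(img, st, cfg)
  expect_equal(as.vector(u), c(0.75, 0.25), tolerance = 1e-12)

  # generic instances up to 6 pixels / 3 clusters against a numerical
  # simplex minimizer of the membership block
  for (seed in 1:6) {
    set.seed(seed)
    h <- sample(1:2, 1); w <- sample(1:3, 1)
    cc <- sample(2:3, 1)
    img <- matrix(runif(h * w, 0, 255), h, w)
    p <- sample(c(2, 2.5), 1)
    cfg <- smbft_config(k = cc, alpha = runif(1, 0, 3), beta = runif(1, 0, 2),
                        p = p)
    st <- list(v = matrix(runif(cc, 0, 255), cc, 1),
               x = runif(cc, 0, h - 1), y = runif(cc, 0, w - 1))
    u <- update_membership(img, st, cfg)
    E <- oracle_effective_distance(img, st, cfg)
    for (k in seq_len(h * w)) {
      expect_equal(u[, k], oracle_simplex_membership(E[, k], p),
                   tolerance = 1e-5)
    }
  }
})

test_that("exact center/pixel coincidence yields a crisp assignment", {
  img <- matrix(7, 3, 3)
  cfg <- smbft_config(k = 2, alpha = 2, beta = 1)
  # cluster 1 sits exactly on pixel (1,1) with the exact intensity; the
  # constant image makes the neighborhood term vanish as well
  st <- list(v = matrix(c(7, 7), 2, 1), x = c(1, 1), y = c(1, 1))
  u <- update_membership(img, st, cfg)
  expect_equal(u[, 5], c(1, 0)) # center pixel: both E zero, lowest index wins
})

test_that("intensity centers follow the closed-form update", {
  cfg0 <- smbft_config(k = 2, alpha = 1, beta = 0)

  # beta = 0, p = 2, crisp memberships on two pixels -> plain weighted mean
  img <- matrix(c(0, 10, 0, 10), 2, 2)
  u <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  v <- update_intensity_centers(img, u, cfg0)
  expect_equal(as.vector(v), c(0, 10))
  u5 <- matrix(0.5, 2, 4)
  expect_equal(as.vector(update_intensity_centers(img, u5, cfg0)),
               c(5, 5))

  # constant image is a fixed point for any feasible membership
  cfg1 <- smbft_config(k = 2, alpha = 1, beta = 1)
  imgc <- matrix(42, 4, 5)
  uc <- random_membership(2, 20, 31)
  expect_equal(as.vector(update_intensity_centers(imgc, uc, cfg1)),
               c(42, 42))

  # hand evaluation: center pixel 2 with 8 neighbors of 4, beta = 1,
  # N_R = 8 -> v = (2 + 32/8) / 2 = 3
  img3 <- matrix(4, 3, 3); img3[2, 2] <- 2
  uh <- rbind(as.numeric(seq_len(9) == 5), as.numeric(seq_len(9) != 5))
  vh <- update_intensity_centers(img3, uh, cfg1)
  expect_equal(vh[1, 1], 3)
})

test_that("degenerate clusters keep their previous centers with a warning", {
  img <- matrix(1:4, 2, 2)
  cfg <- smbft_config(k = 2, alpha = 1, beta = 0)
  u <- rbind(rep(1, 4), rep(0, 4))
  expect_warning(
    v <- update_intensity_centers(img, u, cfg, previous = matrix(c(9, 77), 2, 1)),
    "degenerate")
  expect_equal(v[2, 1], 77)
  expect_error(update_intensity_centers(img, u, cfg), "degenerate")
})

test_that("coordinate centers are membership-weighted centroids", {
  cfg <- smbft_config(k = 1, alpha = 1, beta = 0)
  # single pixel with full membership
  cen <- update_coordinate_centers(matrix(1, 1, 1), cfg,
                                   cbind(3, 7))
  expect_equal(c(cen$x, cen$y), c(3, 7))
  # uniform membership over a 2x2 block
  coords <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  cen2 <- update_coordinate_centers(matrix(0.5, 2, 4), cfg, coords)
  expect_equal(cen2$x, c(0.5, 0.5))
  expect_equal(cen2$y, c(0.5, 0.5))
  # p = 2 memberships whose squares weight rows {0, 4} as {3, 1} -> X = 1
  u <- matrix(sqrt(c(3, 1)), 1, 2)
  cen3 <- update_coordinate_centers(u, cfg, rbind(c(0, 0), c(4, 0)))
  expect_equal(cen3$x, 1)
})

test_that("with alpha = beta = 0 the updates reduce to classical FCM", {
  for (seed in 1:8) {
    set.seed(seed)
    img <- matrix(runif(6, 0, 255), 2, 3)
    cc <- sample(2:3, 1)
    p <- sample(c(2, 3), 1)
    cfg <- smbft_config(k = cc, alpha = 0, beta = 0, p = p)
    st <- list(v = matrix(runif(cc, 0, 255), cc, 1),
               x = runif(cc, 0, 1), y = runif(cc, 0, 2))
    D <- outer(st$v[, 1], as.vector(img), function(v, y) (y - v)^2)
    u <- update_membership(img, st, cfg)
    expect_equal(u, oracle_fcm_membership(D, p), tolerance = 1e-12)
    v <- update_intensity_centers(img, u, cfg)
    expect_equal(as.vector(v), oracle_fcm_centers(as.vector(img), u, p),
                 tolerance = 1e-12)
  }
})

test_that("run_smbft recovers a two-intensity split", {
  # 8x16: the grid yields exactly two seeds, one per half, and converged
  # labels match the ground truth exactly (up to label identity)
  img <- cbind(matrix(50, 8, 8), matrix(200, 8, 8))
  gt <- cbind(matrix(0L, 8, 8), matrix(1L, 8, 8))
  fit <- run_smbft(img, smbft_config(k = 2, alpha = 1, beta = 0))
  expect_equal(nrow(fit$state$v), 2)
  expect_true(all((fit$labels == fit$labels[1, 1]) == (gt == 0L)))

  # 16x16 with k = 2: the grid rule yields 4 seeds; every superpixel must
  # then lie entirely inside one ground-truth region (a refinement: UE = 0)
  img2 <- cbind(matrix(50, 16, 8), matrix(200, 16, 8))
  gt2 <- cbind(matrix(0L, 16, 8), matrix(1L, 16, 8))
  fit2 <- run_smbft(img2, smbft_config(k = 2, alpha = 1, beta = 0))
  expect_equal(undersegmentation_error(fit2$labels, gt2), 0)
  tab <- table(fit2$labels, gt2)
  expect_true(all(rowSums(tab > 0) == 1)) # no superpixel straddles regions
  expect_true(all(colSums(tab) == 128))   # both regions fully covered
})

test_that("the iteration is deterministic and monotone with unit column sums", {
  ph <- generate_phantom(phantom_spec(shape = c(24, 24), template = "brain",
                                      intensities = c(30, 130, 220),
                                      noise_pct = 4, rng_seed = 8))
  cfg <- smbft_config(k = 9, alpha = 2, beta = 1)
  f1 <- run_smbft(ph$image, cfg)
  f2 <- run_smbft(ph$image, cfg)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$trace$objective, f2$trace$objective)

  obj <- f1$trace$objective
  expect_true(all(diff(obj) <= 1e-8 * abs(obj[-length(obj)])))
  expect_equal(length(obj), f1$trace$iterations)
  expect_equal(colSums(f1$u), rep(1, 24 * 24), tolerance = 1e-9)
})

test_that("max_iter = 0 returns the nearest-seed assignment", {
  img <- cbind(matrix(10, 6, 6), matrix(240, 6, 6))
  cfg <- smbft_config(k = 4, alpha = 1, beta = 1, max_iter = 0)
  fit <- run_smbft(img, cfg)
  expect_equal(fit$trace$iterations, 0L)
  expect_false(fit$trace$converged)
  # every pixel carries the label of its closest seed under pixel_distance
  seeds <- fit$seeds
  for (pix in list(c(0, 0), c(5, 11), c(3, 6))) {
    d <- vapply(seq_len(nrow(seeds)), function(i) {
      pixel_distance(img[pix[1] + 1, pix[2] + 1], seeds$value[i],
                     pix, c(seeds$row[i], seeds$col[i]), cfg$alpha)
    }, numeric(1))
    expect_equal(fit$labels[pix[1] + 1, pix[2] + 1], which.min(d) - 1L)
  }
})

test_that("windowed assignment restricts competition but stays feasible", {
  ph <- generate_phantom(phantom_spec(shape = c(32, 32), template = "stripes",
                                      intensities = c(40, 220), rng_seed = 2))
  fit <- run_smbft(ph$image, smbft_config(k = 16, alpha = 2, beta = 1,
                                          windowed = TRUE))
  expect_equal(colSums(fit$u), rep(1, 32 * 32), tolerance = 1e-9)
  # a single windowed membership update zeroes out clusters whose centers
  # lie farther than twice the grid side from the pixel
  cfg <- smbft_config(k = 16, alpha = 2, beta = 1, windowed = TRUE)
  seeds <- grid_seeds(ph$image, 16)
  state <- list(v = matrix(seeds$value, ncol = 1),
                x = as.numeric(seeds$row), y = as.numeric(seeds$col))
  u <- update_membership(ph$image, state, cfg)
  s <- sqrt(32 * 32 / 16)
  for (k in c(1, 500, 1024)) {
    r0 <- (k - 1) %% 32; c0 <- (k - 1) %/% 32
    far <- abs(state$x - r0) > 2 * s | abs(state$y - c0) > 2 * s
    if (any(far)) expect_equal(max(u[far, k]), 0)
  }
  expect_equal(colSums(u), rep(1, 1024), tolerance = 1e-9)
})
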