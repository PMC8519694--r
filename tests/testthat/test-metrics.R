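test_that("undersegmentation error handles the canonical cases", {
  gt <- cbind(matrix(0L, 4, 2), matrix(1L, 4, 2))
  # perfect match
  expect_equal(undersegmentation_error(gt, gt), 0)
  # every pixel its own superpixel: no superpixel leaks anywhere
  expect_equal(undersegmentation_error(singleton_labels(4, 4), gt), 0)
  # one superpixel covering everything leaks half of each region
  expect_equal(undersegmentation_error(matrix(0L, 4, 4), gt), 1)
  expect_equal(oracle_ue(matrix(0L, 4, 4), gt), 1)
  expect_error(undersegmentation_error(matrix(0L, 3, 3), gt), "shape")
})

test_that("UE and BR match brute-force enumeration on random label maps", {
  for (seed in 1:20) {
    lab <- random_label_map(8, 8, 4, seed)
    gt <- random_label_map(8, 8, 3, seed + 1000)
    expect_equal(undersegmentation_error(lab, gt), oracle_ue(lab, gt))
    if (length(unique(as.vector(gt))) > 1) {
      for (eps in c(1, 2, 3.5)) {
        expect_equal(boundary_recall(lab, gt, eps), oracle_br(lab, gt, eps))
      }
    }
  }
})

test_that("boundary recall follows the strict epsilon rule", {
  gt <- cbind(matrix(0L, 16, 8), matrix(1L, 16, 8))
  # identical boundaries
  expect_equal(boundary_recall(gt, gt), 1)
  # superpixel boundary offset by one column still within eps = 2
  lab1 <- cbind(matrix(0L, 16, 9), matrix(1L, 16, 7))
  expect_equal(boundary_recall(lab1, gt, eps = 2), 1)
  # offset of five columns: compare to the exhaustive search
  lab5 <- cbind(matrix(0L, 16, 13), matrix(1L, 16, 3))
  expect_equal(boundary_recall(lab5, gt, eps = 2), oracle_br(lab5, gt, 2))
  expect_lt(boundary_recall(lab5, gt, eps = 2), 1)
  # strictness: boundary pixels exactly eps away do not count
  expect_equal(boundary_recall(lab1, gt, eps = 1), oracle_br(lab1, gt, 1))
  # single-region ground truth has no boundary
  expect_error(boundary_recall(gt, matrix(0L, 16, 16)), "undefined")
  expect_error(boundary_recall(gt, gt, eps = 0), "eps")
})

test_that("boundary recall is monotone non-decreasing in eps", {
  for (seed in 1:5) {
    lab <- random_label_map(10, 10, 5, seed)
    gt <- random_label_map(10, 10, 3, seed + 50)
    if (length(unique(as.vector(gt))) < 2) next
    brs <- vapply(c(0.5, 1, 1.5, 2, 3, 5), function(e)
      boundary_recall(lab, gt, e), numeric(1))
    expect_true(all(diff(brs) >= 0))
  }
})

test_that("average accuracy rate is the stated convex combination", {
  expect_equal(round(average_accuracy_rate(0.2942, 0.4879, 0.5), 4), 0.5968)
  expect_equal(round(average_accuracy_rate(0.3932, 0.4156, 0.5), 4), 0.5112)
  # perfect segmentation scores 1 for every weight
  for (mu in c(0.1, 0.5, 0.9)) {
    expect_equal(average_accuracy_rate(0, 1, mu), 1)
  }
  # linear in both arguments
  expect_equal(average_accuracy_rate(0.4, 0.6, 0.25),
               0.25 * 0.6 + 0.75 * 0.6)
  expect_error(average_accuracy_rate(0.1, 0.9, mu = 0), "mu")
  expect_error(average_accuracy_rate(0.1, 0.9, mu = 1), "mu")
})

test_that("singleton superpixels reach the analytic extreme on any truth", {
  for (template in c("stripes", "brain")) {
    ph <- generate_phantom(phantom_spec(shape = c(12, 14), template = template,
                                        rng_seed = 2))
    singles <- singleton_labels(12, 14)
    expect_equal(undersegmentation_error(singles, ph$gt), 0)
    expect_equal(boundary_recall(singles, ph$gt, eps = 2), 1)
    expect_equal(average_accuracy_rate(0, 1), 1)
  }
})

test_that("superpixel entropy distinguishes homogeneous regions", {
  img <- cbind(matrix(0, 4, 2), matrix(255, 4, 2))
  lab <- cbind(matrix(0L, 4, 2), matrix(1L, 4, 2))
  e <- superpixel_entropy(img, lab)
  # each superpixel holds a single intensity
  expect_equal(e$per_superpixel, c(0, 0))
  expect_equal(e$mean, 0)

  # two intensities in equal counts -> ln 2
  img2 <- matrix(c(0, 0, 255, 255), 2, 2)
  e2 <- superpixel_entropy(img2, matrix(0L, 2, 2))
  expect_equal(e2$mean, log(2))

  # literal variant on a uniform region of n pixels gives ln n
  img3 <- matrix(17, 3, 5)
  e3 <- superpixel_entropy(img3, matrix(0L, 3, 5), variant = "literal")
  expect_equal(e3$mean, log(15))

  expect_error(superpixel_entropy(array(1, c(2, 2, 3)), matrix(0L, 2, 2)),
               "grayscale")
})

test_that("evaluate_segmentation bundles the metrics and writes reports", {
  ph <- generate_phantom(phantom_spec(shape = c(16, 16), template = "stripes",
                                      intensities = c(10, 250), rng_seed = 6))
  rep0 <- evaluate_segmentation(ph$gt, ph$gt, image = ph$image)
  expect_equal(rep0$ue, 0)
  expect_equal(rep0$br, 1)
  expect_equal(rep0$aar, 1)
  expect_false(is.na(rep0$mean_entropy))

  kv <- file.path(tempdir(), "report.txt")
  write_metric_report(rep0, kv)
  lines <- readLines(kv)
  expect_true(any(grepl("^ue=0$", lines)))
  expect_true(any(grepl("^br=1$", lines)))

  cs <- file.path(tempdir(), "report.csv")
  write_metric_report(rep0, cs, format = "csv", image = "phantom", k = 2)
  write_metric_report(rep0, cs, format = "csv", image = "phantom", k = 4,
                      append = TRUE)
  df <- read.csv(cs)
  expect_equal(nrow(df), 2)
  expect_equal(df$k, c(2, 4))
  expect_equal(df$ue, c(0, 0))
})
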