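# Segmentation evaluation: undersegmentation error (UE), boundary recall
# (BR), their composite average accuracy rate (AAR), and per-superpixel
# intensity entropy for images without a ground truth.

.check_same_shape <- function(labels, gt) {
  if (!identical(dim(labels), dim(gt))) {
    stop("label map and ground truth must have the same shape", call. = FALSE)
  }
}

#' Undersegmentation error
#'
#' For every ground-truth region \eqn{R_i} and every superpixel \eqn{S_k}
#' that overlaps it (any nonzero overlap counts), the pixels of \eqn{S_k}
#' lying outside \eqn{R_i} are counted as leakage:
#' \deqn{UE = \frac{\sum_i \sum_{k : S_k \cap R_i \neq \emptyset}
#'   |S_k - R_i|}{\sum_i |R_i|}}{
#'   UE = sum_i sum_{k: S_k meets R_i} |S_k \\ R_i| / sum_i |R_i|}
#' A perfect match gives 0, as does the degenerate labeling in which every
#' pixel is its own superpixel. Because any nonzero overlap counts, values
#' can exceed those of UE variants that ignore small overlaps.
#'
#' @param labels Integer superpixel label matrix.
#' @param gt Integer ground-truth region matrix of the same shape.
#' @return Nonnegative scalar.
#' @export
undersegmentation_error <- function(labels, gt) {
  .check_same_shape(labels, gt)
  lab <- as.vector(labels); g <- as.vector(gt)
  n <- length(lab)
  tab <- table(lab, g)
  sizes <- rowSums(tab)
  overlaps <- rowSums(tab > 0)
  # sum over nonzero cells of (|S_k| - |S_k o R_i|) = sum_k m_k |S_k| - N
  (sum(sizes * overlaps) - n) / n
}

# pixels with at least one 4-neighbor carrying a different label
.boundary_mask <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  b <- matrix(FALSE, h, w)
  if (h > 1L) {
    d <- labels[-h, ] != labels[-1L, ]
    b[-h, ] <- b[-h, ] | d
    b[-1L, ] <- b[-1L, ] | d
  }
  if (w > 1L) {
    d <- labels[, -w] != labels[, -1L]
    b[, -w] <- b[, -w] | d
    b[, -1L] <- b[, -1L] | d
  }
  b
}

#' Boundary recall
#'
#' Fraction of ground-truth boundary pixels lying strictly within `eps`
#' (Euclidean pixel distance) of the nearest superpixel boundary pixel.
#' Boundary pixels are those with a 4-neighbor of different label; image
#' border pixels are not automatically boundary.
#'
#' @param labels Integer superpixel label matrix.
#' @param gt Integer ground-truth region matrix of the same shape; must
#'   contain more than one region (otherwise the metric is undefined and an
#'   error is raised).
#' @param eps Distance threshold in pixels (> 0); the conventional value
#'   is 2.
#' @return Scalar in \[0, 1\].
#' @export
boundary_recall <- function(labels, gt, eps = 2) {
  .check_same_shape(labels, gt)
  if (!is.finite(eps) || eps <= 0) stop("eps must be > 0", call. = FALSE)
  dR <- .boundary_mask(gt)
  if (!any(dR)) {
    stop("ground truth has no boundary pixels; boundary recall is undefined",
         call. = FALSE)
  }
  dS <- .boundary_mask(labels)
  # dilate dS by all integer offsets with squared distance < eps^2; pixel
  # coordinates are integers so this is an exact nearest-boundary test
  rad <- ceiling(eps)
  covered <- matrix(FALSE, nrow(labels), ncol(labels))
  for (dr in -rad:rad) for (dc in -rad:rad) {
    if (dr * dr + dc * dc >= eps * eps) next
    s <- .shift_pad(dS * 1, dr, dc)
    covered <- covered | (s$values > 0)
  }
  sum(covered & dR) / sum(dR)
}

#' Average accuracy rate
#'
#' The composite criterion \eqn{AAR = \mu(1 - UE) + (1 - \mu)\,BR}, which
#' weighs boundary leakage against boundary adherence; \eqn{\mu = 0.5}
#' weighs them equally.
#'
#' @param ue Undersegmentation error.
#' @param br Boundary recall.
#' @param mu Weight in the open interval (0, 1).
#' @return Scalar; equals 1 exactly when `ue = 0` and `br = 1`.
#' @export
#' @examples
#' average_accuracy_rate(0.2942, 0.4879) # 0.59685
average_accuracy_rate <- function(ue, br, mu = 0.5) {
  if (!is.finite(mu) || mu <= 0 || mu >= 1) {
    stop("mu must lie strictly between 0 and 1", call. = FALSE)
  }
  mu * (1 - ue) + (1 - mu) * br
}

#' Per-superpixel intensity entropy
#'
#' Measures how homogeneous each superpixel is on a grayscale image. The
#' default `"histogram"` variant computes the Shannon entropy
#' \eqn{-\sum_g p_g \ln p_g} of the superpixel's intensity histogram (256
#' equal-width bins spanning the image's value range), which is 0 for a
#' perfectly homogeneous region. The `"literal"` variant instead normalizes
#' the raw pixel values themselves, \eqn{p_j = x_j / \sum_j x_j}, and
#' returns \eqn{-\sum_j p_j \ln p_j}; note that for a uniform region of
#' \eqn{n} pixels this equals \eqn{\ln n} regardless of homogeneity, which
#' is why the histogram variant is the default.
#'
#' @param image Grayscale matrix (color input is an error).
#' @param labels Integer superpixel label matrix of the same shape.
#' @param variant `"histogram"` (default) or `"literal"`.
#' @return List with `mean` (unweighted mean over superpixels) and
#'   `per_superpixel` (entropy per label id, in id order).
#' @export
superpixel_entropy <- function(image, labels,
                               variant = c("histogram", "literal")) {
  variant <- match.arg(variant)
  if (.n_channels(image) != 1L) {
    stop("superpixel_entropy requires a grayscale image", call. = FALSE)
  }
  .check_same_shape(labels, image)
  .check_labels(labels)
  v <- as.vector(image)
  f <- factor(as.vector(labels), levels = sort(unique(as.vector(labels))))
  ent_one <- if (variant == "histogram") {
    lo <- min(v); hi <- max(v)
    bin <- if (hi > lo) pmin(floor((v - lo) / (hi - lo) * 256), 255) else
      rep(0L, length(v))
    function(idx) {
      p <- tabulate(bin[idx] + 1L, nbins = 256L)
      p <- p[p > 0] / length(idx)
      -sum(p * log(p))
    }
  } else {
    function(idx) {
      x <- v[idx]
      tot <- sum(x)
      if (tot == 0) return(0)
      p <- x[x > 0] / tot
      -sum(p * log(p))
    }
  }
  per <- vapply(split(seq_along(v), f), ent_one, numeric(1))
  list(mean = mean(per), per_superpixel = unname(per))
}

#' Evaluate a segmentation against a ground truth
#'
#' Convenience wrapper producing the full metric report: UE, BR, AAR and
#' (for grayscale images, when `image` is supplied) mean superpixel
#' entropy.
#'
#' @param labels Integer superpixel label matrix.
#' @param gt Integer ground-truth matrix, or `NULL` for entropy-only
#'   reports.
#' @param image Optional grayscale image for the entropy term.
#' @param eps Boundary-recall distance threshold.
#' @param mu AAR weight.
#' @param entropy_variant Passed to [superpixel_entropy()].
#' @return An object of class `metric_report`: list with `ue`, `br`,
#'   `aar`, `mean_entropy` (NA when not computed), `per_superpixel_entropy`
#'   and `n_superpixels`.
#' @export
evaluate_segmentation <- function(labels, gt = NULL, image = NULL, eps = 2,
                                  mu = 0.5,
                                  entropy_variant = c("histogram", "literal")) {
  ue <- br <- aar <- NA_real_
  if (!is.null(gt)) {
    ue <- undersegmentation_error(labels, gt)
    br <- boundary_recall(labels, gt, eps = eps)
    aar <- average_accuracy_rate(ue, br, mu = mu)
  }
  me <- NA_real_; per <- NULL
  if (!is.null(image) && .n_channels(image) == 1L) {
    e <- superpixel_entropy(image, labels, variant = match.arg(entropy_variant))
    me <- e$mean; per <- e$per_superpixel
  }
  structure(list(ue = ue, br = br, aar = aar, mean_entropy = me,
                 per_superpixel_entropy = per,
                 n_superpixels = length(unique(as.vector(labels)))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Segmentation metrics\n")
  cat(sprintf("  superpixels:  %d\n", x$n_superpixels))
  if (!is.na(x$ue)) cat(sprintf("  UE:           %.4f\n", x$ue))
  if (!is.na(x$br)) cat(sprintf("  BR:           %.4f\n", x$br))
  if (!is.na(x$aar)) cat(sprintf("  AAR:          %.4f\n", x$aar))
  if (!is.na(x$mean_entropy)) {
    cat(sprintf("  mean entropy: %.4f\n", x$mean_entropy))
  }
  invisible(x)
}

#' Write a metric report as key-value text or as a CSV row
#'
#' The key-value format writes one `key=value` line per scalar metric. The
#' CSV format writes (or appends) a single row with columns
#' `image,method,k,ue,br,aar,mean_entropy`, suited to collecting sweeps
#' over images, methods and superpixel counts.
#'
#' @param report A `metric_report` from [evaluate_segmentation()].
#' @param path Output file path.
#' @param format `"keyvalue"` or `"csv"`.
#' @param image,method,k Identifying fields for the CSV row.
#' @param append For CSV: append without header if the file exists.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path, format = c("keyvalue", "csv"),
                                image = "", method = "smbft", k = NA,
                                append = FALSE) {
  format <- match.arg(format)
  if (format == "keyvalue") {
    keys <- c(n_superpixels = report$n_superpixels, ue = report$ue,
              br = report$br, aar = report$aar,
              mean_entropy = report$mean_entropy)
    writeLines(sprintf("%s=%s", names(keys), vapply(
      keys, function(v) if (is.na(v)) "NA" else format(v, digits = 10),
      character(1))), path)
  } else {
    row <- data.frame(image = image, method = method, k = k, ue = report$ue,
                      br = report$br, aar = report$aar,
                      mean_entropy = report$mean_entropy)
    write_header <- !(append && file.exists(path))
    utils::write.table(row, path, sep = ",", row.names = FALSE,
                       col.names = write_header, append = !write_header,
                       qmethod = "double")
  }
  invisible(path)
}
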