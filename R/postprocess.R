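# Postprocessing: every superpixel must form one 4-connected region, and
# regions below a size threshold are absorbed by the adjacent region with
# the closest mean intensity.

#' Split disconnected superpixels into connected components
#'
#' Relabels the map so that every 4-connected component of every input
#' label becomes its own output label. Output ids are contiguous, 0-based,
#' in row-major discovery order. Idempotent.
#'
#' @param labels Integer matrix of superpixel ids.
#' @return Integer matrix of relabeled, connected superpixels.
#' @export
enforce_connectivity <- function(labels) {
  .check_labels(labels)
  h <- nrow(labels); w <- ncol(labels)
  out <- matrix(-1L, h, w)
  next_id <- 0L
  queue <- integer(h * w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (out[r, c] >= 0L) next
    lab <- labels[r, c]
    # BFS flood fill over same-label 4-neighbors
    out[r, c] <- next_id
    queue[1L] <- (c - 1L) * h + r
    head <- 1L; tail <- 1L
    while (head <= tail) {
      idx <- queue[head]; head <- head + 1L
      cr <- ((idx - 1L) %% h) + 1L
      cc <- ((idx - 1L) %/% h) + 1L
      if (cr > 1L && out[cr - 1L, cc] < 0L && labels[cr - 1L, cc] == lab) {
        out[cr - 1L, cc] <- next_id; tail <- tail + 1L; queue[tail] <- idx - 1L
      }
      if (cr < h && out[cr + 1L, cc] < 0L && labels[cr + 1L, cc] == lab) {
        out[cr + 1L, cc] <- next_id; tail <- tail + 1L; queue[tail] <- idx + 1L
      }
      if (cc > 1L && out[cr, cc - 1L] < 0L && labels[cr, cc - 1L] == lab) {
        out[cr, cc - 1L] <- next_id; tail <- tail + 1L; queue[tail] <- idx - h
      }
      if (cc < w && out[cr, cc + 1L] < 0L && labels[cr, cc + 1L] == lab) {
        out[cr, cc + 1L] <- next_id; tail <- tail + 1L; queue[tail] <- idx + h
      }
    }
    next_id <- next_id + 1L
  }
  out
}

#' Per-region statistics of a label map
#'
#' @param labels Integer matrix of 0-based, contiguous superpixel ids.
#' @param image Gray matrix or H x W x 3 array, same spatial size.
#' @return A list with `size` (pixel count per id), `mean` (region mean
#'   intensity, regions x channels) and `adjacency` (list of 4-adjacent
#'   region ids per region, 0-based).
#' @export
region_stats <- function(labels, image) {
  nc <- .check_image(image)
  .check_labels(labels)
  n_lab <- max(labels) + 1L
  f <- factor(as.vector(labels), levels = 0:(n_lab - 1L))
  size <- as.integer(table(f))
  mean_i <- matrix(NA_real_, n_lab, nc)
  for (ch in seq_len(nc)) {
    mean_i[, ch] <- as.vector(tapply(as.vector(.get_channel(image, ch)), f, mean))
  }
  h <- nrow(labels); w <- ncol(labels)
  pairs <- rbind(
    cbind(as.vector(labels[-h, ]), as.vector(labels[-1L, ])),
    cbind(as.vector(labels[, -w]), as.vector(labels[, -1L]))
  )
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  pairs <- unique(rbind(pairs, pairs[, 2:1, drop = FALSE]))
  adjacency <- vector("list", n_lab)
  for (i in seq_len(n_lab)) adjacency[[i]] <- integer(0)
  if (nrow(pairs) > 0L) {
    sp <- split(pairs[, 2L], pairs[, 1L])
    for (nm in names(sp)) {
      adjacency[[as.integer(nm) + 1L]] <- sort(unique(sp[[nm]]))
    }
  }
  list(size = size, mean = mean_i, adjacency = adjacency)
}

#' Merge undersized superpixels into their most similar neighbor
#'
#' Superpixels smaller than `min_size` are treated as isolated point sets
#' and absorbed: each is merged into the 4-adjacent superpixel whose mean
#' intensity (Euclidean over channels) is closest to its own. Small regions
#' are processed in increasing size order (ties by lowest id) and region
#' means are frozen at the start of a pass, which makes the result
#' independent of incidental ordering; passes repeat until no region is
#' below the threshold (unless the whole image is smaller). Output ids are
#' contiguous and 0-based.
#'
#' @param labels Integer label matrix; should already be
#'   connectivity-enforced (see [enforce_connectivity()]).
#' @param image Gray matrix or H x W x 3 array, same spatial size.
#' @param min_size Minimum region size in pixels.
#' @return Integer matrix of merged, relabeled superpixels.
#' @export
merge_small_superpixels <- function(labels, image, min_size) {
  .check_labels(labels)
  .check_image(image)
  if (min_size > length(labels)) {
    stop("min_size exceeds the number of image pixels", call. = FALSE)
  }
  repeat {
    st <- region_stats(labels, image)
    n_lab <- length(st$size)
    small <- which(st$size < min_size) # 1-based region indices
    if (length(small) == 0L || n_lab == 1L) break
    ord <- small[order(st$size[small], small)]
    parent <- seq_len(n_lab)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (s in ord) {
      rs <- find(s)
      nbrs <- unique(vapply(st$adjacency[[s]] + 1L, find, integer(1)))
      nbrs <- sort(setdiff(nbrs, rs)) # sorted so ties go to the lowest id
      if (length(nbrs) == 0L) next # region spans everything reachable
      d <- sqrt(colSums((t(st$mean[nbrs, , drop = FALSE]) - st$mean[s, ])^2))
      target <- nbrs[which.min(d)] # which.min: lowest id on ties
      parent[rs] <- target
    }
    roots <- vapply(seq_len(n_lab), find, integer(1))
    new_lab <- matrix(roots[labels + 1L] - 1L, nrow(labels), ncol(labels))
    if (all(new_lab == labels)) break # no merge possible; avoid spinning
    labels <- .relabel_rowmajor(new_lab)
  }
  .relabel_rowmajor(labels)
}

# contiguous 0-based ids in row-major first-appearance order
.relabel_rowmajor <- function(labels) {
  v <- as.vector(t(labels)) # row-major order
  ids <- unique(v)
  lut <- integer(max(ids) + 1L)
  lut[ids + 1L] <- seq_along(ids) - 1L
  matrix(lut[as.vector(labels) + 1L], nrow(labels), ncol(labels))
}

#' Full postprocessing chain
#'
#' [enforce_connectivity()] followed by [merge_small_superpixels()] with
#' the configured (or automatic `floor(S^2/4)`) size threshold, where
#' \eqn{S = \sqrt{MN/k}} is the initialization grid side.
#'
#' @param labels Integer label matrix (e.g. `fit$labels` from
#'   [run_smbft()]).
#' @param image The segmented image (used for region means).
#' @param config The [smbft_config()] used for the segmentation, or a bare
#'   `min_size` count.
#' @return Integer matrix of contiguous, 0-based, 4-connected superpixels.
#' @export
postprocess_labels <- function(labels, image, config) {
  if (is.numeric(config)) {
    min_size <- config
  } else if (!is.null(config$min_size)) {
    min_size <- config$min_size
  } else {
    min_size <- floor(prod(dim(image)[1:2]) / config$k / 4)
  }
  merge_small_superpixels(enforce_connectivity(labels), image, min_size)
}
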