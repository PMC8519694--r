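# Raster input/output. Images are exchanged on a 0-255 intensity scale:
# PNG and TIFF files (which the readers deliver normalized) are rescaled by
# 255; PGM files keep their native values. Label maps round-trip losslessly
# through 16-bit single-channel TIFF or through a (row, col, label) CSV.

#' Read a raster image
#'
#' Supports PNG, TIFF and PGM (both ASCII `P2` and binary `P5`). Returns a
#' grayscale matrix or an H x W x 3 sRGB array on the 0-255 scale (PGM
#' values are returned as stored; 16-bit PNG/TIFF are mapped onto 0-255).
#' An alpha channel, if present, is dropped with a warning.
#'
#' @param path Path to the image file.
#' @return Numeric matrix or H x W x 3 array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: no such file: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path) * 255,
    pgm = .read_pgm(path),
    stop("unsupported image format '", ext, "' for ", path,
         " (PNG, TIFF or PGM expected)", call. = FALSE)
  )
  d <- dim(raw)
  if (length(d) == 3L) {
    if (d[3L] == 2L) {
      warning("dropping alpha channel of ", path, call. = FALSE)
      raw <- raw[, , 1L]
    } else if (d[3L] == 4L) {
      warning("dropping alpha channel of ", path, call. = FALSE)
      raw <- raw[, , 1:3]
    } else if (d[3L] == 1L) {
      raw <- raw[, , 1L]
    }
  }
  raw
}

#' Write a raster image
#'
#' Writes a grayscale matrix or H x W x 3 array (0-255 scale) as 8-bit
#' PNG, TIFF or ASCII PGM (grayscale only), chosen by the file extension.
#'
#' @param image Numeric matrix or H x W x 3 array on the 0-255 scale.
#' @param path Output path ending in `.png`, `.tif(f)` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  clamped <- pmin(pmax(image, 0), 255) / 255
  switch(ext,
    png = png::writePNG(clamped, path),
    tif = ,
    tiff = tiff::writeTIFF(clamped, path, bits.per.sample = 8L),
    pgm = .write_pgm(image, path),
    stop("unsupported image format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) {
    stop("not a PGM file (P2/P5): ", path, call. = FALSE)
  }
  # header tokens: width, height, maxval; '#' comments run to end of line
  tokens <- integer(0)
  buf <- character(0)
  in_comment <- FALSE
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PGM header", call. = FALSE)
    if (in_comment) {
      if (ch == "\n") in_comment <- FALSE
      next
    }
    if (ch == "#") { in_comment <- TRUE; next }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0L) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1L]; h <- tokens[2L]; maxval <- tokens[3L]
  n <- w * h
  vals <- if (magic == "P5") {
    if (maxval < 256L) {
      as.integer(readBin(con, "raw", n))
    } else {
      readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
    }
  } else {
    txt <- readChar(con, file.info(path)$size, useBytes = TRUE)
    as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1L]])[seq_len(n)]
  }
  matrix(vals, h, w, byrow = TRUE) # PGM stores rows first
}

.write_pgm <- function(image, path) {
  if (length(dim(image)) != 2L) {
    stop("PGM output supports grayscale only", call. = FALSE)
  }
  vals <- round(pmin(pmax(image, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), "255"), con)
  utils::write.table(vals, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write or read a label map losslessly
#'
#' Label maps are stored as 16-bit single-channel TIFF, which round-trips
#' ids 0-65535 exactly; maps with more labels must use the CSV form
#' ([write_labels_csv()]).
#'
#' @param labels Integer matrix of 0-based superpixel ids.
#' @param path Output/input path (`.tif`/`.tiff`).
#' @return `write_labels`: `path`, invisibly. `read_labels`: the integer
#'   label matrix.
#' @export
write_labels <- function(labels, path) {
  .check_labels(labels)
  if (max(labels) > 65535L) {
    stop("more than 65536 labels; use write_labels_csv() instead",
         call. = FALSE)
  }
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read labels: no such file: ", path, call. = FALSE)
  }
  m <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Export a label map as a (row, col, label) CSV
#'
#' Coordinates are 0-based, rows in row-major order; [read_labels_csv()]
#' is the exact inverse.
#'
#' @param labels Integer matrix of 0-based superpixel ids.
#' @param path CSV path.
#' @return `write_labels_csv`: `path`, invisibly. `read_labels_csv`: the
#'   integer label matrix.
#' @export
write_labels_csv <- function(labels, path) {
  .check_labels(labels)
  h <- nrow(labels); w <- ncol(labels)
  df <- data.frame(row = rep(seq_len(h) - 1L, each = w),
                   col = rep(seq_len(w) - 1L, times = h),
                   label = as.integer(t(labels)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path)
  h <- max(df$row) + 1L; w <- max(df$col) + 1L
  m <- matrix(NA_integer_, h, w)
  m[cbind(df$row + 1L, df$col + 1L)] <- as.integer(df$label)
  if (anyNA(m)) stop("label CSV does not cover the image", call. = FALSE)
  m
}

#' Overlay superpixel boundaries on an image
#'
#' Marks every boundary pixel (4-neighbor label change) in the given color
#' and optionally writes the result as an 8-bit PNG/TIFF.
#'
#' @param image Gray matrix or H x W x 3 array on the 0-255 scale.
#' @param labels Integer label matrix of the same spatial size.
#' @param path Optional output path; `NULL` returns the array only.
#' @param color Length-3 sRGB boundary color, default yellow.
#' @return H x W x 3 array with boundaries marked, invisibly if written.
#' @export
boundary_overlay <- function(image, labels, path = NULL,
                             color = c(255, 255, 0)) {
  nc <- .n_channels(image)
  b <- .boundary_mask(labels)
  out <- if (nc == 1L) {
    array(rep(as.vector(image), 3L), c(dim(image), 3L))
  } else {
    image
  }
  for (ch in 1:3) {
    m <- out[, , ch]
    m[b] <- color[ch]
    out[, , ch] <- m
  }
  if (!is.null(path)) {
    write_image(out, path)
    return(invisible(out))
  }
  out
}
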