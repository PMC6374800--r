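# Radiograph container and plain-text image I/O.
#
# A radiograph is a base R numeric matrix [row, col] with intensities in
# [0, 1]. File I/O supports netpbm PGM (ASCII P2 and binary P5, 8- or 16-bit),
# the one grayscale raster format that needs no external decoder, plus
# headerless CSV matrices.

#' Validate a radiograph
#'
#' Checks the radiograph invariants: a numeric matrix with all intensities
#' finite and in \[0, 1\], and at least 32 x 32 pixels.
#'
#' @param img numeric matrix.
#' @param what label used in error messages.
#' @return the validated matrix, invisibly usable downstream.
#' @export
as_radiograph <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("%s: a radiograph must be a numeric matrix", what))
  if (nrow(img) < 32L || ncol(img) < 32L)
    stop(sprintf("%s: radiograph too small (%dx%d), need at least 32x32",
                 what, nrow(img), ncol(img)))
  if (!all(is.finite(img)))
    stop(sprintf("%s: radiograph contains non-finite intensities", what))
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 1)
    stop(sprintf("%s: intensities must lie in [0, 1] (got [%g, %g])",
                 what, rng[1], rng[2]))
  img
}

#' Read a PGM image as a radiograph
#'
#' Reads ASCII (P2) or binary (P5) netpbm grayscale images with a maximum
#' value up to 65535 and scales intensities to \[0, 1\] by the declared
#' maximum representable value (255 for 8-bit, 65535 for 16-bit).
#'
#' @param path file path.
#' @return numeric matrix in \[0, 1\].
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || !nzchar(ch)) break
      if (ch == "#") {  # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || !nzchar(ch) || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) break else next
      }
      tok <- paste0(tok, ch)
    }
    tok
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("read_pgm: not a P2/P5 PGM file: ", path)
  n <- as.integer(read_token())
  m <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(n) || is.na(m) || is.na(maxval) || maxval <= 0L)
    stop("read_pgm: malformed header in ", path)
  scale <- if (maxval <= 255L) 255 else 65535
  npix <- as.numeric(m) * n
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = npix, quiet = TRUE)
  } else {
    bytes <- if (maxval <= 255L) 1L else 2L
    vals <- readBin(con, "integer", n = npix, size = bytes, signed = FALSE,
                    endian = "big")
  }
  if (length(vals) != npix) stop("read_pgm: truncated pixel data in ", path)
  matrix(vals / scale, nrow = m, ncol = n, byrow = TRUE)
}

#' Write a radiograph (or any \[0,1\] matrix) as ASCII PGM
#'
#' @param img numeric matrix in \[0, 1\].
#' @param path output path.
#' @param maxval 255 (8-bit) or 65535 (16-bit).
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  stopifnot(maxval %in% c(255L, 65535L))
  v <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a radiograph from PGM or CSV
#'
#' CSV files are headerless numeric matrices; values greater than 1 are
#' assumed to be 8-bit (max 255) or 16-bit (max 65535) integers and rescaled.
#'
#' @param path file path ending in .pgm or .csv.
#' @return validated radiograph matrix.
#' @export
read_radiograph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "pgm") {
    read_pgm(path)
  } else if (ext %in% c("csv", "txt")) {
    x <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(x) <- NULL
    mx <- max(x)
    if (mx > 1) x <- x / (if (mx <= 255) 255 else 65535)
    x
  } else stop("read_radiograph: unsupported extension: ", ext)
  as_radiograph(img, what = path)
}

#' Serialize segmentation contours to JSON
#'
#' Writes `{"bone1": [[r, c], ...], "bone2": [[r, c], ...]}` in
#' original-image coordinates.
#'
#' @param contours a `ur_contours` object from [assemble_contours()] or
#'   [segment_image()].
#' @param path output JSON path.
#' @export
write_contours <- function(contours, path) {
  jsonlite::write_json(
    list(bone1 = unname(round(contours$bone1, 3)),
         bone2 = unname(round(contours$bone2, 3))),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(p) { p <- as.matrix(p); colnames(p) <- c("row", "col"); p })
}

#' Serialize a seed set to JSON
#'
#' @param seed_set object from [detect_seed_points()].
#' @param path output JSON path.
#' @export
write_seed_set <- function(seed_set, path) {
  jsonlite::write_json(
    list(x0 = seed_set$x0, p_max = seed_set$p_max,
         probe_col = seed_set$probe_col,
         seeds = unname(seed_set$seeds)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save a preprocessed image to a directory
#'
#' Writes the standardized raster as 16-bit PGM, the forearm mask as PGM, and
#' the geometric transform record as JSON
#' `{rotation_deg, crop_box: [r0, c0, r1, c1], ratio, inverted}`
#' (1-based inclusive crop box).
#'
#' @param pre `ur_preprocessed` object.
#' @param dir output directory (created if missing).
#' @export
write_preprocessed <- function(pre, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pgm(pre$pixels, file.path(dir, "standardized.pgm"), maxval = 65535L)
  write_pgm(pre$mask * 1, file.path(dir, "forearm_mask.pgm"))
  tf <- pre$transform
  jsonlite::write_json(
    list(rotation_deg = tf$rot, crop_box = tf$crop, ratio = tf$ratio,
         inverted = isTRUE(pre$provenance$inverted)),
    file.path(dir, "transform.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
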