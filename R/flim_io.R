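#' Rectangular region of interest
#'
#' Constructs a rectangle in the pixel coordinate convention used throughout
#' the package: 0-based, half-open intervals \code{[x0, x1) x [y0, y1)}, with
#' \code{x} indexing columns, \code{y} indexing rows, and the origin at the
#' top-left pixel. A rectangle of width \code{x1 - x0} and height
#' \code{y1 - y0} therefore covers pixels \code{x0 .. x1-1} horizontally.
#'
#' @param x0,y0 Integer coordinates of the top-left corner (inclusive).
#' @param x1,y1 Integer coordinates of the bottom-right corner (exclusive).
#' @return An object of class \code{"roi_rect"}.
#' @examples
#' r <- roi_rect(1, 1, 3, 3) # central 2x2 block of a 4x4 image
#' @export
roi_rect <- function(x0, y0, x1, y1) {
  vals <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (any(!is.finite(vals)) || any(vals != round(vals)))
    stop("roi_rect coordinates must be finite integers")
  if (x1 <= x0 || y1 <= y0)
    stop("roi_rect requires x1 > x0 and y1 > y0 (half-open convention)")
  structure(as.list(as.integer(vals)), names = names(vals), class = "roi_rect")
}

#' @export
print.roi_rect <- function(x, ...) {
  cat(sprintf("<roi_rect [%d,%d) x [%d,%d), %d x %d px>\n",
              x$x0, x$x1, x$y0, x$y1, x$x1 - x$x0, x$y1 - x$y0))
  invisible(x)
}

roi_width  <- function(r) r$x1 - r$x0
roi_height <- function(r) r$y1 - r$y0

assert_lifetime_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("lifetime matrix must be a numeric matrix")
  if (nrow(m) < 1L || ncol(m) < 1L)
    stop("lifetime matrix must have at least one row and column")
  v <- m[is.finite(m)]
  if (any(v < 0))
    stop("lifetime values must be nonnegative (picoseconds)")
  invisible(m)
}

#' Read a per-pixel fluorescence lifetime matrix
#'
#' Lifetime matrices hold one mean fluorescence lifetime (picoseconds) per
#' pixel. Two plain formats are supported: tab-separated text (lossless,
#' full decimal precision) and single-channel 32-bit floating point TIFF.
#' TIFF files store lifetimes in nanoseconds (value = ps / 1000) because
#' 32-bit float TIFF samples are only portable inside [0, 1]; the reader
#' rescales back to picoseconds. Missing pixels may be encoded as NaN in the
#' TSV format.
#'
#' @param path File to read.
#' @param format \code{"tsv"}, \code{"tiff"} or \code{"auto"} (by extension).
#' @return A numeric matrix of lifetimes in picoseconds.
#' @seealso [write_lifetime_matrix()], [extract_roi()]
#' @export
read_lifetime_matrix <- function(path, format = c("auto", "tsv", "tiff")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_matrix_format(path)
  if (!file.exists(path)) stop("no such file: ", path)
  m <- switch(format,
    tsv  = read_matrix_tsv(path),
    tiff = {
      img <- tiff::readTIFF(path)
      if (length(dim(img)) != 2L)
        stop("expected a single-channel TIFF: ", path)
      img * 1000
    }
  )
  assert_lifetime_matrix(m)
}

#' Write a per-pixel fluorescence lifetime matrix
#'
#' @param m Numeric matrix of lifetimes in picoseconds.
#' @param path Output file.
#' @param format \code{"tsv"}, \code{"tiff"} or \code{"auto"} (by extension).
#'   TSV round-trips bit-exactly; TIFF stores nanoseconds as 32-bit floats
#'   and requires all values to lie below 1000 ps.
#' @return \code{path}, invisibly.
#' @export
write_lifetime_matrix <- function(m, path, format = c("auto", "tsv", "tiff")) {
  assert_lifetime_matrix(m)
  format <- match.arg(format)
  if (format == "auto") format <- guess_matrix_format(path)
  if (format == "tsv") {
    lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(lines, path)
  } else {
    if (anyNA(m)) stop("TIFF output does not support NaN pixels; use tsv")
    if (max(m) >= 1000)
      stop("TIFF output stores nanoseconds in [0,1); lifetimes >= 1000 ps need the tsv format")
    tiff::writeTIFF(m / 1000, path, bits.per.sample = 32L, compression = "none")
  }
  invisible(path)
}

guess_matrix_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff"
  else if (ext %in% c("tsv", "txt")) "tsv"
  else stop("cannot guess matrix format from extension: ", path)
}

read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty matrix file: ", path)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  len <- lengths(rows)
  if (length(unique(len)) != 1L)
    stop("ragged rows in matrix file: ", path)
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  bad <- is.na(vals) & unlist(rows) != "NaN" & !grepl("^[nN][aA][nN]$", unlist(rows))
  if (any(bad))
    stop("non-numeric cell in matrix file: ", path,
         " (first offending token: '", unlist(rows)[which(bad)[1L]], "')")
  matrix(vals, nrow = length(rows), ncol = len[1L], byrow = TRUE)
}

#' Extract a rectangular region of interest
#'
#' Returns a copy of the pixels covered by \code{r} under the package's
#' 0-based, half-open coordinate convention (see [roi_rect()]). All feature
#' computations operate on such ROI matrices, which by contract must lie
#' strictly inside the cell footprint and contain no NaN pixels.
#'
#' @param m Lifetime matrix.
#' @param r An [roi_rect()].
#' @return A \code{(y1-y0) x (x1-x0)} numeric matrix (a copy, not a view).
#' @export
extract_roi <- function(m, r) {
  assert_lifetime_matrix(m)
  if (!inherits(r, "roi_rect")) stop("r must be an roi_rect")
  if (r$x0 < 0L || r$y0 < 0L || r$x1 > ncol(m) || r$y1 > nrow(m))
    stop(sprintf("ROI [%d,%d)x[%d,%d) exceeds matrix bounds %d x %d",
                 r$x0, r$x1, r$y0, r$y1, ncol(m), nrow(m)))
  m[(r$y0 + 1L):r$y1, (r$x0 + 1L):r$x1, drop = FALSE]
}

manifest_columns <- c("cell_id", "patient_id", "group", "subtype",
                      "shape_class", "roi_x0", "roi_y0", "roi_x1", "roi_y1",
                      "path")

#' Read or write a cell manifest
#'
#' The manifest is a tab-separated table with one row per cell and the
#' mandatory header columns \code{cell_id, patient_id, group, subtype,
#' shape_class, roi_x0, roi_y0, roi_x1, roi_y1, path}. Unknown extra columns
#' are preserved on round-trip.
#'
#' @param path Manifest file.
#' @return A data frame with one row per cell.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing))
    stop("manifest missing mandatory columns: ", paste(missing, collapse = ", "))
  for (col in c("roi_x0", "roi_y0", "roi_x1", "roi_y1"))
    df[[col]] <- as.integer(df[[col]])
  df
}

#' @param records Data frame of cell records (see [read_manifest()]).
#' @rdname read_manifest
#' @export
write_manifest <- function(records, path) {
  missing <- setdiff(manifest_columns, names(records))
  if (length(missing))
    stop("manifest missing mandatory columns: ", paste(missing, collapse = ", "))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

manifest_roi <- function(record) {
  roi_rect(record$roi_x0, record$roi_y0, record$roi_x1, record$roi_y1)
}
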