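#' Read a strip image from disk
#'
#' Reads a PNG or TIFF file into an 8-bit RGB integer array (rows x columns
#' x 3, values 0--255). Grayscale files are promoted to three identical
#' channels with a message; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An integer array of dimension `c(height, width, 3)`.
#' @export
#' @examples
#' img <- render_strip(strip_spec(seed = 1))$image
#' f <- tempfile(fileext = ".png")
#' write_image(img, f)
#' identical(read_image(f), img)
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    ts_error("`path` must be a single file path", "thalscreen_io_error")
  }
  if (!file.exists(path)) {
    ts_error(sprintf("image file does not exist: '%s'", path),
             "thalscreen_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    ts_error(sprintf("unsupported image format '.%s' for '%s' (PNG/TIFF)",
                     ext, path), "thalscreen_io_error")
  )
  if (length(dim(raw)) == 2L) {
    message("promoting grayscale image to 3 channels: ", path)
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  } else if (dim(raw)[3] > 3L) {
    raw <- raw[, , 1:3, drop = FALSE]
  }
  img <- array(as.integer(round(raw * 255)), dim = dim(raw))
  attr(img, "source_path") <- path
  img
}

#' Write a strip or lane image to disk
#'
#' Writes an 8-bit RGB array as PNG or TIFF. The PNG round-trip through
#' [read_image()] is lossless.
#'
#' @param img An H x W x 3 array with values in 0--255.
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot_rgb(img)
  ext <- tolower(tools::file_ext(path))
  norm <- array(clip255(img) / 255, dim = dim(img))
  switch(ext,
    png  = png::writePNG(norm, target = path),
    tif  = ,
    tiff = tiff::writeTIFF(norm, where = path, bits.per.sample = 8L),
    ts_error(sprintf("unsupported image format '.%s'", ext),
             "thalscreen_io_error")
  )
  invisible(path)
}

#' Construct a lane bounding box
#'
#' Boxes are 0-based and half-open: rows `[row0, row1)`, columns
#' `[col0, col1)`, with rows along the migration axis (application point at
#' row 0).
#'
#' @param row0,row1,col0,col1 Integer box edges, `row0 < row1`,
#'   `col0 < col1`.
#' @return A `lane_box` object.
#' @export
lane_box <- function(row0, row1, col0, col1) {
  b <- list(row0 = as.integer(row0), row1 = as.integer(row1),
            col0 = as.integer(col0), col1 = as.integer(col1))
  if (b$row0 < 0L || b$col0 < 0L || b$row0 >= b$row1 || b$col0 >= b$col1) {
    ts_error("invalid lane box: need 0 <= row0 < row1 and 0 <= col0 < col1",
             "thalscreen_geometry_error")
  }
  structure(b, class = "lane_box")
}

#' @export
print.lane_box <- function(x, ...) {
  cat(sprintf("<lane_box rows [%d,%d) cols [%d,%d)>\n",
              x$row0, x$row1, x$col0, x$col1))
  invisible(x)
}
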