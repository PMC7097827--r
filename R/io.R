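#' Read a cervicogram image
#'
#' Reads an 8-bit RGB PNG/JPEG into the package's native representation:
#' a numeric array `height x width x 3` with values in 0..255, channel order
#' R, G, B, 1-based (row, col) indexing, origin top-left.
#'
#' @param path image file path.
#' @return numeric array in 0..255.
#' @export
read_cervicogram <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2) {
    arr <- array(t(img) * 255, dim = c(d[2], d[1], 3))
  } else {
    arr <- aperm(img[, , 1:3, drop = FALSE], c(2, 1, 3)) * 255
  }
  arr <- round(arr)
  dimnames(arr) <- NULL
  arr
}

#' Write a cervicogram image as PNG
#'
#' @param img numeric array `H x W x 3` in 0..255 (or an `H x W` matrix,
#'   written as grayscale).
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
write_cervicogram <- function(img, path) {
  if (length(dim(img)) == 2) {
    e <- EBImage::Image(t(img) / 255)
  } else {
    e <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
  }
  EBImage::writeImage(e, path, type = "png")
  invisible(path)
}

#' Write a binary mask as a 1-bit-content PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path, type = "png")
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path PNG path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  m <- EBImage::readImage(path)
  if (length(dim(m)) > 2) m <- m[, , 1]
  t(m > 0.5)
}

#' Write a fiducial set to JSON
#'
#' Format: `{"center":[x,y],"os":[[x1,y1],[x2,y2]]}` with pixel coordinates
#' (x = column, y = row, 1-based).
#'
#' @param fid a [fiducial_set()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(fid, path) {
  jsonlite::write_json(
    list(center = fid$center, os = list(fid$os_a, fid$os_b)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a fiducial set from JSON
#' @param path JSON path as written by [write_fiducials()].
#' @return a [fiducial_set()].
#' @export
read_fiducials <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fiducial_set(center = as.numeric(x$center),
               os_a = as.numeric(x$os[1, ]),
               os_b = as.numeric(x$os[2, ]))
}
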