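#' Detect saturated specular reflections
#'
#' Specular highlights on the moist ectocervix saturate the sensor; they are
#' detected by thresholding the per-pixel maximum over the R, G, B channels
#' at a fraction of the 8-bit range. The default 0.6 flags pixels with
#' max-channel intensity >= 0.6 * 255 = 153.
#'
#' @param img RGB array in 0..255 (see [read_cervicogram()]).
#' @param threshold_fraction fraction of 255 in (0, 1].
#' @return logical matrix, `TRUE` at specular pixels.
#' @export
detect_specular <- function(img, threshold_fraction = 0.6) {
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1 ||
      threshold_fraction <= 0 || threshold_fraction > 1)
    stop("threshold_fraction must lie in (0, 1]")
  gray <- pmax(img[, , 1], img[, , 2], img[, , 3])
  gray >= threshold_fraction * 255
}

#' Interpolate away masked specular pixels
#'
#' Replaces pixels under `sr_mask` with a distance-weighted (1/d) average of
#' unmasked pixels within `radius`, applied per channel; pixels whose whole
#' neighborhood is masked are filled in later passes from already-filled
#' values, so any mask with at least one unmasked pixel converges. Pixels
#' outside the mask are returned unchanged.
#'
#' @param img RGB array in 0..255.
#' @param sr_mask logical matrix matching the image plane.
#' @param radius neighborhood radius in pixels.
#' @return RGB array with the masked region filled.
#' @export
inpaint_specular <- function(img, sr_mask, radius = 5) {
  d <- dim(img)
  if (!all(dim(sr_mask) == d[1:2]))
    stop("sr_mask shape does not match the image")
  if (all(sr_mask)) stop("mask covers the whole image; nothing to interpolate from")
  if (!any(sr_mask)) return(img)

  # inverse-distance kernel over the disk of given radius (center excluded)
  r <- ceiling(radius)
  off <- seq(-r, r)
  dist <- sqrt(outer(off^2, off^2, `+`))
  kern <- ifelse(dist > 0 & dist <= radius, 1 / dist, 0)

  valid <- !sr_mask
  out <- img
  todo <- sr_mask
  while (any(todo)) {
    w <- ebi_conv(valid * 1, kern)
    newly <- todo & w > 1e-8
    if (!any(newly)) stop("inpainting failed to progress")  # unreachable
    for (ch in 1:3) {
      num <- ebi_conv(out[, , ch] * valid, kern)
      plane <- out[, , ch]
      plane[newly] <- num[newly] / w[newly]
      out[, , ch] <- plane
    }
    valid <- valid | newly
    todo <- todo & !newly
  }
  out
}

# 2D convolution via EBImage (FFT-based, zero-ish border handling is
# acceptable because weights are renormalized by the valid-pixel kernel sum)
ebi_conv <- function(mat, kern) {
  as.matrix(EBImage::filter2(EBImage::Image(mat), kern, boundary = 0))
}

#' Segment the ectocervix by red-channel bit-plane slicing
#'
#' The ectocervix carries the highest red-channel values in a cervicogram.
#' The 8-bit red channel is sliced into bit planes 0 (LSB) .. 7 (MSB); the
#' two most significant planes capture the major cervix region. The raw mask
#' keeps pixels whose red value has any (mode `"or"`, red >= 64) or all
#' (mode `"and"`, red >= 192) of the requested bits set; morphological
#' cleanup (closing, largest connected component, hole filling) then removes
#' bit-plane speckle and background clutter such as the vaginal wall.
#'
#' @param img RGB array in 0..255.
#' @param planes bit-plane indices in 0..7 (0 = LSB); default `c(6, 7)`.
#' @param combine `"or"` (permissive union, default) or `"and"`.
#' @param clean apply morphological cleanup (default `TRUE`); `FALSE` returns
#'   the raw bit-plane mask.
#' @param brush_size diameter in pixels of the closing structuring element.
#' @return logical matrix, `TRUE` on the segmented cervix.
#' @export
bitplane_roi <- function(img, planes = c(6, 7), combine = c("or", "and"),
                         clean = TRUE, brush_size = 5) {
  combine <- match.arg(combine)
  if (!all(planes %in% 0:7)) stop("planes must lie in 0..7")
  red <- round(img[, , 1])
  bits <- lapply(planes, function(p) bitwAnd(red, 2^p) > 0)
  raw <- Reduce(if (combine == "or") `|` else `&`, bits)
  dim(raw) <- dim(red)
  if (!clean || !any(raw)) return(raw)

  m <- EBImage::Image(raw * 1)
  m <- EBImage::closing(m, EBImage::makeBrush(brush_size, shape = "disc"))
  lab <- EBImage::bwlabel(m)
  tab <- tabulate(as.integer(lab))
  if (!length(tab)) return(matrix(FALSE, nrow(raw), ncol(raw)))
  m <- EBImage::Image((as.matrix(lab) == which.max(tab)) * 1)
  m <- EBImage::fillHull(m)
  as.matrix(m) > 0.5
}

#' Intersect pre and post ROI masks
#'
#' The pre- and post-acetic images differ slightly in framing; the combined
#' region of interest keeps only pixels segmented as cervix in both.
#'
#' @param mask_pre,mask_post logical matrices of equal shape.
#' @return logical matrix, the elementwise AND.
#' @export
combine_roi <- function(mask_pre, mask_post) {
  if (!all(dim(mask_pre) == dim(mask_post)))
    stop("mask shapes differ")
  mask_pre & mask_post
}

#' Run the full preprocessing chain on one image
#'
#' Specular detection, inpainting, and bit-plane ROI segmentation in order.
#'
#' @param img RGB array in 0..255.
#' @param sr_threshold_fraction specular threshold (see [detect_specular()]).
#' @param roi_planes,roi_combine forwarded to [bitplane_roi()].
#' @return list with `image` (inpainted), `specular` and `roi` masks.
#' @export
preprocess_image <- function(img, sr_threshold_fraction = 0.6,
                             roi_planes = c(6, 7), roi_combine = "or") {
  sr <- detect_specular(img, sr_threshold_fraction)
  clean <- if (any(sr) && !all(sr)) inpaint_specular(img, sr) else img
  roi <- bitplane_roi(clean, planes = roi_planes, combine = roi_combine)
  list(image = clean, specular = sr, roi = roi)
}
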