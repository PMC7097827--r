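#' The three manual fiducials of a cervicogram
#'
#' The center of the cervix plus the two endpoints of the cervical os, as
#' annotated by a reader. Coordinates are (x, y) pixels, x = column,
#' y = row, 1-based.
#'
#' @param center numeric (x, y), cervix center.
#' @param os_a,os_b numeric (x, y), os endpoints; `os_a` is mapped to the
#'   left after registration.
#' @return object of class `fiducial_set`.
#' @export
fiducial_set <- function(center, os_a, os_b) {
  if (length(center) != 2 || length(os_a) != 2 || length(os_b) != 2)
    stop("fiducials must be (x, y) pairs")
  if (isTRUE(all.equal(os_a, os_b)))
    stop("os endpoints must be distinct")
  structure(list(center = as.numeric(center), os_a = as.numeric(os_a),
                 os_b = as.numeric(os_b)), class = "fiducial_set")
}

# Rigid warp: rotate by `angle_deg` about `center_src` (x, y), then translate
# that center to `center_dst` on an `out_dim` = c(H, W) canvas. Positive
# angles rotate the os line onto the horizontal when angle_deg = -os_angle.
# Inverse mapping with bilinear or nearest-neighbor sampling; out-of-bounds
# pixels are `fill` and reported in the `valid` mask.
warp_rigid <- function(img, center_src, angle_deg, out_dim, center_dst,
                       interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  is_mat <- length(dim(img)) == 2
  H <- out_dim[1]; W <- out_dim[2]
  sh <- if (is_mat) nrow(img) else dim(img)[1]
  sw <- if (is_mat) ncol(img) else dim(img)[2]
  oy <- matrix(seq_len(H), H, W)
  ox <- matrix(seq_len(W), H, W, byrow = TRUE)
  # forward: out = center_dst + Rot(angle) (src - center_src); inverse
  # mapping therefore rotates output offsets by -angle
  b <- -angle_deg * pi / 180
  dx <- ox - center_dst[1]; dy <- oy - center_dst[2]
  sx <- center_src[1] + cos(b) * dx - sin(b) * dy
  sy <- center_src[2] + sin(b) * dx + cos(b) * dy

  if (interp == "nearest") {
    ix <- round(sx); iy <- round(sy)
    valid <- ix >= 1 & ix <= sw & iy >= 1 & iy <= sh
    idx <- cbind(as.vector(pmin(pmax(iy, 1), sh)),
                 as.vector(pmin(pmax(ix, 1), sw)))
    sample_plane <- function(p) {
      v <- matrix(p[idx], H, W)
      v[!valid] <- fill
      v
    }
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    # a source position exactly on the last row/col has zero weight on the
    # (clamped) far neighbor, so the boundary is sampled exactly
    valid <- sx >= 1 & sx <= sw & sy >= 1 & sy <= sh
    cx0 <- pmin(pmax(x0, 1), sw); cx1 <- pmin(pmax(x0 + 1, 1), sw)
    cy0 <- pmin(pmax(y0, 1), sh); cy1 <- pmin(pmax(y0 + 1, 1), sh)
    i00 <- cbind(as.vector(cy0), as.vector(cx0))
    i01 <- cbind(as.vector(cy0), as.vector(cx1))
    i10 <- cbind(as.vector(cy1), as.vector(cx0))
    i11 <- cbind(as.vector(cy1), as.vector(cx1))
    sample_plane <- function(p) {
      v <- (1 - fy) * ((1 - fx) * p[i00] + fx * p[i01]) +
           fy * ((1 - fx) * p[i10] + fx * p[i11])
      v <- matrix(v, H, W)
      v[!valid] <- fill
      v
    }
  }
  if (is_mat) {
    out <- sample_plane(img)
  } else {
    out <- array(fill, dim = c(H, W, dim(img)[3]))
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- sample_plane(img[, , ch])
  }
  list(image = out, valid = valid)
}

os_angle_deg <- function(fid) {
  d <- fid$os_b - fid$os_a
  atan2(d[2], d[1]) * 180 / pi
}

#' Register a pre/post cervicogram pair from manual fiducials
#'
#' Each image is rotated about its own center fiducial so that the line
#' through the two os endpoints becomes horizontal (with `os_a` on the
#' left), then translated so both center fiducials coincide at the center of
#' a shared canvas. The transform is rigid: rotation plus translation, no
#' scaling. ROI masks are transformed with nearest-neighbor sampling and
#' intersected (with the in-bounds masks of both warps) into the pair's
#' combined ROI.
#'
#' @param pre,post RGB arrays in 0..255, already specular-inpainted.
#' @param fid_pre,fid_post [fiducial_set()]s for each image.
#' @param roi_pre,roi_post optional logical ROI masks in each image's own
#'   frame; computed with [bitplane_roi()] when omitted.
#' @param patient_id optional identifier carried through to slices.
#' @return object of class `cervicogram_pair`: `pre`, `post`, `roi`,
#'   `fiducials` (shared, post-transform), `angles` (applied rotations,
#'   degrees).
#' @export
register_pair <- function(pre, post, fid_pre, fid_post,
                          roi_pre = NULL, roi_post = NULL,
                          patient_id = NA_character_) {
  if (is.null(roi_pre)) roi_pre <- bitplane_roi(pre)
  if (is.null(roi_post)) roi_post <- bitplane_roi(post)
  a_pre <- os_angle_deg(fid_pre)
  a_post <- os_angle_deg(fid_post)
  H <- max(dim(pre)[1], dim(post)[1])
  W <- max(dim(pre)[2], dim(post)[2])
  center_dst <- c((W + 1) / 2, (H + 1) / 2)

  wp <- warp_rigid(pre, fid_pre$center, -a_pre, c(H, W), center_dst)
  wq <- warp_rigid(post, fid_post$center, -a_post, c(H, W), center_dst)
  mp <- warp_rigid(roi_pre, fid_pre$center, -a_pre, c(H, W), center_dst,
                   interp = "nearest")
  mq <- warp_rigid(roi_post, fid_post$center, -a_post, c(H, W), center_dst,
                   interp = "nearest")
  roi <- combine_roi(mp$image > 0.5 & mp$valid, mq$image > 0.5 & mq$valid) &
    wp$valid & wq$valid

  L <- sqrt(sum((fid_pre$os_b - fid_pre$os_a)^2)) / 2
  fid <- fiducial_set(center = center_dst,
                      os_a = center_dst - c(L, 0),
                      os_b = center_dst + c(L, 0))
  structure(list(pre = wp$image, post = wq$image, roi = roi,
                 fiducials = fid, angles = c(pre = -a_pre, post = -a_post),
                 patient_id = patient_id), class = "cervicogram_pair")
}

#' Slice a registered pair into 12 clock-position sectors
#'
#' Every ROI pixel is assigned to exactly one clock sector by its angle
#' about the center fiducial: hour 12 points up, hours increase clockwise,
#' and sector k covers the half-open 30-degree arc centered on hour k. This
#' matches how excised tissue is sectioned for histopathology. Twelve slices
#' are always returned; a slice whose mask is empty has `valid = FALSE`.
#'
#' @param pair a [register_pair()] result.
#' @return list of 12 `clock_slice` objects (fields `patient_id`, `sector`,
#'   `pre`, `post`, `mask`, `label`, `valid`), in sector order 1..12.
#' @export
slice_clock <- function(pair) {
  H <- dim(pair$pre)[1]; W <- dim(pair$pre)[2]
  cx <- pair$fiducials$center[1]; cy <- pair$fiducials$center[2]
  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  sector <- sector_of_angle(col - cx, row - cy)
  empty_roi <- !any(pair$roi)
  lapply(1:12, function(k) {
    m <- pair$roi & sector == k
    structure(list(patient_id = pair$patient_id, sector = k,
                   pre = pair$pre, post = pair$post, mask = m,
                   label = "UNKNOWN",
                   valid = !empty_roi && any(m),
                   empty_roi = empty_roi),
              class = "clock_slice")
  })
}

#' Attach histopathology labels to clock slices
#'
#' Grades `NORMAL` and `CIN1` map to `VIA_NEG`; `CIN2PLUS` maps to
#' `VIA_POS`. Missing grades leave the slice `UNKNOWN` (excluded from
#' training downstream).
#'
#' @param slices list of 12 `clock_slice`s from [slice_clock()].
#' @param grades character vector of 12 grades in sector order (values
#'   `"NORMAL"`, `"CIN1"`, `"CIN2PLUS"`, or `NA`).
#' @return the slices with `label` and `grade` fields filled.
#' @export
attach_labels <- function(slices, grades) {
  if (length(grades) != 12) stop("grades must have length 12")
  for (k in 1:12) {
    g <- grades[[k]]
    slices[[k]]$grade <- g
    slices[[k]]$label <-
      if (is.na(g) || !nzchar(g)) "UNKNOWN"
      else if (g == "CIN2PLUS") "VIA_POS"
      else if (g %in% c("NORMAL", "CIN1")) "VIA_NEG"
      else stop("unknown grade: ", g)
  }
  slices
}
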