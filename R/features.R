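#' Color-ratio histogram of a slice
#'
#' Histogram of per-pixel green-to-red or blue-to-red intensity ratios over
#' the slice mask, on a fixed range [0, 2] with 256 uniform bins (ratios
#' above 2 fall into the top bin). Pixels with zero red are excluded. The
#' mode index is the smallest bin index attaining the maximum count, so ties
#' break deterministically. Intensity ratios cancel a common illumination
#' factor, making the mode shift robust to device and lighting variation.
#'
#' @param slice a `clock_slice`.
#' @param phase `"pre"` or `"post"`.
#' @param channel_pair `"G_over_R"` or `"B_over_R"`.
#' @param bins number of bins over [0, 2].
#' @return list with `counts` (length `bins`), `mode_index` (0-based bin
#'   index of the mode), `n` valid pixels.
#' @export
ratio_histogram <- function(slice, phase = c("post", "pre"),
                            channel_pair = c("G_over_R", "B_over_R"),
                            bins = 256) {
  phase <- match.arg(phase)
  channel_pair <- match.arg(channel_pair)
  img <- slice[[phase]]
  m <- slice$mask
  r <- img[, , 1][m]
  num <- img[, , if (channel_pair == "G_over_R") 2 else 3][m]
  keep <- r > 0
  ratio <- num[keep] / r[keep]
  width <- 2 / bins
  idx <- pmin(floor(ratio / width), bins - 1)
  counts <- tabulate(idx + 1, nbins = bins)
  list(counts = counts, mode_index = which.max(counts) - 1L,
       n = sum(keep))
}

#' Mode shift of a color-ratio histogram between phases
#'
#' The signed difference `I_post(mode) - I_pre(mode)` of the ratio-histogram
#' mode index between the post- and pre-acetic image of the same slice.
#' Aceto-whitening raises green and blue relative to red, shifting the mode
#' to higher ratio bins.
#'
#' @param slice a `clock_slice` (carries both phases).
#' @param channel_pair `"G_over_R"` or `"B_over_R"`.
#' @param bins histogram bins over [0, 2].
#' @param min_pixels minimum valid pixels per phase; below it the feature is
#'   missing (`NA`).
#' @return signed bin-index difference, or `NA_real_`.
#' @export
ratio_mode_difference <- function(slice, channel_pair = c("G_over_R", "B_over_R"),
                                  bins = 256, min_pixels = 50) {
  channel_pair <- match.arg(channel_pair)
  hp <- ratio_histogram(slice, "pre", channel_pair, bins)
  hq <- ratio_histogram(slice, "post", channel_pair, bins)
  if (hp$n < min_pixels || hq$n < min_pixels) return(NA_real_)
  as.numeric(hq$mode_index - hp$mode_index)
}

#' Average ratio-histogram mode shift (D_ave)
#'
#' Arithmetic mean of the green-to-red and blue-to-red mode shifts.
#'
#' @inheritParams ratio_mode_difference
#' @return mean mode shift in bin-index units, or `NA_real_` if either
#'   component is missing.
#' @export
d_ave <- function(slice, bins = 256, min_pixels = 50) {
  g <- ratio_mode_difference(slice, "G_over_R", bins, min_pixels)
  b <- ratio_mode_difference(slice, "B_over_R", bins, min_pixels)
  (g + b) / 2
}

#' Channel standard deviation of the post-acetic slice
#'
#' Population standard deviation of the green or blue channel over the slice
#' mask of the post-acetic image. Aceto-white patches broaden the green and
#' blue histograms.
#'
#' @param slice a `clock_slice`.
#' @param channel `"GREEN"` or `"BLUE"`.
#' @param phase image phase, default `"post"`.
#' @return SD in 8-bit intensity units; `NA_real_` with fewer than 2 pixels.
#' @export
channel_sd <- function(slice, channel = c("GREEN", "BLUE"), phase = "post") {
  channel <- match.arg(channel)
  x <- slice[[phase]][, , if (channel == "GREEN") 2 else 3][slice$mask]
  if (length(x) < 2) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Mean CIELAB a* of the post-acetic slice
#'
#' Converts masked sRGB pixels to CIELAB (D65 reference white, standard sRGB
#' transfer function) and averages the a* (green-magenta) channel.
#' Aceto-white epithelium blocks the reddish stroma, so abnormal slices have
#' lower a* than the surrounding pink tissue.
#'
#' @param slice a `clock_slice`.
#' @param phase image phase, default `"post"`.
#' @return mean a*; `NA_real_` for an empty slice.
#' @export
astar_mean <- function(slice, phase = "post") {
  m <- slice$mask
  if (!any(m)) return(NA_real_)
  img <- slice[[phase]]
  rgb <- cbind(img[, , 1][m], img[, , 2][m], img[, , 3][m]) / 255
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  mean(lab[, 2])
}

# HSV saturation channel: (max - min) / max, 0 for black pixels
saturation_channel <- function(img) {
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}

# Accumulate a non-symmetric GLCM for one (drow, dcol) offset over a
# quantized level matrix `q` (values 0..levels-1, NA invalid).
glcm_accumulate <- function(q, levels, drow, dcol) {
  H <- nrow(q); W <- ncol(q)
  r0 <- max(1, 1 - drow); r1 <- min(H, H - drow)
  c0 <- max(1, 1 - dcol); c1 <- min(W, W - dcol)
  if (r0 > r1 || c0 > c1) return(matrix(0, levels, levels))
  a <- q[r0:r1, c0:c1, drop = FALSE]
  b <- q[(r0 + drow):(r1 + drow), (c0 + dcol):(c1 + dcol), drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, levels, levels))
  idx <- a[ok] * levels + b[ok] + 1
  matrix(tabulate(idx, nbins = levels * levels), levels, levels, byrow = TRUE)
}

haralick_correlation <- function(P) {
  tot <- sum(P)
  if (tot == 0) return(NA_real_)
  P <- P / tot
  lv <- seq_len(nrow(P)) - 1
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mu_i <- sum(lv * pi_); mu_j <- sum(lv * pj_)
  si <- sqrt(sum((lv - mu_i)^2 * pi_)); sj <- sqrt(sum((lv - mu_j)^2 * pj_))
  if (si == 0 || sj == 0) return(NA_real_)
  (sum(outer(lv, lv) * P) - mu_i * mu_j) / (si * sj)
}

#' Haralick correlation of the saturation-difference texture
#'
#' Computes HSV saturation for the pre and post slice, forms the difference
#' image `S_post - S_pre` on the slice's bounding box (out-of-mask pixels
#' invalid), linearly quantizes valid values to `levels` gray levels over
#' their observed range, accumulates one non-symmetric gray-level
#' co-occurrence matrix per offset angle (0, 45, 90, 135 degrees at the
#' given interpixel distance, counting only pairs with both pixels valid),
#' sums the four matrices, normalizes to probabilities, and returns the
#' Haralick correlation statistic.
#'
#' @param slice a `clock_slice`.
#' @param levels number of quantization levels.
#' @param distance interpixel offset distance in pixels.
#' @return correlation in [-1, 1]; `NA_real_` for degenerate (constant) or
#'   too-small slices.
#' @export
glcm_correlation <- function(slice, levels = 8, distance = 5) {
  m <- slice$mask
  if (!any(m)) return(NA_real_)
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  if (diff(rr) + 1 < distance + 1 || diff(cc) + 1 < distance + 1)
    return(NA_real_)
  rows <- rr[1]:rr[2]; cols <- cc[1]:cc[2]
  sp <- saturation_channel(slice$pre)[rows, cols, drop = FALSE]
  sq <- saturation_channel(slice$post)[rows, cols, drop = FALSE]
  D <- sq - sp
  D[!m[rows, cols, drop = FALSE]] <- NA
  rng <- range(D, na.rm = TRUE)
  if (rng[2] - rng[1] <= 0) return(NA_real_)
  q <- floor((D - rng[1]) / (rng[2] - rng[1]) * levels)
  q[q == levels] <- levels - 1L
  offs <- list(c(0, distance), c(-distance, distance),
               c(-distance, 0), c(-distance, -distance))
  P <- Reduce(`+`, lapply(offs, function(o)
    glcm_accumulate(q, levels, o[1], o[2])))
  haralick_correlation(P)
}

#' Extract the five VIA predictors for one clock slice
#'
#' Assembles the feature vector used for classification: average
#' ratio-histogram mode shift (`d_ave`), post-acetic green and blue channel
#' standard deviations, mean CIELAB a*, and the Haralick correlation of the
#' saturation-difference texture, plus the slice's binary label.
#'
#' @param slice a labelled `clock_slice`.
#' @param ratio_bins bins for the ratio histograms.
#' @param glcm_levels,glcm_distance GLCM parameters.
#' @param min_pixels minimum valid pixels for the ratio features.
#' @return one-row data.frame: `patient_id`, `sector`, `d_ave`, `sd_green`,
#'   `sd_blue`, `astar_mean`, `glcm_correlation`, `label`. Missing features
#'   are `NA`.
#' @export
extract_features <- function(slice, ratio_bins = 256, glcm_levels = 8,
                             glcm_distance = 5, min_pixels = 50) {
  data.frame(
    patient_id = slice$patient_id,
    sector = slice$sector,
    d_ave = d_ave(slice, bins = ratio_bins, min_pixels = min_pixels),
    sd_green = channel_sd(slice, "GREEN"),
    sd_blue = channel_sd(slice, "BLUE"),
    astar_mean = astar_mean(slice),
    glcm_correlation = glcm_correlation(slice, glcm_levels, glcm_distance),
    label = slice$label,
    stringsAsFactors = FALSE)
}

#' Feature table for a list of slices
#'
#' @param slices list of labelled `clock_slice`s (any number of patients).
#' @param ... forwarded to [extract_features()].
#' @return data.frame with one row per slice.
#' @export
extract_feature_table <- function(slices, ...) {
  do.call(rbind, lapply(slices, extract_features, ...))
}

feature_columns <- c("d_ave", "sd_green", "sd_blue", "astar_mean",
                     "glcm_correlation")
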