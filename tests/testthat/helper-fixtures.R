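# Shared fixtures: toy images, toy slices, and small scene specs.

const_img <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# Minimal clock_slice for feature unit tests
toy_slice <- function(pre, post, mask = NULL, sector = 1, label = "UNKNOWN") {
  if (is.null(mask)) mask <- matrix(TRUE, dim(pre)[1], dim(pre)[2])
  structure(list(patient_id = "T", sector = sector, pre = pre, post = post,
                 mask = mask, label = label, valid = any(mask)),
            class = "clock_slice")
}

# Small, fast scene spec used across registration/feature tests
small_spec <- function(...) {
  scene_spec(image_size = 192, ...)
}

# Clock-sector index recomputed independently of the package internals:
# angle from "up" measured clockwise, sector k centered on hour k.
expected_sector <- function(dx, dy) {
  theta <- (atan2(dx, -dy) * 180 / pi) %% 360
  k <- floor((theta + 15) / 30) %% 12
  ifelse(k == 0, 12, k)
}

# Synthetic feature table with well-separated classes (no images involved),
# for classifier unit tests.
separable_features <- function(n_per_class = 60, gap = 6, sd = 1, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(c("VIA_NEG", "VIA_POS"), each = n_per_class)
  shift <- ifelse(lab == "VIA_POS", gap, 0)
  data.frame(
    patient_id = rep(sprintf("P%02d", 1:(n / 12 + 1)), each = 12,
                     length.out = n),
    sector = rep(1:12, length.out = n),
    d_ave = rnorm(n, shift, sd),
    sd_green = rnorm(n, shift, sd),
    sd_blue = rnorm(n, shift, sd),
    astar_mean = rnorm(n, -shift, sd),
    glcm_correlation = rnorm(n, shift / 10, sd / 10),
    label = lab, stringsAsFactors = FALSE)
}
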