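#' Parametric description of a synthetic cervicogram pair
#'
#' A `scene_spec` describes one synthetic pre/post acetic-acid cervicogram
#' pair: an elliptical pinkish ectocervix on a dark background, surrounded by
#' a dimmer vaginal-wall annulus, with a central os slit whose endpoints and
#' midpoint serve as the three manual fiducials. After acetic-acid
#' application, clock sectors listed in `abnormal_sectors` (histopathology
#' CIN2+) develop aceto-white patches: a smooth multiplicative gain on the
#' green and blue channels plus additive speckle, which raises green/blue
#' intensity and their dispersion, lowers CIELAB a*, and structures the
#' saturation-difference texture. Sectors in `cin1_sectors` receive the same
#' treatment at 0.3 times the whitening strength, producing the confusable
#' low-grade class that is still labelled screen-negative.
#'
#' @param image_size side of the square output images in pixels.
#' @param cervix_center numeric (x, y) in pixels; default image center.
#' @param cervix_radii numeric (rx, ry) ellipse semi-axes in pixels.
#' @param os_half_length half-length of the cervical os slit in pixels.
#' @param os_angle_deg orientation of the os line in degrees (0 = horizontal);
#'   the registration step must undo this rotation.
#' @param abnormal_sectors integer clock indices 1..12 with CIN2+ lesions.
#' @param cin1_sectors integer clock indices 1..12 with CIN1 (screen-negative)
#'   whitening; must be disjoint from `abnormal_sectors`.
#' @param whitening_strength unitless in [0, 1]; green/blue gain amplitude in
#'   abnormal sectors of the post image.
#' @param n_specular_spots number of saturated specular disks per image.
#' @param illumination_gain multiplicative gain applied to both images.
#' @param noise_sd Gaussian pixel noise standard deviation in 8-bit units,
#'   drawn independently for the pre and post image.
#' @param seed integer seed making the scene fully reproducible.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 512,
                       cervix_center = NULL,
                       cervix_radii = NULL,
                       os_half_length = NULL,
                       os_angle_deg = 0,
                       abnormal_sectors = integer(),
                       cin1_sectors = integer(),
                       whitening_strength = 0.5,
                       n_specular_spots = 6,
                       illumination_gain = 1,
                       noise_sd = 4,
                       seed = 1L) {
  if (is.null(cervix_center)) cervix_center <- c(image_size, image_size) / 2
  if (is.null(cervix_radii))  cervix_radii <- c(0.34, 0.28) * image_size
  if (is.null(os_half_length)) os_half_length <- 0.11 * image_size
  spec <- structure(list(
    image_size = as.integer(image_size),
    cervix_center = as.numeric(cervix_center),
    cervix_radii = as.numeric(cervix_radii),
    os_half_length = as.numeric(os_half_length),
    os_angle_deg = as.numeric(os_angle_deg),
    abnormal_sectors = as.integer(abnormal_sectors),
    cin1_sectors = as.integer(cin1_sectors),
    whitening_strength = as.numeric(whitening_strength),
    n_specular_spots = as.integer(n_specular_spots),
    illumination_gain = as.numeric(illumination_gain),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  ), class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (length(abnormal_sectors) &&
        !all(abnormal_sectors %in% 1:12))
      stop("invalid scene_spec: abnormal_sectors must be a subset of 1..12")
    if (length(cin1_sectors) && !all(cin1_sectors %in% 1:12))
      stop("invalid scene_spec: cin1_sectors must be a subset of 1..12")
    if (length(intersect(abnormal_sectors, cin1_sectors)))
      stop("invalid scene_spec: abnormal_sectors and cin1_sectors overlap")
    if (whitening_strength < 0 || whitening_strength > 1)
      stop("invalid scene_spec: whitening_strength must lie in [0, 1]")
    if (noise_sd < 0)
      stop("invalid scene_spec: noise_sd must be >= 0")
    if (any(cervix_radii <= 0))
      stop("invalid scene_spec: cervix radii rx, ry must be > 0")
    if (illumination_gain <= 0)
      stop("invalid scene_spec: illumination_gain must be > 0")
    if (n_specular_spots < 0)
      stop("invalid scene_spec: n_specular_spots must be >= 0")
    r <- max(cervix_radii)
    if (cervix_center[1] - r < 1 || cervix_center[1] + r > image_size ||
        cervix_center[2] - r < 1 || cervix_center[2] + r > image_size)
      stop("invalid scene_spec: cervix ellipse does not fit inside the image")
  })
  invisible(spec)
}

# Clock-sector index (1..12) of canonical offsets (u right, v down), with
# hour 12 straight up and hours increasing clockwise; sector k spans the
# half-open arc [30k - 15, 30k + 15) degrees.
sector_of_angle <- function(u, v) {
  theta <- (atan2(u, -v) * 180 / pi) %% 360
  k <- (floor((theta + 15) / 30)) %% 12
  k[k == 0] <- 12
  as.integer(k)
}

# Smooth low-frequency field in [-1, 1] over canonical coordinates; the
# spatial structure of the aceto-white gain (and of the fixed mottling of the
# ectocervix), so the saturation-difference texture is correlated at the
# GLCM working distance.
smooth_field <- function(u, v, wavelength, phase) {
  sin(2 * pi * u / wavelength + phase[1]) * sin(2 * pi * v / wavelength + phase[2])
}

#' Generate one synthetic pre/post cervicogram pair
#'
#' Renders the scene described by a [scene_spec()]: both phases share the
#' cervix geometry, fiducials and base coloring; the post image differs only
#' inside whitened (CIN1/CIN2+) sectors, plus freshly drawn specular spots
#' and pixel noise. Images are 8-bit RGB arrays of dimension
#' `image_size x image_size x 3`, channel order R, G, B, 1-based (row, col)
#' indexing with the origin at the top-left.
#'
#' @param spec a [scene_spec()].
#' @return a list of class `cervia_scene` with elements `pre`, `post`
#'   (numeric arrays in 0..255), `fiducials` (a [fiducial_set()]), `truth`
#'   (list with `sector_labels`, grades `"NORMAL"/"CIN1"/"CIN2PLUS"`, and
#'   `binary_labels`, `"VIA_NEG"/"VIA_POS"`), and the `spec` itself.
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  set.seed(spec$seed)
  n <- spec$image_size
  cx <- spec$cervix_center[1]; cy <- spec$cervix_center[2]
  rx <- spec$cervix_radii[1];  ry <- spec$cervix_radii[2]

  row <- matrix(seq_len(n), n, n)            # y
  col <- matrix(seq_len(n), n, n, byrow = TRUE)  # x
  dx <- col - cx; dy <- row - cy
  phi <- spec$os_angle_deg * pi / 180
  # canonical frame: os horizontal, os_a on the left
  u <-  cos(phi) * dx + sin(phi) * dy
  v <- -sin(phi) * dx + cos(phi) * dy

  e <- sqrt((u / rx)^2 + (v / ry)^2)
  cervix <- e <= 1
  wall <- e > 1 & e <= 1.45
  sector <- sector_of_angle(u, v)

  ph <- runif(6, 0, 2 * pi)
  mottle <- smooth_field(u, v, wavelength = 0.35 * n, phase = ph[1:2])

  # base coloring (shared by pre and post); red kept in [64, 153) on the
  # cervix so the bit-plane ROI includes it while the 60% saturation
  # threshold does not
  R <- matrix(25, n, n); G <- matrix(18, n, n); B <- matrix(20, n, n)
  R[wall] <- 52; G[wall] <- 33; B[wall] <- 38
  R[cervix] <- 132 - 12 * e[cervix] + 5 * mottle[cervix]
  G[cervix] <- 78 - 8 * e[cervix] + 4 * mottle[cervix]
  B[cervix] <- 84 - 8 * e[cervix] + 4 * mottle[cervix]
  os_w <- max(2, round(0.012 * n))
  os <- abs(v) <= os_w & abs(u) <= spec$os_half_length
  R[os] <- 95; G[os] <- 36; B[os] <- 44

  base <- array(c(R, G, B), dim = c(n, n, 3))

  # aceto-white gain field on G and B (post image only), smooth within each
  # whitened sector; CIN1 at 0.3 x strength
  gain <- matrix(0, n, n)
  blob <- 0.45 + 0.25 * smooth_field(u, v, wavelength = 0.5 * n, phase = ph[3:4])
  for (k in spec$abnormal_sectors)
    gain[cervix & sector == k] <- spec$whitening_strength * blob[cervix & sector == k]
  for (k in spec$cin1_sectors)
    gain[cervix & sector == k] <- 0.3 * spec$whitening_strength * blob[cervix & sector == k]

  post <- base
  post[, , 2] <- base[, , 2] * (1 + gain)
  post[, , 3] <- base[, , 3] * (1 + gain)
  post[, , 1] <- base[, , 1] * (1 + 0.12 * gain)
  # additive speckle texture inside whitened areas
  if (any(gain > 0)) {
    spk <- matrix(rnorm(n * n, 0, 6), n, n) * (gain > 0)
    for (ch in 1:3) post[, , ch] <- post[, , ch] + spk * (0.5 + gain)
  }
  pre <- base

  pre <- pre * spec$illumination_gain
  post <- post * spec$illumination_gain

  pre <- add_specular_spots(pre, spec, cervix)
  post <- add_specular_spots(post, spec, cervix)

  if (spec$noise_sd > 0) {
    pre <- pre + array(rnorm(length(pre), 0, spec$noise_sd), dim = dim(pre))
    post <- post + array(rnorm(length(post), 0, spec$noise_sd), dim = dim(post))
  }
  pre <- round(pmin(pmax(pre, 0), 255))
  post <- round(pmin(pmax(post, 0), 255))

  # fiducials in (x, y) pixels: os endpoints at u = -L (os_a, left after
  # registration) and u = +L
  L <- spec$os_half_length
  fid <- fiducial_set(
    center = c(cx, cy),
    os_a = c(cx - L * cos(phi), cy - L * sin(phi)),
    os_b = c(cx + L * cos(phi), cy + L * sin(phi))
  )

  grades <- rep("NORMAL", 12)
  grades[spec$cin1_sectors] <- "CIN1"
  grades[spec$abnormal_sectors] <- "CIN2PLUS"
  truth <- list(
    sector_labels = stats::setNames(grades, paste0("sector_", 1:12)),
    binary_labels = stats::setNames(
      ifelse(grades == "CIN2PLUS", "VIA_POS", "VIA_NEG"),
      paste0("sector_", 1:12))
  )

  structure(list(pre = pre, post = post, fiducials = fid, truth = truth,
                 spec = spec), class = "cervia_scene")
}

add_specular_spots <- function(img, spec, cervix) {
  if (spec$n_specular_spots == 0) return(img)
  n <- spec$image_size
  cx <- spec$cervix_center[1]; cy <- spec$cervix_center[2]
  rx <- spec$cervix_radii[1];  ry <- spec$cervix_radii[2]
  for (i in seq_len(spec$n_specular_spots)) {
    # rejection-free placement inside the 0.85-scaled ellipse
    a <- runif(1, 0, 2 * pi); r <- sqrt(runif(1)) * 0.85
    sx <- cx + r * rx * cos(a); sy <- cy + r * ry * sin(a)
    rad <- runif(1, 2.5, 5.5)
    r0 <- max(1, floor(sy - rad)); r1 <- min(n, ceiling(sy + rad))
    c0 <- max(1, floor(sx - rad)); c1 <- min(n, ceiling(sx + rad))
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - sy)^2, (cc - sx)^2, `+`)
    hit <- d2 <= rad^2
    for (ch in 1:3) {
      block <- img[rr, cc, ch]
      block[hit] <- 255
      img[rr, cc, ch] <- block
    }
  }
  img
}

#' Generate a seeded synthetic screening cohort
#'
#' Emulates the study design: `n_patients` volunteers, a fixed fraction with
#' at least one CIN2+ clock sector (default 0.6, i.e. 12 abnormal and 8
#' normal patients in a 20-patient cohort). Abnormal patients receive a
#' contiguous run of CIN2+ sectors; any patient may additionally carry CIN1
#' sectors, which are whitened weakly but labelled screen-negative.
#' Per-patient seeds are derived deterministically from the master seed.
#'
#' @param n_patients number of patients (>= 1).
#' @param fraction_abnormal_patients fraction in [0, 1] of patients with at
#'   least one CIN2+ sector.
#' @param sectors_per_abnormal integer length-2 range (min, max) of CIN2+
#'   sectors per abnormal patient.
#' @param seed master integer seed.
#' @param image_size,whitening_strength,n_specular_spots,illumination_gain,noise_sd
#'   forwarded to each patient's [scene_spec()].
#' @param out_dir optional directory; when given, images, fiducials and the
#'   manifest are written there (see [write_cohort()]).
#' @return list of class `cervia_cohort`: `scenes` (list of `cervia_scene`),
#'   `manifest` (data.frame with patient_id, seed, label_1..label_12 grades),
#'   and the call parameters.
#' @export
generate_cohort <- function(n_patients,
                            fraction_abnormal_patients = 0.6,
                            sectors_per_abnormal = c(2L, 5L),
                            seed = 1L,
                            image_size = 512,
                            whitening_strength = 0.5,
                            n_specular_spots = 6,
                            illumination_gain = 1,
                            noise_sd = 4,
                            out_dir = NULL) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (fraction_abnormal_patients < 0 || fraction_abnormal_patients > 1)
    stop("fraction_abnormal_patients must lie in [0, 1]")
  set.seed(seed)
  n_abn <- round(fraction_abnormal_patients * n_patients)
  abn_ids <- sort(sample.int(n_patients, n_abn))
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n_patients)

  scenes <- vector("list", n_patients)
  rows <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    set.seed(patient_seeds[i])
    abn <- integer()
    if (i %in% abn_ids) {
      k <- sample(seq(sectors_per_abnormal[1], sectors_per_abnormal[2]), 1)
      start <- sample.int(12, 1)
      abn <- ((start + seq_len(k) - 2) %% 12) + 1
    }
    free <- setdiff(1:12, abn)
    n_cin1 <- sample(0:2, 1)
    cin1 <- if (n_cin1 > 0) sample(free, min(n_cin1, length(free))) else integer()
    spec <- scene_spec(
      image_size = image_size,
      os_angle_deg = runif(1, -45, 45),
      abnormal_sectors = abn,
      cin1_sectors = cin1,
      whitening_strength = whitening_strength,
      n_specular_spots = n_specular_spots,
      illumination_gain = illumination_gain,
      noise_sd = noise_sd,
      seed = patient_seeds[i]
    )
    scenes[[i]] <- generate_scene(spec)
    scenes[[i]]$patient_id <- sprintf("P%03d", i)
    grades <- scenes[[i]]$truth$sector_labels
    rows[[i]] <- data.frame(
      patient_id = sprintf("P%03d", i), seed = patient_seeds[i],
      t(stats::setNames(grades, paste0("label_", 1:12))),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  cohort <- structure(list(
    scenes = scenes, manifest = manifest,
    n_patients = n_patients,
    fraction_abnormal_patients = fraction_abnormal_patients,
    seed = seed), class = "cervia_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a synthetic cohort to disk
#'
#' Writes per-patient PNG image pairs, fiducial JSON files
#' (`{"center":[x,y],"os":[[x1,y1],[x2,y2]]}`) and a cohort CSV manifest
#' (patient_id, pre_path, post_path, fiducial_path, label_1..label_12).
#'
#' @param cohort a `cervia_cohort`.
#' @param dir output directory, created if needed.
#' @return the manifest data.frame with file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$pre_path <- file.path(dir, paste0(man$patient_id, "_pre.png"))
  man$post_path <- file.path(dir, paste0(man$patient_id, "_post.png"))
  man$fiducial_path <- file.path(dir, paste0(man$patient_id, "_fiducials.json"))
  for (i in seq_along(cohort$scenes)) {
    sc <- cohort$scenes[[i]]
    write_cervicogram(sc$pre, man$pre_path[i])
    write_cervicogram(sc$post, man$post_path[i])
    write_fiducials(sc$fiducials, man$fiducial_path[i])
  }
  first <- c("patient_id", "pre_path", "post_path", "fiducial_path")
  man <- man[, c(first, setdiff(names(man), first))]
  utils::write.csv(man, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(man)
}
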