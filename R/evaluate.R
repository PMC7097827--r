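#' 2x2 diagnostic confusion matrix
#'
#' @param tp,fn,fp,tn non-negative counts (true/false positives/negatives,
#'   with histopathology as the reference standard).
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0)) stop("confusion-matrix counts must be non-negative")
  if (sum(cells) < 1) stop("confusion matrix must contain at least one case")
  structure(as.list(cells), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("truth +", "truth -"),
                              c("pred +", "pred -")))
  m["truth -", ] <- c(x$fp, x$tn)
  print(m)
  invisible(x)
}

# deterministic half-up rounding (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Reconstruct a confusion matrix from printed sensitivity and specificity
#'
#' Published reader studies report rates, not counts; given the numbers of
#' truly abnormal and normal cases, the 2x2 matrix follows by rounding
#' `sens/100 * n_pos` and `spec/100 * n_neg` to the nearest integers. A
#' warning is raised when the recomputed rate disagrees with the printed one
#' by more than half a count's worth (i.e. the printed rate cannot have come
#' from integer counts).
#'
#' @param sensitivity,specificity percent in [0, 100].
#' @param n_pos,n_neg reference-positive and reference-negative case counts.
#' @return a [confusion_matrix()].
#' @export
confusion_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  if (sensitivity < 0 || sensitivity > 100 || specificity < 0 || specificity > 100)
    stop("rates must lie in [0, 100]")
  tp <- round_half_up(sensitivity / 100 * n_pos)
  tn <- round_half_up(specificity / 100 * n_neg)
  if (abs(sensitivity / 100 * n_pos - tp) > 0.5 ||
      abs(specificity / 100 * n_neg - tn) > 0.5)
    warning("printed rates are inconsistent with integer counts")
  confusion_matrix(tp = tp, fn = n_pos - tp, fp = n_neg - tn, tn = tn)
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' Rates are percentages; a ratio with a zero denominator is `NA` (flagged
#' undefined, never zero-filled).
#'
#' @param cm a [confusion_matrix()].
#' @return list with `sensitivity`, `specificity`, `accuracy` (percent) and
#'   the cell counts.
#' @export
binary_metrics <- function(cm) {
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  list(
    sensitivity = if (cm$tp + cm$fn > 0) 100 * cm$tp / (cm$tp + cm$fn) else NA_real_,
    specificity = if (cm$fp + cm$tn > 0) 100 * cm$tn / (cm$fp + cm$tn) else NA_real_,
    accuracy = 100 * (cm$tp + cm$tn) / total,
    total = total, confusion = cm)
}

#' Cohen kappa of a confusion matrix, with large-sample significance
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with
#' `p_o = (tp + tn)/n` and `p_e` the product of the marginals. The two-sided
#' p-value tests `kappa != 0` with the asymptotic null standard error of
#' Fleiss, `z = kappa / SE0(kappa)` against a standard normal.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `kappa`, `se0` (null SE), `z`, `p_value`. Degenerate
#'   marginals (`p_e = 1`) give `NA` kappa.
#' @export
cohen_kappa <- function(cm) {
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n < 2) stop("kappa needs at least 2 cases")
  p_o <- (cm$tp + cm$tn) / n
  row_pos <- (cm$tp + cm$fn) / n; row_neg <- 1 - row_pos   # truth marginals
  col_pos <- (cm$tp + cm$fp) / n; col_neg <- 1 - col_pos   # rater marginals
  p_e <- row_pos * col_pos + row_neg * col_neg
  if (1 - p_e <= .Machine$double.eps)
    return(list(kappa = NA_real_, se0 = NA_real_, z = NA_real_,
                p_value = NA_real_))
  kappa <- (p_o - p_e) / (1 - p_e)
  s <- row_pos * col_pos * (row_pos + col_pos) +
       row_neg * col_neg * (row_neg + col_neg)
  se0 <- sqrt(max(p_e + p_e^2 - s, 0)) / ((1 - p_e) * sqrt(n))
  z <- if (se0 > 0) kappa / se0 else NA_real_
  list(kappa = kappa, se0 = se0, z = z,
       p_value = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)))
}

#' Pool confusion matrices cellwise
#'
#' Summing the 2x2 tables of several readers gives the pooled agreement
#' table; kappa and rates of the pooled matrix summarize the panel.
#'
#' @param cms nonempty list of [confusion_matrix()] objects.
#' @return a [confusion_matrix()].
#' @export
pool_confusions <- function(cms) {
  if (!length(cms)) stop("empty list")
  confusion_matrix(
    tp = sum(vapply(cms, `[[`, 0, "tp")),
    fn = sum(vapply(cms, `[[`, 0, "fn")),
    fp = sum(vapply(cms, `[[`, 0, "fp")),
    tn = sum(vapply(cms, `[[`, 0, "tn")))
}

#' Patient-level call from 12 sector predictions
#'
#' A patient screens positive if at least one clock sector is predicted
#' VIA-positive. Missing sectors are treated as negative (with a message).
#'
#' @param sector_predictions character vector of up to 12 per-sector labels
#'   (`"VIA_POS"`/`"VIA_NEG"`, `NA` allowed).
#' @return `"VIA_POS"` or `"VIA_NEG"`.
#' @export
aggregate_patient <- function(sector_predictions) {
  if (length(sector_predictions) > 12)
    stop("at most 12 sector predictions expected")
  if (anyNA(sector_predictions) || length(sector_predictions) < 12)
    message("missing sectors treated as VIA_NEG")
  if (any(sector_predictions == "VIA_POS", na.rm = TRUE)) "VIA_POS" else "VIA_NEG"
}

#' Percent agreement between two sector-label vectors
#'
#' @param pred_a,pred_b equal-length character label vectors over the same
#'   sectors; `NA` pairs are dropped.
#' @return percent of sectors with identical labels.
#' @export
agreement_rate <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b)) stop("label vectors differ in length")
  ok <- !is.na(pred_a) & !is.na(pred_b)
  if (!any(ok)) stop("no overlapping sectors")
  100 * mean(pred_a[ok] == pred_b[ok])
}

#' Render the clock-annulus overlay of per-sector predictions
#'
#' Draws the prediction annulus outside the cervix ROI on the post-acetic
#' image: red ring segments where the prediction is VIA-positive, blue where
#' negative; inner radial ticks colored by histopathology grade (red CIN2+,
#' green CIN1, blue normal); yellow outer marks where a positive prediction
#' coincides with CIN2+ truth. Geometry follows the registration clock
#' convention (12 up, clockwise, 30-degree sectors) and is deterministic.
#'
#' @param post_image registered post-acetic RGB array in 0..255.
#' @param center (x, y) clock center (the center fiducial).
#' @param predictions 12 per-sector labels `"VIA_POS"`/`"VIA_NEG"`.
#' @param truth_grades optional 12 grades (`"NORMAL"/"CIN1"/"CIN2PLUS"`);
#'   omitted ticks when `NULL`.
#' @param roi optional ROI mask; sets the annulus inner radius at 1.05 times
#'   the ROI bounding radius (default: 0.38 of the image diagonal).
#' @param margin canvas padding in pixels added on every side.
#' @return annotated RGB array of dimension `(H + 2 margin) x (W + 2 margin) x 3`.
#' @export
render_annulus <- function(post_image, center, predictions,
                           truth_grades = NULL, roi = NULL, margin = 32) {
  stopifnot(length(predictions) == 12)
  H <- dim(post_image)[1]; W <- dim(post_image)[2]
  out <- array(0, dim = c(H + 2 * margin, W + 2 * margin, 3))
  out[margin + seq_len(H), margin + seq_len(W), ] <- post_image
  cx <- center[1] + margin; cy <- center[2] + margin

  if (!is.null(roi) && any(roi)) {
    idx <- which(roi, arr.ind = TRUE)
    r_in <- 1.05 * max(sqrt((idx[, 2] - center[1])^2 + (idx[, 1] - center[2])^2))
  } else {
    r_in <- 0.38 * sqrt(H^2 + W^2) / 2
  }
  r_out <- r_in + 10

  Ho <- dim(out)[1]; Wo <- dim(out)[2]
  row <- matrix(seq_len(Ho), Ho, Wo)
  col <- matrix(seq_len(Wo), Ho, Wo, byrow = TRUE)
  rr <- sqrt((col - cx)^2 + (row - cy)^2)
  sector <- sector_of_angle(col - cx, row - cy)

  paint <- function(img, mask, rgb) {
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[mask] <- rgb[ch]; img[, , ch] <- plane
    }
    img
  }
  ring <- rr >= r_in & rr <= r_out
  for (k in 1:12) {
    colr <- if (predictions[k] == "VIA_POS") c(220, 40, 40) else c(50, 90, 220)
    out <- paint(out, ring & sector == k, colr)
    if (!is.null(truth_grades)) {
      tick <- rr >= r_in - 6 & rr < r_in & sector == k
      g <- truth_grades[k]
      tc <- if (is.na(g)) NULL
            else if (g == "CIN2PLUS") c(220, 40, 40)
            else if (g == "CIN1") c(40, 200, 60)
            else c(50, 90, 220)
      if (!is.null(tc)) out <- paint(out, tick, tc)
      if (!is.na(g) && g == "CIN2PLUS" && predictions[k] == "VIA_POS")
        out <- paint(out, rr > r_out & rr <= r_out + 5 & sector == k,
                     c(250, 230, 40))
    }
  }
  out
}
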