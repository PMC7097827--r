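# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: explicit loops and closed forms only.

# Haralick correlation of the summed 4-angle GLCM by enumerating every pixel
# pair with a double loop.
glcm_oracle <- function(D, valid, levels, distance) {
  rng <- range(D[valid])
  if (rng[2] - rng[1] <= 0) return(NA_real_)
  q <- floor((D - rng[1]) / (rng[2] - rng[1]) * levels)
  q[q >= levels] <- levels - 1
  offsets <- list(c(0, distance), c(-distance, distance),
                  c(-distance, 0), c(-distance, -distance))
  P <- matrix(0, levels, levels)
  H <- nrow(D); W <- ncol(D)
  for (off in offsets) {
    for (r in seq_len(H)) {
      for (c in seq_len(W)) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
            valid[r, c] && valid[r2, c2]) {
          P[q[r, c] + 1, q[r2, c2] + 1] <- P[q[r, c] + 1, q[r2, c2] + 1] + 1
        }
      }
    }
  }
  tot <- sum(P)
  if (tot == 0) return(NA_real_)
  P <- P / tot
  mu_i <- 0; mu_j <- 0
  for (i in 1:levels) for (j in 1:levels) {
    mu_i <- mu_i + (i - 1) * P[i, j]
    mu_j <- mu_j + (j - 1) * P[i, j]
  }
  vi <- 0; vj <- 0; cov <- 0
  for (i in 1:levels) for (j in 1:levels) {
    vi <- vi + (i - 1 - mu_i)^2 * P[i, j]
    vj <- vj + (j - 1 - mu_j)^2 * P[i, j]
    cov <- cov + (i - 1 - mu_i) * (j - 1 - mu_j) * P[i, j]
  }
  if (vi == 0 || vj == 0) return(NA_real_)
  cov / sqrt(vi * vj)
}

# Wrap a pre/post pixel pair into the saturation-difference oracle input
# matching glcm_correlation()'s definition.
glcm_oracle_from_slice <- function(slice, levels, distance) {
  sat <- function(img) {
    mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
    mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
    s <- ifelse(mx == 0, 0, (mx - mn) / mx)
    matrix(s, dim(img)[1], dim(img)[2])
  }
  m <- slice$mask
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  rows <- rr[1]:rr[2]; cols <- cc[1]:cc[2]
  D <- sat(slice$post)[rows, cols] - sat(slice$pre)[rows, cols]
  glcm_oracle(D, m[rows, cols], levels, distance)
}

# AUC as Mann-Whitney pair counting with ties scored one half.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "VIA_POS" | labels == TRUE]
  neg <- scores[labels == "VIA_NEG" | labels == FALSE]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# KNN prediction by exhaustive neighbor enumeration.
knn_oracle <- function(trainX, trainy, testX, k) {
  apply(testX, 1, function(x) {
    d <- sqrt(rowSums(sweep(trainX, 2, x)^2))
    nb <- trainy[order(d)[seq_len(k)]]
    if (sum(nb == "VIA_POS") > k / 2) "VIA_POS" else "VIA_NEG"
  })
}

# Cohen kappa from the closed form, written independently.
kappa_oracle <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  (po - pe) / (1 - pe)
}
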