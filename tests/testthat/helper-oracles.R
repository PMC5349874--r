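# Independent brute-force oracles used to validate the fast implementations.

# lesion with every pixel in the mask
full_mask_lesion <- function(values, pixel_size_cm = 0.1) {
  values <- as.matrix(values)
  lesion_image(values, matrix(TRUE, nrow(values), ncol(values)),
               pixel_size_cm)
}

# 4x4 two-level checkerboard (values 0/1)
checkerboard4 <- function() {
  v <- outer(1:4, 1:4, function(r, c) (r + c) %% 2)
  full_mask_lesion(v)
}

# filled discrete circle mask in an n x n frame
circle_mask <- function(n, radius, cr = (n + 1) / 2, cc = (n + 1) / 2) {
  outer(1:n, 1:n, function(r, c) (r - cr)^2 + (c - cc)^2 <= radius^2)
}

# brute-force symmetric normalized GLCM by pixel-pair enumeration
bf_glcm <- function(q, offset) {
  z <- q$quantized
  G <- q$levels
  M <- matrix(0, G, G)
  for (r in seq_len(nrow(z))) for (c in seq_len(ncol(z))) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 < 1 || r2 > nrow(z) || c2 < 1 || c2 > ncol(z)) next
    a <- z[r, c]; b <- z[r2, c2]
    if (is.na(a) || is.na(b)) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M / sum(M)
}

# brute-force run enumeration along rows
bf_runs <- function(q) {
  z <- q$quantized
  lev <- integer(0); len <- integer(0)
  for (r in seq_len(nrow(z))) {
    cur <- NA; n <- 0
    for (c in seq_len(ncol(z) + 1)) {
      v <- if (c <= ncol(z)) z[r, c] else NA
      if (!is.na(v) && !is.na(cur) && v == cur) {
        n <- n + 1
      } else {
        if (!is.na(cur)) { lev <- c(lev, cur); len <- c(len, n) }
        cur <- v; n <- 1
      }
    }
  }
  list(level = lev, length = len)
}

bf_glrlm_features <- function(q) {
  runs <- bf_runs(q)
  i <- as.numeric(runs$level); l <- as.numeric(runs$length)
  nr <- length(i); np <- sum(!is.na(q$quantized))
  c(glrlm_sre = sum(1 / l^2) / nr, glrlm_lre = sum(l^2) / nr,
    glrlm_gln = sum(tapply(rep(1, nr), i, sum)^2) / nr,
    glrlm_rln = sum(tapply(rep(1, nr), l, sum)^2) / nr,
    glrlm_rp = nr / np,
    glrlm_lgre = sum(1 / i^2) / nr, glrlm_hgre = sum(i^2) / nr,
    glrlm_srlge = sum(1 / (i^2 * l^2)) / nr,
    glrlm_srhge = sum(i^2 / l^2) / nr,
    glrlm_lrlge = sum(l^2 / i^2) / nr,
    glrlm_lrhge = sum(i^2 * l^2) / nr)
}

# all-pairs AUC with half credit for ties
bf_auc <- function(scores, y) {
  xs <- scores[y == 1]; ys <- scores[y == 0]
  tot <- 0
  for (a in xs) for (b in ys)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(xs) * length(ys))
}

# direct 2D correlation with reflect padding, double loop
bf_filter2 <- function(x, krow, kcol) {
  k2 <- length(krow) %/% 2
  xp <- ipmnrad:::pad_reflect(x, k2)
  out <- matrix(0, nrow(x), ncol(x))
  for (r in seq_len(nrow(x))) for (c in seq_len(ncol(x))) {
    acc <- 0
    for (a in seq_along(krow)) for (b in seq_along(kcol))
      acc <- acc + krow[a] * kcol[b] * xp[r + a - 1, c + b - 1]
    out[r, c] <- acc
  }
  out
}

# maximum-likelihood logistic fit through a generic optimizer
bf_logistic <- function(x, y) {
  nll <- function(beta) {
    eta <- beta[1] + beta[2] * x
    -sum(y * eta - log(1 + exp(eta)))
  }
  opt <- optim(c(0, 0), nll, method = "BFGS", hessian = TRUE,
               control = list(reltol = 1e-14, maxit = 1000))
  se <- sqrt(diag(solve(opt$hessian)))
  list(coef = opt$par, se = se)
}

# random quantized ROI on a random mask (for property sweeps)
random_quantized_roi <- function(nr, nc, levels) {
  repeat {
    mask <- matrix(runif(nr * nc) < 0.7, nr, nc)
    if (sum(mask) >= 2) break
  }
  z <- matrix(NA_integer_, nr, nc)
  z[mask] <- sample.int(levels, sum(mask), replace = TRUE)
  structure(list(levels = levels, quantized = z), class = "quantized_roi")
}

# fast all-flags-only cohort settings (small lesions, small frame)
small_cohort_config <- function(n_benign, n_malignant, seed = 1L, ...) {
  small <- function(label) generator_params(
    label, cyst_diameter_mean_cm = 1.0, cyst_diameter_sd_cm = 0.2,
    cyst_diameter_range_cm = c(0.7, 1.4), ...)
  cohort_config(n_benign = n_benign, n_malignant = n_malignant,
                pixel_size_cm = 0.08, image_side = 32L, seed = seed,
                benign = small("benign"), malignant = small("malignant"))
}
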