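#' Wavelet subband statistics
#'
#' A 3-level separable discrete wavelet transform (Daubechies-2, symmetric
#' extension) of the masked bounding box, with out-of-mask pixels replaced
#' by the in-mask mean.  For each of the 9 detail subbands (horizontal,
#' vertical, diagonal at levels 1-3) the mean absolute coefficient, the
#' mean squared coefficient ("energy") and the entropy of the 64-bin
#' coefficient-magnitude histogram are returned; the final approximation
#' contributes its energy and entropy; three summary ratios complete the
#' 32-vector: total detail energy (sum of squared detail coefficients),
#' the fraction of detail energy in level-3 subbands, and the ratio of
#' level-1 to level-3 detail energy.  Ratios are 0 by convention when a
#' denominator vanishes (e.g. a constant ROI).
#'
#' @param img a [lesion_image()].
#' @param levels number of decomposition levels.
#' @return named numeric vector of length 32.
#' @export
wavelet_features <- function(img, levels = 3L) {
  stopifnot(inherits(img, "lesion_image"))
  bb <- mask_bbox(img$mask)
  m <- img$mask[bb$rows, bb$cols, drop = FALSE]
  x <- img$intensity[bb$rows, bb$cols, drop = FALSE]
  x[!m] <- mean(x[m])
  if (nrow(x) < 4L || ncol(x) < 4L) {
    warning("bounding box smaller than wavelet filter support; padding")
    while (nrow(x) < 4L) x <- rbind(x, x[nrow(x):1, , drop = FALSE])[1:max(4L, nrow(x)), , drop = FALSE]
    while (ncol(x) < 4L) x <- cbind(x, x[, ncol(x):1, drop = FALSE])[, 1:max(4L, ncol(x)), drop = FALSE]
  }
  out <- numeric(0)
  sub_energy_sum <- matrix(0, levels, 3,
                           dimnames = list(NULL, c("h", "v", "d")))
  ll <- x
  for (lev in seq_len(levels)) {
    dec <- dwt2_step(ll)
    for (ori in c("h", "v", "d")) {
      co <- as.numeric(dec[[ori]])
      sub_energy_sum[lev, ori] <- sum(co^2)
      st <- c(mean(abs(co)), mean(co^2), entropy_bits(roi_histogram(abs(co), 64L)))
      names(st) <- sprintf("wav_l%d_%s_%s", lev, ori,
                           c("absmean", "energy", "entropy"))
      out <- c(out, st)
    }
    ll <- dec$ll
  }
  appr <- as.numeric(ll)
  total_detail <- sum(sub_energy_sum)
  # guard against pure float residue of the zero-sum highpass on flat input
  eps <- 1e-12 * (sum(appr^2) + 1)
  if (total_detail <= eps) {
    total_detail <- 0
    sub_energy_sum[] <- 0
  }
  l3 <- sum(sub_energy_sum[levels, ])
  l1 <- sum(sub_energy_sum[1, ])
  c(out,
    wav_approx_energy = mean(appr^2),
    wav_approx_entropy = entropy_bits(roi_histogram(abs(appr), 64L)),
    wav_detail_energy_total = total_detail,
    wav_level3_energy_fraction = if (total_detail > 0) l3 / total_detail else 0,
    wav_l1_l3_energy_ratio = if (l3 > 0) l1 / l3 else 0)
}

db2_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  list(h = h, g = g)
}

# one analysis step of the 1D DWT with half-sample symmetric extension
dwt1_step <- function(v, f) {
  n <- length(v)
  left <- v[pmin(n, 3:1)]
  right <- v[pmax(1, n:(n - 2))]
  vp <- c(left, v, right)
  starts <- seq(1L, by = 2L, length.out = ceiling(n / 2))
  f[1] * vp[starts] + f[2] * vp[starts + 1] +
    f[3] * vp[starts + 2] + f[4] * vp[starts + 3]
}

# filter every column of x along the row index, keeping columns
dwt_dim1 <- function(x, f) {
  k <- ceiling(nrow(x) / 2)
  matrix(vapply(seq_len(ncol(x)), function(j) dwt1_step(x[, j], f),
                numeric(k)), nrow = k)
}

# one 2D analysis step: ll approximation, h/v/d details.  "v" (vertical
# detail) is highpass along the column index, so it responds to vertical
# edges; "h" is highpass along the row index.
dwt2_step <- function(x) {
  fl <- db2_filters()
  lo1 <- dwt_dim1(x, fl$h)            # lowpass down columns
  hi1 <- dwt_dim1(x, fl$g)            # highpass down columns
  ll <- t(dwt_dim1(t(lo1), fl$h))
  dv <- t(dwt_dim1(t(lo1), fl$g))
  dh <- t(dwt_dim1(t(hi1), fl$h))
  dd <- t(dwt_dim1(t(hi1), fl$g))
  list(ll = as.matrix(ll), h = as.matrix(dh),
       v = as.matrix(dv), d = as.matrix(dd))
}
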