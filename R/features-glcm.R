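#' Gray-level co-occurrence matrix at one offset
#'
#' Counts co-occurring gray-level pairs `(q[r, c], q[r + dr, c + dc])` for
#' pixel pairs that both lie inside the mask, symmetrizes (each pair is
#' counted in both directions) and normalizes to sum 1.
#'
#' @param q a [quantize()]d ROI.
#' @param offset integer pair `(dr, dc)`, not both zero; distance-1 unit
#'   offsets `(0,1)`, `(-1,1)`, `(-1,0)`, `(-1,-1)` correspond to the 0,
#'   45, 90 and 135 degree directions.
#' @return a G x G matrix summing to 1.
#' @export
glcm <- function(q, offset = c(0L, 1L)) {
  stopifnot(inherits(q, "quantized_roi"))
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  if (dr == 0L && dc == 0L) stop("offset must be nonzero")
  z <- q$quantized
  nr <- nrow(z); nc <- ncol(z)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- z[r1, c1, drop = FALSE]
  b <- z[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no valid in-mask pixel pairs for this offset")
  G <- q$levels
  tab <- matrix(0, G, G)
  counts <- table(factor(a[ok], levels = 1:G), factor(b[ok], levels = 1:G))
  tab <- tab + counts
  tab <- tab + t(counts)          # symmetrize: count both directions
  unclass(tab / sum(tab))
}

#' Haralick-style co-occurrence features
#'
#' Sixteen scalar statistics of the gray-level co-occurrence matrix.  By
#' default the four distance-1 GLCMs (0, 45, 90, 135 degrees) are averaged
#' into a single matrix before the statistics are taken, making the
#' features invariant to 90/180-degree image rotations.  Entropies are in
#' bits.  Correlation is 0 by convention when a marginal variance is zero.
#'
#' @param q a [quantize()]d ROI.
#' @param offsets list of `(dr, dc)` offsets whose GLCMs are averaged.
#' @return named numeric vector of length 16.
#' @export
glcm_features <- function(q, offsets = list(c(0L, 1L), c(-1L, 1L),
                                            c(-1L, 0L), c(-1L, -1L))) {
  mats <- lapply(offsets, function(o) glcm(q, o))
  p <- Reduce(`+`, mats) / length(mats)
  G <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)   # equal, p is symmetric
  mu_x <- sum((1:G) * px); mu_y <- sum((1:G) * py)
  sd_x <- sqrt(sum(((1:G) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((1:G) - mu_y)^2 * py))

  contrast <- sum((i - j)^2 * p)
  energy <- sum(p^2)
  entropy <- entropy_bits(p)
  homogeneity <- sum(p / (1 + (i - j)^2))
  dissimilarity <- sum(abs(i - j) * p)
  correlation <- if (sd_x > 0 && sd_y > 0)
    sum((i - mu_x) * (j - mu_y) * p) / (sd_x * sd_y) else 0
  max_prob <- max(p)

  # sum / difference distributions
  s <- i + j                           # 2 .. 2G
  d <- abs(i - j)                      # 0 .. G-1
  p_sum <- vapply(2:(2 * G), function(k) sum(p[s == k]), numeric(1))
  p_dif <- vapply(0:(G - 1), function(k) sum(p[d == k]), numeric(1))
  sum_avg <- sum((2:(2 * G)) * p_sum)
  sum_var <- sum(((2:(2 * G)) - sum_avg)^2 * p_sum)
  sum_ent <- entropy_bits(p_sum)
  dif_avg <- sum((0:(G - 1)) * p_dif)
  dif_var <- sum(((0:(G - 1)) - dif_avg)^2 * p_dif)
  dif_ent <- entropy_bits(p_dif)

  cluster_shade <- sum((i + j - mu_x - mu_y)^3 * p)
  cluster_prom <- sum((i + j - mu_x - mu_y)^4 * p)

  # information measures of correlation
  hx <- entropy_bits(px); hy <- entropy_bits(py)
  pxy_ind <- outer(px, py)
  nz <- p > 0 & pxy_ind > 0
  hxy1 <- -sum(p[nz] * log2(pxy_ind[nz]))
  hxy2 <- entropy_bits(pxy_ind)
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2_arg <- 1 - exp(-2 * log(2) * (hxy2 - entropy))
  imc2 <- sqrt(max(0, imc2_arg))

  c(glcm_contrast = contrast, glcm_energy = energy, glcm_entropy = entropy,
    glcm_homogeneity = homogeneity, glcm_dissimilarity = dissimilarity,
    glcm_correlation = correlation, glcm_max_probability = max_prob,
    glcm_sum_average = sum_avg, glcm_sum_variance = sum_var,
    glcm_sum_entropy = sum_ent, glcm_difference_variance = dif_var,
    glcm_difference_entropy = dif_ent, glcm_cluster_shade = cluster_shade,
    glcm_cluster_prominence = cluster_prom, glcm_imc1 = imc1,
    glcm_imc2 = imc2)
}
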