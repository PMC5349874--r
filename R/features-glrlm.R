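#' Gray-level run-length features (0-degree direction)
#'
#' Runs are maximal horizontal stretches of equal gray level inside the
#' mask; a run ends at a mask boundary or a level change.  Eleven standard
#' run-length statistics are returned, normalized by the total number of
#' runs (and by the pixel count for run percentage).
#'
#' @param q a [quantize()]d ROI.
#' @return named numeric vector of length 11: short/long run emphasis
#'   (`glrlm_sre`, `glrlm_lre`), gray-level and run-length non-uniformity
#'   (`glrlm_gln`, `glrlm_rln`), run percentage (`glrlm_rp`), low/high
#'   gray-level run emphasis (`glrlm_lgre`, `glrlm_hgre`) and the four
#'   joint emphases (`glrlm_srlge`, `glrlm_srhge`, `glrlm_lrlge`,
#'   `glrlm_lrhge`).
#' @export
glrlm_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  z <- q$quantized
  runs_level <- integer(0)
  runs_len <- integer(0)
  for (r in seq_len(nrow(z))) {
    row <- z[r, ]
    if (all(is.na(row))) next
    # NA (out of mask) breaks runs; encode NA as level 0 then drop
    enc <- ifelse(is.na(row), 0L, row)
    rl <- rle(enc)
    keep <- rl$values > 0L
    runs_level <- c(runs_level, rl$values[keep])
    runs_len <- c(runs_len, rl$lengths[keep])
  }
  n_runs <- length(runs_level)
  if (n_runs == 0L) stop("empty mask: no runs")
  n_px <- sum(!is.na(z))
  i <- as.numeric(runs_level)
  l <- as.numeric(runs_len)
  c(glrlm_sre = sum(1 / l^2) / n_runs,
    glrlm_lre = sum(l^2) / n_runs,
    glrlm_gln = sum(tapply(rep(1, n_runs), i, sum)^2) / n_runs,
    glrlm_rln = sum(tapply(rep(1, n_runs), l, sum)^2) / n_runs,
    glrlm_rp = n_runs / n_px,
    glrlm_lgre = sum(1 / i^2) / n_runs,
    glrlm_hgre = sum(i^2) / n_runs,
    glrlm_srlge = sum(1 / (i^2 * l^2)) / n_runs,
    glrlm_srhge = sum(i^2 / l^2) / n_runs,
    glrlm_lrlge = sum(l^2 / i^2) / n_runs,
    glrlm_lrhge = sum(i^2 * l^2) / n_runs)
}
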