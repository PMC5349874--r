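#' Size, shape and location features
#'
#' Eighteen non-texture descriptors of the binary ROI.  Lengths suffixed
#' `_px`/`_cm2` indicate units; moment-based axis lengths follow the
#' regionprops convention (4 * sqrt(eigenvalue) of the pixel-coordinate
#' covariance).  The largest-enclosed-circle radius is the maximum of the
#' Euclidean distance transform.  The Fourier descriptor is the fraction
#' of boundary-radius-signature spectral energy above the second harmonic
#' (64-point angular resampling), so it is ~0 for circles and ellipses and
#' grows with boundary irregularity.
#'
#' @param img a [lesion_image()].
#' @return named numeric vector of length 18.
#' @export
shape_features <- function(img) {
  stopifnot(inherits(img, "lesion_image"))
  mask <- img$mask
  assert_connected(mask)
  ps <- img$pixel_size_cm
  area <- sum(mask)
  idx <- which(mask, arr.ind = TRUE)
  rr <- idx[, 1]; cc <- idx[, 2]

  # boundary pixels: in-mask pixels with an out-of-mask 4/8-neighbour
  bmask <- boundary_pixels(mask)
  border_len <- sum(bmask)
  perim <- crofton_perimeter(mask)

  # second moments (add 1/12 for pixel extent, as in regionprops)
  mu_r <- mean(rr); mu_c <- mean(cc)
  crr <- mean((rr - mu_r)^2) + 1 / 12
  ccc <- mean((cc - mu_c)^2) + 1 / 12
  crc <- mean((rr - mu_r) * (cc - mu_c))
  tr <- crr + ccc
  det <- crr * ccc - crc^2
  l1 <- tr / 2 + sqrt(max(0, tr^2 / 4 - det))
  l2 <- tr / 2 - sqrt(max(0, tr^2 / 4 - det))
  major <- 4 * sqrt(max(0, l1))
  minor <- 4 * sqrt(max(0, l2))

  bbh <- diff(range(rr)) + 1
  bbw <- diff(range(cc)) + 1

  hull <- grDevices::chull(cc, rr)
  hx <- cc[hull]; hy <- rr[hull]
  hull_perim <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  # pixel-center polygon area plus boundary band (Pick-style correction)
  hull_area <- polygon_area(hx, hy) + hull_perim / 2 + 1

  dmax <- max(EBImage::distmap(EBImage::Image(mask * 1)))

  fd <- fourier_descriptor(mask, n_points = 64L)

  c(shape_area_px = area,
    shape_area_cm2 = area * ps^2,
    shape_equiv_diameter_px = 2 * sqrt(area / pi),
    shape_border_length_px = border_len,
    shape_perimeter_px = perim,
    shape_major_axis_px = major,
    shape_minor_axis_px = minor,       # "Width"
    shape_bbox_height_px = bbh,
    shape_bbox_width_px = bbw,
    shape_compactness = 4 * pi * area / perim^2,
    shape_eccentricity = if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0,
    shape_solidity = min(1, area / hull_area),
    shape_extent = area / (bbh * bbw),
    shape_inscribed_radius_px = dmax,
    shape_centroid_row_offset_px = mu_r - (nrow(mask) + 1) / 2,
    shape_centroid_col_offset_px = mu_c - (ncol(mask) + 1) / 2,
    shape_fourier_descriptor = fd,
    shape_aspect_ratio = if (minor > 0) major / minor else 1)
}

boundary_pixels <- function(mask) {
  padded <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  inner <- padded
  nr <- nrow(padded); nc <- ncol(padded)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(FALSE, nr, nc)
    shifted[pmax(1, 1 + dr):pmin(nr, nr + dr),
            pmax(1, 1 + dc):pmin(nc, nc + dc)] <-
      padded[pmax(1, 1 - dr):pmin(nr, nr - dr),
             pmax(1, 1 - dc):pmin(nc, nc - dc)]
    inner <- inner & shifted
  }
  (padded & !inner)[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
}

# Crofton perimeter estimate from chord (intercept) counts in 4
# directions; each chord produces two transitions, hence the halving
crofton_perimeter <- function(mask) {
  h <- count_transitions(mask) / 2
  v <- count_transitions(t(mask)) / 2
  d1 <- count_diag_transitions(mask, 1L) / 2
  d2 <- count_diag_transitions(mask[nrow(mask):1, , drop = FALSE], 1L) / 2
  (pi / 4) * (h + v + (d1 + d2) / sqrt(2))
}

count_transitions <- function(mask) {
  m <- cbind(FALSE, mask, FALSE)
  sum(m[, -1] != m[, -ncol(m)])
}

count_diag_transitions <- function(mask, d) {
  nr <- nrow(mask); nc <- ncol(mask)
  n <- 0L
  for (s in (-nr + 1):(nc - 1)) {
    r <- seq_len(nr)
    c <- r + s
    ok <- c >= 1 & c <= nc
    if (!any(ok)) next
    line <- c(FALSE, mask[cbind(r[ok], c[ok])], FALSE)
    n <- n + sum(line[-1] != line[-length(line)])
  }
  n
}

polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# radius signature of the boundary, resampled at n_points angles, and the
# fraction of its spectral energy above harmonic 2
fourier_descriptor <- function(mask, n_points = 64L) {
  b <- which(boundary_pixels(mask), arr.ind = TRUE)
  idx <- which(mask, arr.ind = TRUE)
  mu_r <- mean(idx[, 1]); mu_c <- mean(idx[, 2])
  th <- atan2(b[, 1] - mu_r, b[, 2] - mu_c)
  rad <- sqrt((b[, 1] - mu_r)^2 + (b[, 2] - mu_c)^2)
  o <- order(th)
  th <- th[o]; rad <- rad[o]
  # wrap for periodic interpolation
  th2 <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  rad2 <- c(rad[length(rad)], rad, rad[1])
  grid <- seq(-pi, pi, length.out = n_points + 1)[1:n_points]
  sig <- stats::approx(th2, rad2, xout = grid, ties = mean)$y
  co <- stats::fft(sig) / n_points
  # share of total signature power (DC included) above harmonic 2: ~0 for
  # circles and ellipses, grows with boundary irregularity
  mag2 <- Mod(co[1:(n_points / 2 + 1)])^2
  tot <- sum(mag2)
  if (tot < 1e-12) return(0)
  sum(mag2[-(1:3)]) / tot
}
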