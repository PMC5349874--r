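#' Laws texture energy features
#'
#' The in-mask intensities are mean-subtracted (out-of-mask pixels in the
#' bounding box are set to zero, i.e. the in-mask mean), the bounding box
#' is filtered with all 25 separable 5x5 kernels formed as outer products
#' of the 1D Laws kernels (Level, Edge, Spot, Ripple, Wave) with reflect
#' padding, and the energy of each response is the mean squared response
#' over in-mask pixels.
#'
#' @param img a [lesion_image()].
#' @return named numeric vector of length 25 (`laws_L5E5_energy` is the
#'   kernel with L5 applied along rows and E5 along columns, etc.).
#' @export
laws_features <- function(img) {
  stopifnot(inherits(img, "lesion_image"))
  kernels <- laws_kernels()
  bb <- mask_bbox(img$mask)
  m <- img$mask[bb$rows, bb$cols, drop = FALSE]
  x <- img$intensity[bb$rows, bb$cols, drop = FALSE]
  x <- x - mean(x[m])
  x[!m] <- 0
  out <- numeric(25)
  names_out <- character(25)
  k <- 1L
  for (a in names(kernels)) {
    for (b in names(kernels)) {
      resp <- sep_filter2(x, kernels[[a]], kernels[[b]])
      out[k] <- mean(resp[m]^2)
      names_out[k] <- sprintf("laws_%s%s_energy", a, b)
      k <- k + 1L
    }
  }
  names(out) <- names_out
  out
}

laws_kernels <- function() {
  list(L5 = c(1, 4, 6, 4, 1),
       E5 = c(-1, -2, 0, 2, 1),
       S5 = c(-1, 0, 2, 0, -1),
       R5 = c(1, -4, 6, -4, 1),
       W5 = c(-1, 2, 0, -2, 1))
}

mask_bbox <- function(mask) {
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  list(rows = rr[1]:rr[2], cols = cc[1]:cc[2])
}

# reflect (half-sample symmetric) padding by k on every side
pad_reflect <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(pmin(nr, pmax(1, k:1)), 1:nr, pmin(nr, pmax(1, nr:(nr - k + 1))))
  ci <- c(pmin(nc, pmax(1, k:1)), 1:nc, pmin(nc, pmax(1, nc:(nc - k + 1))))
  x[ri, ci, drop = FALSE]
}

# separable same-size filtering (correlation): krow along the row index,
# kcol along the column index; reflect boundary
sep_filter2 <- function(x, krow, kcol) {
  stopifnot(length(krow) == 5L, length(kcol) == 5L)
  xp <- pad_reflect(x, 2L)
  nr <- nrow(x); nc <- ncol(x)
  tmp <- matrix(0, nrow(xp), nc)
  for (b in 1:5) tmp <- tmp + kcol[b] * xp[, b:(b + nc - 1), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (a in 1:5) out <- out + krow[a] * tmp[a:(a + nr - 1), , drop = FALSE]
  out
}
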