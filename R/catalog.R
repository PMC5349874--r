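#' The 112-feature radiomic catalog
#'
#' The ordered registry of all features emitted by [extract_all()]:
#' 18 size/shape, 10 histogram, 27 co-occurrence/run-length (16 GLCM +
#' 11 GLRLM) and 57 Laws/wavelet (25 Laws + 32 wavelet) features, for a
#' total of 112 (18 non-texture + 94 texture).  The ordering is stable
#' across runs and versions; compute parameters (gray levels, offsets,
#' wavelet basis) are recorded per feature.
#'
#' @param levels gray-level count used by the matrix features.
#' @return a data.frame of class `feature_catalog` with columns
#'   `feature_id`, `family` and `parameters`.
#' @export
feature_catalog <- function(levels = 64L) {
  dummy <- lesion_image(matrix(c(0, 1, 2, 3, 4, 5, 6, 7, 8), 3, 3),
                        matrix(1, 3, 3), 0.1)
  q <- quantize(dummy, levels = 4L)
  ids <- list(
    shape_size = names(shape_features(dummy)),
    histogram = names(histogram_features(dummy)),
    cooccurrence_runlength = c(names(glcm_features(q)),
                               names(glrlm_features(q))),
    laws_wavelet = c(names(laws_features(dummy)),
                     suppressWarnings(names(wavelet_features(dummy))))
  )
  params <- c(
    shape_size = "boundary=8-connected; perimeter=crofton4",
    histogram = "bins=64",
    cooccurrence_runlength =
      sprintf("G=%d; glcm: distance=1, directions=0/45/90/135 averaged; glrlm: direction=0", levels),
    laws_wavelet = "laws: 5x5 separable, reflect; wavelet: db2, symmetric, levels=3"
  )
  cat <- do.call(rbind, lapply(names(ids), function(fam) {
    data.frame(feature_id = ids[[fam]], family = fam,
               parameters = unname(params[fam]))
  }))
  rownames(cat) <- NULL
  class(cat) <- c("feature_catalog", "data.frame")
  cat
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat(sprintf("<feature_catalog> %d features: %s\n", nrow(x),
              paste(sprintf("%s(%d)", names(table(x$family)[unique(x$family)]),
                            table(x$family)[unique(x$family)]),
                    collapse = ", ")))
  invisible(x)
}

#' Write the catalog as JSON
#' @param catalog a [feature_catalog()].
#' @param path output file.
#' @export
write_catalog_json <- function(catalog, path) {
  jsonlite::write_json(as.data.frame(catalog), path, pretty = TRUE)
  invisible(path)
}

#' Extract the full 112-feature radiomic vector from one lesion
#'
#' Runs every feature family in catalog order.  Matrix features use the
#' gray-level count recorded in the catalog (default 64, equal-width
#' range-relative quantization, so they are invariant to intensity
#' shifts).
#'
#' @param img a [lesion_image()].
#' @param catalog a [feature_catalog()]; used to validate ordering.
#' @param levels gray levels for the quantized-matrix families.
#' @return named numeric vector of length 112 in catalog order.
#' @export
extract_all <- function(img, catalog = feature_catalog(), levels = 64L) {
  stopifnot(inherits(img, "lesion_image"))
  if (sum(img$mask) < 25)
    stop("mask has fewer than 25 pixels; texture features unreliable")
  q <- quantize(img, levels = levels)
  fam <- function(name, vals) {
    if (any(!is.finite(vals)))
      stop(sprintf("non-finite %s feature(s): %s", name,
                   paste(names(vals)[!is.finite(vals)], collapse = ", ")))
    vals
  }
  v <- c(fam("shape", shape_features(img)),
         fam("histogram", histogram_features(img)),
         fam("glcm", glcm_features(q)),
         fam("glrlm", glrlm_features(q)),
         fam("laws", laws_features(img)),
         fam("wavelet", wavelet_features(img)))
  if (!identical(names(v), catalog$feature_id))
    stop("extracted features do not match catalog ordering")
  v
}

#' Extract features for every case of a cohort
#'
#' @param cohort an `ipmn_cohort` from [generate_cohort()] or
#'   [read_cohort()].
#' @param catalog a [feature_catalog()].
#' @return a data.frame with `case_id` plus one column per catalog
#'   feature; cases whose extraction fails (e.g. missing image) are
#'   dropped with a message, mirroring incomplete real-world extraction.
#' @export
extract_cohort_features <- function(cohort, catalog = feature_catalog()) {
  stopifnot(inherits(cohort, "ipmn_cohort"))
  rows <- lapply(cohort$cases, function(cs) {
    if (is.null(cs$image)) return(NULL)
    v <- tryCatch(extract_all(cs$image, catalog),
                  error = function(e) NULL)
    if (is.null(v)) return(NULL)
    cbind(data.frame(case_id = cs$case_id), as.data.frame(t(v)))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    message(sprintf("radiomic features could not be extracted for %d case(s); dropped",
                    dropped))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
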