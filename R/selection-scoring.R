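#' Greedy Pearson redundancy filter
#'
#' Walks the feature columns in catalog order and drops a feature iff its
#' absolute Pearson correlation with any already-kept feature exceeds
#' `threshold`.  Deterministic and order-stable; zero-variance columns
#' are dropped first with a warning.
#'
#' @param x numeric matrix or data.frame of features (cases x features).
#' @param threshold absolute-correlation cutoff in (0, 1); default 0.90.
#' @return character vector of kept feature names, in input order.
#' @export
pearson_filter <- function(x, threshold = 0.90) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 cases")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance feature(s)", sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
  }
  kept <- character(0)
  for (f in colnames(x)) {
    if (length(kept) == 0) { kept <- f; next }
    r <- suppressWarnings(abs(stats::cor(x[, f], x[, kept, drop = FALSE])))
    if (all(r <= threshold, na.rm = TRUE)) kept <- c(kept, f)
  }
  kept
}

#' Univariate logistic screening of one feature
#'
#' Maximum-likelihood simple logistic regression of the binary label on
#' the (by default standardized) feature, with Wald 95% CI and p-value,
#' plus the feature's own AUC as a univariate classifier.  Under complete
#' or quasi-complete separation the fit falls back to Firth's
#' bias-reduced penalized likelihood and the result is flagged.
#'
#' @param x numeric feature vector.
#' @param y labels: logical/0-1/factor with the second level as the
#'   positive (malignant) class.
#' @param standardize scale `x` to zero mean, unit SD before fitting so
#'   the odds ratio is per-SD.
#' @return one-row data.frame: `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `auc`, `penalized`.
#' @export
univariate_logistic <- function(x, y, standardize = TRUE) {
  y <- as_binary_label(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (standardize) {
    if (stats::sd(x) == 0) stop("constant feature cannot be standardized")
    x <- (x - mean(x)) / stats::sd(x)
  }
  X <- cbind(1, x)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  sep <- !fit$converged || any(fit$fitted.values > 1 - 1e-8) ||
    any(fit$fitted.values < 1e-8) || abs(fit$coefficients[2]) > 15
  if (sep) {
    ff <- firth_logistic(X, y)
    beta <- ff$coef[2]; se <- ff$se[2]
  } else {
    beta <- fit$coefficients[2]
    w <- fit$weights
    se <- sqrt(diag(solve(crossprod(X, X * w))))[2]
  }
  z <- beta / se
  data.frame(odds_ratio = exp(beta),
             ci_low = exp(beta - 1.96 * se),
             ci_high = exp(beta + 1.96 * se),
             p_value = 2 * stats::pnorm(-abs(z)),
             auc = auc_mann_whitney(x, y)$auc,
             penalized = sep)
}

#' Screen every feature of a table against the label
#'
#' @param x features (cases x features).
#' @param y labels (see [univariate_logistic()]).
#' @param standardize per-SD odds ratios (default TRUE).
#' @return data.frame of class `screening_result`, one row per feature,
#'   in input column order, with a `feature_id` column.
#' @export
screen_features <- function(x, y, standardize = TRUE) {
  x <- as.matrix(x)
  rows <- lapply(colnames(x), function(f)
    cbind(data.frame(feature_id = f),
          univariate_logistic(x[, f], y, standardize)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Select features significant at level alpha
#'
#' Unadjusted by default (no multiplicity correction); a
#' Benjamini-Hochberg option is available.  Input order (catalog order)
#' is preserved.
#'
#' @param results a [screen_features()] table.
#' @param alpha significance level in (0, 1).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return character vector of selected feature ids (possibly empty; an
#'   empty selection leaves the PC1 composite undefined downstream).
#' @export
select_significant <- function(results, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  p <- results$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  results$feature_id[p < alpha]
}

#' First-principal-component composite score
#'
#' Variables are z-scored, PCA is taken on the correlation scale, and
#' the PC1 sign is fixed so that the sum of loadings is positive
#' (deterministic orientation; the observed class direction is reported,
#' not forced).
#'
#' @param x numeric matrix/data.frame (cases x variables), >= 2 variables
#'   and >= 3 cases; constant variables are an error.
#' @return object of class `pc_score`: `scores`, `loadings`,
#'   `variance_explained` (fraction for PC1), `orientation_sign`,
#'   `center`, `scale`.
#' @export
pca_pc1 <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need >= 2 variables")
  if (nrow(x) < 3) stop("need >= 3 cases")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("constant variable(s): ",
                          paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  s <- if (sum(pc$rotation[, 1]) >= 0) 1 else -1
  structure(list(
    scores = s * pc$x[, 1],
    loadings = s * pc$rotation[, 1],
    variance_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
    orientation_sign = s,
    center = pc$center, scale = pc$scale),
    class = "pc_score")
}

#' @export
print.pc_score <- function(x, ...) {
  cat(sprintf("<pc_score> %d cases, %d variables, PC1 explains %.1f%%\n",
              length(x$scores), length(x$loadings),
              100 * x$variance_explained))
  invisible(x)
}

#' Project new cases onto a fitted PC1
#' @param pc a [pca_pc1()] fit.
#' @param newdata matrix with the same variables.
#' @return numeric scores.
#' @export
predict_pc1 <- function(pc, newdata) {
  z <- scale(as.matrix(newdata)[, names(pc$loadings), drop = FALSE],
             center = pc$center, scale = pc$scale)
  drop(z %*% pc$loadings)
}

#' miRNA genomic classifier (MGC) score
#'
#' PC1 of the 5-miRNA log2-expression matrix; with default synthetic
#' cohorts the benign class has the higher mean score (its panel
#' expression is higher).
#'
#' @param mirna data.frame/matrix with the five [mirna_panel()] columns.
#' @return a `pc_score`.
#' @export
mgc_score <- function(mirna) {
  mirna <- as.data.frame(mirna)
  missing <- setdiff(mirna_panel(), colnames(mirna))
  if (length(missing))
    stop("missing miRNA column(s): ", paste(missing, collapse = ", "))
  pca_pc1(mirna[, mirna_panel()])
}

#' Firth bias-reduced logistic regression
#'
#' Penalized-likelihood IRLS with the Jeffreys-prior score correction;
#' used as the fallback when maximum likelihood separates.
#'
#' @param X design matrix (with intercept column).
#' @param y 0/1 response.
#' @param max_iter,tol iteration controls.
#' @return list with `coef`, `se`, `converged`.
#' @export
firth_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  ridge <- diag(1e-10, ncol(X))
  safe_inv <- function(M) tryCatch(solve(M), error = function(e)
    solve(M + diag(1e-6 * max(diag(M), 1), ncol(M))))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-12)
    XWX <- crossprod(X, X * w) + ridge
    XWX_inv <- safe_inv(XWX)
    # hat diagonal of W^(1/2) X (X'WX)^-1 X' W^(1/2)
    h <- rowSums((X %*% XWX_inv) * X) * w
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    delta <- drop(XWX_inv %*% U)
    # step-halving keeps the iteration inside the well-behaved region
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  XWX <- crossprod(X, X * pmax(p * (1 - p), 1e-12)) + ridge
  se <- sqrt(pmax(diag(safe_inv(XWX)), 0))
  list(coef = beta, se = se, converged = it < max_iter)
}

as_binary_label <- function(y) {
  if (is.factor(y)) return(as.integer(y == levels(y)[2]))
  if (is.character(y)) {
    lv <- sort(unique(y))
    if (identical(lv, c("benign", "malignant")))
      return(as.integer(y == "malignant"))
    return(as.integer(y == lv[length(lv)]))
  }
  if (is.logical(y)) return(as.integer(y))
  if (all(y %in% c(0, 1))) return(as.integer(y))
  stop("labels must be binary")
}
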