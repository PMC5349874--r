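#' AUC with DeLong variance and 95% CI
#'
#' The AUC is the normalized Mann-Whitney U statistic (ties get half
#' credit); its variance comes from the DeLong structural components
#' (per-positive and per-negative placement values), and the Wald 95% CI
#' is clipped to \[0, 1\].
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param y binary labels (see [univariate_logistic()] for coding).
#' @return list: `auc`, `var`, `ci` (length 2), `n_pos`, `n_neg`.
#' @export
auc_mann_whitney <- function(scores, y) {
  y <- as_binary_label(y)
  xs <- scores[y == 1]; ys <- scores[y == 0]
  m <- length(xs); n <- length(ys)
  if (m == 0 || n == 0) stop("both classes must be present")
  cmp <- delong_placements(xs, ys)
  auc <- mean(cmp$v10)
  v <- (if (m > 1) stats::var(cmp$v10) / m else 0) +
       (if (n > 1) stats::var(cmp$v01) / n else 0)
  ci <- pmin(1, pmax(0, auc + c(-1.96, 1.96) * sqrt(v)))
  list(auc = auc, var = v, ci = ci, n_pos = m, n_neg = n)
}

# placement values: v10[i] = P-hat(score_pos_i > score_neg), v01[j] likewise
delong_placements <- function(xs, ys) {
  cmp <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp))
}

#' DeLong paired test for two correlated AUCs
#'
#' Two-sided test of AUC_A = AUC_B when both models score the same
#' cases, accounting for the pairing through the covariance of the
#' DeLong placement components.  A zero-variance difference (e.g.
#' identical or rank-identical scores) returns p = 1, flagged.
#'
#' @param scores_a,scores_b scores from the two models on the same cases.
#' @param y binary labels.
#' @return list: `auc_a`, `auc_b`, `z`, `p_value`, `flagged`.
#' @export
delong_paired_test <- function(scores_a, scores_b, y) {
  y <- as_binary_label(y)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(y))
    stop("scores and labels must align case-by-case")
  pos <- y == 1; neg <- y == 0
  if (!any(pos) || !any(neg)) stop("both classes must be present")
  pa <- delong_placements(scores_a[pos], scores_a[neg])
  pb <- delong_placements(scores_b[pos], scores_b[neg])
  m <- sum(pos); n <- sum(neg)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (v < 1e-14)
    return(list(auc_a = auc_a, auc_b = auc_b, z = 0, p_value = 1,
                flagged = TRUE))
  z <- (auc_a - auc_b) / sqrt(v)
  list(auc_a = auc_a, auc_b = auc_b, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), flagged = FALSE)
}

#' Youden-index optimal cutpoint
#'
#' Scans the midpoints of adjacent distinct scores and returns the
#' cutpoint maximizing J = sensitivity + specificity - 1 (classification
#' rule: score > cutpoint is called positive).  Ties are broken toward
#' higher specificity (the larger cutpoint).  If all scores are
#' identical, J = 0 and the common value is returned, flagged.
#'
#' @param scores numeric scores.
#' @param y binary labels.
#' @return list: `cutpoint`, `sens`, `spec`, `j`, `flagged`.
#' @export
youden_cutpoint <- function(scores, y) {
  y <- as_binary_label(y)
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) == 1)
    return(list(cutpoint = u, sens = 0, spec = 1, j = 0, flagged = TRUE))
  cands <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (ct in cands) {
    pred <- scores > ct
    sens <- mean(pred[y == 1])
    spec <- mean(!pred[y == 0])
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && ct > best$cutpoint))
      best <- list(cutpoint = ct, sens = sens, spec = spec, j = j,
                   flagged = FALSE)
  }
  best
}

#' Confusion-matrix diagnostic metrics
#'
#' @param tp,fn,fp,tn nonnegative integer cell counts (positives =
#'   malignant).
#' @return named numeric vector `sens`, `spec`, `ppv`, `npv`,
#'   `accuracy`; a metric with a zero denominator is `NA`.
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  c(sens = safe(tp, tp + fn),
    spec = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp),
    npv = safe(tn, tn + fn),
    accuracy = safe(tp + tn, tp + fn + fp + tn))
}

# ---- logistic fitting helpers -------------------------------------------

# ML logistic fit on a design matrix, Firth fallback on separation
logistic_fit <- function(X, y) {
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop("singular design; collinear predictor(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  sep <- !fit$converged || any(fit$fitted.values > 1 - 1e-8) ||
    any(fit$fitted.values < 1e-8) || any(abs(fit$coefficients[-1]) > 15)
  if (sep) {
    ff <- firth_logistic(X, y)
    list(coef = ff$coef, penalized = TRUE)
  } else {
    list(coef = fit$coefficients, penalized = FALSE)
  }
}

logistic_predict <- function(coef, X) {
  1 / (1 + exp(-drop(as.matrix(X) %*% coef)))
}

#' Predictor-set specification for one diagnostic model
#'
#' @param name model label.
#' @param predictors character vector of predictor blocks, from
#'   `"demographic"` (age, gender, symptoms), `"high_risk"`,
#'   `"worrisome"`, `"mgc"`, `"features_pc1"`.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(name, predictors) {
  known <- c("demographic", "high_risk", "worrisome", "mgc", "features_pc1")
  bad <- setdiff(predictors, known)
  if (length(predictors) == 0) stop("predictor set must be nonempty")
  if (length(bad)) stop("unknown predictor block(s): ",
                        paste(bad, collapse = ", "))
  structure(list(name = name, predictors = predictors),
            class = "model_spec")
}

#' The nine-model diagnostic suite
#'
#' The predictor sets evaluated side by side in the pipeline report:
#' demographic/clinical, high-risk stigmata, MGC, high-risk + MGC,
#' worrisome features, worrisome + MGC, radiomic PC1, radiomic PC1 +
#' MGC, and worrisome + radiomic PC1 + MGC.
#'
#' @return list of [model_spec()]s.
#' @export
model_suite <- function() {
  list(
    model_spec("demographic_clinical", "demographic"),
    model_spec("high_risk_stigmata", "high_risk"),
    model_spec("mgc", "mgc"),
    model_spec("high_risk_plus_mgc", c("high_risk", "mgc")),
    model_spec("worrisome_features", "worrisome"),
    model_spec("worrisome_plus_mgc", c("worrisome", "mgc")),
    model_spec("radiomic_pc1", "features_pc1"),
    model_spec("radiomic_pc1_plus_mgc", c("features_pc1", "mgc")),
    model_spec("worrisome_radiomic_pc1_mgc",
               c("worrisome", "features_pc1", "mgc")))
}

# expand predictor blocks into design-matrix columns of an analysis table
block_columns <- function(predictors) {
  cols <- c()
  for (p in predictors)
    cols <- c(cols, switch(p,
      demographic = c("age_years", "gender_male", "symptoms"),
      high_risk = "high_risk",
      worrisome = "worrisome",
      mgc = "mgc",
      features_pc1 = "features_pc1"))
  cols
}

#' Fit one diagnostic model and measure its performance
#'
#' ML logistic fit (Firth fallback on separation) of the label on the
#' requested predictor blocks; scores are fitted probabilities; the
#' operating point is the Youden cutpoint, at which the confusion-matrix
#' metrics are computed.  Cases with missing predictors are dropped with
#' a message (effective n is recorded).
#'
#' @param spec a [model_spec()].
#' @param data analysis table from [assemble_analysis_table()].
#' @return object of class `model_result`: `name`, `scores`, `auc`,
#'   `auc_ci_95`, `cutpoint`, `sens`, `spec`, `ppv`, `npv`, `accuracy`,
#'   `n`, `fit_flags`.
#' @export
fit_model <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  cols <- block_columns(spec$predictors)
  missing_cols <- setdiff(cols, colnames(data))
  if (length(missing_cols))
    stop("analysis table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  if (any(!keep))
    message(sprintf("%s: dropping %d case(s) with missing predictors",
                    spec$name, sum(!keep)))
  d <- data[keep, , drop = FALSE]
  y <- as_binary_label(d$label)
  constant <- cols[vapply(cols, function(cc)
    length(unique(d[[cc]])) < 2, logical(1))]
  if (length(constant)) {
    message(sprintf("%s: dropping constant predictor(s): %s", spec$name,
                    paste(constant, collapse = ", ")))
    cols <- setdiff(cols, constant)
    if (length(cols) == 0) stop("all predictors constant")
  }
  X <- cbind(intercept = 1, as.matrix(d[, cols, drop = FALSE]))
  fit <- logistic_fit(X, y)
  scores <- logistic_predict(fit$coef, X)
  a <- auc_mann_whitney(scores, y)
  yc <- youden_cutpoint(scores, y)
  pred <- scores > yc$cutpoint
  cm <- confusion_metrics(sum(pred & y == 1), sum(!pred & y == 1),
                          sum(pred & y == 0), sum(!pred & y == 0))
  structure(list(
    name = spec$name, spec = spec, coef = fit$coef,
    case_id = d$case_id, scores = scores,
    auc = a$auc, auc_ci_95 = a$ci, cutpoint = yc$cutpoint,
    sens = cm[["sens"]], spec_metric = cm[["spec"]], ppv = cm[["ppv"]],
    npv = cm[["npv"]], accuracy = cm[["accuracy"]],
    n = nrow(d), n_dropped = sum(!keep),
    fit_flags = list(penalized = fit$penalized,
                     degenerate_cutpoint = yc$flagged)),
    class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf(
    "<model_result> %s (n=%d%s): AUC %.2f (%.2f-%.2f), sens %.2f, spec %.2f, ppv %.2f, npv %.2f%s\n",
    x$name, x$n,
    if (x$n_dropped > 0) sprintf(", %d dropped", x$n_dropped) else "",
    x$auc, x$auc_ci_95[1], x$auc_ci_95[2], x$sens, x$spec_metric,
    x$ppv, x$npv, if (x$fit_flags$penalized) " [penalized]" else ""))
  invisible(x)
}

# ---- cross-validation ----------------------------------------------------

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# in-fold re-derivation of data-dependent predictors: MGC loadings and the
# radiomic filter/screen/PC1 are estimated on the training rows only
fold_design <- function(spec, data, features, train, test,
                        pearson_threshold, alpha) {
  cols <- block_columns(spec$predictors)
  tr <- data[train, , drop = FALSE]
  te <- data[test, , drop = FALSE]
  flags <- character(0)
  if ("mgc" %in% spec$predictors) {
    pc <- pca_pc1(tr[, mirna_panel()])
    tr$mgc <- pc$scores
    te$mgc <- predict_pc1(pc, te[, mirna_panel()])
  }
  if ("features_pc1" %in% spec$predictors) {
    Xtr <- as.matrix(features[train, , drop = FALSE])
    kept <- suppressWarnings(pearson_filter(Xtr, pearson_threshold))
    scr <- screen_features(Xtr[, kept, drop = FALSE], tr$label)
    sel <- select_significant(scr, alpha)
    if (length(sel) < 2) {
      flags <- c(flags, "min_p_fallback")
      sel <- scr$feature_id[order(scr$p_value)][1:2]
    }
    pc <- pca_pc1(Xtr[, sel, drop = FALSE])
    tr$features_pc1 <- pc$scores
    te$features_pc1 <- predict_pc1(
      pc, as.matrix(features[test, sel, drop = FALSE]))
  }
  list(train = tr[, c("label", cols)], test = te[, c("label", cols)],
       flags = flags)
}

#' Repeated stratified k-fold cross-validation of a diagnostic model
#'
#' For every repetition the cases are partitioned into `k` stratified
#' folds; all data-dependent steps (MGC PCA loadings, Pearson filter,
#' univariate screening, radiomic PC1 loadings, logistic coefficients)
#' are re-estimated on each training fold and applied to the held-out
#' fold; the pooled out-of-fold probabilities of the repetition give one
#' AUC and one set of Youden-cutpoint metrics.  The summary is the mean
#' and the 2.5/97.5 percentile interval over repetitions.
#'
#' @param spec a [model_spec()].
#' @param data analysis table from [assemble_analysis_table()] (raw
#'   miRNA columns must be present when the model uses the MGC).
#' @param features cases x 112 radiomic feature matrix aligned to
#'   `data` rows (required when the model uses `features_pc1`).
#' @param k folds (default 10).
#' @param reps repetitions (default 200; 10000 for a full run).
#' @param seed integer seed governing all partitions.
#' @param pearson_threshold,alpha in-fold selection settings.
#' @return object of class `cv_result`: `per_rep` (data.frame of
#'   out-of-fold metrics per repetition), `mean_auc`, `ci_95`, `k`,
#'   `reps`, `seed`, `n_fallback`.
#' @export
repeated_kfold_cv <- function(spec, data, features = NULL, k = 10L,
                              reps = 200L, seed = 1L,
                              pearson_threshold = 0.90, alpha = 0.05) {
  stopifnot(inherits(spec, "model_spec"))
  y <- as_binary_label(data$label)
  if (k > min(table(y)))
    stop("k exceeds the size of the smaller class")
  if ("features_pc1" %in% spec$predictors && is.null(features))
    stop("model uses features_pc1 but no feature matrix was given")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  per_rep <- vector("list", reps)
  n_fallback <- 0L
  for (r in seq_len(reps)) {
    fold <- NULL
    for (try in 1:25) {
      cand <- stratified_folds(y, k)
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(y[cand != f])) == 2, logical(1)))
      if (ok) { fold <- cand; break }
    }
    if (is.null(fold)) stop("could not build folds with both classes in training")
    oof <- numeric(length(y))
    for (f in seq_len(k)) {
      test <- which(fold == f)
      if (length(test) == 0) next
      train <- which(fold != f)
      des <- fold_design(spec, data, features, train, test,
                         pearson_threshold, alpha)
      n_fallback <- n_fallback + length(des$flags)
      ytr <- as_binary_label(des$train$label)
      Xtr <- cbind(1, as.matrix(des$train[, -1, drop = FALSE]))
      Xte <- cbind(1, as.matrix(des$test[, -1, drop = FALSE]))
      # a predictor can be constant within a training fold; drop it there
      keep_col <- c(TRUE, apply(Xtr[, -1, drop = FALSE], 2,
                                function(v) length(unique(v)) > 1))
      Xtr <- Xtr[, keep_col, drop = FALSE]
      Xte <- Xte[, keep_col, drop = FALSE]
      fit <- logistic_fit(Xtr, ytr)
      oof[test] <- logistic_predict(fit$coef, Xte)
    }
    a <- auc_mann_whitney(oof, y)
    yc <- youden_cutpoint(oof, y)
    pred <- oof > yc$cutpoint
    cm <- confusion_metrics(sum(pred & y == 1), sum(!pred & y == 1),
                            sum(pred & y == 0), sum(!pred & y == 0))
    per_rep[[r]] <- data.frame(rep = r, auc = a$auc, sens = cm[["sens"]],
                               spec = cm[["spec"]], ppv = cm[["ppv"]],
                               npv = cm[["npv"]],
                               accuracy = cm[["accuracy"]])
  }
  per_rep <- do.call(rbind, per_rep)
  structure(list(
    per_rep = per_rep,
    mean_auc = mean(per_rep$auc),
    ci_95 = unname(stats::quantile(per_rep$auc, c(0.025, 0.975))),
    k = k, reps = reps, seed = seed, n_fallback = n_fallback,
    model = spec$name),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s: %d x %d-fold CV, mean AUC %.3f (95%% CI %.3f-%.3f), seed %d\n",
    x$model, x$reps, x$k, x$mean_auc, x$ci_95[1], x$ci_95[2], x$seed))
  invisible(x)
}
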