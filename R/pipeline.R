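#' Radiomic composite score: filter, screen, PC1
#'
#' The three-stage reduction of the radiomic feature table: greedy
#' Pearson redundancy filter, per-feature univariate logistic screening,
#' and PC1 of the features significant at `alpha` (the "Features PC1"
#' composite).
#'
#' @param features cases x features numeric matrix/data.frame (no id
#'   column).
#' @param labels binary labels aligned to rows.
#' @param pearson_threshold redundancy cutoff (default 0.90).
#' @param alpha screening significance level (default 0.05).
#' @param min_p_fallback if no feature is significant, use the two
#'   smallest-p features instead of failing (used inside CV); default
#'   FALSE: an empty selection is an error.
#' @return list: `score` (a `pc_score`), `kept` (post-filter ids),
#'   `screening` (the [screen_features()] table), `selected`.
#' @export
radiomic_score <- function(features, labels, pearson_threshold = 0.90,
                           alpha = 0.05, min_p_fallback = FALSE) {
  X <- as.matrix(features)
  kept <- pearson_filter(X, pearson_threshold)
  scr <- screen_features(X[, kept, drop = FALSE], labels)
  sel <- select_significant(scr, alpha)
  if (length(sel) < 2) {
    if (!min_p_fallback)
      stop(sprintf(
        "only %d feature(s) significant at alpha=%g; Features PC1 undefined",
        length(sel), alpha))
    sel <- scr$feature_id[order(scr$p_value)][1:2]
  }
  list(score = pca_pc1(X[, sel, drop = FALSE]), kept = kept,
       screening = scr, selected = sel)
}

#' Assemble the per-case analysis table for the model suite
#'
#' Joins clinical flags, the MGC score (PC1 of the 5-miRNA panel over
#' all cases) and, when a feature table is supplied, the Features PC1
#' composite (cases without extracted features get `NA` and are dropped
#' only from models that use radiomics).
#'
#' @param cohort an `ipmn_cohort` (only its `table` is used), or a
#'   compatible per-case data.frame.
#' @param features optional output of [extract_cohort_features()].
#' @param pearson_threshold,alpha settings for [radiomic_score()].
#' @return data.frame with `case_id`, `label`, `age_years`,
#'   `gender_male`, `symptoms`, `high_risk`, `worrisome`, `main_duct`,
#'   the five miRNA columns, `mgc`, and (if features given)
#'   `features_pc1`; carries the fitted scorers as attributes
#'   `mgc_fit` and `radiomic_fit`.
#' @export
assemble_analysis_table <- function(cohort, features = NULL,
                                    pearson_threshold = 0.90, alpha = 0.05) {
  tab <- if (inherits(cohort, "ipmn_cohort")) cohort$table else cohort
  d <- tab
  d$gender_male <- as.integer(d$gender == "M")
  mgc <- mgc_score(d[, mirna_panel()])
  d$mgc <- unname(mgc$scores)
  rad <- NULL
  if (!is.null(features)) {
    fx <- features[match(d$case_id, features$case_id), , drop = FALSE]
    X <- as.matrix(fx[, setdiff(colnames(fx), "case_id"), drop = FALSE])
    have <- !is.na(fx$case_id)
    rad <- radiomic_score(X[have, , drop = FALSE], d$label[have],
                          pearson_threshold, alpha)
    d$features_pc1 <- NA_real_
    d$features_pc1[have] <- unname(rad$score$scores)
  }
  attr(d, "mgc_fit") <- mgc
  attr(d, "radiomic_fit") <- rad
  d
}

#' Associations between composite scores and clinical flags
#'
#' For each binary flag, a two-sample t-test and a Wilcoxon rank-sum
#' test of the continuous score across flag levels; for score-score
#' pairs, Pearson correlation with its test.  Constant flags give
#' flagged `NA` rows.
#'
#' @param data an [assemble_analysis_table()] output containing `mgc`
#'   and (optionally) `features_pc1`.
#' @param scores character vector of score columns to test.
#' @param flags character vector of binary flag columns.
#' @return data.frame: `score`, `versus`, `type`, `statistic`,
#'   `p_t_test`, `p_wilcoxon`, `pearson_r`, `p_pearson`.
#' @export
correlate_blocks <- function(data,
                             scores = intersect(c("features_pc1", "mgc"),
                                                colnames(data)),
                             flags = c("high_risk", "worrisome")) {
  rows <- list()
  for (s in scores) {
    v <- data[[s]]
    for (f in flags) {
      g <- data[[f]]
      ok <- !is.na(v) & !is.na(g)
      if (length(unique(g[ok])) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          score = s, versus = f, type = "flag", statistic = NA,
          p_t_test = NA, p_wilcoxon = NA, pearson_r = NA, p_pearson = NA)
        next
      }
      tt <- stats::t.test(v[ok] ~ g[ok])
      wt <- suppressWarnings(stats::wilcox.test(v[ok] ~ g[ok]))
      rows[[length(rows) + 1]] <- data.frame(
        score = s, versus = f, type = "flag",
        statistic = unname(tt$statistic),
        p_t_test = tt$p.value, p_wilcoxon = wt$p.value,
        pearson_r = NA, p_pearson = NA)
    }
  }
  if (all(c("features_pc1", "mgc") %in% colnames(data))) {
    ok <- !is.na(data$features_pc1) & !is.na(data$mgc)
    ct <- stats::cor.test(data$features_pc1[ok], data$mgc[ok])
    rows[[length(rows) + 1]] <- data.frame(
      score = "features_pc1", versus = "mgc", type = "score",
      statistic = unname(ct$statistic),
      p_t_test = NA, p_wilcoxon = NA,
      pearson_r = unname(ct$estimate), p_pearson = ct$p.value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run configuration for the end-to-end pipeline
#'
#' @param mode `"synthetic"` (generate a phantom cohort) or
#'   `"from_files"` (read a cohort directory written by
#'   [write_cohort()]).
#' @param cohort a [cohort_config()] (synthetic mode).
#' @param input_dir cohort directory (from_files mode).
#' @param pearson_threshold,alpha selection settings.
#' @param cv_k,cv_reps,cv_seed cross-validation settings.
#' @param output_dir where artifacts are written.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "from_files"),
                       cohort = cohort_config(), input_dir = NULL,
                       pearson_threshold = 0.90, alpha = 0.05,
                       cv_k = 10L, cv_reps = 200L, cv_seed = 1L,
                       output_dir = tempfile("ipmnrad_run_")) {
  mode <- match.arg(mode)
  if (mode == "from_files" && is.null(input_dir))
    stop("from_files mode requires input_dir")
  structure(list(mode = mode, cohort = cohort, input_dir = input_dir,
                 pearson_threshold = pearson_threshold, alpha = alpha,
                 cv_k = as.integer(cv_k), cv_reps = as.integer(cv_reps),
                 cv_seed = as.integer(cv_seed), output_dir = output_dir),
            class = "run_config")
}

#' Run the full radiogenomic pipeline
#'
#' Generate (or load) the cohort, extract the 112-feature radiomic
#' vectors, screen and score, fit the nine-model suite, cross-validate
#' the combined radiomic + MGC model, and write all artifacts (feature
#' table, screening table, model report, CV report, association table,
#' run manifest) as CSV/JSON under `config$output_dir`.  Identical
#' config + seed yields identical artifacts.
#'
#' @param config a [run_config()].
#' @param cv_models names of suite models to cross-validate (default the
#'   combined radiomic + MGC model).
#' @return list of class `pipeline_run`: `cohort`, `features`,
#'   `analysis`, `screening`, `models` (list of `model_result`),
#'   `model_report` (data.frame), `cv` (list of `cv_result`),
#'   `associations`, `paths`.
#' @export
run_pipeline <- function(config = run_config(),
                         cv_models = "radiomic_pc1_plus_mgc") {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (config$mode == "synthetic")
    generate_cohort(config$cohort) else read_cohort(config$input_dir)
  catalog <- feature_catalog()
  features <- extract_cohort_features(cohort, catalog)
  analysis <- assemble_analysis_table(cohort, features,
                                      config$pearson_threshold,
                                      config$alpha)
  rad <- attr(analysis, "radiomic_fit")

  models <- lapply(model_suite(), function(sp)
    suppressMessages(fit_model(sp, analysis)))
  names(models) <- vapply(models, `[[`, "", "name")
  model_report <- do.call(rbind, lapply(models, function(m)
    data.frame(model = m$name, n = m$n, n_dropped = m$n_dropped,
               auc = m$auc, auc_ci_low = m$auc_ci_95[1],
               auc_ci_high = m$auc_ci_95[2], cutpoint = m$cutpoint,
               sens = m$sens, spec = m$spec_metric, ppv = m$ppv,
               npv = m$npv, accuracy = m$accuracy,
               penalized = m$fit_flags$penalized)))
  rownames(model_report) <- NULL

  have_rad <- !is.na(analysis$features_pc1)
  cv <- lapply(cv_models, function(nm) {
    sp <- Filter(function(s) s$name == nm, model_suite())[[1]]
    uses_rad <- "features_pc1" %in% sp$predictors
    rows <- if (uses_rad) which(have_rad) else seq_len(nrow(analysis))
    fx <- NULL
    if (uses_rad) {
      fm <- features[match(analysis$case_id[rows], features$case_id), ]
      fx <- as.matrix(fm[, setdiff(colnames(fm), "case_id")])
    }
    repeated_kfold_cv(sp, analysis[rows, ], fx, k = config$cv_k,
                      reps = config$cv_reps, seed = config$cv_seed,
                      pearson_threshold = config$pearson_threshold,
                      alpha = config$alpha)
  })
  names(cv) <- cv_models

  associations <- correlate_blocks(analysis)

  paths <- list(
    features = file.path(config$output_dir, "features.csv"),
    screening = file.path(config$output_dir, "screening.csv"),
    models = file.path(config$output_dir, "model_report.csv"),
    cv = file.path(config$output_dir, "cv_report.csv"),
    associations = file.path(config$output_dir, "associations.csv"),
    catalog = file.path(config$output_dir, "catalog.json"),
    manifest = file.path(config$output_dir, "run_manifest.json"))
  utils::write.csv(features, paths$features, row.names = FALSE)
  utils::write.csv(rad$screening, paths$screening, row.names = FALSE)
  utils::write.csv(model_report, paths$models, row.names = FALSE)
  cv_report <- do.call(rbind, lapply(names(cv), function(nm)
    cbind(model = nm, cv[[nm]]$per_rep)))
  utils::write.csv(cv_report, paths$cv, row.names = FALSE)
  utils::write.csv(associations, paths$associations, row.names = FALSE)
  write_catalog_json(catalog, paths$catalog)
  manifest <- list(
    mode = config$mode,
    seed = if (config$mode == "synthetic") config$cohort$seed else NA,
    cv = list(k = config$cv_k, reps = config$cv_reps,
              seed = config$cv_seed),
    pearson_threshold = config$pearson_threshold, alpha = config$alpha,
    n_cases = nrow(analysis), n_with_features = sum(have_rad),
    selected_features = rad$selected,
    pc1_variance_explained = rad$score$variance_explained,
    package_version = as.character(utils::packageVersion("ipmnrad")))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  structure(list(cohort = cohort, features = features,
                 analysis = analysis, screening = rad$screening,
                 selected = rad$selected, models = models,
                 model_report = model_report, cv = cv,
                 associations = associations, paths = paths,
                 config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d cases, %d with features; %d significant features; PC1 %.0f%% variance\n",
              nrow(x$analysis), sum(!is.na(x$analysis$features_pc1)),
              length(x$selected),
              100 * attr(x$analysis, "radiomic_fit")$score$variance_explained))
  print(x$model_report[, c("model", "n", "auc", "sens", "spec", "ppv", "npv")],
        digits = 2)
  invisible(x)
}
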