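# analysis table built directly (no images): clinical + miRNA + optional
# synthetic feature block, for fast model/CV checks
toy_analysis <- function(n0 = 20, n1 = 18, seed = 1, mgc_effect = TRUE) {
  set.seed(seed)
  label <- c(rep("benign", n0), rep("malignant", n1))
  y <- as.integer(label == "malignant")
  mir <- sapply(1:5, function(j) rnorm(n0 + n1, 8 - mgc_effect * 1.32 * y, 2.2))
  colnames(mir) <- mirna_panel()
  d <- data.frame(case_id = sprintf("c%02d", seq_along(label)), label = label,
                  age_years = rnorm(n0 + n1, 69, 11),
                  gender_male = rbinom(n0 + n1, 1, 0.35),
                  symptoms = rbinom(n0 + n1, 1, 0.15),
                  high_risk = rbinom(n0 + n1, 1, 0.15 + 0.68 * y),
                  worrisome = rbinom(n0 + n1, 1, 0.65 + 0.07 * y),
                  check.names = FALSE)
  d <- cbind(d, as.data.frame(mir, check.names = FALSE))
  mgc <- mgc_score(d[, mirna_panel()])
  d$mgc <- unname(mgc$scores)
  d
}

# synthetic radiomic feature matrix with planted effects
toy_features <- function(n, y, n_feat = 30, planted = 5, effect = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * n_feat), n, n_feat,
              dimnames = list(NULL, sprintf("f%03d", 1:n_feat)))
  for (j in seq_len(planted)) X[, j] <- X[, j] + effect * y
  X
}

test_that("the model suite defines the nine predictor sets", {
  suite <- model_suite()
  expect_length(suite, 9)
  nm <- vapply(suite, `[[`, "", "name")
  expect_true(all(c("demographic_clinical", "high_risk_stigmata", "mgc",
                    "high_risk_plus_mgc", "worrisome_features",
                    "worrisome_plus_mgc", "radiomic_pc1",
                    "radiomic_pc1_plus_mgc",
                    "worrisome_radiomic_pc1_mgc") %in% nm))
  expect_error(model_spec("x", character(0)), "nonempty")
  expect_error(model_spec("x", "nope"), "unknown")
})

test_that("a single binary predictor's model AUC equals the flag's empirical AUC", {
  d <- toy_analysis(seed = 2)
  # overwrite with the published 2x2: 3/20 exposed benign, 15/18 malignant
  d$high_risk <- c(rep(1, 3), rep(0, 17), rep(1, 15), rep(0, 3))
  m <- fit_model(model_spec("hr", "high_risk"), d)
  sens <- 15 / 18; spec <- 17 / 20
  expect_equal(m$auc, (sens + spec) / 2, tolerance = 1e-12)
  expect_equal(m$n, 38)
})

test_that("null predictors give chance-level AUC at large n", {
  d <- toy_analysis(400, 400, seed = 3, mgc_effect = FALSE)
  m <- fit_model(model_spec("null", "demographic"), d)
  expect_lt(abs(m$auc - 0.5), 0.06)
})

test_that("nested models never lose in-sample AUC", {
  for (s in 1:5) {
    d <- toy_analysis(seed = 10 + s)
    a1 <- fit_model(model_spec("hr", "high_risk"), d)$auc
    a2 <- fit_model(model_spec("hr_mgc", c("high_risk", "mgc")), d)$auc
    expect_gte(a2 + 1e-9, a1)
  }
})

test_that("collinear designs are rejected with the offending column named", {
  d <- toy_analysis(seed = 4)
  d$mgc <- d$high_risk          # perfect collinearity
  expect_error(fit_model(model_spec("bad", c("high_risk", "mgc")), d),
               "collinear")
})

test_that("cases with missing predictors are dropped and counted", {
  d <- toy_analysis(seed = 5)
  d$features_pc1 <- rnorm(nrow(d)); d$features_pc1[4] <- NA
  expect_message(m <- fit_model(model_spec("rad", "features_pc1"), d),
                 "dropping 1")
  expect_equal(m$n, 37)
  expect_equal(m$n_dropped, 1)
})

test_that("repeated k-fold CV is deterministic in its seed", {
  d <- toy_analysis(seed = 6)
  cv1 <- repeated_kfold_cv(model_spec("mgc", "mgc"), d, k = 5, reps = 10,
                           seed = 42)
  cv2 <- repeated_kfold_cv(model_spec("mgc", "mgc"), d, k = 5, reps = 10,
                           seed = 42)
  expect_identical(cv1$per_rep, cv2$per_rep)
  cv3 <- repeated_kfold_cv(model_spec("mgc", "mgc"), d, k = 5, reps = 10,
                           seed = 43)
  expect_false(identical(cv1$per_rep, cv3$per_rep))
  expect_true(all(cv1$per_rep$auc >= 0 & cv1$per_rep$auc <= 1))
})

test_that("CV guards its preconditions", {
  d <- toy_analysis(6, 5, seed = 7)
  expect_error(repeated_kfold_cv(model_spec("mgc", "mgc"), d, k = 10,
                                 reps = 2, seed = 1), "smaller class")
  expect_error(repeated_kfold_cv(model_spec("rad", "features_pc1"), d,
                                 k = 3, reps = 2, seed = 1),
               "feature matrix")
})

test_that("label-permuted CV is calibrated to chance", {
  d <- toy_analysis(seed = 8)
  set.seed(99)
  d$label <- sample(d$label)   # break all associations
  d$mgc <- unname(mgc_score(d[, mirna_panel()])$scores)
  cv <- repeated_kfold_cv(model_spec("m", c("high_risk", "mgc")), d,
                          k = 10, reps = 60, seed = 7)
  expect_gt(cv$mean_auc, 0.38)
  expect_lt(cv$mean_auc, 0.62)
})

test_that("out-of-fold performance shows the optimism gap versus resubstitution", {
  gaps <- numeric(12)
  for (s in seq_along(gaps)) {
    d <- toy_analysis(seed = 100 + s)
    y <- as.integer(d$label == "malignant")
    X <- toy_features(nrow(d), y, n_feat = 25, planted = 5, effect = 0.6,
                      seed = 200 + s)
    fx <- as.data.frame(X)
    rad <- radiomic_score(X, d$label, min_p_fallback = TRUE)
    d$features_pc1 <- unname(rad$score$scores)
    resub <- fit_model(model_spec("rad", "features_pc1"), d)$auc
    cv <- repeated_kfold_cv(model_spec("rad", "features_pc1"), d, fx,
                            k = 5, reps = 5, seed = 300 + s)
    gaps[s] <- resub - cv$mean_auc
  }
  expect_gt(mean(gaps), 0)
})
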