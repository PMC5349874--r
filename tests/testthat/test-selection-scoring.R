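test_that("the Pearson filter follows the greedy keep-first rule", {
  set.seed(41)
  n <- 60
  a <- rnorm(n)
  x <- cbind(A = a,
             B = a + rnorm(n, 0, 0.03),   # r(A,B) ~ 0.999
             C = a + rnorm(n, 0, 0.05))   # r(A,C) high too
  stopifnot(abs(cor(x[, "A"], x[, "B"])) > 0.95,
            abs(cor(x[, "A"], x[, "C"])) > 0.95)
  expect_equal(pearson_filter(x, 0.95), "A")

  # exact duplicate dropped
  y <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  y <- cbind(y, f1_copy = y[, "f1"])
  expect_equal(pearson_filter(y, 0.9), c("f1", "f2"))

  # independent features at large n survive
  z <- matrix(rnorm(500 * 6), 500, 6,
              dimnames = list(NULL, paste0("g", 1:6)))
  expect_equal(pearson_filter(z, 0.9), paste0("g", 1:6))

  # zero variance dropped with a warning
  w <- cbind(const = rep(1, n), ok = rnorm(n))
  expect_warning(kept <- pearson_filter(w, 0.9), "zero-variance")
  expect_equal(kept, "ok")
})

test_that("the Pearson filter is idempotent", {
  set.seed(42)
  co <- generate_cohort(small_cohort_config(10, 10, seed = 8))
  X <- as.matrix(extract_cohort_features(co)[, -1])
  kept <- suppressWarnings(pearson_filter(X, 0.9))
  expect_equal(suppressWarnings(pearson_filter(X[, kept], 0.9)), kept)
})

test_that("univariate logistic matches an independent optimizer to 6 decimals", {
  set.seed(43)
  for (i in 1:5) {
    x <- rnorm(40)
    y <- rbinom(40, 1, plogis(0.3 + 0.8 * x))
    if (length(unique(y)) < 2) next
    res <- univariate_logistic(x, y, standardize = FALSE)
    bf <- bf_logistic(x, y)
    expect_lt(abs(log(res$odds_ratio) - bf$coef[2]), 1e-6)
    expect_lt(abs((log(res$ci_high) - log(res$odds_ratio)) / 1.96 - bf$se[2]),
              1e-4)
  }
})

test_that("a saturated binary feature reproduces the cross-product odds ratio", {
  # exposure 3/20 in benign, 15/18 in malignant: OR = (15*17)/(3*3)
  y <- c(rep(0, 20), rep(1, 18))
  x <- c(rep(1, 3), rep(0, 17), rep(1, 15), rep(0, 3))
  res <- univariate_logistic(x, y, standardize = FALSE)
  expect_equal(res$odds_ratio, (15 * 17) / (3 * 3), tolerance = 1e-4)
  expect_false(res$penalized)
})

test_that("perfect separation falls back to a flagged penalized fit", {
  y <- rep(c(0, 1), each = 10)
  x <- c(rnorm(10, -3), rnorm(10, 3))
  res <- univariate_logistic(x, y)
  expect_true(res$penalized)
  expect_true(is.finite(res$odds_ratio))
  expect_gt(res$odds_ratio, 1)
})

test_that("screening p-values are null-uniform and selection respects alpha", {
  set.seed(44)
  n <- 200; m <- 400
  X <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("f", 1:m)))
  y <- rbinom(n, 1, 0.5)
  scr <- screen_features(X, y)
  ks <- suppressWarnings(ks.test(scr$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(select_significant(scr, alpha = 1), scr$feature_id)
  scr0 <- scr; scr0$p_value <- rep(0.5, m)
  expect_length(select_significant(scr0, 0.05), 0)
  # BH adjustment is more conservative than raw selection
  expect_lte(length(select_significant(scr, 0.05, adjust = "BH")),
             length(select_significant(scr, 0.05)))
})

test_that("PC1 matches the closed-form 2x2 eigendecomposition on a toy matrix", {
  x <- cbind(a = c(1, 2, 3, 5), b = c(2, 1, 4, 6))
  pc <- pca_pc1(x)
  z <- scale(x)
  r <- cor(x[, 1], x[, 2])
  # 2x2 correlation matrix eigenvector for the top eigenvalue 1 + |r|
  v <- c(1, sign(r)) / sqrt(2)
  expect_equal(unname(pc$loadings), v, tolerance = 1e-10)
  expect_equal(unname(pc$scores), unname(drop(z %*% v)), tolerance = 1e-10)
  expect_equal(pc$variance_explained, (1 + abs(r)) / 2, tolerance = 1e-10)
})

test_that("PC1 is invariant to variable order and affine rescaling", {
  set.seed(45)
  x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, letters[1:4]))
  p1 <- pca_pc1(x)
  p2 <- pca_pc1(x[, c(3, 1, 4, 2)])
  expect_equal(unname(p2$scores), unname(p1$scores), tolerance = 1e-10)
  x2 <- sweep(sweep(x, 2, c(2, 3, 10, 0.5), `*`), 2, c(1, 0, -5, 2), `+`)
  p3 <- pca_pc1(x2)
  expect_equal(unname(p3$scores), unname(p1$scores), tolerance = 1e-10)
  expect_equal(pca_pc1(cbind(u = x[, 1], v = 2 * x[, 1] + 1))$variance_explained, 1)
})

test_that("degenerate PCA inputs are rejected", {
  expect_error(pca_pc1(cbind(a = c(1, 1, 1), b = c(1, 2, 3))), "constant")
  expect_error(pca_pc1(matrix(1:3, 3, 1)), ">= 2 variables")
  expect_error(pca_pc1(matrix(rnorm(4), 2, 2)), ">= 3 cases")
})

test_that("the MGC separates classes in the configured direction", {
  set.seed(46)
  cfg <- small_cohort_config(200, 200, seed = 12)
  co <- generate_cohort(cfg)
  expect_error(mgc_score(co$table[, 1:4]), "missing miRNA")
  sc <- mgc_score(co$table[, mirna_panel()])
  ben <- sc$scores[co$table$label == "benign"]
  mal <- sc$scores[co$table$label == "malignant"]
  expect_gt(mean(ben), mean(mal))
  # near-noiseless panels form two separated clusters
  cfg2 <- small_cohort_config(20, 20, seed = 13, mirna_sd = 0.01)
  co2 <- generate_cohort(cfg2)
  sc2 <- mgc_score(co2$table[, mirna_panel()])
  expect_gt(min(sc2$scores[co2$table$label == "benign"]),
            max(sc2$scores[co2$table$label == "malignant"]))
})
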