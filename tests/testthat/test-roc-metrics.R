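test_that("AUC reproduces the enumerated toy examples", {
  expect_equal(auc_mann_whitney(c(0.1, 0.2, 0.3, 0.4, 0.5),
                                c(0, 0, 0, 1, 1))$auc, 1)
  expect_equal(auc_mann_whitney(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_error(auc_mann_whitney(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals all-pairs enumeration on random score vectors", {
  set.seed(51)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(round(rnorm(n), 1))   # rounding forces frequent ties
    expect_equal(auc_mann_whitney(s, y)$auc, bf_auc(s, y))
  }
})

test_that("AUC and DeLong variance agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(52)
  y <- rbinom(120, 1, 0.45)
  s <- rnorm(120) + y
  a <- auc_mann_whitney(s, y)
  r <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(a$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
  expect_equal(a$var, pROC::var(r, method = "delong"), tolerance = 1e-12)
  ci <- pROC::ci.auc(r, method = "delong")
  expect_equal(unname(a$ci), as.numeric(ci[c(1, 3)]), tolerance = 1e-3)
})

test_that("AUC is complementary and rank-invariant", {
  set.seed(53)
  y <- rbinom(60, 1, 0.5)
  s <- rnorm(60)
  a <- auc_mann_whitney(s, y)$auc
  expect_equal(auc_mann_whitney(-s, y)$auc, 1 - a)
  expect_equal(auc_mann_whitney(exp(3 * s), y)$auc, a)
})

test_that("the paired DeLong test handles identical and transformed scores", {
  set.seed(54)
  y <- rbinom(80, 1, 0.5)
  s <- rnorm(80) + 0.8 * y
  r1 <- delong_paired_test(s, s, y)
  expect_equal(r1$p_value, 1)
  expect_true(r1$flagged)
  r2 <- delong_paired_test(s, plogis(2 * s), y)   # monotone transform
  expect_equal(r2$auc_a, r2$auc_b)
  expect_equal(r2$p_value, 1)
})

test_that("the paired DeLong test matches pROC on correlated markers", {
  skip_if_not_installed("pROC")
  set.seed(55)
  y <- rbinom(100, 1, 0.5)
  s1 <- rnorm(100) + 1.2 * y
  s2 <- 0.5 * s1 + rnorm(100, 0, 0.8) + 0.3 * y
  mine <- delong_paired_test(s1, s2, y)
  ref <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE, direction = "<"),
                        pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("a strong marker beats a null marker decisively at n=200 per class", {
  set.seed(56)
  rejected <- 0L
  for (i in 1:20) {
    y <- rep(c(0, 1), each = 200)
    strong <- rnorm(400) + 1.82 * y      # true AUC ~0.9
    null <- rnorm(400)                   # true AUC 0.5
    p <- delong_paired_test(strong, null, y)$p_value
    rejected <- rejected + (p < 0.001)
  }
  expect_gte(rejected, 19)
})

test_that("DeLong variance tracks the bootstrap variance of the AUC", {
  set.seed(57)
  y <- rep(c(0, 1), each = 120)
  s <- rnorm(240) + 1.0 * y
  v_delong <- auc_mann_whitney(s, y)$var
  boots <- replicate(800, {
    i0 <- sample(which(y == 0), replace = TRUE)
    i1 <- sample(which(y == 1), replace = TRUE)
    auc_mann_whitney(s[c(i0, i1)], y[c(i0, i1)])$auc
  })
  expect_lt(abs(v_delong - var(boots)) / var(boots), 0.2)
})

test_that("the Youden cutpoint maximizes J with the specified tie-break", {
  r <- youden_cutpoint(c(0.1, 0.4, 0.35, 0.8), c(0, 1, 0, 1))
  expect_gt(r$cutpoint, 0.35)
  expect_lte(r$cutpoint, 0.4)
  expect_equal(r$sens, 1)
  expect_equal(r$spec, 1)
  expect_equal(r$j, 1)

  # perfectly separated
  r2 <- youden_cutpoint(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_equal(r2$j, 1)

  # all identical: J = 0, flagged
  r3 <- youden_cutpoint(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(r3$j, 0)
  expect_true(r3$flagged)
  expect_equal(r3$cutpoint, 0.5)

  # ties in J resolved toward higher specificity (larger cutpoint)
  r4 <- youden_cutpoint(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_gt(r4$cutpoint, 3)
})

test_that("confusion metrics match hand arithmetic and flag zero denominators", {
  cm <- confusion_metrics(tp = 15, fn = 3, fp = 2, tn = 17)
  expect_equal(round(unname(cm["sens"]), 2), 0.83)
  expect_equal(round(unname(cm["spec"]), 2), 0.89)
  expect_equal(round(unname(cm["ppv"]), 2), 0.88)
  expect_equal(round(unname(cm["npv"]), 2), 0.85)
  expect_equal(unname(confusion_metrics(5, 0, 0, 5)[c("sens", "spec", "ppv", "npv", "accuracy")]),
               rep(1, 5))
  expect_true(is.na(confusion_metrics(0, 0, 2, 3)[["sens"]]))
})
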