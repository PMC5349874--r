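test_that("generator parameters validate and carry class defaults", {
  b <- generator_params("benign")
  m <- generator_params("malignant")
  expect_equal(b$cyst_diameter_mean_cm, 2.8)
  expect_equal(m$cyst_diameter_mean_cm, 3.9)
  expect_equal(b$p_high_risk, 0.15)
  expect_equal(m$p_high_risk, 15 / 18, tolerance = 1e-12)
  # malignant panel shift sits in the 2-3 fold band on the linear scale
  expect_gte(2^m$mirna_log2_shift, 2)
  expect_lte(2^m$mirna_log2_shift, 3)
  expect_error(generator_params("benign", p_high_risk = 1.5), "probabilities")
  expect_error(generator_params("benign", nonsense = 1), "unknown")
})

test_that("all texture sources off yields a constant ROI with zero entropy", {
  set.seed(1)
  p <- generator_params("benign", heterogeneity_level = 0L,
                        texture_noise_sd = 0, gradient_hu = 0,
                        nodule_prob = 0)
  img <- generate_lesion(p, 0.08, 128L)
  expect_equal(sd(img$intensity[img$mask]), 0)
  expect_equal(histogram_features(img)[["hist_entropy"]], 0)
})

test_that("an unperturbed boundary is an ellipse whose inscribed circle is the semi-minor axis", {
  set.seed(2)
  for (i in 1:5) {
    p <- generator_params("benign", boundary_irregularity = 0)
    img <- generate_lesion(p, 0.08, 128L)
    f <- shape_features(img)
    expect_lt(abs(f[["shape_inscribed_radius_px"]] -
                  f[["shape_minor_axis_px"]] / 2), 1.5)
    expect_lt(f[["shape_fourier_descriptor"]], 0.01)
  }
})

test_that("lesions that cannot fit the frame are a configuration error", {
  p <- generator_params("malignant", cyst_diameter_mean_cm = 5,
                        cyst_diameter_sd_cm = 0.1,
                        cyst_diameter_range_cm = c(4.9, 5.1))
  expect_error(generate_lesion(p, 0.08, 32L), "fit")
  expect_error(cohort_config(image_side = 32L), "contain")
})

test_that("malignant-parameterized lesions are more heterogeneous in expectation", {
  set.seed(30)
  n <- 40
  ent <- function(p) replicate(n, {
    img <- generate_lesion(p, 0.08, 128L)
    histogram_features(img)[["hist_entropy"]]
  })
  wid <- function(p) replicate(n, {
    img <- generate_lesion(p, 0.08, 128L)
    shape_features(img)[["shape_minor_axis_px"]]
  })
  e_b <- ent(generator_params("benign"))
  e_m <- ent(generator_params("malignant"))
  expect_gt(mean(e_m), mean(e_b))
  set.seed(31)
  w_b <- wid(generator_params("benign"))
  w_m <- wid(generator_params("malignant"))
  expect_gt(mean(w_m), mean(w_b))
})

test_that("miRNA generation shifts the malignant panel down by the configured amount", {
  set.seed(4)
  b <- generator_params("benign", mirna_sd = 1e-9)
  m <- generator_params("malignant", mirna_sd = 1e-9)
  vb <- generate_mirna(b); vm <- generate_mirna(m)
  expect_equal(unname(vm - vb), rep(-1.32, 5), tolerance = 1e-6)
  expect_identical(names(vb), mirna_panel())
})

test_that("cohorts are deterministic in (config, seed) and sized per config", {
  cfg <- small_cohort_config(6, 5, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$table, c2$table)
  expect_identical(c1$cases[[3]]$image$intensity, c2$cases[[3]]$image$intensity)
  expect_equal(sum(c1$table$label == "benign"), 6)
  expect_equal(sum(c1$table$label == "malignant"), 5)
  c3 <- generate_cohort(small_cohort_config(6, 5, seed = 100))
  expect_false(identical(c1$table, c3$table))
  # default configuration reproduces the 20/18 cohort composition
  def <- cohort_config()
  expect_equal(def$n_benign, 20L)
  expect_equal(def$n_malignant, 18L)
})

test_that("clinical flag prevalences recover their configured values", {
  cfg <- small_cohort_config(400, 400, seed = 17)
  co <- generate_cohort(cfg)
  tab <- co$table
  for (cl in c("benign", "malignant")) {
    p <- if (cl == "benign") cfg$benign else cfg$malignant
    sub <- tab[tab$label == cl, ]
    for (pair in list(c("high_risk", "p_high_risk"),
                      c("worrisome", "p_worrisome"),
                      c("main_duct", "p_main_duct"))) {
      prev <- mean(sub[[pair[1]]])
      pr <- p[[pair[2]]]
      se <- sqrt(pr * (1 - pr) / nrow(sub))
      expect_lt(abs(prev - pr), 4 * se + 1e-9)
    }
  }
})

test_that("cohort disk round trip preserves tables and images", {
  co <- generate_cohort(small_cohort_config(3, 3, seed = 5))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(back$table$label, co$table$label)
  expect_equal(back$table[, mirna_panel()], co$table[, mirna_panel()],
               tolerance = 1e-12)
  expect_identical(back$cases[[2]]$image$mask, co$cases[[2]]$image$mask)
  expect_equal(back$cases[[2]]$image$intensity,
               co$cases[[2]]$image$intensity, tolerance = 0)
})
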