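#' Class-conditional generator parameters for phantom lesions
#'
#' Defaults encode the published class-conditional structure of the IPMN
#' cohort this pipeline emulates: cyst diameters (benign mean 2.8 cm,
#' range 1.1-6.6; malignant mean 3.9 cm, range 1.6-5.4), clinical-flag
#' prevalences (high-risk stigmata 15% vs 83%, worrisome features 65% vs
#' 72%, main-duct involvement 20% vs 72%, solid nodule 15% vs 50%,
#' jaundice 5% vs 28%, female 75% vs 56%, age 68.0 (10.4) vs 70.9 (11.7)
#' years), a 5-miRNA panel shifted down by 1.32 log2 units in the
#' malignant class (2.5-fold, inside the 2-3x band), and texture/shape
#' settings that give malignant lesions higher intensity heterogeneity,
#' more irregular borders and more frequent mural nodules.
#'
#' @param label `"benign"` or `"malignant"`; selects the default set.
#' @param ... named overrides of any field.
#' @return a list of class `generator_params`.
#' @export
generator_params <- function(label = c("benign", "malignant"), ...) {
  label <- match.arg(label)
  p <- if (label == "benign") {
    list(cyst_diameter_mean_cm = 2.8, cyst_diameter_sd_cm = 1.2,
         cyst_diameter_range_cm = c(1.1, 6.6),
         texture_noise_sd = 4, heterogeneity_level = 2L,
         gradient_hu = 6, nodule_prob = 0.15,
         boundary_irregularity = 0.04,
         p_high_risk = 0.15, p_worrisome = 0.65, p_main_duct = 0.20,
         p_jaundice = 0.05, p_female = 0.75,
         age_mean = 68.0, age_sd = 10.4,
         mirna_baseline = c(8, 8, 8, 8, 8),
         mirna_log2_shift = 0, mirna_sd = 2.2)
  } else {
    list(cyst_diameter_mean_cm = 3.9, cyst_diameter_sd_cm = 1.0,
         cyst_diameter_range_cm = c(1.6, 5.4),
         texture_noise_sd = 16, heterogeneity_level = 8L,
         gradient_hu = 6, nodule_prob = 0.50,
         boundary_irregularity = 0.12,
         p_high_risk = 15 / 18, p_worrisome = 13 / 18, p_main_duct = 13 / 18,
         p_jaundice = 5 / 18, p_female = 10 / 18,
         age_mean = 70.9, age_sd = 11.7,
         mirna_baseline = c(8, 8, 8, 8, 8),
         mirna_log2_shift = 1.32, mirna_sd = 2.2)
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stop("unknown generator parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  probs <- unlist(p[c("p_high_risk", "p_worrisome", "p_main_duct",
                      "p_jaundice", "p_female", "nodule_prob")])
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (p$cyst_diameter_sd_cm <= 0 || p$mirna_sd < 0 || p$texture_noise_sd < 0)
    stop("scale parameters must be positive")
  structure(p, class = "generator_params", label = label)
}

#' The five miRNAs of the genomic classifier panel
#' @export
mirna_panel <- function() {
  c("miR-200a-3p", "miR-1185-5p", "miR-33a-5p", "miR-574-3p", "miR-663b")
}

#' Cohort-level configuration
#'
#' @param n_benign,n_malignant class sizes (defaults 20 and 18, the
#'   published cohort composition).
#' @param pixel_size_cm pixel edge length; default 0.08 cm.
#' @param image_side image side in pixels; must accommodate the largest
#'   configured lesion.
#' @param seed integer seed; identical `(config, seed)` pairs yield
#'   identical cohorts.
#' @param benign,malignant [generator_params()] for each class.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_benign = 20L, n_malignant = 18L,
                          pixel_size_cm = 0.08, image_side = 128L,
                          seed = 1L,
                          benign = generator_params("benign"),
                          malignant = generator_params("malignant")) {
  stopifnot(n_benign >= 0, n_malignant >= 0, image_side >= 8)
  max_d <- max(benign$cyst_diameter_range_cm[2],
               malignant$cyst_diameter_range_cm[2])
  if (max_d / pixel_size_cm + 6 > image_side)
    stop(sprintf(
      "image_side %d cannot contain the largest configured lesion (%.1f cm at %.3f cm/px)",
      image_side, max_d, pixel_size_cm))
  structure(list(n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 pixel_size_cm = pixel_size_cm,
                 image_side = as.integer(image_side),
                 seed = as.integer(seed),
                 benign = benign, malignant = malignant),
            class = "cohort_config")
}

rtrunc_norm <- function(n, mean, sd, range) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= range[1] && x <= range[2]) break
    }
    out[i] <- x
  }
  out
}

#' Generate one phantom lesion image
#'
#' The lesion is a radially perturbed ellipse (random orientation and
#' axis ratio; Fourier-series boundary perturbation with relative
#' amplitude `boundary_irregularity`).  Its texture is the sum of a
#' smooth radial gradient (`gradient_hu` HU from center to rim), white
#' noise (`texture_noise_sd`), `heterogeneity_level` Gaussian "habitat"
#' patches of random contrast, and, with probability `nodule_prob`, a
#' compact mural nodule of +60 HU.  The cyst base intensity is 20 HU
#' (cystic fluid); background is 50 HU (parenchyma).  Intensities are
#' rounded to 1/16 HU so disk round trips are exact.  Uses the current
#' RNG state.
#'
#' @param params a [generator_params()].
#' @param pixel_size_cm,image_side geometry of the frame.
#' @return a [lesion_image()] whose mask is a single connected component.
#' @export
generate_lesion <- function(params, pixel_size_cm = 0.08, image_side = 128L) {
  stopifnot(inherits(params, "generator_params"))
  d_cm <- rtrunc_norm(1, params$cyst_diameter_mean_cm,
                      params$cyst_diameter_sd_cm,
                      params$cyst_diameter_range_cm)
  a <- d_cm / 2 / pixel_size_cm               # semi-major axis, px
  if (2 * a + 6 > image_side)
    stop("lesion does not fit in frame; increase image_side")
  ratio <- stats::runif(1, 0.65, 0.95)
  b <- a * ratio                              # semi-minor axis, px
  phi <- stats::runif(1, 0, pi)               # orientation
  # Fourier boundary perturbation, harmonics 2..6
  n_h <- 5L
  amp <- stats::rnorm(n_h, 0, params$boundary_irregularity / sqrt(n_h))
  pha <- stats::runif(n_h, 0, 2 * pi)

  ctr <- (image_side + 1) / 2
  rows <- matrix(seq_len(image_side), image_side, image_side)
  cols <- t(rows)
  dx <- cols - ctr; dy <- rows - ctr
  # coordinates in the ellipse frame
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  theta <- atan2(v, u)
  r_ell <- (a * b) / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  pert <- rep(1, length(theta))
  for (k in seq_len(n_h))
    pert <- pert + amp[k] * cos((k + 1) * theta + pha[k])
  r_bound <- r_ell * pmax(0.5, pert)
  rho <- sqrt(u^2 + v^2)
  mask <- rho <= r_bound

  # keep the largest connected component (extreme perturbations can pinch)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  if (max(lab) > 1) {
    tab <- tabulate(as.integer(lab)[as.integer(lab) > 0])
    mask <- matrix(as.integer(lab) == which.max(tab), image_side, image_side)
  }

  inten <- matrix(50, image_side, image_side)  # parenchyma background
  base <- 20
  rel <- pmin(1, rho / pmax(r_bound, 1e-9))
  inten[mask] <- base + params$gradient_hu * rel[mask]^2
  if (params$heterogeneity_level > 0) {
    in_idx <- which(mask, arr.ind = TRUE)
    for (k in seq_len(params$heterogeneity_level)) {
      c0 <- in_idx[sample.int(nrow(in_idx), 1), ]
      sig <- stats::runif(1, 0.10, 0.30) * a
      con <- stats::rnorm(1, 0, 20)
      g <- con * exp(-((rows - c0[1])^2 + (cols - c0[2])^2) / (2 * sig^2))
      inten[mask] <- inten[mask] + g[mask]
    }
  }
  if (stats::runif(1) < params$nodule_prob) {
    in_idx <- which(mask & rel > 0.4 & rel < 0.9, arr.ind = TRUE)
    if (nrow(in_idx) == 0) in_idx <- which(mask, arr.ind = TRUE)
    c0 <- in_idx[sample.int(nrow(in_idx), 1), ]
    sig <- max(1.5, 0.12 * a)
    g <- 60 * exp(-((rows - c0[1])^2 + (cols - c0[2])^2) / (2 * sig^2))
    inten[mask] <- inten[mask] + g[mask]
  }
  if (params$texture_noise_sd > 0)
    inten[mask] <- inten[mask] +
      stats::rnorm(sum(mask), 0, params$texture_noise_sd)
  inten <- round(inten * 16) / 16
  lesion_image(inten, mask, pixel_size_cm)
}

#' Generate the 5-miRNA log2-expression vector for one case
#'
#' Benign values are Normal(baseline, `mirna_sd`) per miRNA; malignant
#' values are shifted down by `mirna_log2_shift` log2 units (default
#' 1.32, i.e. ~2.5-fold lower).  Uses the current RNG state.
#'
#' @param params a [generator_params()] (its label determines the shift
#'   applied, via `mirna_log2_shift`).
#' @return named numeric vector over [mirna_panel()].
#' @export
generate_mirna <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  v <- stats::rnorm(5, params$mirna_baseline - params$mirna_log2_shift,
                    params$mirna_sd)
  names(v) <- mirna_panel()
  v
}

#' Generate a phantom cohort
#'
#' Draws `n_benign + n_malignant` cases: lesion image + mask, 5-miRNA
#' panel, and clinical flags with class-conditional prevalences, all
#' deterministically from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return an object of class `ipmn_cohort`: `cases` (list of case
#'   records with `case_id`, `label`, `image`, `mirna`, `clinical`),
#'   `table` (per-case data.frame of label, clinical flags and miRNA
#'   values) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  labels <- c(rep("benign", config$n_benign),
              rep("malignant", config$n_malignant))
  cases <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    p <- if (labels[i] == "benign") config$benign else config$malignant
    img <- generate_lesion(p, config$pixel_size_cm, config$image_side)
    mirna <- generate_mirna(p)
    clinical <- list(
      age_years = round(stats::rnorm(1, p$age_mean, p$age_sd), 1),
      gender = if (stats::runif(1) < p$p_female) "F" else "M",
      symptoms = as.integer(stats::runif(1) < p$p_jaundice),
      high_risk = as.integer(stats::runif(1) < p$p_high_risk),
      worrisome = as.integer(stats::runif(1) < p$p_worrisome),
      main_duct = as.integer(stats::runif(1) < p$p_main_duct))
    cases[[i]] <- list(case_id = sprintf("case_%03d", i),
                       label = labels[i], image = img,
                       mirna = mirna, clinical = clinical)
  }
  tab <- do.call(rbind, lapply(cases, function(cs) {
    df <- data.frame(case_id = cs$case_id, label = cs$label,
                     cs$clinical, check.names = FALSE)
    mir <- as.data.frame(t(cs$mirna), check.names = FALSE)
    cbind(df, mir)
  }))
  rownames(tab) <- NULL
  structure(list(cases = cases, table = tab, config = config),
            class = "ipmn_cohort")
}

#' @export
print.ipmn_cohort <- function(x, ...) {
  cat(sprintf("<ipmn_cohort> %d cases (%d benign, %d malignant), seed %d\n",
              length(x$cases), sum(x$table$label == "benign"),
              sum(x$table$label == "malignant"), x$config$seed))
  invisible(x)
}

#' Write / read a cohort to a directory
#'
#' Layout: `manifest.csv` (case_id, label, image/mask file names),
#' `clinical.csv`, `mirna.csv`, and one 16-bit grayscale TIFF pair per
#' case under `images/`.  Masks are 0/1; pixel indexing is (row, col),
#' 0-based in the manifest documentation.
#'
#' @param cohort an `ipmn_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ipmn_cohort"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  man <- do.call(rbind, lapply(cohort$cases, function(cs) {
    imgf <- file.path("images", paste0(cs$case_id, "_image.tif"))
    mskf <- file.path("images", paste0(cs$case_id, "_mask.tif"))
    if (!is.null(cs$image))
      write_lesion_tiff(cs$image, file.path(dir, imgf), file.path(dir, mskf))
    data.frame(case_id = cs$case_id, label = cs$label,
               image_file = if (is.null(cs$image)) NA else imgf,
               mask_file = if (is.null(cs$image)) NA else mskf,
               pixel_size_cm = cohort$config$pixel_size_cm)
  }))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  clin_cols <- c("case_id", "label", "age_years", "gender", "symptoms",
                 "high_risk", "worrisome", "main_duct")
  utils::write.csv(cohort$table[, clin_cols],
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(cohort$table[, c("case_id", mirna_panel())],
                   file.path(dir, "mirna.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  clin <- utils::read.csv(file.path(dir, "clinical.csv"), check.names = FALSE)
  mir <- utils::read.csv(file.path(dir, "mirna.csv"), check.names = FALSE)
  cases <- lapply(seq_len(nrow(man)), function(i) {
    have_files <- !is.na(man$image_file[i]) &&
      file.exists(file.path(dir, man$image_file[i])) &&
      file.exists(file.path(dir, man$mask_file[i]))
    if (!is.na(man$image_file[i]) && !have_files)
      warning(sprintf("image/mask file missing for %s; case kept without radiomics",
                      man$case_id[i]))
    img <- if (!have_files) NULL else
      read_lesion_tiff(file.path(dir, man$image_file[i]),
                       file.path(dir, man$mask_file[i]),
                       man$pixel_size_cm[i])
    mirna <- unlist(mir[mir$case_id == man$case_id[i], mirna_panel()])
    cl <- clin[clin$case_id == man$case_id[i], ]
    list(case_id = man$case_id[i], label = man$label[i], image = img,
         mirna = mirna,
         clinical = list(age_years = cl$age_years, gender = cl$gender,
                         symptoms = cl$symptoms, high_risk = cl$high_risk,
                         worrisome = cl$worrisome, main_duct = cl$main_duct))
  })
  tab <- merge(clin, mir, by = "case_id", sort = FALSE)
  structure(list(cases = cases, table = tab, config = NULL),
            class = "ipmn_cohort")
}
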