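# Per-variable ANOVA, BH-FDR, tiers, profiles, biomarker tables

test_that("two-group F equals the squared pooled-variance t statistic", {
  set.seed(1)
  m <- matrix(rnorm(12 * 20), 12, 20)
  g <- rep(c("a", "b"), each = 6)
  av <- anova_f(m, g)
  for (j in c(1, 7, 20)) {
    tt <- stats::t.test(m[g == "a", j], m[g == "b", j], var.equal = TRUE)
    expect_equal(av$F[j], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(av$p[j], tt$p.value, tolerance = 1e-10)
  }
})

test_that("anova_f agrees with stats::aov across several groups", {
  set.seed(2)
  m <- matrix(rnorm(18 * 5), 18, 5)
  g <- rep(c("a", "b", "c"), each = 6)
  av <- anova_f(m, g)
  for (j in 1:5) {
    fit <- summary(stats::aov(m[, j] ~ factor(g)))[[1]]
    expect_equal(av$F[j], fit$`F value`[1], tolerance = 1e-10)
    expect_equal(av$p[j], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("identical data across groups takes the p = 1 convention path", {
  # constant variables: zero between- and within-group sums of squares
  m <- matrix(rep(c(1, 5, 2, 7), each = 6), 6, 4)
  g <- rep(c("a", "b"), each = 3)
  av <- anova_f(m, g)
  expect_true(all(av$p == 1))
  expect_true(all(av$degenerate))
  # equal group means but real spread: F = 0, p = 1, not degenerate
  m2 <- matrix(c(1, 2, 3, 1, 2, 3), 6, 2)
  av2 <- anova_f(m2, g)
  expect_true(all(av2$p == 1))
  expect_false(any(av2$degenerate))
})

test_that("null p-values are uniform (KS check)", {
  set.seed(3)
  m <- matrix(rnorm(12 * 1000), 12, 1000)
  g <- rep(c("a", "b"), each = 6)
  av <- anova_f(m, g)
  ks <- suppressWarnings(stats::ks.test(av$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH matches the worked example and the brute-force oracle", {
  r <- bh_adjust(c(0.001, 0.02, 0.03, 0.5), q = 0.1)
  expect_equal(r$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$threshold, 0.03)
  r0 <- bh_adjust(rep(1, 5), q = 0.05)
  expect_false(any(r0$significant))
  expect_equal(r0$threshold, 0)
  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    mine <- bh_adjust(p, q)
    oracle <- bh_brute_force(p, q)
    expect_identical(mine$significant, oracle$significant)
    expect_equal(mine$threshold, oracle$threshold)
    # cross-check against p.adjust: the BH mask equals adjusted p <= q
    expect_identical(mine$significant, unname(stats::p.adjust(p, "BH") <= q))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("lowering q never adds discoveries", {
  set.seed(5)
  p <- runif(200)^2
  d1 <- bh_adjust(p, 0.10)$significant
  d2 <- bh_adjust(p, 0.05)$significant
  d3 <- bh_adjust(p, 0.01)$significant
  expect_true(all(d2 <= d1))
  expect_true(all(d3 <= d2))
})

test_that("tier classification follows the FDR/liberal hierarchy", {
  p <- c(0.001, 0.01, 0.2)
  mask <- c(TRUE, FALSE, FALSE)
  tiers <- classify_tiers(p, mask)
  expect_equal(
    as.character(tiers),
    c("FDR_significant", "potential", "ns")
  )
  # at q <= 0.05 every masked p also clears the liberal 0.05 bar
  set.seed(6)
  p <- runif(500)^3
  r <- bh_adjust(p, 0.05)
  expect_true(all(p[r$significant] < 0.05))
})

test_that("significance profile is antisymmetric and flags planted signal", {
  pe <- tibble::tibble(template = "met_a", genotype = NA, week = 60, log2fc = 1)
  d <- cohort_design(
    templates = toy_templates(),
    groups = tibble::tibble(
      genotype = "WT", week = c(15, 60), n_mice = 6, spectra_per_mouse = 1
    ),
    planted_effects = pe,
    dilution_log_range = c(1, 1), mult_noise_cv = 0.1, mouse_cv = 0,
    add_noise_sd = 0, grid = c(1, 4, 0.002), seed = 7
  )
  coh <- simulate_cohort(d)
  lt <- log_transform(coh$spectra, offset = 1e-6, check_normalized = FALSE)
  wk <- as.character(lt$meta$week)
  pr60 <- significance_profile(lt, wk, group_a = "60")
  pr15 <- significance_profile(lt, wk, group_a = "15")
  expect_equal(pr60$difference, -pr15$difference)
  at_peak <- which.min(abs(pr60$ppm - 2.0))
  expect_gt(pr60$difference[at_peak], 0)
  expect_lt(pr60$p[at_peak], 0.01)
  expect_error(
    significance_profile(lt, rep(c("a", "b", "c"), length.out = 12)),
    "two groups"
  )
})

test_that("identical groups give a near-zero profile", {
  coh <- simulate_cohort(noise_free_design(
    groups = tibble::tibble(
      genotype = "WT", week = c(15, 60), n_mice = 3, spectra_per_mouse = 1
    )
  ))
  pr <- significance_profile(
    coh$spectra, as.character(coh$spectra$meta$week)
  )
  expect_true(all(abs(pr$difference) < 1e-9))
})

test_that("biomarker tables recover planted effects with directions", {
  pe <- tibble::tibble(
    template = c("citrate", "taurine"), genotype = NA,
    week = 60, log2fc = c(1, -1)
  )
  d <- cohort_design(
    templates = urine_templates(jitter_sd = 0),
    groups = tibble::tibble(
      genotype = "WT", week = c(15, 60), n_mice = 4, spectra_per_mouse = 1
    ),
    planted_effects = pe,
    dilution_log_range = c(0.8, 1.25), mult_noise_cv = 0.15, mouse_cv = 0,
    add_noise_sd = 0.02, grid = c(0.5, 4.5, 0.001), seed = 30
  )
  coh <- simulate_cohort(d)
  sm <- exclude_regions(coh$spectra, preset = "urine")
  sm <- pqn_normalize(sm)$spectra
  sm <- log_transform(sm)
  an <- read_annotation_windows()
  an <- an[an$ppm_hi <= 4.5, ] # windows on this grid
  tb <- build_biomarker_table(
    sm,
    comparison = list(a = list(week = 60), b = list(week = 15)),
    annotations = an, fdr = 0.1
  )
  met <- tb$metabolites
  cit <- met[met$metabolite == "citrate", ]
  tau <- met[met$metabolite == "taurine", ]
  expect_true(cit$tier %in% c("FDR_significant", "potential"))
  expect_equal(cit$direction, "up")
  expect_true(tau$tier %in% c("FDR_significant", "potential"))
  expect_equal(tau$direction, "down")
  # direction consistency with the signed profile
  keep <- match_rows <- tb$variables
  prof <- significance_profile(
    sm, ifelse(sm$meta$week == 60, "A", "B"),
    group_a = "A"
  )
  prof <- prof[order(prof$ppm), ]
  expect_equal(
    as.character(keep$direction),
    as.character(prof$direction)
  )
})

test_that("comparisons naming absent levels list what is available", {
  coh <- simulate_cohort(noise_free_design())
  expect_error(
    build_biomarker_table(
      coh$spectra,
      comparison = list(a = list(week = 60), b = list(week = 15))
    ),
    "available.*15"
  )
})
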