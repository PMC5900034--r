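# Reference selection, rigid segment shifts, RSPA, custom intervals

# citrate/taurine-like mobile signals plus two anchored singlets; windows
# around the mobile signals contain no other metabolite
align_templates <- function(jitter_sd) {
  list(
    citrate = metabolite_template(
      "citrate",
      tibble::tibble(
        center = c(2.56, 2.70), multiplicity = "d", J = 15.8,
        relative_integral = c(0.5, 0.5), fwhm = 1.2
      ),
      shift_jitter_sd = jitter_sd
    ),
    taurine = metabolite_template(
      "taurine",
      tibble::tibble(
        center = c(3.27, 3.43), multiplicity = "t", J = 6.6,
        relative_integral = c(0.5, 0.5), fwhm = 1.0
      ),
      shift_jitter_sd = jitter_sd
    ),
    anchor1 = metabolite_template("anchor1", tibble::tibble(
      center = 1.5, multiplicity = "s", J = 0,
      relative_integral = 1, fwhm = 1
    )),
    anchor2 = metabolite_template("anchor2", tibble::tibble(
      center = 4.2, multiplicity = "s", J = 0,
      relative_integral = 1, fwhm = 1
    ))
  )
}

align_design <- function(jitter_sd = 0.01, n_mice = 10, seed = 21,
                         add_noise_sd = 0.02, mult_noise_cv = 0.05) {
  cohort_design(
    templates = align_templates(jitter_sd),
    groups = tibble::tibble(
      genotype = "WT", week = 15, n_mice = n_mice, spectra_per_mouse = 1
    ),
    dilution_log_range = c(1, 1), mult_noise_cv = mult_noise_cv,
    mouse_cv = 0, add_noise_sd = add_noise_sd,
    grid = c(0.5, 4.5, 0.001), seed = seed
  )
}

# sd over samples of the position of the window maximum
peak_pos_sd <- function(mat, window) {
  pos <- apply(mat$intensities, 1, function(y) {
    ppm_peak_pos(mat$ppm, y, window)
  })
  sd(pos)
}

# sd over samples of the intensity centroid (apex flips between the two
# equal lines of a doublet, the centroid does not)
centroid_sd <- function(mat, window) {
  idx <- which(mat$ppm >= window[1] & mat$ppm <= window[2])
  pos <- apply(mat$intensities, 1, function(y) {
    w <- pmax(y[idx], 0)
    sum(mat$ppm[idx] * w) / sum(w)
  })
  sd(pos)
}

test_that("reference selection prefers mutually similar samples", {
  ppm <- seq(4, 1, by = -0.005)
  base <- exp(-((seq_along(ppm) - 200) / 30)^2)
  set.seed(1)
  scram <- sample(base)
  m <- rbind(base, base, scram)
  rownames(m) <- c("s1", "s2", "s3")
  sm <- spectra_matrix(ppm, m, stub_meta(c("s1", "s2", "s3")))
  expect_true(select_reference(sm) %in% c("s1", "s2"))
  # all-tie case: lexicographically smallest id wins
  m2 <- rbind(base, base, base)
  rownames(m2) <- c("s2", "s3", "s1")
  sm2 <- spectra_matrix(ppm, m2, stub_meta(c("s2", "s3", "s1")))
  expect_equal(select_reference(sm2), "s1")
})

test_that("segment_shift equals brute-force enumeration on single peaks", {
  x <- seq(0, 1, length.out = 201)
  for (true_lag in c(-17, -3, 0, 8, 25)) {
    ref <- 1 / (1 + ((x - 0.5) / 0.02)^2)
    test <- c(
      rep(ref[1], max(0, true_lag)),
      ref[max(1, 1 - true_lag):min(201, 201 - true_lag)],
      rep(ref[201], max(0, -true_lag))
    )
    sh <- segment_shift(test, ref, max_lag = 40)
    expect_equal(sh$lag, brute_force_shift(test, ref, 40))
    expect_equal(sh$lag, -true_lag)
  }
})

test_that("segment_shift handles identity, flats and clipping", {
  ref <- dnorm(seq(-3, 3, length.out = 101))
  id <- segment_shift(ref, ref, 10)
  expect_equal(id$lag, 0L)
  fl <- segment_shift(rep(2, 101), ref, 10)
  expect_true(fl$flat)
  expect_equal(fl$lag, 0L)
  # displacement beyond the window pins at the bound and is flagged
  test <- c(rep(ref[1], 30), ref[1:71])
  sh <- segment_shift(test, ref, 10)
  expect_equal(abs(sh$lag), 10L)
  expect_true(sh$clipped)
})

test_that("an aligned cohort passes through rspa unchanged", {
  coh <- simulate_cohort(noise_free_design(grid = c(1, 4, 0.002)))
  res <- rspa(coh$spectra)
  expect_equal(nrow(res$shifts), 0)
  expect_identical(res$spectra$intensities, coh$spectra$intensities)
})

test_that("rspa reduces planted peak-position scatter at least 5-fold", {
  coh <- simulate_cohort(align_design(jitter_sd = 0.01, seed = 21))
  sm <- coh$spectra
  res <- rspa(sm, alignment_params(max_shift = 0.04))
  expect_gt(centroid_sd(sm, c(2.58, 2.82)) /
    centroid_sd(res$spectra, c(2.58, 2.82)), 5)
  expect_gt(peak_pos_sd(sm, c(3.35, 3.51)) /
    max(peak_pos_sd(res$spectra, c(3.35, 3.51)), 1e-6), 5)
  expect_true(all(abs(res$shifts$shift_ppm) <= 0.04 + 1e-12))
})

test_that("rspa never worsens correlation to the reference", {
  coh <- simulate_cohort(align_design(jitter_sd = 0.008, seed = 13))
  sm <- coh$spectra
  ref <- select_reference(sm)
  res <- rspa(sm, alignment_params(max_shift = 0.04), reference = ref)
  before <- cor(t(sm$intensities), sm$intensities[ref, ])
  after <- cor(t(res$spectra$intensities), sm$intensities[ref, ])
  expect_true(all(after - before > -1e-9))
})

test_that("a second rspa pass is near-idempotent", {
  coh <- simulate_cohort(align_design(jitter_sd = 0.008, seed = 17))
  r1 <- rspa(coh$spectra, alignment_params(max_shift = 0.04))
  r2 <- rspa(r1$spectra, alignment_params(max_shift = 0.04),
    reference = r1$reference
  )
  step <- 0.001
  if (nrow(r2$shifts)) {
    expect_true(all(abs(r2$shifts$shift_ppm) < 2 * step + 1e-12))
  } else {
    succeed()
  }
})

test_that("interval alignment is local and recovers large jitter", {
  coh <- simulate_cohort(align_design(
    jitter_sd = 0.015, n_mice = 8, seed = 8,
    add_noise_sd = 0, mult_noise_cv = 0
  ))
  sm <- coh$spectra
  ref <- select_reference(sm)
  res <- align_interval(
    sm, list(taurine = c(3.15, 3.55)),
    alignment_params(interval_max_shift = 0.08),
    reference = ref
  )
  outside <- sm$ppm < 3.15 | sm$ppm > 3.55
  expect_identical(
    res$spectra$intensities[, outside],
    sm$intensities[, outside]
  )
  # taurine jitter is recovered (relative to the reference's own jitter)
  truth <- coh$truth$shifts
  ref_shift <- truth$shift_ppm[truth$template == "taurine" &
    truth$sample_id == ref]
  for (sid in setdiff(sm$meta$sample_id, ref)) {
    planted <- truth$shift_ppm[truth$template == "taurine" &
      truth$sample_id == sid]
    applied <- res$shifts$shift_ppm[res$shifts$sample_id == sid]
    if (length(applied) == 0) applied <- 0
    expect_lt(abs((planted - ref_shift) + applied), 0.002 + 1e-12)
  }
  # empty interval list is the identity
  id <- align_interval(sm, list(), reference = ref)
  expect_identical(id$spectra$intensities, sm$intensities)
  expect_error(
    align_interval(sm, list(a = c(3.2, 3.5), b = c(3.4, 3.6)), reference = ref),
    "overlap"
  )
})
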