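#' Lorentzian line fit for FWHM measurement
#'
#' Least-squares fit of a four-parameter Lorentzian (amplitude, centre,
#' FWHM, constant baseline) over a window containing one dominant peak,
#' via Levenberg-Marquardt. The width is reported in Hz
#' (ppm width x spectrometer frequency in MHz).
#'
#' @param ppm ppm axis (any direction) or a `spectra_matrix`.
#' @param intensity Intensity vector (ignored when `ppm` is a
#'   `spectra_matrix`).
#' @param window Length-2 ppm interval containing the peak.
#' @param freq Spectrometer frequency, MHz.
#' @param sample_id Sample to measure when a `spectra_matrix` is given.
#' @param residual_flag Relative RMS residual above which the fit is
#'   flagged (overlapping peaks, poor window).
#' @return A tibble with one row: `center_ppm`, `fwhm_hz`, `fwhm_ppm`,
#'   `method = "lorentzian_fit"`, `residual`, `flagged`.
#' @export
fwhm_fit <- function(ppm, intensity = NULL, window, freq = 600.44,
                     sample_id = NULL, residual_flag = 0.05) {
  xy <- extract_window(ppm, intensity, window, sample_id)
  x <- xy$x
  y <- xy$y
  if (length(x) < 6) abort("Window contains fewer than 6 grid points.")
  i0 <- which.max(y)
  b0 <- min(y)
  a0 <- y[i0] - b0
  w0 <- max(half_max_estimate(x, y - b0, i0), diff(range(x)) / 20)
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * (w / 2)^2 / ((x - c0)^2 + (w / 2)^2),
      data = df,
      start = list(a = a0, c0 = x[i0], w = w0, b = b0),
      lower = c(a = 0, c0 = min(x), w = 1e-9, b = -Inf),
      upper = c(a = Inf, c0 = max(x), w = diff(range(x)) * 2, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(paste0("Lorentzian fit failed to converge: ", conditionMessage(e)))
    }
  )
  cf <- stats::coef(fit)
  resid_rel <- sqrt(mean(stats::resid(fit)^2)) / max(abs(y - cf[["b"]]))
  tibble(
    center_ppm = cf[["c0"]],
    fwhm_hz = cf[["w"]] * freq,
    fwhm_ppm = cf[["w"]],
    method = "lorentzian_fit",
    residual = resid_rel,
    flagged = resid_rel > residual_flag
  )
}

extract_window <- function(ppm, intensity, window, sample_id) {
  if (inherits(ppm, "spectra_matrix")) {
    sm <- ppm
    if (is.null(sample_id)) abort("`sample_id` required for a spectra_matrix.")
    idx <- ppm_window_idx(sm$ppm, window[1], window[2])
    x <- rev(sm$ppm[idx]) # ascending
    y <- rev(sm$intensities[sample_id, idx])
  } else {
    sel <- ppm >= window[1] & ppm <= window[2]
    o <- order(ppm[sel])
    x <- ppm[sel][o]
    y <- intensity[sel][o]
  }
  list(x = x, y = y)
}

half_max_estimate <- function(x, y, i0) {
  half <- y[i0] / 2
  left <- which(y[seq_len(i0)] <= half)
  right <- which(y[i0:length(y)] <= half)
  xl <- if (length(left)) x[max(left)] else min(x)
  xr <- if (length(right)) x[i0 - 1 + min(right)] else max(x)
  xr - xl
}

#' Interpolated half-band-width measurement
#'
#' The "manual" width measurement: after subtracting a baseline (median of
#' the outer 10% of window points), the two half-maximum crossings flanking
#' the apex are located by linear interpolation and their separation
#' reported in Hz. Invariant to uniform intensity scaling and to an
#' additive constant baseline.
#'
#' @inheritParams fwhm_fit
#' @return A tibble with one row: `center_ppm`, `fwhm_hz`, `fwhm_ppm`,
#'   `method = "half_max_interpolation"`, `residual = NA`, `flagged`.
#' @export
half_max_width <- function(ppm, intensity = NULL, window, freq = 600.44,
                           sample_id = NULL) {
  xy <- extract_window(ppm, intensity, window, sample_id)
  x <- xy$x
  y <- xy$y
  n <- length(x)
  if (n < 5) abort("Window contains fewer than 5 grid points.")
  n_edge <- max(1L, floor(0.05 * n))
  baseline <- median(c(y[seq_len(n_edge)], y[(n - n_edge + 1):n]))
  yb <- y - baseline
  i0 <- which.max(yb)
  if (i0 == 1 || i0 == n) abort("Peak maximum lies on the window edge.")
  half <- yb[i0] / 2
  cross <- function(i1, i2) { # linear interpolation of the crossing
    x[i1] + (half - yb[i1]) * (x[i2] - x[i1]) / (yb[i2] - yb[i1])
  }
  below_l <- which(yb[seq_len(i0 - 1)] <= half)
  below_r <- which(yb[(i0 + 1):n] <= half) + i0
  if (!length(below_l) || !length(below_r)) {
    abort("Half maximum is not crossed inside the window on both sides.")
  }
  il <- max(below_l)
  ir <- min(below_r)
  xl <- cross(il, il + 1L)
  xr <- cross(ir, ir - 1L)
  w_ppm <- xr - xl
  tibble(
    center_ppm = x[i0], fwhm_hz = w_ppm * freq, fwhm_ppm = w_ppm,
    method = "half_max_interpolation", residual = NA_real_, flagged = FALSE
  )
}

#' Welch two-sample comparison of line widths
#'
#' Two-tailed t test assuming unequal variances (Welch-Satterthwaite
#' degrees of freedom), the standard test for filtered-vs-unfiltered
#' half-band-width changes. Delegates to [stats::t.test()]; the degenerate
#' case (zero variance in both groups, equal means) returns `t = 0, p = 1`
#' by convention.
#'
#' @param widths_a,widths_b Numeric width measurements (Hz), n >= 2 each.
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble: `mean_a`, `mean_b`, `t`, `df`, `p`, `significant`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4)) # t = -1.2247, df = 4, p ~ 0.288
welch_t <- function(widths_a, widths_b, alpha = 0.05) {
  if (length(widths_a) < 2 || length(widths_b) < 2) {
    abort("Both groups need n >= 2.")
  }
  if (var(widths_a) == 0 && var(widths_b) == 0) {
    if (mean(widths_a) == mean(widths_b)) {
      return(tibble(
        mean_a = mean(widths_a), mean_b = mean(widths_b),
        t = 0, df = length(widths_a) + length(widths_b) - 2,
        p = 1, significant = FALSE
      ))
    }
    return(tibble(
      mean_a = mean(widths_a), mean_b = mean(widths_b),
      t = sign(mean(widths_a) - mean(widths_b)) * Inf,
      df = length(widths_a) + length(widths_b) - 2,
      p = 0, significant = TRUE
    ))
  }
  tt <- stats::t.test(widths_a, widths_b, var.equal = FALSE)
  tibble(
    mean_a = mean(widths_a), mean_b = mean(widths_b),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, significant = tt$p.value < alpha
  )
}

#' Metabolite identification carbon efficiency (MICE) score
#'
#' MICE summarises identification confidence as identification-information
#' bits per carbon atom: the total bits tallied across all evidence items
#' (1H/13C shifts, multiplicities, couplings, 2D correlations, spike-in
#' confirmation) divided by the carbon count. For 6H6MH3O, 24 bits across
#' the two tautomers over 8 carbons give a MICE of 3.0. No confidence
#' threshold is applied here; the score is reported as-is.
#'
#' @param evidence An evidence tally: either a data frame with columns
#'   `kind` and `bits`, or a single total-bits number. The package ships an
#'   illustrative tally at `system.file("extdata",
#'   "mice_evidence_6h6mh3o.tsv", package = "nmrage")`.
#' @param n_carbons Number of carbon atoms (>= 1).
#' @return A tibble: `total_bits`, `n_carbons`, `mice`.
#' @export
#' @examples
#' mice_score(24, 8) # 3.0
mice_score <- function(evidence, n_carbons) {
  if (is.data.frame(evidence)) {
    stopifnot(all(c("kind", "bits") %in% names(evidence)))
    if (any(evidence$bits <= 0)) abort("Evidence bits must be positive.")
    total <- sum(evidence$bits)
  } else {
    total <- as.numeric(evidence)
    if (length(total) != 1 || total < 0) abort("Invalid total bits.")
  }
  if (is.na(n_carbons) || n_carbons < 1) abort("`n_carbons` must be >= 1.")
  tibble(total_bits = total, n_carbons = n_carbons, mice = total / n_carbons)
}
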