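#' Calibrate the ppm axis to a reference peak
#'
#' Locates the maximum inside a search window for each spectrum and shifts
#' that spectrum (by interpolation back onto the shared grid) so the peak
#' sits at `target`. Urine spectra are conventionally referenced to TSP at
#' 0.0 ppm; plasma to the anomeric doublet of alpha-D-glucose at 5.233 ppm.
#'
#' @param x A `spectra_matrix`.
#' @param window Length-2 ppm interval searched for the reference peak.
#' @param target Target ppm of the located peak (default 0, TSP).
#' @param noise_mult The peak maximum must exceed `noise_mult` x the median
#'   absolute intensity of the spectrum, else an error is raised.
#' @return The calibrated `spectra_matrix`; applied shifts are recorded in
#'   the processing log and as attribute `shifts`.
#' @export
calibrate_ppm <- function(x, window = c(-0.05, 0.05), target = 0,
                          noise_mult = 5) {
  stopifnot(inherits(x, "spectra_matrix"))
  idx <- ppm_window_idx(x$ppm, window[1], window[2])
  if (length(idx) < 3) abort("Search window contains fewer than 3 grid points.")
  shifts <- numeric(nrow(x$intensities))
  for (i in seq_len(nrow(x$intensities))) {
    seg <- x$intensities[i, idx]
    floor_i <- noise_mult * median(abs(x$intensities[i, ]))
    if (max(seg) <= floor_i) {
      abort(sprintf(
        "No reference peak above the noise floor in [%g, %g] ppm for sample %s.",
        window[1], window[2], x$meta$sample_id[i]
      ))
    }
    peak_ppm <- x$ppm[idx[which.max(seg)]]
    delta <- target - peak_ppm
    shifts[i] <- delta
    if (delta != 0) {
      # shift spectrum by delta: value at ppm p comes from original p - delta
      x$intensities[i, ] <- interp_spectrum(x$ppm, x$intensities[i, ], -delta)
    }
  }
  x <- log_step(x, "calibrate_ppm", list(
    window = window, target = target, mean_shift = mean(shifts)
  ))
  attr(x, "shifts") <- tibble(sample_id = x$meta$sample_id, shift_ppm = shifts)
  x
}

# evaluate spectrum at ppm + delta via linear interpolation (edge padding)
interp_spectrum <- function(ppm, y, delta) {
  asc <- rev(ppm)
  yv <- rev(y)
  out <- stats::approx(asc, yv, xout = asc + delta, rule = 2)$y
  rev(out)
}

#' Resample spectra onto a target ppm grid
#'
#' Linear interpolation of every spectrum onto a new axis (values outside
#' the original axis take the nearest edge value). Linear — not spline —
#' interpolation is used deliberately: splines ring next to sharp
#' Lorentzian lines.
#'
#' @param x A `spectra_matrix`.
#' @param target_ppm Target axis (monotone, either direction).
#' @return A `spectra_matrix` on the target grid.
#' @export
resample_spectra <- function(x, target_ppm) {
  stopifnot(inherits(x, "spectra_matrix"))
  tp <- as.numeric(target_ppm)
  d <- diff(tp)
  if (!(all(d > 0) || all(d < 0))) abort("`target_ppm` must be monotone.")
  if (all(d > 0)) tp <- rev(tp)
  asc <- rev(x$ppm)
  out <- matrix(0, nrow(x$intensities), length(tp))
  for (i in seq_len(nrow(x$intensities))) {
    out[i, ] <- rev(stats::approx(asc, rev(x$intensities[i, ]),
      xout = rev(tp), rule = 2
    )$y)
  }
  rownames(out) <- x$meta$sample_id
  y <- spectra_matrix(tp, out, x$meta, log = x$log)
  log_step(y, "resample", list(
    n_from = length(x$ppm), n_to = length(tp)
  ))
}

# exclusion presets from the processing conventions for each fluid
exclusion_presets <- list(
  urine = list(c(-Inf, 0.8), c(4.7, 4.9), c(10, Inf)),
  plasma_1d = list(c(-Inf, 0.2), c(4.2, 5.2), c(10, Inf)),
  plasma_cpmg = list(c(-Inf, 0.8), c(4.6, 5.15), c(10, Inf))
)

#' Exclude spectral regions
#'
#' Drops grid points lying strictly inside any excluded interval. Presets
#' follow the standard urine/plasma conventions: urine keeps
#' \[0.8, 4.7\] U \[4.9, 10\] (water region delta 4.7-4.9 and the noise
#' regions upfield of 0.8 / downfield of 10 ppm removed); plasma 1D keeps
#' \[0.2, 4.2\] U \[5.2, 10\]; plasma CPMG keeps \[0.8, 4.6\] U \[5.15, 10\].
#' Interval endpoints themselves are retained. Overlapping intervals are
#' unioned; an inverted interval is an error.
#'
#' @param x A `spectra_matrix`.
#' @param preset One of `"urine"`, `"plasma_1d"`, `"plasma_cpmg"`, or `NULL`
#'   when `intervals` is given.
#' @param intervals A list of length-2 ppm intervals to exclude (used when
#'   `preset` is `NULL`; an empty list is the identity).
#' @return A `spectra_matrix` restricted to the retained variables.
#' @export
exclude_regions <- function(x, preset = NULL, intervals = NULL) {
  stopifnot(inherits(x, "spectra_matrix"))
  if (!is.null(preset)) {
    if (!preset %in% names(exclusion_presets)) {
      abort(paste0(
        "Unknown preset; available: ",
        toString(names(exclusion_presets))
      ))
    }
    intervals <- exclusion_presets[[preset]]
  }
  if (is.null(intervals)) intervals <- list()
  drop <- rep(FALSE, length(x$ppm))
  for (iv in intervals) {
    if (iv[1] > iv[2]) {
      abort(sprintf("Inverted exclusion interval (%g, %g).", iv[1], iv[2]))
    }
    drop <- drop | (x$ppm > iv[1] & x$ppm < iv[2])
  }
  x$intensities <- x$intensities[, !drop, drop = FALSE]
  x$ppm <- x$ppm[!drop]
  log_step(x, "exclude_regions", list(
    preset = preset %||% "explicit", n_excluded = sum(drop)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution (urine concentration differences): for each
#' sample the quotients against a reference spectrum are formed over
#' variables where the reference is positive, the sample's dilution factor
#' is the median quotient, and the sample is divided by it. The reference is
#' the element-wise median spectrum of the cohort by default (the canonical
#' choice), or a named sample.
#'
#' @param x A `spectra_matrix` (at least 2 samples; region exclusion should
#'   be applied first so water artefacts do not drive the factors).
#' @param reference `"median"`, a sample id, or a numeric reference
#'   spectrum on the same grid (e.g. the `reference_spectrum` of an earlier
#'   `pqn_result`, for self-consistent renormalization).
#' @param floor_frac Quotients are computed only where the reference exceeds
#'   `floor_frac` x its maximum.
#' @return A `pqn_result`: list with `spectra` (normalized matrix),
#'   `factors` (tibble `sample_id`, `dilution_factor`) and `reference`.
#' @export
pqn_normalize <- function(x, reference = "median", floor_frac = 1e-3) {
  stopifnot(inherits(x, "spectra_matrix"))
  if (nrow(x$intensities) < 2) abort("PQN needs at least 2 samples.")
  ref <- if (is.numeric(reference)) {
    if (length(reference) != ncol(x$intensities)) {
      abort("Numeric reference length does not match the variable count.")
    }
    reference
  } else if (identical(reference, "median")) {
    apply(x$intensities, 2, median)
  } else {
    if (!reference %in% x$meta$sample_id) {
      abort(sprintf("Reference sample %s not found.", reference))
    }
    x$intensities[reference, ]
  }
  keep <- ref > floor_frac * max(ref)
  if (!any(keep)) abort("Reference spectrum has no positive variables.")
  factors <- numeric(nrow(x$intensities))
  for (i in seq_len(nrow(x$intensities))) {
    xi <- x$intensities[i, ]
    if (all(xi == 0)) {
      abort(sprintf("Sample %s is all zero.", x$meta$sample_id[i]))
    }
    q <- xi[keep] / ref[keep]
    factors[i] <- median(q)
    if (!is.finite(factors[i]) || factors[i] <= 0) {
      abort(sprintf(
        "Non-positive dilution factor for sample %s.", x$meta$sample_id[i]
      ))
    }
    x$intensities[i, ] <- xi / factors[i]
  }
  ref_label <- if (is.numeric(reference)) "numeric" else reference
  x <- log_step(x, "pqn_normalize", list(reference = ref_label))
  structure(
    list(
      spectra = x,
      factors = tibble(
        sample_id = x$meta$sample_id, dilution_factor = factors
      ),
      reference = ref_label,
      reference_spectrum = ref
    ),
    class = "pqn_result"
  )
}

#' @export
print.pqn_result <- function(x, ...) {
  cat(sprintf(
    "<pqn_result> %d samples, dilution factors %.3g .. %.3g\n",
    nrow(x$factors), min(x$factors$dilution_factor),
    max(x$factors$dilution_factor)
  ))
  invisible(x)
}

#' @export
tidy.pqn_result <- function(x, ...) x$factors

#' Log-transform intensities
#'
#' Applies `y = ln(x + offset)`, converting multiplicative (e.g. lognormal
#' concentration) noise into approximately additive noise ahead of pattern
#' recognition. The default offset is the smallest positive entry of the
#' matrix.
#'
#' @param x A `spectra_matrix`, normally PQN-normalized first (a warning is
#'   given otherwise; override with `check_normalized = FALSE`).
#' @param offset Non-negative offset, or `"auto"`: the smallest positive
#'   entry of the matrix; when noise takes the baseline below zero the
#'   offset is raised so every argument of the logarithm stays positive.
#' @param check_normalized Warn when `pqn_normalize` is not in the
#'   processing log.
#' @return The transformed `spectra_matrix`.
#' @export
log_transform <- function(x, offset = "auto", check_normalized = TRUE) {
  stopifnot(inherits(x, "spectra_matrix"))
  if (check_normalized && !"pqn_normalize" %in% processing_steps(x)) {
    warn("Matrix has not been PQN-normalized; log-transforming anyway.")
  }
  if (identical(offset, "auto")) {
    pos <- x$intensities[x$intensities > 0]
    if (!length(pos)) abort("No positive intensities; cannot pick an offset.")
    offset <- min(pos)
    lo <- min(x$intensities)
    if (lo <= 0) {
      # noise takes the baseline below zero: raise the offset so the argument
      # stays positive and the baseline sits a noise-scale above zero
      offset <- offset - lo + mad(x$intensities[x$intensities <= 0], center = 0)
    }
  }
  if (offset < 0) abort("`offset` must be >= 0.")
  shifted <- x$intensities + offset
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)
    ex <- head(sprintf(
      "sample %s @ %.4f ppm", x$meta$sample_id[bad[, 1]], x$ppm[bad[, 2]]
    ), 5)
    abort(paste0(
      "x + offset <= 0 at ", nrow(bad), " position(s), e.g. ",
      toString(ex), ". Increase `offset`."
    ))
  }
  x$intensities <- log(shifted)
  log_step(x, "log_transform", list(offset = offset))
}
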