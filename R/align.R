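#' Alignment parameters
#'
#' @param max_shift Maximum segment shift, ppm (global pass default 0.02).
#' @param min_segment_width Minimum segment width for recursion, ppm.
#' @param peak_prominence_floor Fraction of the reference spectrum's maximum
#'   a segment's reference maximum must reach before the segment is shifted
#'   or recursed into; keeps pure-baseline segments from being shuffled to
#'   fit noise.
#' @param recursion_depth_limit Maximum recursion depth.
#' @param acceptance Minimum relative correlation gain required to keep a
#'   candidate shift.
#' @param interval_max_shift Maximum shift for the custom-interval second
#'   pass, ppm (citrate/taurine-scale variation).
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(max_shift = 0.02, min_segment_width = 0.01,
                             peak_prominence_floor = 0.01,
                             recursion_depth_limit = 20L, acceptance = 1e-3,
                             interval_max_shift = 0.05) {
  if (max_shift <= 0) abort("`max_shift` must be > 0.")
  structure(
    list(
      max_shift = max_shift, min_segment_width = min_segment_width,
      peak_prominence_floor = peak_prominence_floor,
      recursion_depth_limit = as.integer(recursion_depth_limit),
      acceptance = acceptance, interval_max_shift = interval_max_shift
    ),
    class = "alignment_params"
  )
}

#' Select the alignment reference sample
#'
#' Returns the sample whose spectrum has the highest mean Pearson
#' correlation to all other samples; ties are broken by lexicographically
#' smallest sample id.
#'
#' @param x A `spectra_matrix` with at least 2 samples.
#' @return A sample id.
#' @export
select_reference <- function(x) {
  stopifnot(inherits(x, "spectra_matrix"))
  n <- nrow(x$intensities)
  if (n < 2) abort("Need at least 2 samples to pick a reference.")
  cm <- suppressWarnings(cor(t(x$intensities)))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- NA
  mean_cor <- rowMeans(cm, na.rm = TRUE)
  ids <- x$meta$sample_id
  best <- max(mean_cor)
  cand <- sort(ids[mean_cor >= best - 1e-12])
  cand[1]
}

#' Optimal rigid shift of a segment against a reference
#'
#' Enumerates every integer grid shift in `[-max_lag, max_lag]` and returns
#' the one maximising the Pearson correlation between the shifted test
#' segment (edges padded with the edge value) and the reference segment.
#' Ties are broken towards the smallest `|shift|`. A flat (zero-variance)
#' segment gets shift 0 and is flagged.
#'
#' @param test,reference Equal-length numeric segments.
#' @param max_lag Maximum shift in grid points.
#' @return List with `lag` (signed grid points; positive moves the segment
#'   towards higher index), `corr_before`, `corr_after`, `flat`, `clipped`.
#' @export
segment_shift <- function(test, reference, max_lag) {
  n <- length(test)
  stopifnot(length(reference) == n)
  max_lag <- min(as.integer(max_lag), n - 1L)
  flat <- sd(test) == 0 || sd(reference) == 0
  corr0 <- if (flat) 0 else cor(test, reference)
  if (flat) {
    return(list(
      lag = 0L, corr_before = corr0, corr_after = corr0,
      flat = TRUE, clipped = FALSE
    ))
  }
  lags <- seq.int(-max_lag, max_lag)
  best_lag <- 0L
  best_cor <- -Inf
  for (L in lags[order(abs(lags), lags)]) { # visit small |shift| first
    cand <- shift_padded(test, L)
    cc <- if (sd(cand) == 0) 0 else cor(cand, reference)
    if (cc > best_cor + 1e-15) {
      best_cor <- cc
      best_lag <- L
    }
  }
  list(
    lag = best_lag, corr_before = corr0, corr_after = best_cor,
    flat = FALSE, clipped = abs(best_lag) == max_lag && max_lag > 0
  )
}

# shift a vector by L grid points, padding with the edge value
shift_padded <- function(v, L) {
  n <- length(v)
  if (L == 0) {
    return(v)
  }
  if (L > 0) {
    c(rep(v[1], L), v[seq_len(n - L)])
  } else {
    c(v[(-L + 1):n], rep(v[n], -L))
  }
}

# deepest local minimum within the central half of a reference segment;
# restricting the split point keeps the recursion balanced, so depth grows
# logarithmically instead of peeling slivers off one end
deepest_minimum <- function(ref, margin) {
  n <- length(ref)
  margin <- max(margin, n %/% 4L)
  if (n < 2 * margin + 3) {
    return(NA_integer_)
  }
  core <- (margin + 1):(n - margin)
  v <- ref[core]
  is_min <- v <= c(Inf, head(v, -1)) & v <= c(tail(v, -1), Inf)
  if (!any(is_min)) {
    return(NA_integer_)
  }
  core[which(is_min & v == min(v[is_min]))[1]]
}

#' Recursive segment-wise peak alignment
#'
#' Aligns every spectrum to a reference (chosen by [select_reference()]
#' unless given): each segment is rigidly shifted by the cross-correlation
#' optimum, then split at the deepest interior local minimum of the
#' reference and the halves aligned recursively, while the segment is wider
#' than `min_segment_width`, recursion is within the depth limit, and
#' shifting improves the correlation by at least the acceptance fraction.
#' Shifts never exceed `max_shift`; a candidate pinned at the window bound
#' is flagged clipped.
#'
#' @param x A `spectra_matrix` (post-exclusion).
#' @param params An [alignment_params()].
#' @param reference A sample id, or `NULL` to auto-select.
#' @return An `alignment_result`: `spectra` (aligned matrix), `reference`,
#'   and `shifts` — a tibble with one row per applied segment shift
#'   (`sample_id`, `segment_start`, `segment_end`, `shift_ppm`,
#'   `corr_before`, `corr_after`, `clipped`).
#' @export
rspa <- function(x, params = alignment_params(), reference = NULL) {
  stopifnot(inherits(x, "spectra_matrix"))
  step <- grid_step(x$ppm)
  if (is.null(reference)) reference <- select_reference(x)
  ref_row <- x$intensities[reference, ]
  max_lag <- max(1L, floor(params$max_shift / step))
  min_pts <- max(3L, ceiling(params$min_segment_width / step))
  prominence <- params$peak_prominence_floor * max(ref_row)
  recs <- list()

  align_one <- function(y, sid) {
    recurse <- function(lo, hi, depth) {
      n_seg <- hi - lo + 1L
      if (max(ref_row[lo:hi]) < prominence) {
        return(invisible()) # no real peak in this segment
      }
      seg_lag <- min(max_lag, n_seg - 1L)
      sh <- segment_shift(y[lo:hi], ref_row[lo:hi], seg_lag)
      gain_ok <- !sh$flat &&
        (sh$corr_after - sh$corr_before) >=
          params$acceptance * max(abs(sh$corr_before), 1e-12) &&
        sh$corr_after >= sh$corr_before
      if (gain_ok && sh$lag != 0L) {
        y[lo:hi] <<- shift_padded(y[lo:hi], sh$lag)
        recs[[length(recs) + 1L]] <<- tibble(
          sample_id = sid,
          segment_start = x$ppm[hi], segment_end = x$ppm[lo],
          shift_ppm = -sh$lag * step, # positive index lag = downfield-to-upfield
          corr_before = sh$corr_before, corr_after = sh$corr_after,
          clipped = sh$clipped
        )
      }
      if (depth >= params$recursion_depth_limit) {
        return(invisible())
      }
      split <- deepest_minimum(ref_row[lo:hi], margin = max(2L, min_pts %/% 2L))
      if (is.na(split)) {
        return(invisible())
      }
      mid <- lo + split - 1L
      if ((mid - lo + 1L) >= min_pts && (hi - mid) >= min_pts) {
        recurse(lo, mid, depth + 1L)
        recurse(mid + 1L, hi, depth + 1L)
      }
      invisible()
    }
    recurse(1L, length(y), 0L)
    y
  }

  for (i in seq_len(nrow(x$intensities))) {
    sid <- x$meta$sample_id[i]
    if (sid == reference) next
    x$intensities[i, ] <- align_one(x$intensities[i, ], sid)
  }
  x <- log_step(x, "rspa", list(
    reference = reference, max_shift = params$max_shift
  ))
  shifts <- if (length(recs)) bind_rows(recs) else empty_shift_table()
  structure(
    list(spectra = x, reference = reference, shifts = shifts),
    class = "alignment_result"
  )
}

empty_shift_table <- function() {
  tibble(
    sample_id = character(), segment_start = numeric(),
    segment_end = numeric(), shift_ppm = numeric(),
    corr_before = numeric(), corr_after = numeric(), clipped = logical()
  )
}

#' Custom-interval alignment pass
#'
#' Second alignment step for signals with large chemical-shift variation
#' (citrate, taurine): each user-defined, baseline-separated interval is
#' aligned to the reference as one rigid segment per sample, with no
#' recursion; intensities outside the intervals are untouched.
#'
#' @param x A `spectra_matrix`.
#' @param intervals Named list of length-2 ppm intervals (must not overlap).
#' @param params An [alignment_params()]; `interval_max_shift` bounds the
#'   rigid shifts.
#' @param reference A sample id, or `NULL` to auto-select.
#' @param edge_floor_frac Warn when interval-edge intensity of the reference
#'   exceeds this fraction of the interval maximum (interval not
#'   baseline-separated).
#' @return An `alignment_result` (see [rspa()]).
#' @export
align_interval <- function(x, intervals, params = alignment_params(),
                           reference = NULL, edge_floor_frac = 0.1) {
  stopifnot(inherits(x, "spectra_matrix"))
  step <- grid_step(x$ppm)
  if (is.null(reference)) reference <- select_reference(x)
  ref_row <- x$intensities[reference, ]
  if (length(intervals) > 1) {
    ivm <- do.call(rbind, intervals)
    o <- order(ivm[, 1])
    ivm <- ivm[o, , drop = FALSE]
    if (any(ivm[-1, 1] < ivm[-nrow(ivm), 2])) {
      abort("Custom alignment intervals overlap.")
    }
  }
  max_lag <- max(1L, floor(params$interval_max_shift / step))
  recs <- list()
  for (nmi in seq_along(intervals)) {
    iv <- intervals[[nmi]]
    iname <- names(intervals)[nmi] %||% as.character(nmi)
    idx <- ppm_window_idx(x$ppm, iv[1], iv[2])
    if (length(idx) < 3) abort(sprintf("Interval %s is off-grid.", iname))
    rseg <- ref_row[idx]
    if (max(rseg) > 0 &&
      max(rseg[1], rseg[length(rseg)]) > edge_floor_frac * max(rseg)) {
      warn(sprintf(
        "Interval %s [%g, %g] is not baseline-separated at its edges.",
        iname, iv[1], iv[2]
      ))
    }
    for (i in seq_len(nrow(x$intensities))) {
      sid <- x$meta$sample_id[i]
      if (sid == reference) next
      sh <- segment_shift(x$intensities[i, idx], rseg, max_lag)
      if (!sh$flat && sh$lag != 0L && sh$corr_after >= sh$corr_before) {
        x$intensities[i, idx] <- shift_padded(x$intensities[i, idx], sh$lag)
        recs[[length(recs) + 1L]] <- tibble(
          sample_id = sid, segment_start = iv[1], segment_end = iv[2],
          shift_ppm = -sh$lag * step,
          corr_before = sh$corr_before, corr_after = sh$corr_after,
          clipped = sh$clipped
        )
      }
    }
  }
  x <- log_step(x, "align_interval", list(
    n_intervals = length(intervals), reference = reference
  ))
  shifts <- if (length(recs)) bind_rows(recs) else empty_shift_table()
  structure(
    list(spectra = x, reference = reference, shifts = shifts),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> reference %s, %d segment shifts (max |shift| %.4g ppm)\n",
    x$reference, nrow(x$shifts),
    if (nrow(x$shifts)) max(abs(x$shifts$shift_ppm)) else 0
  ))
  invisible(x)
}

#' @export
tidy.alignment_result <- function(x, ...) x$shifts

#' @export
glance.alignment_result <- function(x, ...) {
  tibble(
    reference = x$reference,
    n_shifts = nrow(x$shifts),
    max_abs_shift_ppm = if (nrow(x$shifts)) max(abs(x$shifts$shift_ppm)) else 0,
    n_clipped = sum(x$shifts$clipped)
  )
}
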