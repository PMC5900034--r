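#' Spectra matrix container
#'
#' A `spectra_matrix` bundles a set of 1D NMR spectra that share a common
#' chemical-shift axis: the ppm axis (stored in descending order, the NMR
#' plotting convention), a samples x variables intensity matrix, a per-sample
#' metadata table, and an append-only processing log recording every
#' preprocessing step applied with its parameters.
#'
#' @param ppm Numeric chemical-shift axis. Must be strictly monotone; stored
#'   descending (the intensity columns are reordered to match if an ascending
#'   axis is supplied).
#' @param intensities Numeric matrix, one row per sample, `length(ppm)`
#'   columns. Row names, if present, must match `meta$sample_id`.
#' @param meta A data frame with columns `sample_id`, `mouse_id`, `genotype`,
#'   `week`, `fluid`, `batch` (additional columns are kept). `sample_id` must
#'   be unique.
#' @param log A list of processing-log entries; normally left empty and grown
#'   by the preprocessing functions.
#'
#' @return An object of class `spectra_matrix`.
#' @export
#' @examples
#' ppm <- seq(4, 1, by = -0.01)
#' y <- matrix(rexp(2 * length(ppm)), nrow = 2)
#' meta <- tibble::tibble(
#'   sample_id = c("s1", "s2"), mouse_id = c("m1", "m2"),
#'   genotype = "WT", week = 15, fluid = "urine", batch = 1
#' )
#' sm <- spectra_matrix(ppm, y, meta)
#' sm
spectra_matrix <- function(ppm, intensities, meta, log = list()) {
  ppm <- as.numeric(ppm)
  if (length(ppm) < 2L) abort("`ppm` must have at least two points.")
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) {
    abort("`ppm` axis must be strictly monotone.")
  }
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(ppm)) {
    abort(sprintf(
      "`intensities` has %d columns but `ppm` has %d points.",
      ncol(intensities), length(ppm)
    ))
  }
  if (all(d > 0)) { # store descending
    ppm <- rev(ppm)
    intensities <- intensities[, rev(seq_along(ppm)), drop = FALSE]
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    abort("`intensities` contains non-finite values.")
  }
  meta <- as_tibble(meta)
  required <- c("sample_id", "mouse_id", "genotype", "week", "fluid", "batch")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort(paste0("`meta` is missing columns: ", toString(missing_cols)))
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
    abort(paste0("Duplicated sample ids: ", toString(dup)))
  }
  if (nrow(meta) != nrow(intensities)) {
    abort(sprintf(
      "%d metadata rows for %d spectra.", nrow(meta), nrow(intensities)
    ))
  }
  if (!is.null(rownames(intensities)) &&
    !identical(rownames(intensities), meta$sample_id)) {
    if (!setequal(rownames(intensities), meta$sample_id)) {
      only_m <- setdiff(meta$sample_id, rownames(intensities))
      only_i <- setdiff(rownames(intensities), meta$sample_id)
      abort(paste0(
        "Sample ids disagree between intensities and metadata. ",
        if (length(only_m)) paste0("Only in metadata: ", toString(only_m), ". "),
        if (length(only_i)) paste0("Only in matrix: ", toString(only_i), ".")
      ))
    }
    intensities <- intensities[meta$sample_id, , drop = FALSE]
  }
  rownames(intensities) <- meta$sample_id
  structure(
    list(ppm = ppm, intensities = intensities, meta = meta, log = log),
    class = "spectra_matrix"
  )
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf(
    "<spectra_matrix> %d spectra x %d variables, ppm %.4f..%.4f\n",
    nrow(x$intensities), length(x$ppm), max(x$ppm), min(x$ppm)
  ))
  cat("fluids:", toString(unique(x$meta$fluid)), "\n")
  if (length(x$log)) {
    cat("processing log:\n")
    for (e in x$log) cat("  -", format_log_entry(e), "\n")
  } else {
    cat("processing log: (empty)\n")
  }
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$intensities)

format_log_entry <- function(e) {
  pars <- vapply(e$params, function(p) {
    paste(format(unlist(p), trim = TRUE), collapse = ",")
  }, character(1))
  paste0(e$step, if (length(pars)) {
    paste0("(", paste(names(pars), pars, sep = "=", collapse = ", "), ")")
  })
}

log_step <- function(x, step, params = list()) {
  x$log <- c(x$log, list(list(step = step, params = params)))
  x
}

#' Names of processing steps already applied
#' @param x A `spectra_matrix`.
#' @return Character vector of step names, in order of application.
#' @export
processing_steps <- function(x) {
  vapply(x$log, `[[`, character(1), "step")
}

#' Long-format view of a spectra matrix
#'
#' @param x A `spectra_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `ppm`, `intensity`, joined with
#'   the sample metadata.
#' @export
tidy.spectra_matrix <- function(x, ...) {
  long <- tibble(
    sample_id = rep(x$meta$sample_id, each = length(x$ppm)),
    ppm = rep(x$ppm, times = nrow(x$intensities)),
    intensity = as.vector(t(x$intensities))
  )
  left_join(long, x$meta, by = "sample_id")
}

#' @export
#' @rdname tidy.spectra_matrix
glance.spectra_matrix <- function(x, ...) {
  tibble(
    n_samples = nrow(x$intensities),
    n_variables = length(x$ppm),
    ppm_max = max(x$ppm),
    ppm_min = min(x$ppm),
    n_steps = length(x$log)
  )
}

#' Plot spectra as overlaid traces
#'
#' @param object A `spectra_matrix`.
#' @param colour_by Metadata column used for the colour aesthetic.
#' @param ... Unused.
#' @return A ggplot object (ppm axis reversed, NMR convention).
#' @export
autoplot.spectra_matrix <- function(object, colour_by = "genotype", ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$ppm, y = .data$intensity,
    group = .data$sample_id, colour = .data[[colour_by]]
  )) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity")
}

#' Read / write a spectra matrix
#'
#' The on-disk form is a CSV intensity table (first column `ppm`, descending;
#' one column per sample, named by sample id) plus a TSV metadata table with
#' columns `sample_id`, `mouse_id`, `genotype`, `week`, `fluid`, `batch`.
#' `write_spectra()` then `read_spectra()` round-trips to at least 12
#' significant digits.
#'
#' @param matrix_path Path of the intensity CSV.
#' @param metadata_path Path of the metadata TSV.
#' @return `read_spectra()` returns a `spectra_matrix`; `write_spectra()`
#'   returns its input invisibly.
#' @export
read_spectra <- function(matrix_path, metadata_path) {
  mat <- readr::read_csv(matrix_path, show_col_types = FALSE, progress = FALSE)
  if (names(mat)[1] != "ppm") abort("First column of the matrix CSV must be `ppm`.")
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE, progress = FALSE)
  ppm <- mat$ppm
  ids <- names(mat)[-1]
  if (anyDuplicated(ids)) {
    abort(paste0(
      "Duplicated sample columns: ", toString(unique(ids[duplicated(ids)]))
    ))
  }
  inten <- t(as.matrix(mat[, -1, drop = FALSE]))
  rownames(inten) <- ids
  meta$sample_id <- as.character(meta$sample_id)
  only_m <- setdiff(meta$sample_id, ids)
  only_i <- setdiff(ids, meta$sample_id)
  if (length(only_m) || length(only_i)) {
    abort(paste0(
      "Sample ids disagree between files. ",
      if (length(only_m)) paste0("Missing from matrix: ", toString(only_m), ". "),
      if (length(only_i)) paste0("Missing from metadata: ", toString(only_i), ".")
    ))
  }
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  spectra_matrix(ppm, inten, meta)
}

#' @param x A `spectra_matrix` to write.
#' @rdname read_spectra
#' @export
write_spectra <- function(x, matrix_path, metadata_path) {
  stopifnot(inherits(x, "spectra_matrix"))
  df <- as.data.frame(t(x$intensities))
  names(df) <- x$meta$sample_id
  df <- cbind(ppm = x$ppm, df)
  readr::write_csv(as_tibble(df), matrix_path, progress = FALSE)
  readr::write_tsv(x$meta, metadata_path, progress = FALSE)
  invisible(x)
}

grid_step <- function(ppm) {
  d <- diff(ppm)
  s <- mean(abs(d))
  if (max(abs(abs(d) - s)) > 1e-9 * s) {
    abort("ppm grid is not uniform (relative step deviation exceeds 1e-9).")
  }
  s
}

# index range (ascending-in-index order) of a ppm interval on a descending axis
ppm_window_idx <- function(ppm, lo, hi) {
  if (lo > hi) abort("Inverted ppm interval.")
  which(ppm >= lo & ppm <= hi)
}
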