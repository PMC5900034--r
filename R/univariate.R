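#' Per-variable one-way ANOVA
#'
#' Vectorised one-way F test across groups for every spectral variable,
#' intended for log-transformed, normalized intensities. Variables with zero
#' between-group difference and zero within-group variance get `p = 1` by
#' convention (flagged in `degenerate`); zero within-group variance with a
#' real group difference gives `p = 0`.
#'
#' @param x A `spectra_matrix` or samples x variables matrix.
#' @param groups Group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @return A tibble with one row per variable: `ppm` (or column index), `F`,
#'   `p`, `degenerate`.
#' @export
anova_f <- function(x, groups) {
  m <- as_feature_matrix(x)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  gl <- sort(unique(groups))
  k <- length(gl)
  n <- nrow(m)
  if (k < 2) abort("Need at least 2 groups.")
  if (any(table(groups) < 2)) abort("Every group needs n >= 2.")
  grand <- colMeans(m)
  ssb <- numeric(ncol(m))
  ssw <- numeric(ncol(m))
  for (g in gl) {
    mg <- m[groups == g, , drop = FALSE]
    mu_g <- colMeans(mg)
    ssb <- ssb + nrow(mg) * (mu_g - grand)^2
    ssw <- ssw + colSums(sweep(mg, 2, mu_g)^2)
  }
  df1 <- k - 1
  df2 <- n - k
  f_stat <- (ssb / df1) / (ssw / df2)
  p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  degenerate <- ssw == 0 & ssb == 0
  f_stat[degenerate] <- 0
  p[degenerate] <- 1
  zero_w <- ssw == 0 & ssb > 0
  f_stat[zero_w] <- Inf
  p[zero_w] <- 0
  ppm <- if (inherits(x, "spectra_matrix")) x$ppm else seq_len(ncol(m))
  tibble(ppm = ppm, F = f_stat, p = p, degenerate = degenerate)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Sorts the p-values ascending, finds the largest `k` with
#' `p_(k) <= k q / m`, and declares every p-value at or below `p_(k)`
#' significant. The attained threshold `p_(k)` (0 when nothing passes) is
#' the quantity quoted alongside FDR-filtered biomarker tables.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param q Target false discovery rate, in (0, 1).
#' @return List with `significant` (logical mask, same order as `p`),
#'   `threshold` (attained p-value cutoff) and `q`.
#' @export
bh_adjust <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  if (q <= 0 || q >= 1) abort("`q` must be in (0, 1).")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- ps <= seq_len(m) * q / m
  if (!any(ok)) {
    return(list(significant = rep(FALSE, m), threshold = 0, q = q))
  }
  thr <- ps[max(which(ok))]
  list(significant = p <= thr, threshold = thr, q = q)
}

#' Classify variables into significance tiers
#'
#' Three tiers, matching the reporting convention of FDR-filtered
#' metabonomics tables: `FDR_significant` (passes the BH mask), `potential`
#' (fails FDR but `p < 0.05`, the liberal threshold, reported with a "p"
#' flag), `ns` otherwise.
#'
#' @param p p-values.
#' @param bh_mask Logical mask from [bh_adjust()].
#' @return Factor with levels `FDR_significant`, `potential`, `ns`.
#' @export
classify_tiers <- function(p, bh_mask) {
  stopifnot(length(p) == length(bh_mask))
  tier <- ifelse(bh_mask, "FDR_significant", ifelse(p < 0.05, "potential", "ns"))
  factor(tier, levels = c("FDR_significant", "potential", "ns"))
}

#' Signed significance profile for a two-group comparison
#'
#' The per-variable log-scale mean difference (group A minus group B) paired
#' with its ANOVA p-value — the data behind ANOVA plots with positive peaks
#' for signals more intense in A, colour-coded by p.
#'
#' @param x A `spectra_matrix` or matrix (log scale).
#' @param groups Label per sample; exactly two distinct values.
#' @param group_a The label treated as "A" (positive direction); defaults to
#'   the first sorted label.
#' @param p Optional precomputed p-values (recomputed via [anova_f()] if
#'   `NULL`).
#' @return A tibble: `ppm`, `difference`, `p`, `direction` (`up`/`down`/
#'   `none`).
#' @export
significance_profile <- function(x, groups, group_a = NULL, p = NULL) {
  m <- as_feature_matrix(x)
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  if (length(gl) != 2) {
    abort("Exactly two groups required; run pairwise comparisons instead.")
  }
  if (is.null(group_a)) group_a <- gl[1]
  if (!group_a %in% gl) abort(sprintf("Unknown group %s.", group_a))
  group_b <- setdiff(gl, group_a)
  if (is.null(p)) p <- anova_f(x, groups)$p
  diff_ab <- colMeans(m[groups == group_a, , drop = FALSE]) -
    colMeans(m[groups == group_b, , drop = FALSE])
  ppm <- if (inherits(x, "spectra_matrix")) x$ppm else seq_len(ncol(m))
  tibble(
    ppm = ppm, difference = diff_ab, p = p,
    direction = factor(
      ifelse(diff_ab > 0, "up", ifelse(diff_ab < 0, "down", "none")),
      levels = c("up", "down", "none")
    )
  )
}

#' Plot a signed significance profile
#'
#' @param profile Output of [significance_profile()].
#' @param threshold p-value threshold used for the colour split (e.g. the
#'   attained BH threshold).
#' @return A ggplot object: the signed difference profile over ppm
#'   (axis reversed), coloured by -log10 p, with sub-threshold points
#'   highlighted.
#' @export
plot_significance_profile <- function(profile, threshold = 0.05) {
  ggplot2::ggplot(profile, ggplot2::aes(
    x = .data$ppm, y = .data$difference,
    colour = pmin(-log10(.data$p), 6)
  )) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_colour_viridis_c(name = "-log10 p", option = "plasma") +
    ggplot2::labs(
      x = "chemical shift (ppm)",
      y = "mean log-intensity difference",
      subtitle = sprintf("significance threshold p = %.3g", threshold)
    )
}

#' Read an annotation window library
#'
#' @param path TSV with columns `metabolite`, `ppm_lo`, `ppm_hi` (one row
#'   per signal window; a metabolite may own several windows). The package
#'   ships a urine library seeded from literature 1H shifts at
#'   `system.file("extdata", "urine_annotation_windows.tsv",
#'   package = "nmrage")`.
#' @return A tibble.
#' @export
read_annotation_windows <- function(path = system.file(
                                      "extdata", "urine_annotation_windows.tsv",
                                      package = "nmrage"
                                    )) {
  an <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("metabolite", "ppm_lo", "ppm_hi") %in% names(an)))
  an
}

#' Build a biomarker table for one pairwise comparison
#'
#' Runs the univariate chain — per-variable ANOVA, BH-FDR, tier
#' classification, direction of change — for one comparison (e.g. "WT 60
#' vs. 15"), and optionally collapses variables to annotated metabolites by
#' ppm windows: a metabolite's tier is the best tier among its windows, its
#' direction the consensus across windows (conflicts flagged, not
#' resolved).
#'
#' @param x A `spectra_matrix` (log scale, normalized).
#' @param comparison A list `list(a = <filter>, b = <filter>)` where each
#'   filter is a named list of metadata values, e.g.
#'   `list(genotype = "WT", week = 60)`.
#' @param annotations Optional annotation window tibble
#'   (see [read_annotation_windows()]).
#' @param fdr Target FDR (0.05 or 0.10 in the standard workflow).
#' @return A `biomarker_table`: `variables` (per-variable tibble),
#'   `metabolites` (per-metabolite tibble or `NULL`), `comparison` label,
#'   `fdr`, `threshold` (attained BH cutoff).
#' @export
build_biomarker_table <- function(x, comparison, annotations = NULL,
                                  fdr = 0.1) {
  stopifnot(inherits(x, "spectra_matrix"))
  sel_a <- match_meta(x$meta, comparison$a)
  sel_b <- match_meta(x$meta, comparison$b)
  if (!any(sel_a)) abort_absent(x$meta, comparison$a)
  if (!any(sel_b)) abort_absent(x$meta, comparison$b)
  if (any(sel_a & sel_b)) abort("Comparison groups overlap.")
  keep <- sel_a | sel_b
  m <- x$intensities[keep, , drop = FALSE]
  grp <- ifelse(sel_a[keep], "A", "B")
  av <- anova_f(m, grp)
  av$ppm <- x$ppm
  bh <- bh_adjust(av$p, q = fdr)
  prof <- significance_profile(m, grp, group_a = "A", p = av$p)
  variables <- tibble(
    ppm = x$ppm, F = av$F, p = av$p,
    significant_fdr = bh$significant,
    tier = classify_tiers(av$p, bh$significant),
    direction = prof$direction,
    mean_log_difference = prof$difference
  ) %>% arrange(.data$ppm)
  metabolites <- NULL
  if (!is.null(annotations)) {
    metabolites <- collapse_to_metabolites(variables, annotations, x$ppm)
  }
  structure(
    list(
      variables = variables, metabolites = metabolites,
      comparison = comparison_label(comparison),
      fdr = fdr, threshold = bh$threshold
    ),
    class = "biomarker_table"
  )
}

match_meta <- function(meta, filt) {
  sel <- rep(TRUE, nrow(meta))
  for (nm in names(filt)) {
    if (!nm %in% names(meta)) abort(sprintf("No metadata column `%s`.", nm))
    sel <- sel & meta[[nm]] %in% filt[[nm]]
  }
  sel
}

abort_absent <- function(meta, filt) {
  avail <- vapply(names(filt), function(nm) {
    paste0(nm, " in {", toString(sort(unique(meta[[nm]]))), "}")
  }, character(1))
  abort(paste0(
    "No samples match ", comparison_label(list(a = filt, b = filt)),
    "; available: ", paste(avail, collapse = "; ")
  ))
}

comparison_label <- function(comparison) {
  lab <- function(f) paste(unlist(f), collapse = " ")
  paste(lab(comparison$a), "vs.", lab(comparison$b))
}

collapse_to_metabolites <- function(variables, annotations, ppm) {
  tier_rank <- c(FDR_significant = 1, potential = 2, ns = 3)
  rows <- list()
  for (met in unique(annotations$metabolite)) {
    wins <- annotations[annotations$metabolite == met, , drop = FALSE]
    win_best <- list()
    for (w in seq_len(nrow(wins))) {
      inw <- variables$ppm >= wins$ppm_lo[w] & variables$ppm <= wins$ppm_hi[w]
      if (!any(inw)) {
        warn(sprintf(
          "Annotation window [%g, %g] for %s is off-grid; skipped.",
          wins$ppm_lo[w], wins$ppm_hi[w], met
        ))
        next
      }
      vv <- variables[inw, , drop = FALSE]
      b <- vv[which.min(vv$p), , drop = FALSE]
      win_best[[length(win_best) + 1L]] <- b
    }
    if (!length(win_best)) next
    wb <- bind_rows(win_best)
    best <- wb[which.min(tier_rank[as.character(wb$tier)]), , drop = FALSE]
    informative <- wb[as.character(wb$tier) != "ns", , drop = FALSE]
    dirs <- unique(as.character(
      (if (nrow(informative)) informative else best)$direction
    ))
    conflict <- length(setdiff(dirs, "none")) > 1
    rows[[met]] <- tibble(
      metabolite = met,
      ppm_windows = paste(sprintf("%.3f-%.3f", wins$ppm_lo, wins$ppm_hi),
        collapse = ","
      ),
      tier = best$tier,
      direction = if (conflict) "conflict" else dirs[1],
      p_min = min(wb$p),
      conflict = conflict
    )
  }
  if (!length(rows)) {
    return(NULL)
  }
  bind_rows(rows) %>% arrange(.data$metabolite)
}

#' @export
print.biomarker_table <- function(x, ...) {
  cat(sprintf(
    "<biomarker_table> %s (FDR %.2f, attained threshold %.4g)\n",
    x$comparison, x$fdr, x$threshold
  ))
  cat(sprintf(
    "  %d / %d variables FDR-significant; %d potential\n",
    sum(x$variables$tier == "FDR_significant"), nrow(x$variables),
    sum(x$variables$tier == "potential")
  ))
  if (!is.null(x$metabolites)) {
    sig <- x$metabolites[x$metabolites$tier != "ns", , drop = FALSE]
    cat(sprintf("  %d annotated metabolites at tier >= potential\n", nrow(sig)))
  }
  invisible(x)
}

#' @export
tidy.biomarker_table <- function(x, ...) {
  if (!is.null(x$metabolites)) x$metabolites else x$variables
}

#' @export
glance.biomarker_table <- function(x, ...) {
  tibble(
    comparison = x$comparison, fdr = x$fdr, threshold = x$threshold,
    n_fdr_significant = sum(x$variables$tier == "FDR_significant"),
    n_potential = sum(x$variables$tier == "potential")
  )
}
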