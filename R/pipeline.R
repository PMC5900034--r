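#' Study configuration
#'
#' Bundles every choice of a full study analysis: the input (a
#' [cohort_design()] to simulate, or spectra/metadata paths to load), the
#' fluid exclusion preset, alignment parameters and custom intervals,
#' normalization/log options, multivariate options, the univariate
#' comparison list with FDR levels, and the seed propagated to every
#' stochastic step.
#'
#' @param input Either a `cohort_design` or
#'   `list(matrix = <csv>, metadata = <tsv>)`.
#' @param fluid Exclusion preset: `"urine"`, `"plasma_1d"`, `"plasma_cpmg"`.
#' @param align Logical: run the alignment stage.
#' @param align_params An [alignment_params()].
#' @param custom_intervals Named list of ppm intervals for the second
#'   alignment pass (`NULL` = skip).
#' @param calibrate Logical: run ppm calibration (needs a reference peak,
#'   e.g. TSP, inside `calibrate_window`).
#' @param calibrate_window,calibrate_target Reference-peak search window
#'   and target ppm.
#' @param log_offset Offset for [log_transform()] (`"auto"` = smallest
#'   positive intensity).
#' @param max_rank Candidate-rank ceiling for [bcv_rank()].
#' @param label_schemes Character subset of
#'   `c("genotype", "week", "genotype_week")`: the class labellings
#'   cross-validated.
#' @param shrinkage QDA covariance shrinkage.
#' @param comparisons List of comparisons for [build_biomarker_table()],
#'   each `list(a = <filter>, b = <filter>, fdr = <level>)`.
#' @param annotations Annotation window tibble, or `NULL`.
#' @param seed Integer seed.
#' @return A `study_config` list.
#' @export
study_config <- function(input,
                         fluid = "urine",
                         align = TRUE,
                         align_params = alignment_params(),
                         custom_intervals = list(
                           citrate = c(2.50, 2.75), taurine = c(3.20, 3.50)
                         ),
                         calibrate = FALSE,
                         calibrate_window = c(-0.05, 0.05),
                         calibrate_target = 0,
                         log_offset = "auto",
                         max_rank = 10,
                         label_schemes = c("genotype", "week"),
                         shrinkage = 0.1,
                         comparisons = list(),
                         annotations = NULL,
                         seed = 1L) {
  structure(
    list(
      input = input, fluid = fluid, align = align,
      align_params = align_params, custom_intervals = custom_intervals,
      calibrate = calibrate, calibrate_window = calibrate_window,
      calibrate_target = calibrate_target, log_offset = log_offset,
      max_rank = max_rank, label_schemes = label_schemes,
      shrinkage = shrinkage, comparisons = comparisons,
      annotations = annotations, seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' Run the full study analysis
#'
#' Executes the stages in fixed order: load/simulate -> calibrate ->
#' exclude regions -> align (global RSPA, then custom intervals) -> PQN ->
#' log transform -> PCA with bi-cross-validated rank -> MMC +
#' leave-mouse-out CV per label scheme -> pairwise ANOVA/FDR biomarker
#' tables. Any stage error aborts with the stage named; all parameters are
#' echoed in the provenance, and the same config reproduces identical
#' outputs.
#'
#' @param config A [study_config()].
#' @return A `study_report`: `spectra` (fully processed matrix),
#'   `pqn`, `alignment`, `pca`, `bcv_rank`, `cv` (named list of
#'   `cv_report`s), `tables` (named list of `biomarker_table`s), `truth`
#'   (when simulated), `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }
  truth <- NULL
  sm <- stage("input", {
    if (inherits(config$input, "cohort_design")) {
      coh <- simulate_cohort(config$input)
      truth <- coh$truth
      coh$spectra
    } else {
      read_spectra(config$input$matrix, config$input$metadata)
    }
  })
  if (config$calibrate) {
    sm <- stage("calibrate", calibrate_ppm(
      sm, config$calibrate_window, config$calibrate_target
    ))
  }
  sm <- stage("exclude", exclude_regions(sm, preset = config$fluid))
  alignment <- NULL
  if (config$align) {
    alignment <- stage("rspa", rspa(sm, config$align_params))
    sm <- alignment$spectra
    if (length(config$custom_intervals)) {
      al2 <- stage("align_interval", align_interval(
        sm, config$custom_intervals, config$align_params,
        reference = alignment$reference
      ))
      sm <- al2$spectra
      alignment$shifts <- bind_rows(alignment$shifts, al2$shifts)
    }
  }
  pqn <- stage("pqn", pqn_normalize(sm))
  sm <- pqn$spectra
  sm <- stage("log", log_transform(sm, offset = config$log_offset))

  rank_sel <- stage("bcv_rank", bcv_rank(
    sm,
    max_rank = config$max_rank, seed = config$seed
  ))
  pca <- stage("pca", pca_fit(sm, rank = max(2L, rank_sel)))

  cv <- list()
  for (scheme in config$label_schemes) {
    lab <- switch(scheme,
      genotype = sm$meta$genotype,
      week = as.character(sm$meta$week),
      genotype_week = paste(sm$meta$genotype, sm$meta$week, sep = "_"),
      abort(sprintf("Unknown label scheme %s.", scheme))
    )
    cv[[scheme]] <- stage(paste0("cv_", scheme), leave_mouse_out_cv(
      sm, lab, sm$meta$mouse_id,
      pca_rank = max(2L, rank_sel), shrinkage = config$shrinkage
    ))
  }

  tables <- list()
  for (cmp in config$comparisons) {
    lab <- comparison_label(cmp)
    tables[[lab]] <- stage(paste0("table `", lab, "`"), build_biomarker_table(
      sm, cmp,
      annotations = config$annotations, fdr = cmp$fdr %||% 0.1
    ))
  }

  provenance <- list(
    steps = sm$log,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("nmrage")),
    seed = config$seed,
    selected_rank = as.integer(rank_sel)
  )
  structure(
    list(
      spectra = sm, pqn = pqn, alignment = alignment,
      pca = pca, bcv_rank = as.integer(rank_sel),
      cv = cv, tables = tables, truth = truth,
      provenance = provenance
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf(
    "  %d spectra x %d variables after processing\n",
    nrow(x$spectra$intensities), length(x$spectra$ppm)
  ))
  cat(sprintf("  bi-cross-validated rank: %d\n", x$bcv_rank))
  for (nm in names(x$cv)) {
    cat(sprintf(
      "  CV [%s]: accuracy %.3f\n", nm, x$cv[[nm]]$accuracy
    ))
  }
  for (nm in names(x$tables)) {
    g <- glance(x$tables[[nm]])
    cat(sprintf(
      "  table [%s]: %d FDR-significant, %d potential\n",
      nm, g$n_fdr_significant, g$n_potential
    ))
  }
  invisible(x)
}

#' PCA trajectory scores with group centroids
#'
#' Per-sample PC1/PC2 scores joined with genotype and week, plus per
#' (genotype, week) centroids and dispersions (mean pairwise within-group
#' score distance) — the data behind an ageing trajectory plot.
#'
#' @param report A `study_report`.
#' @return List of two tibbles: `scores` and `centroids`.
#' @export
trajectory_scores <- function(report) {
  stopifnot(inherits(report, "study_report"))
  sc <- tidy(report$pca) %>%
    select(all_of(c("sample_id", "PC1", "PC2"))) %>%
    left_join(report$spectra$meta, by = "sample_id")
  centroids <- sc %>%
    group_by(.data$genotype, .data$week) %>%
    summarise(
      PC1 = mean(.data$PC1), PC2 = mean(.data$PC2),
      dispersion = mean_pairwise_dist(cbind(.data$PC1, .data$PC2)),
      n = dplyr::n(), .groups = "drop"
    )
  list(scores = sc, centroids = centroids)
}

mean_pairwise_dist <- function(m) {
  if (nrow(m) < 2) {
    return(0)
  }
  mean(stats::dist(m))
}

#' Plot the PCA ageing trajectory
#'
#' @param report A `study_report`.
#' @return A ggplot: per-sample scores plus per-group centroids connected
#'   in week order, one path per genotype.
#' @export
plot_trajectory <- function(report) {
  tr <- trajectory_scores(report)
  ggplot2::ggplot(tr$scores, ggplot2::aes(
    x = .data$PC1, y = .data$PC2, colour = factor(.data$week)
  )) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$genotype), alpha = 0.6) +
    ggplot2::geom_path(
      data = tr$centroids %>% arrange(.data$genotype, .data$week),
      ggplot2::aes(group = .data$genotype, linetype = .data$genotype),
      colour = "grey30"
    ) +
    ggplot2::geom_point(
      data = tr$centroids, size = 4,
      ggplot2::aes(shape = .data$genotype)
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * report$pca$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * report$pca$explained[2]),
      colour = "week"
    )
}

#' Write study report artefacts
#'
#' Writes the processed spectra, dilution factors, alignment shift report,
#' PCA scores, CV reports (JSON when jsonlite is available) and biomarker
#' tables as TSVs under `dir`.
#'
#' @param report A `study_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spectra(
    report$spectra,
    file.path(dir, "processed_spectra.csv"),
    file.path(dir, "metadata.tsv")
  )
  readr::write_tsv(report$pqn$factors, file.path(dir, "dilution_factors.tsv"))
  if (!is.null(report$alignment)) {
    readr::write_tsv(report$alignment$shifts, file.path(dir, "shifts.tsv"))
  }
  readr::write_tsv(tidy(report$pca), file.path(dir, "pca_scores.tsv"))
  for (nm in names(report$tables)) {
    tb <- report$tables[[nm]]
    slug <- gsub("[^A-Za-z0-9]+", "_", nm)
    readr::write_tsv(
      tb$variables, file.path(dir, paste0("table_", slug, "_variables.tsv"))
    )
    if (!is.null(tb$metabolites)) {
      readr::write_tsv(
        tb$metabolites,
        file.path(dir, paste0("table_", slug, "_metabolites.tsv"))
      )
    }
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cvs <- lapply(report$cv, function(r) {
      list(
        accuracy = r$accuracy, predicted_variance = r$predicted_variance,
        confusion = as.data.frame(r$confusion)
      )
    })
    jsonlite::write_json(
      list(
        cv = cvs, selected_rank = report$bcv_rank,
        config_hash = report$provenance$config_hash
      ),
      file.path(dir, "cv_report.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
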