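#' Specify a synthetic NMR cohort
#'
#' A cohort design captures the generative conditions the analysis is tested
#' under: metabolite templates and base concentrations, the group layout
#' (genotype x week, mice per group, spectra per mouse), planted log2
#' fold-change effects, per-sample dilution (log-uniform, exercises PQN),
#' multiplicative concentration noise (exercises the log transform),
#' chemical-shift jitter (per template, exercises alignment), additive noise,
#' and the ppm grid.
#'
#' @param templates Named list of [metabolite_template()] objects.
#' @param base_concentrations Named positive numeric, one entry per template.
#' @param groups Data frame with columns `genotype`, `week`, `n_mice`,
#'   `spectra_per_mouse`.
#' @param planted_effects Data frame with columns `template`, `genotype`,
#'   `week`, `log2fc` (use `NA` in `genotype`/`week` to match any level), or
#'   `NULL` for none.
#' @param dilution_log_range Length-2 positive numeric: dilution factors are
#'   drawn log-uniformly between these bounds.
#' @param mult_noise_cv Coefficient of variation of multiplicative
#'   (lognormal) concentration noise.
#' @param mouse_cv Coefficient of variation of a per-mouse lognormal
#'   concentration effect shared by all spectra of one mouse (gives
#'   leave-mouse-out CV something to guard against).
#' @param add_noise_sd Additive Gaussian noise sd, intensity units.
#' @param grid Length-3 numeric `(ppm_min, ppm_max, step)`.
#' @param spectrometer_freq Spectrometer frequency, MHz.
#' @param fluid Fluid label stored in the metadata.
#' @param batch Batch label stored in the metadata.
#' @param seed Integer seed; fixed seed implies bit-reproducible output.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(templates = urine_templates(),
                          base_concentrations = NULL,
                          groups = tibble(
                            genotype = rep(c("WT", "KO"), each = 4),
                            week = rep(c(15, 30, 45, 60), 2),
                            n_mice = 4, spectra_per_mouse = 1
                          ),
                          planted_effects = NULL,
                          dilution_log_range = c(0.5, 2),
                          mult_noise_cv = 0.15,
                          mouse_cv = 0.05,
                          add_noise_sd = 0.5,
                          grid = c(0.5, 10, 0.00025),
                          spectrometer_freq = 600.44,
                          fluid = "urine",
                          batch = 1L,
                          seed = 1L) {
  if (!length(templates)) abort("`templates` must not be empty.")
  nm <- vapply(templates, `[[`, character(1), "name")
  names(templates) <- nm
  if (is.null(base_concentrations)) {
    base_concentrations <- setNames(rep(100, length(templates)), nm)
  }
  if (!all(nm %in% names(base_concentrations))) {
    abort("`base_concentrations` must name every template.")
  }
  if (any(base_concentrations <= 0)) abort("Concentrations must be > 0.")
  groups <- as_tibble(groups)
  stopifnot(all(c("genotype", "week", "n_mice", "spectra_per_mouse")
  %in% names(groups)))
  if (any(groups$n_mice < 1)) abort("`n_mice` must be >= 1.")
  if (any(dilution_log_range <= 0) || length(dilution_log_range) != 2) {
    abort("`dilution_log_range` must be two positive bounds.")
  }
  if (grid[3] <= 0) abort("Grid step must be > 0.")
  if (!is.null(planted_effects)) {
    planted_effects <- as_tibble(planted_effects)
    stopifnot(all(c("template", "log2fc") %in% names(planted_effects)))
    if (!"genotype" %in% names(planted_effects)) planted_effects$genotype <- NA
    if (!"week" %in% names(planted_effects)) planted_effects$week <- NA
    bad <- setdiff(planted_effects$template, nm)
    if (length(bad)) abort(paste0("Unknown templates in effects: ", toString(bad)))
  }
  structure(
    list(
      templates = templates, base_concentrations = base_concentrations,
      groups = groups, planted_effects = planted_effects,
      dilution_log_range = dilution_log_range,
      mult_noise_cv = mult_noise_cv, mouse_cv = mouse_cv,
      add_noise_sd = add_noise_sd, grid = grid,
      spectrometer_freq = spectrometer_freq, fluid = fluid,
      batch = batch, seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "<cohort_design> %d templates, %d groups, seed %d\n",
    length(x$templates), nrow(x$groups), x$seed
  ))
  invisible(x)
}

fold_change_for <- function(design, template, genotype, week) {
  pe <- design$planted_effects
  if (is.null(pe)) {
    return(1)
  }
  hit <- pe$template == template &
    (is.na(pe$genotype) | pe$genotype == genotype) &
    (is.na(pe$week) | pe$week == week)
  if (!any(hit)) {
    return(1)
  }
  2^sum(pe$log2fc[hit])
}

# deterministic per-unit substream seed: adding samples to a design must not
# perturb the draws of earlier ones
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647L)
}

#' Simulate a synthetic NMR cohort
#'
#' Generates one spectrum per (mouse, replicate): true concentrations are
#' base x planted fold change x per-mouse effect x lognormal multiplicative
#' noise; each template's multiplets are displaced by one Gaussian shift draw
#' (pH jitter); the whole spectrum is scaled by a log-uniform dilution factor
#' and Gaussian noise is added. Everything drawn is recorded in the ground
#' truth so recovery can be tested.
#'
#' @param design A [cohort_design()].
#' @param ultrafiltered If `TRUE`, protein binding is switched off
#'   (`bound_fraction` treated as 0), emulating 10 kDa ultrafiltration.
#' @return A list with class `nmr_cohort`: `spectra` (a
#'   [spectra_matrix()]) and `truth`, itself a list of tibbles
#'   (`dilution`, `shifts`, `concentrations`) plus the echoed
#'   `planted_effects`.
#' @export
#' @examples
#' des <- cohort_design(grid = c(0.5, 4.5, 0.005), seed = 7)
#' coh <- simulate_cohort(des)
#' coh$spectra
simulate_cohort <- function(design, ultrafiltered = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  grid <- seq(design$grid[1], design$grid[2], by = design$grid[3])
  grid <- rev(grid) # descending, NMR convention
  tpl <- design$templates
  nm <- names(tpl)

  units <- design$groups %>%
    mutate(.g = dplyr::row_number()) %>%
    tidyr::uncount(.data$n_mice, .id = "mouse_i") %>%
    tidyr::uncount(.data$spectra_per_mouse, .id = "rep_i")
  units <- units %>%
    mutate(
      mouse_id = sprintf("%s_w%s_m%d", .data$genotype, .data$week, .data$mouse_i),
      sample_id = sprintf("%s_r%d", .data$mouse_id, .data$rep_i)
    )

  sdlog <- sqrt(log(1 + design$mult_noise_cv^2))
  sdlog_mouse <- sqrt(log(1 + design$mouse_cv^2))

  # per-mouse effects from their own substreams (shared across replicates)
  mouse_tbl <- unique(units$mouse_id)
  mouse_eff <- matrix(1, length(mouse_tbl), length(nm),
    dimnames = list(mouse_tbl, nm)
  )
  for (i in seq_along(mouse_tbl)) {
    set.seed(substream_seed(design$seed, 500000L + i))
    if (design$mouse_cv > 0) {
      mouse_eff[i, ] <- rlnorm(length(nm), -sdlog_mouse^2 / 2, sdlog_mouse)
    }
  }

  n <- nrow(units)
  inten <- matrix(0, n, length(grid))
  dil <- numeric(n)
  conc_rec <- vector("list", n)
  shift_rec <- vector("list", n)

  for (i in seq_len(n)) {
    u <- units[i, ]
    set.seed(substream_seed(design$seed, i))
    fc <- vapply(
      nm, fold_change_for,
      numeric(1),
      design = design, genotype = u$genotype, week = u$week
    )
    mult <- if (design$mult_noise_cv > 0) {
      rlnorm(length(nm), -sdlog^2 / 2, sdlog)
    } else {
      rep(1, length(nm))
    }
    conc <- design$base_concentrations[nm] * fc *
      mouse_eff[u$mouse_id, nm] * mult
    jit <- vapply(tpl, function(t) {
      if (t$shift_jitter_sd > 0) rnorm(1, 0, t$shift_jitter_sd) else 0
    }, numeric(1))
    dil[i] <- exp(runif(
      1, log(design$dilution_log_range[1]),
      log(design$dilution_log_range[2])
    ))
    y <- numeric(length(grid))
    for (t in nm) {
      y <- y + render_template(tpl[[t]], conc[[t]], grid,
        design$spectrometer_freq,
        shift = jit[[t]], ultrafiltered = ultrafiltered
      )
    }
    y <- y * dil[i]
    if (design$add_noise_sd > 0) {
      y <- y + rnorm(length(grid), 0, design$add_noise_sd)
    }
    inten[i, ] <- y
    conc_rec[[i]] <- tibble(
      sample_id = u$sample_id, template = nm, concentration = unname(conc)
    )
    shift_rec[[i]] <- tibble(
      sample_id = u$sample_id, template = nm, shift_ppm = unname(jit)
    )
  }

  meta <- tibble(
    sample_id = units$sample_id, mouse_id = units$mouse_id,
    genotype = units$genotype, week = units$week,
    fluid = design$fluid, batch = design$batch
  )
  sm <- spectra_matrix(grid, inten, meta)
  sm <- log_step(sm, "simulate", list(
    seed = design$seed, ultrafiltered = ultrafiltered
  ))
  truth <- list(
    dilution = tibble(sample_id = meta$sample_id, dilution = dil),
    shifts = bind_rows(shift_rec),
    concentrations = bind_rows(conc_rec),
    planted_effects = design$planted_effects
  )
  structure(list(spectra = sm, truth = truth, design = design),
    class = "nmr_cohort"
  )
}

#' @export
print.nmr_cohort <- function(x, ...) {
  cat("<nmr_cohort>\n")
  print(x$spectra)
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes the spectra CSV + metadata TSV (see [write_spectra()]), the ground
#' truth as flat TSVs, and the design as YAML (templates serialised field by
#' field).
#'
#' @param cohort An `nmr_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spectra(
    cohort$spectra,
    file.path(dir, "spectra.csv"), file.path(dir, "metadata.tsv")
  )
  readr::write_tsv(cohort$truth$dilution, file.path(dir, "truth_dilution.tsv"))
  readr::write_tsv(cohort$truth$shifts, file.path(dir, "truth_shifts.tsv"))
  readr::write_tsv(
    cohort$truth$concentrations,
    file.path(dir, "truth_concentrations.tsv")
  )
  if (requireNamespace("yaml", quietly = TRUE)) {
    d <- cohort$design
    ser <- list(
      base_concentrations = as.list(d$base_concentrations),
      groups = as.data.frame(d$groups),
      planted_effects = if (is.null(d$planted_effects)) {
        NULL
      } else {
        as.data.frame(d$planted_effects)
      },
      dilution_log_range = d$dilution_log_range,
      mult_noise_cv = d$mult_noise_cv, mouse_cv = d$mouse_cv,
      add_noise_sd = d$add_noise_sd, grid = d$grid,
      spectrometer_freq = d$spectrometer_freq, fluid = d$fluid,
      batch = d$batch, seed = d$seed,
      templates = lapply(d$templates, function(t) {
        list(
          name = t$name, multiplets = as.data.frame(t$multiplets),
          shift_jitter_sd = t$shift_jitter_sd,
          bound_fraction = t$bound_fraction, bound_fwhm = t$bound_fwhm
        )
      })
    )
    yaml::write_yaml(ser, file.path(dir, "design.yaml"))
  }
  invisible(dir)
}
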