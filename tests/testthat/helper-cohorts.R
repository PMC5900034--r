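# Shared fixtures: small template sets and cohort designs used across tests.
# Everything is generated in code; grids are coarser than the acquisition
# default so suites stay fast while keeping several points per line width.

# two clean singlets, no jitter, no binding
toy_templates <- function(jitter_sd = 0) {
  list(
    a = metabolite_template(
      "met_a",
      tibble::tibble(
        center = 2.0, multiplicity = "s", J = 0,
        relative_integral = 1, fwhm = 1.2
      ),
      shift_jitter_sd = jitter_sd
    ),
    b = metabolite_template(
      "met_b",
      tibble::tibble(
        center = 3.0, multiplicity = "s", J = 0,
        relative_integral = 1, fwhm = 1.2
      )
    )
  )
}

# deterministic design: no noise of any kind, unit dilution
noise_free_design <- function(templates = toy_templates(), seed = 1,
                              groups = tibble::tibble(
                                genotype = "WT", week = 15,
                                n_mice = 3, spectra_per_mouse = 1
                              ),
                              grid = c(0.5, 4.5, 0.002), ...) {
  cohort_design(
    templates = templates,
    groups = groups,
    dilution_log_range = c(1, 1),
    mult_noise_cv = 0, mouse_cv = 0, add_noise_sd = 0,
    grid = grid, seed = seed, ...
  )
}

# small realistic urine-like design for recovery tests
small_urine_design <- function(seed = 1, jitter_sd = 0.01, ...) {
  cohort_design(
    templates = urine_templates(jitter_sd = jitter_sd),
    groups = tibble::tibble(
      genotype = "WT", week = c(15, 60), n_mice = 4, spectra_per_mouse = 1
    ),
    dilution_log_range = c(0.5, 2),
    mult_noise_cv = 0.15, mouse_cv = 0.05, add_noise_sd = 0.05,
    grid = c(0.5, 4.5, 0.001), seed = seed, ...
  )
}

# metadata table for hand-built matrices
stub_meta <- function(ids, mouse = ids, genotype = "WT", week = 15,
                      fluid = "urine", batch = 1) {
  tibble::tibble(
    sample_id = ids, mouse_id = mouse, genotype = genotype,
    week = week, fluid = fluid, batch = batch
  )
}

# brute-force BH oracle: evaluate all m cutoffs directly
bh_brute_force <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  passing <- which(ps <= seq_len(m) * q / m)
  if (!length(passing)) {
    return(list(significant = rep(FALSE, m), threshold = 0))
  }
  thr <- ps[max(passing)]
  list(significant = p <= thr, threshold = thr)
}

# local maxima of a rendered trace above a height fraction
find_local_maxima <- function(grid, y, frac = 0.05) {
  n <- length(y)
  i <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf) & y > frac * max(y))
  grid[i]
}

# position of the maximum within a ppm window
ppm_peak_pos <- function(ppm, y, window) {
  idx <- which(ppm >= window[1] & ppm <= window[2])
  ppm[idx[which.max(y[idx])]]
}

# brute-force best rigid shift by enumerating every lag
brute_force_shift <- function(test, ref, max_lag) {
  pad <- function(v, L) {
    n <- length(v)
    if (L == 0) return(v)
    if (L > 0) c(rep(v[1], L), v[seq_len(n - L)]) else c(v[(-L + 1):n], rep(v[n], -L))
  }
  lags <- seq.int(-max_lag, max_lag)
  cors <- vapply(lags, function(L) {
    v <- pad(test, L)
    if (sd(v) == 0) 0 else cor(v, ref)
  }, numeric(1))
  best <- max(cors)
  cand <- lags[cors >= best - 1e-15]
  cand[which.min(abs(cand))]
}
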