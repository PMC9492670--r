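#' Configuration for the synthetic multi-site cohort generator
#'
#' Defaults mirror the structure of the multi-site clinical resting-state
#' cohort the package is designed around: 1101 controls and 1276 patients
#' spread over 24 sites, ages uniform on 12-82 years, 116-region
#' connectomes (6670 edges), per-(site, edge) additive and multiplicative
#' effects, edgewise linear age trends of mixed sign, and an accelerated
#' aging offset for patients (default +4.43 years, with an extra +2.09
#' years for medicated patients).
#'
#' @param n_controls,n_patients,n_sites,n_regions Cohort dimensions.
#' @param age_range Two ages (years); subjects sampled uniformly between.
#' @param delta_years Patient aging offset (years, any sign).
#' @param edge_slope_sd SD of per-edge age slopes (latent correlation units
#'   per year). The aggregate age signal scales with
#'   `edge_slope_sd * sqrt(n_edges)`, so scaled-down benchmarks with fewer
#'   regions should scale this up by `sqrt(6670 / n_edges)` to keep
#'   paper-scale prediction accuracy.
#' @param site_shift_sd SD of additive per-(site, edge) shifts.
#' @param site_scale_sd SD of log multiplicative per-(site, edge) noise
#'   scales.
#' @param noise_sd SD of per-edge measurement noise (latent units).
#' @param subject_sd SD (years) of the per-subject latent brain-age
#'   deviation — the irreducible spread between biological and
#'   chronological age that bounds any estimator's accuracy. Default 9.5
#'   years targets a brain-PAD SD near 10 years at the 116-region defaults.
#' @param edge_quad_sd SD of per-edge quadratic age terms (latent units per
#'   year^2); default 0 (linear aging). Nonzero values exercise the
#'   age-squared covariate of the downstream GLM.
#' @param n_timepoints 0 for edge-feature mode (default); a positive T
#'   switches to time-series mode, emitting a T x R series per subject.
#' @param medication_fraction Fraction of patients on antidepressants.
#' @param medication_delta_years Additional aging offset (years) for
#'   medicated patients.
#' @param seed Integer seed; required, makes cohorts bit-reproducible.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_controls = 1101,
                             n_patients = 1276,
                             n_sites = 24,
                             n_regions = 116,
                             age_range = c(12, 82),
                             delta_years = 4.43,
                             edge_slope_sd = 0.0015,
                             site_shift_sd = 0.05,
                             site_scale_sd = 0.1,
                             noise_sd = 0.35,
                             subject_sd = 9.5,
                             edge_quad_sd = 0,
                             n_timepoints = 0,
                             medication_fraction = 0.5,
                             medication_delta_years = 2.09,
                             seed = 1L) {
  cfg <- list(
    n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
    n_sites = as.integer(n_sites), n_regions = as.integer(n_regions),
    age_range = as.numeric(age_range), delta_years = as.numeric(delta_years),
    edge_slope_sd = as.numeric(edge_slope_sd),
    site_shift_sd = as.numeric(site_shift_sd),
    site_scale_sd = as.numeric(site_scale_sd),
    noise_sd = as.numeric(noise_sd), subject_sd = as.numeric(subject_sd),
    edge_quad_sd = as.numeric(edge_quad_sd),
    n_timepoints = as.integer(n_timepoints),
    medication_fraction = as.numeric(medication_fraction),
    medication_delta_years = as.numeric(medication_delta_years),
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  counts <- c("n_controls", "n_patients", "n_sites", "n_regions")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1) abort(sprintf("%s must be >= 1", f))
  }
  if (cfg$n_regions < 2) abort("n_regions must be >= 2")
  if (is.na(cfg$n_timepoints) || cfg$n_timepoints < 0) abort("n_timepoints must be >= 0")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] >= cfg$age_range[2]) {
    abort("age_range must be (min, max) with min < max")
  }
  for (f in c("edge_slope_sd", "site_shift_sd", "site_scale_sd", "noise_sd",
              "subject_sd", "edge_quad_sd")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) abort(sprintf("%s must be >= 0", f))
  }
  if (is.na(cfg$medication_fraction) || cfg$medication_fraction < 0 ||
      cfg$medication_fraction > 1) {
    abort("medication_fraction must lie in [0, 1]")
  }
  if (is.na(cfg$seed)) abort("seed is required")
  invisible(cfg)
}

#' Generate a synthetic multi-site brain-age cohort
#'
#' Draws a controls + patients cohort with known generating structure. Each
#' edge `e` has a latent Fisher-z value
#' `mu_e + beta_e * a_i + gamma_e * a_i^2 + shift(site, e) + scale(site, e) * eps`,
#' where the effective age `a_i` (centered at the age-range midpoint) is
#' `age + delta * is_patient + delta_med * on_medication + g_i` with
#' `g_i ~ N(0, subject_sd^2)` the subject's latent brain-age deviation.
#' Stored edge values are `tanh(latent)`, keeping correlations in (-1, 1)
#' without mass at the boundaries. With `n_timepoints > 0` each subject
#' instead receives a T x R BOLD-like series whose population correlation is
#' the nearest positive-definite correlation matrix to the subject's edge
#' matrix (see [series_from_fc()]).
#'
#' Identical configs (including seed) produce bit-identical cohorts.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_cohort` with elements
#'   `phenotypes` (tibble: subject_id, site, age, sex, group, medication,
#'   episode, education_years, illness_months, hdrs), `features` (feature
#'   tibble; edge mode) or `time_series` (named list of T x R matrices),
#'   `true_params` (generating slopes/offsets) and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(
#'   n_controls = 20, n_patients = 20, n_sites = 3, n_regions = 8, seed = 7
#' ))
#' cohort$phenotypes
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  validate_synthetic_config(config)
  cfg <- config
  n <- cfg$n_controls + cfg$n_patients
  p <- n_edges_for(cfg$n_regions)
  if (cfg$n_timepoints > 0 && cfg$n_timepoints < cfg$n_regions + 2) {
    warn(sprintf(
      "n_timepoints = %d < n_regions + 2 = %d: empirical connectomes will be rank-deficient",
      cfg$n_timepoints, cfg$n_regions + 2
    ))
  }
  with_seed(cfg$seed, {
    group <- c(rep("control", cfg$n_controls), rep("mdd", cfg$n_patients))
    subject_id <- sprintf("sub%05d", seq_len(n))
    # round-robin site assignment within each group keeps every site
    # populated with both groups whenever counts allow
    site_lab <- sprintf("site%02d", seq_len(cfg$n_sites))
    site <- c(
      site_lab[((seq_len(cfg$n_controls) - 1L) %% cfg$n_sites) + 1L],
      site_lab[((seq_len(cfg$n_patients) - 1L) %% cfg$n_sites) + 1L]
    )
    site <- site[sample.int(n)] # shuffle so site is independent of id order
    age <- runif(n, cfg$age_range[1], cfg$age_range[2])
    sex <- sample(c("female", "male"), n, replace = TRUE)
    is_pat <- group == "mdd"
    medication <- ifelse(is_pat, rbinom(n, 1, cfg$medication_fraction), NA_integer_)
    episode <- ifelse(is_pat,
                      sample(c("first", "recurrent"), n, replace = TRUE, prob = c(0.66, 0.34)),
                      NA_character_)
    education_years <- ifelse(is_pat, pmin(pmax(round(rnorm(n, 12, 3)), 3), 22), NA_real_)
    illness_months <- ifelse(is_pat, round(rlnorm(n, log(12), 1.2), 1), NA_real_)
    hdrs <- ifelse(is_pat, pmin(pmax(round(rnorm(n, 22, 5)), 7), 40), NA_real_)

    g <- rnorm(n, 0, cfg$subject_sd)
    a_eff <- age + cfg$delta_years * is_pat +
      cfg$medication_delta_years * ifelse(is.na(medication), 0, medication) + g
    a_c <- a_eff - mean(cfg$age_range) # centered effective age

    mu <- rnorm(p, 0.15, 0.25)
    beta <- rnorm(p, 0, cfg$edge_slope_sd)
    gamma <- if (cfg$edge_quad_sd > 0) rnorm(p, 0, cfg$edge_quad_sd) else rep(0, p)
    site_shift <- matrix(rnorm(cfg$n_sites * p, 0, cfg$site_shift_sd),
                         nrow = cfg$n_sites, dimnames = list(site_lab, NULL))
    site_scale <- matrix(exp(rnorm(cfg$n_sites * p, 0, cfg$site_scale_sd)),
                         nrow = cfg$n_sites, dimnames = list(site_lab, NULL))

    eps <- matrix(rnorm(n * p, 0, cfg$noise_sd), nrow = n)
    latent <- outer(a_c, beta) + outer(a_c^2, gamma) +
      site_shift[site, , drop = FALSE] +
      site_scale[site, , drop = FALSE] * eps
    latent <- sweep(latent, 2, mu, "+")
    values <- tanh(latent)
    colnames(values) <- edge_names(cfg$n_regions)
    rownames(values) <- subject_id

    phenotypes <- tibble::tibble(
      subject_id = subject_id, site = site, age = age, sex = sex, group = group,
      medication = as.integer(medication), episode = episode,
      education_years = education_years, illness_months = illness_months,
      hdrs = hdrs
    )
    true_params <- list(
      mu = mu, beta = beta, gamma = gamma,
      site_shift = site_shift, site_scale = site_scale,
      subject_offset = setNames(g, subject_id),
      delta_years = cfg$delta_years,
      medication_delta_years = cfg$medication_delta_years
    )
    out <- list(phenotypes = phenotypes, true_params = true_params, config = cfg)
    if (cfg$n_timepoints > 0) {
      ts_seeds <- cfg$seed + seq_len(n)
      out$time_series <- lapply(seq_len(n), function(i) {
        fc <- devectorize(values[i, ], cfg$n_regions)
        series_from_fc(fc, cfg$n_timepoints, seed = ts_seeds[i])
      })
      names(out$time_series) <- subject_id
    } else {
      out$features <- feature_tibble(values)
    }
    structure(out, class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synthetic_cohort> %d controls + %d patients, %d sites, %d regions (%s mode)\n",
    cfg$n_controls, cfg$n_patients, cfg$n_sites, cfg$n_regions,
    if (cfg$n_timepoints > 0) sprintf("time-series T=%d", cfg$n_timepoints) else "edge-feature"
  ))
  invisible(x)
}

#' Nearest positive-definite correlation matrix
#'
#' Eigenvalue clipping at a small floor followed by rescaling to unit
#' diagonal. A matrix that is already positive definite (all eigenvalues
#' above the floor) is returned unchanged up to floating error.
#'
#' @param m Symmetric matrix with unit diagonal.
#' @param floor Minimum eigenvalue after clipping.
#' @return Positive-definite correlation matrix of the same dimension.
#' @export
nearest_pd_correlation <- function(m, floor = 1e-6) {
  m <- as.matrix(m)
  if (max(abs(m - t(m))) > 1e-8) abort("matrix is not symmetric")
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values >= floor)) return(m)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}

#' Sample a multivariate time series with a target correlation matrix
#'
#' Draws T Gaussian samples whose population correlation equals the nearest
#' positive-definite correlation matrix to `target_fc` (eigenvalue clipping,
#' see [nearest_pd_correlation()]). The empirical Pearson connectome of the
#' output converges to that target as T grows.
#'
#' @param target_fc Symmetric R x R matrix with unit diagonal.
#' @param n_timepoints Number of samples T (>= 2).
#' @param seed Integer seed.
#' @return T x R numeric matrix with region labels as column names.
#' @export
series_from_fc <- function(target_fc, n_timepoints, seed) {
  m <- as.matrix(target_fc)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    abort("target_fc must be a symmetric square matrix")
  }
  if (max(abs(diag(m) - 1)) > 1e-8) abort("target_fc must have unit diagonal")
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 2) abort("n_timepoints must be >= 2")
  pd <- nearest_pd_correlation(m)
  L <- chol(pd)
  with_seed(as.integer(seed), {
    z <- matrix(rnorm(n_timepoints * nrow(m)), nrow = n_timepoints)
    out <- z %*% L
    colnames(out) <- colnames(m)
    out
  })
}
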