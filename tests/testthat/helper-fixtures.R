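# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing binary is stored.

# Small cohort config for fast module tests. Scaled down from the
# 116-region defaults by shrinking per-edge noise with sqrt(p/6670), which
# preserves the aggregate signal-to-noise of the full-size cohort while
# keeping edge-age relations in the linear regime.
scaled_noise <- function(n_regions) {
  0.35 * sqrt((n_regions * (n_regions - 1) / 2) / 6670)
}

small_config <- function(...) {
  defaults <- list(
    n_controls = 60, n_patients = 40, n_sites = 3, n_regions = 8,
    noise_sd = scaled_noise(8), delta_years = 4, seed = 101
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

# Scaled replicate benchmark: 16 regions / 120 edges with noise scaled by
# sqrt(120/6670) so the aggregate age signal-to-noise matches the
# 116-region defaults; cohort sizes mirror the study split (219 hold-out
# controls at fraction 0.2, 500 patients). The medication sub-offset is
# zeroed so the injected delta IS the whole group offset (the quantity the
# recovery and null experiments are about).
benchmark_config <- function(seed, delta_years = 4, n_controls = 1095,
                             n_patients = 500, n_regions = 16, ...) {
  do.call(synthetic_config, utils::modifyList(
    list(n_controls = n_controls, n_patients = n_patients, n_sites = 24,
         n_regions = n_regions, noise_sd = scaled_noise(n_regions),
         delta_years = delta_years, medication_delta_years = 0, seed = seed),
    list(...)
  ))
}

# A feature tibble with explicit values (subjects x edges).
make_features <- function(x, ids = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    r <- (1 + sqrt(1 + 8 * ncol(x))) / 2
    colnames(x) <- if (abs(r - round(r)) < 1e-9) {
      edge_names(as.integer(round(r)))
    } else {
      sprintf("e%03d", seq_len(ncol(x)))
    }
  }
  rownames(x) <- ids %||% sprintf("s%03d", seq_len(nrow(x)))
  dplyr::bind_cols(tibble::tibble(subject_id = rownames(x)),
                   tibble::as_tibble(x, .name_repair = "minimal"))
}

regions_from_edges <- function(n_edges) {
  r <- (1 + sqrt(1 + 8 * n_edges)) / 2
  stopifnot(abs(r - round(r)) < 1e-9)
  as.integer(round(r))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run the full pipeline on a config and return the corrected group
# comparison (used by the recovery/null suites).
run_benchmark_comparison <- function(cfg, seed = cfg$seed,
                                     holdout_fraction = 0.2) {
  rc <- run_config(mode = "synthetic", synthetic = cfg, seed = seed,
                   holdout_fraction = holdout_fraction)
  run <- run_pipeline(rc)
  run$comparison_corrected
}

# Run the bundled 60-subject fixture config end to end.
fixture_run <- function(output_dir = NULL) {
  cfg_json <- jsonlite::read_json(
    system.file("extdata", "fixture_config.json", package = "brainpad"),
    simplifyVector = TRUE
  )
  args <- cfg_json
  args$synthetic <- do.call(synthetic_config, as.list(cfg_json$synthetic))
  args$output_dir <- output_dir
  run_pipeline(do.call(run_config, args))
}
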