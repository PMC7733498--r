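# programmatic fixtures shared across test files

# balanced 2x2 monitoring frame with constant values per cell, 2 sites and
# 2 subsamples per arm, 2 times per period; saturated Poisson fits on it have
# closed-form log-ratio estimates
make_cell_records <- function(bc = 10, bi = 10, ac = 10, ai = 20,
                              measure = "count", randomised = FALSE,
                              n_sites = 2L, n_sub = 2L, n_times = 2L) {
  g <- expand.grid(arm = c("control", "impact"), s = seq_len(n_sites),
                   subsample = seq_len(n_sub), time = seq_len(2L * n_times),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$period <- ifelse(g$time <= n_times, "before", "after")
  cell <- paste(g$period, g$arm, sep = ".")
  vals <- c(before.control = bc, before.impact = bi,
            after.control = ac, after.impact = ai)
  site <- paste0(substr(g$arm, 1, 1), g$s)
  data.frame(dataset_id = "fx", response_id = "r1", measure = measure,
             randomised = randomised, site = site,
             subsample = paste0(site, ".", g$subsample),
             treatment = g$arm, period = g$period, time = g$time,
             value = as.numeric(vals[cell]), stringsAsFactors = FALSE)
}

make_saturated_dataset <- function(...) response_dataset(make_cell_records(...))

# dataset with a chosen fraction of zeros in selected period.treatment cells
make_sparse_dataset <- function(zero_frac, cells, base = 5) {
  rec <- make_cell_records(bc = base, bi = base, ac = base, ai = base,
                           n_sites = 5L, n_sub = 2L, n_times = 2L)
  for (cl in cells) {
    idx <- which(paste(rec$period, rec$treatment, sep = ".") == cl)
    nz <- floor(zero_frac * length(idx))
    rec$value[idx[seq_len(nz)]] <- 0
  }
  response_dataset(rec)
}

# minimal estimate row for comparison-metric tests (normal-theory p and CI)
make_est <- function(point, se, response_id = "r1", estimator = "CI",
                     arm = "non-randomised", converged = TRUE) {
  data.frame(response_id = response_id, arm = arm, estimator = estimator,
             point = point, se = se, df = Inf,
             p_value = 2 * pnorm(-abs(point / se)),
             ci_low = point - 1.96 * se, ci_high = point + 1.96 * se,
             family = "poisson", mixed = FALSE, converged = converged,
             note = "", stringsAsFactors = FALSE)
}

# stack estimate rows into an estimate_matrix-shaped data frame
make_estimates <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("estimate_matrix", "data.frame")
  out
}

# quick, quiet bias-model fit for structural tests
quick_fit <- function(beta_hat, se, seed = 1, draws = 200, warmup = 200,
                      thin = 1, chains = 2) {
  suppressWarnings(fit_bias_model(beta_hat, se,
    bias_model_config(seed = seed, draws = draws, warmup = warmup,
                      thin = thin, chains = chains)))
}
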