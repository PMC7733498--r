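#' Define a monitoring simulation scenario
#'
#' A scenario fixes the sampling structure and the generative parameters of
#' one synthetic before-after-control-impact monitoring response. All effects
#' act on the log (link) scale of the mean:
#' \deqn{\log \mu = \log(\mathrm{baseline}) + \theta\,[impact \cap after]
#'   + \delta\,[impact] + \tau\,[after] + b_{site} + b_{subsample}.}
#' `theta` is the estimand (the true causal effect of the impact); `delta`
#' is a pre-existing impact-minus-control difference (the confounding that
#' biases an after-only CI comparison); `tau` is a before-to-after trend
#' shared by both groups (the temporal change that biases an uncontrolled
#' BA comparison). Under `randomised = TRUE` the `delta` offset is carried
#' by a fixed half of the sites whose allocation to arms is random, so the
#' expected group difference is zero — the defining property of randomised
#' designs.
#'
#' @param n_sites_per_arm sites in each of the control and impact arms.
#' @param n_subsamples subsamples (replicates) within each site.
#' @param n_times_before,n_times_after sampling occasions per period; each
#'   year/season is treated as an independent observation downstream.
#' @param baseline_mean positive mean of the response in the
#'   before-period control cell (natural scale).
#' @param theta true effect of the impact (log response ratio).
#' @param delta log-scale confound: pre-existing impact-minus-control
#'   difference.
#' @param tau log-scale trend: before-to-after change common to both arms.
#' @param site_sd,subsample_sd standard deviations of the log-normal random
#'   intercepts for site and for subsample-within-site.
#' @param dispersion quasi-overdispersion factor (variance/mean) for
#'   `measure = "density"`; must be >= 1 (1 = Poisson).
#' @param residual_sd residual standard deviation on the natural scale for
#'   `measure = "size"`.
#' @param measure one of `"count"`, `"density"`, `"percentage"`, `"size"`.
#' @param randomised were sites randomly allocated to arms?
#' @param seed optional integer seed used by [simulate_monitoring_dataset()].
#'
#' @return An object of class `monitoring_scenario` (a validated list).
#' @export
monitoring_scenario <- function(n_sites_per_arm = 10, n_subsamples = 3,
                                n_times_before = 3, n_times_after = 3,
                                baseline_mean = 20,
                                theta = 0, delta = 0, tau = 0,
                                site_sd = 0.3, subsample_sd = 0.15,
                                dispersion = 2, residual_sd = 2,
                                measure = c("count", "density", "percentage", "size"),
                                randomised = FALSE, seed = NULL) {
  measure <- match.arg(measure)
  scn <- list(n_sites_per_arm = as.integer(n_sites_per_arm),
              n_subsamples = as.integer(n_subsamples),
              n_times_before = as.integer(n_times_before),
              n_times_after = as.integer(n_times_after),
              baseline_mean = baseline_mean, theta = theta, delta = delta,
              tau = tau, site_sd = site_sd, subsample_sd = subsample_sd,
              dispersion = dispersion, residual_sd = residual_sd,
              measure = measure, randomised = isTRUE(randomised),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (scn$n_sites_per_arm < 1L || scn$n_subsamples < 1L ||
      scn$n_times_before < 1L || scn$n_times_after < 1L)
    db_stop("InvalidScenario", "all sampling dimensions must be >= 1")
  if (!is.finite(scn$baseline_mean) || scn$baseline_mean <= 0)
    db_stop("InvalidScenario", "baseline_mean must be positive")
  if (scn$site_sd < 0 || scn$subsample_sd < 0 || scn$residual_sd < 0)
    db_stop("InvalidScenario", "standard deviations must be >= 0")
  if (scn$dispersion < 1)
    db_stop("InvalidScenario", "dispersion must be >= 1")
  if (scn$measure == "percentage" && scn$baseline_mean > 100)
    db_stop("InvalidScenario", "percentage baseline must lie in (0, 100]")
  structure(scn, class = "monitoring_scenario")
}

#' @export
print.monitoring_scenario <- function(x, ...) {
  cat("<monitoring_scenario> measure=", x$measure,
      if (x$randomised) " (randomised)" else "", "\n", sep = "")
  cat(sprintf("  structure: %d sites/arm x %d subsamples x (%d before + %d after) times\n",
              x$n_sites_per_arm, x$n_subsamples, x$n_times_before, x$n_times_after))
  cat(sprintf("  effects (log scale): theta=%.3g  delta=%.3g  tau=%.3g\n",
              x$theta, x$delta, x$tau))
  cat(sprintf("  variation: site_sd=%.3g subsample_sd=%.3g dispersion=%.3g\n",
              x$site_sd, x$subsample_sd, x$dispersion))
  invisible(x)
}

#' Read a monitoring scenario from a YAML or JSON config file
#'
#' The file holds a flat mapping of [monitoring_scenario()] fields; omitted
#' fields keep their defaults. YAML files (`.yml`/`.yaml`) are read with the
#' \pkg{yaml} package, anything else as JSON with \pkg{jsonlite}.
#'
#' @param path path to the config file.
#' @return A validated [monitoring_scenario()].
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      db_stop("MissingDependency", "reading YAML scenarios requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      db_stop("MissingDependency", "reading JSON scenarios requires the 'jsonlite' package")
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  bad <- setdiff(names(cfg), names(formals(monitoring_scenario)))
  if (length(bad))
    db_stop("InvalidScenario",
            paste0("unknown scenario field(s): ", paste(bad, collapse = ", ")))
  do.call(monitoring_scenario, cfg)
}

#' Simulate one monitoring response with known truth
#'
#' Draws a complete before-after-control-impact monitoring dataset from a
#' [monitoring_scenario()]. Values are generated per measure family:
#' counts are Poisson; densities are overdispersed counts (NB1
#' parameterisation, variance = dispersion x mean); percentages are
#' binomial on the proportion scale with denominator 100; sizes are normal
#' around the exponentiated log-mean. Site and subsample random intercepts
#' are normal on the log scale for every family.
#'
#' @param scn a [monitoring_scenario()].
#' @param response_id,dataset_id identifiers stamped on the records.
#'
#' @return A list with elements `dataset` (a [response_dataset()]) and
#'   `truth` (class `simulation_truth`: the estimand `theta`, the bias
#'   sources `delta` and `tau`, and the generating scenario).
#' @export
simulate_monitoring_dataset <- function(scn, response_id = "r1",
                                        dataset_id = "sim") {
  stopifnot(inherits(scn, "monitoring_scenario"))
  if (!is.null(scn$seed)) set.seed(scn$seed)
  ns <- scn$n_sites_per_arm
  n_sites <- 2L * ns
  # half the sites carry the confound offset; under randomisation the
  # allocation of sites to arms is shuffled so the expected arm difference is 0
  site_conf <- c(rep(scn$delta, ns), rep(0, ns))
  if (scn$randomised) {
    arm_of_site <- sample(rep(c("impact", "control"), each = ns))
  } else {
    arm_of_site <- rep(c("impact", "control"), each = ns)
  }
  b_site <- rnorm(n_sites, 0, scn$site_sd)
  b_sub <- matrix(rnorm(n_sites * scn$n_subsamples, 0, scn$subsample_sd),
                  nrow = n_sites)
  times <- seq_len(scn$n_times_before + scn$n_times_after)
  period_of_time <- ifelse(times <= scn$n_times_before, "before", "after")

  grid <- expand.grid(site_idx = seq_len(n_sites),
                      subsample = seq_len(scn$n_subsamples),
                      time = times, KEEP.OUT.ATTRS = FALSE)
  treatment <- arm_of_site[grid$site_idx]
  period <- period_of_time[grid$time]
  is_impact <- treatment == "impact"
  is_after <- period == "after"
  # the confound is a fixed attribute of the site (carried by the sites that
  # form the impact arm when allocation is not randomised); under random
  # allocation it lands in both arms and cancels in expectation
  log_mu <- log(scn$baseline_mean) +
    scn$theta * (is_impact & is_after) +
    site_conf[grid$site_idx] +
    scn$tau * is_after +
    b_site[grid$site_idx] +
    b_sub[cbind(grid$site_idx, grid$subsample)]
  mu <- exp(log_mu)
  n <- length(mu)
  value <- switch(scn$measure,
    count = rpois(n, mu),
    density = if (scn$dispersion == 1) rpois(n, mu) else
      rnbinom(n, mu = mu, size = mu / (scn$dispersion - 1)),
    percentage = rbinom(n, 100L, pmin(mu / 100, 1 - 1e-8)),
    size = rnorm(n, mu, scn$residual_sd))
  records <- data.frame(dataset_id = dataset_id, response_id = response_id,
                        measure = scn$measure, randomised = scn$randomised,
                        site = paste0("s", grid$site_idx),
                        subsample = paste0("s", grid$site_idx, ".",
                                           grid$subsample),
                        treatment = treatment, period = period,
                        time = grid$time, value = as.numeric(value),
                        stringsAsFactors = FALSE)
  truth <- structure(list(theta = scn$theta, delta = scn$delta,
                          tau = scn$tau, scenario = scn),
                     class = "simulation_truth")
  list(dataset = response_dataset(records), truth = truth)
}

#' Simulate effect estimates from the hierarchical bias model
#'
#' Draws an estimate matrix directly from the generative model used to
#' quantify design bias: for response \eqn{i} and design \eqn{j},
#' \deqn{\hat\beta_{ij} = \beta_i + \gamma_{ij} + \varepsilon_{ij},\qquad
#'   \beta_i \sim N(0, \sigma_\beta^2),\ \gamma_{ij} \sim N(0, \sigma_j^2),\
#'   \varepsilon_i \sim N(0, \lambda\,D_i \Omega D_i),}
#' with \eqn{D_i = \mathrm{diag}(\hat\sigma_i)} the reported standard
#' errors. This is the route by which parameter recovery of
#' [fit_bias_model()] is validated.
#'
#' @param n_responses number of responses (rows).
#' @param sigma_beta standard deviation of the true effects.
#' @param sigma vector of per-design bias standard deviations (length J).
#' @param lambda scaling of the squared reported standard errors.
#' @param Omega J x J correlation matrix of the statistical errors.
#' @param se_matrix reported standard errors: an `n_responses` x J matrix,
#'   or a scalar / length-J vector recycled across responses.
#' @param labels design labels for the J columns.
#' @param seed optional integer seed.
#'
#' @return A list with `beta_hat` and `se` matrices (n x J, columns named by
#'   `labels`) and `truth` (class `simulation_truth`: the drawn `beta`,
#'   `gamma` and the generating parameters).
#' @export
simulate_estimates <- function(n_responses, sigma_beta, sigma, lambda, Omega,
                               se_matrix, labels = estimator_labels(),
                               seed = NULL) {
  J <- length(sigma)
  if (!is.matrix(Omega) || nrow(Omega) != J || ncol(Omega) != J)
    db_stop("DimensionMismatch", "Omega must be J x J with J = length(sigma)")
  if (max(abs(Omega - t(Omega))) > 1e-8 || max(abs(diag(Omega) - 1)) > 1e-8)
    db_stop("NotPositiveDefinite", "Omega must be symmetric with unit diagonal")
  U <- tryCatch(chol(Omega), error = function(e)
    db_stop("NotPositiveDefinite", "Omega is not positive definite"))
  if (length(labels) != J)
    db_stop("DimensionMismatch", "labels must have length J")
  if (any(sigma < 0) || sigma_beta < 0 || lambda < 0)
    db_stop("InvalidScenario", "sigma_beta, sigma and lambda must be >= 0")
  se <- se_matrix
  if (!is.matrix(se)) {
    if (!length(se) %in% c(1L, J))
      db_stop("DimensionMismatch", "se_matrix must be n x J, length J, or scalar")
    se <- matrix(se, n_responses, J, byrow = length(se) == J)
  }
  if (nrow(se) != n_responses || ncol(se) != J)
    db_stop("DimensionMismatch", "se_matrix must be n_responses x J")
  if (any(se <= 0) && lambda > 0)
    db_stop("InvalidScenario", "reported standard errors must be positive")
  if (!is.null(seed)) set.seed(seed)
  beta <- rnorm(n_responses, 0, sigma_beta)
  gamma <- sapply(seq_len(J), function(j) rnorm(n_responses, 0, sigma[j]))
  gamma <- matrix(gamma, n_responses, J)
  z <- matrix(rnorm(n_responses * J), n_responses, J)
  eps <- sqrt(lambda) * (z %*% U) * se
  beta_hat <- beta + gamma + eps
  colnames(beta_hat) <- colnames(se) <- colnames(gamma) <- labels
  truth <- structure(list(beta = beta, gamma = gamma,
                          params = list(sigma_beta = sigma_beta, sigma = sigma,
                                        lambda = lambda, Omega = Omega)),
                     class = "simulation_truth")
  list(beta_hat = beta_hat, se = se, truth = truth)
}

#' Empirical bias of design estimates against simulation truth
#'
#' Computes, per design, the mean estimation error
#' \eqn{\mathrm{mean}(\hat\beta_{ij} - \beta_i)} together with its standard
#' deviation and Monte-Carlo standard error. The mean error estimates the
#' design bias; for an unbiased design it should sit within about two
#' Monte-Carlo standard errors of zero.
#'
#' @param beta_hat n x J matrix of estimates (columns = designs), e.g. from
#'   [simulate_estimates()] or stacked replicate fits.
#' @param beta_true true effects: a scalar or length-n vector.
#'
#' @return Data frame with columns `design`, `mean_error`, `sd_error`,
#'   `mc_se` and `n`.
#' @export
empirical_bias <- function(beta_hat, beta_true) {
  if (is.list(beta_hat) && !is.null(beta_hat$beta_hat)) {
    if (missing(beta_true)) beta_true <- beta_hat$truth$beta
    beta_hat <- beta_hat$beta_hat
  }
  beta_hat <- as.matrix(beta_hat)
  if (length(beta_true) == 0L || anyNA(beta_true))
    db_stop("MissingTruth", "true effects are missing")
  if (!length(beta_true) %in% c(1L, nrow(beta_hat)))
    db_stop("MissingTruth", "truth must cover every response")
  err <- beta_hat - beta_true
  keep_n <- colSums(!is.na(err))
  data.frame(design = colnames(beta_hat) %||% paste0("design", seq_len(ncol(err))),
             mean_error = colMeans(err, na.rm = TRUE),
             sd_error = apply(err, 2L, sd, na.rm = TRUE),
             mc_se = apply(err, 2L, sd, na.rm = TRUE) / sqrt(keep_n),
             n = keep_n, row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
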