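#' Configuration for the hierarchical bias model
#'
#' Priors and sampler settings for [fit_bias_model()]. The defaults are the
#' disperse priors of the model: Inverse-Gamma(1, 0.02) on the standard
#' deviations \eqn{\sigma_\beta, \sigma_1, \ldots, \sigma_J},
#' Gamma(shape = 2, rate = 2) on the standard-error scaling \eqn{\lambda}
#' (prior mean 1, i.e. reported standard errors believed on average), and
#' LKJ(1) — uniform over correlation matrices — on \eqn{\Omega}.
#'
#' @param prior_sd_shape,prior_sd_scale Inverse-Gamma hyperparameters for
#'   the bias and true-effect standard deviations.
#' @param prior_on `"sd"` places the Inverse-Gamma on the standard
#'   deviations themselves; `"variance"` on their squares.
#' @param lambda_shape,lambda_rate Gamma (shape-rate) hyperparameters for
#'   \eqn{\lambda}.
#' @param lkj_eta LKJ concentration for \eqn{\Omega} (1 = uniform).
#' @param chains,warmup,draws MCMC chains, warmup iterations per chain
#'   (adaptation happens here), and retained draws per chain.
#' @param thin keep every `thin`-th post-warmup sweep (the chain runs
#'   `draws * thin` slice sweeps after warmup).
#' @param seed optional integer seed.
#' @param target_accept unused by the slice kernel; retained so stored
#'   configurations remain valid.
#'
#' @return A list of class `bias_model_config`.
#' @export
bias_model_config <- function(prior_sd_shape = 1, prior_sd_scale = 0.02,
                              prior_on = c("sd", "variance"),
                              lambda_shape = 2, lambda_rate = 2, lkj_eta = 1,
                              chains = 2, warmup = 500, draws = 1000,
                              thin = 2, seed = NULL, target_accept = 0.234) {
  prior_on <- match.arg(prior_on)
  cfg <- list(prior_sd_shape = prior_sd_shape, prior_sd_scale = prior_sd_scale,
              prior_on = prior_on, lambda_shape = lambda_shape,
              lambda_rate = lambda_rate, lkj_eta = lkj_eta,
              chains = as.integer(chains), warmup = as.integer(warmup),
              draws = as.integer(draws), thin = as.integer(thin),
              seed = if (is.null(seed)) NULL else as.integer(seed),
              target_accept = target_accept)
  if (any(unlist(cfg[c("prior_sd_shape", "prior_sd_scale", "lambda_shape",
                       "lambda_rate", "lkj_eta")]) <= 0))
    db_stop("InvalidConfig", "all prior hyperparameters must be positive")
  if (cfg$draws < 1L || cfg$chains < 1L || cfg$warmup < 0L || cfg$thin < 1L)
    db_stop("InvalidConfig", "chains, draws and thin must be >= 1, warmup >= 0")
  structure(cfg, class = "bias_model_config")
}

#' Assemble estimate and standard-error matrices for the bias model
#'
#' Reshapes an [estimate_all()] table from one arm into the complete-case
#' `n x 4` matrices the hierarchical model consumes, in the fixed column
#' order `BACI_DiD`, `BACI_CA`, `CI`, `BA`. Responses missing any converged
#' estimator are dropped and reported.
#'
#' @param m an `estimate_matrix` data frame.
#' @param arm optionally select `"randomised"` or `"non-randomised"` rows;
#'   required if `m` mixes arms.
#'
#' @return List with `beta_hat` and `se` matrices, `labels`, `dropped`
#'   (response ids) and `n`.
#' @export
build_model_inputs <- function(m, arm = NULL) {
  stopifnot(is.data.frame(m))
  if (!is.null(arm)) m <- m[m$arm == arm, , drop = FALSE]
  if (nrow(m) == 0L) db_stop("NoCompleteRows", "no estimates in this arm")
  if (length(unique(m$arm)) > 1L)
    db_stop("InvalidInput", "estimates mix arms; pass arm = 'randomised' or 'non-randomised'")
  ok <- m$converged & is.finite(m$point) & is.finite(m$se) & m$se > 0
  beta_hat <- estimate_wide(m[ok, , drop = FALSE], "point")
  se <- estimate_wide(m[ok, , drop = FALSE], "se")
  complete <- rowSums(is.na(beta_hat)) == 0L & rowSums(is.na(se)) == 0L
  all_ids <- unique(m$response_id)
  dropped <- setdiff(all_ids, rownames(beta_hat)[complete])
  if (!any(complete))
    db_stop("NoCompleteRows", "no response has all four converged estimates")
  list(beta_hat = beta_hat[complete, , drop = FALSE],
       se = se[complete, , drop = FALSE],
       labels = colnames(beta_hat), dropped = dropped, n = sum(complete))
}

bias_parameter_names <- function(labels) {
  J <- length(labels)
  pairs <- utils::combn(J, 2L)
  c("sigma_beta", paste0("sigma[", labels, "]"), "lambda",
    paste0("Omega[", labels[pairs[1L, ]], ",", labels[pairs[2L, ]], "]"))
}

#' Fit the hierarchical Bayesian model of study-design bias
#'
#' Estimates how much systematic bias each study design contributes to its
#' effect estimates. For response \eqn{i} and design \eqn{j},
#' \deqn{\hat\beta_{ij} = \beta_i + \gamma_{ij} + \varepsilon_{ij},\quad
#'   \beta_i \sim N(0,\sigma_\beta^2),\ \gamma_{ij} \sim N(0,\sigma_j^2),\
#'   \varepsilon_i \sim N(0,\ \lambda\,\mathrm{diag}(\hat\sigma_i)\,\Omega\,
#'   \mathrm{diag}(\hat\sigma_i)),}
#' so that \eqn{\sigma_j} measures the magnitude of design \eqn{j}'s bias
#' (assumed zero on average across responses), \eqn{\lambda} the systematic
#' under- (\eqn{\lambda > 1}) or over-estimation of the reported standard
#' errors, and \eqn{\Omega} the within-response correlation of the
#' estimators' statistical errors. The per-response effects \eqn{\beta_i}
#' and biases \eqn{\gamma_{ij}} are integrated out analytically and the
#' remaining \eqn{2 + J + J(J-1)/2} hyperparameters are sampled by a
#' covariance-adaptive slice sampler (see `src/`). Split-\eqn{\hat R}
#' and effective sample sizes are computed per parameter; a warning of
#' class `ConvergenceWarning` is raised if any \eqn{\hat R > 1.01}.
#'
#' @param beta_hat n x J matrix of effect estimates (one row per response),
#'   or the list returned by [build_model_inputs()].
#' @param se matching n x J matrix of reported standard errors.
#' @param config a [bias_model_config()].
#' @param labels design labels for the J columns.
#'
#' @return An object of class `bias_model` with components `draws`
#'   (iterations x parameters x chains array of posterior draws), `summary`
#'   (the [posterior_report()] data frame), `diagnostics` (per-parameter
#'   `rhat`, `ess`, per-chain likelihood evaluations per sweep), `labels`,
#'   `n`, `config`,
#'   and the input `data`.
#' @seealso [simulate_estimates()] to generate data with known parameters,
#'   [posterior_true_effects()] for the implied per-response effects.
#' @export
fit_bias_model <- function(beta_hat, se = NULL, config = bias_model_config(),
                           labels = NULL) {
  if (is.list(beta_hat) && !is.null(beta_hat$beta_hat)) {
    if (is.null(labels)) labels <- beta_hat$labels
    se <- beta_hat$se
    beta_hat <- beta_hat$beta_hat
  }
  beta_hat <- as.matrix(beta_hat)
  se <- as.matrix(se)
  J <- ncol(beta_hat)
  if (is.null(labels))
    labels <- colnames(beta_hat) %||%
      (if (J == 4L) estimator_labels() else paste0("design", seq_len(J)))
  if (!all(dim(beta_hat) == dim(se)))
    db_stop("DimensionMismatch", "beta_hat and se must have the same dimensions")
  if (nrow(beta_hat) > 0L && (!all(is.finite(beta_hat)) || !all(is.finite(se)) ||
                              any(se <= 0)))
    db_stop("NonFiniteInput", "estimates must be finite and standard errors positive")
  if (nrow(beta_hat) < 10L)
    db_warn("SmallSample",
            paste0("only ", nrow(beta_hat),
                   " complete responses; posterior will be prior-dominated"))
  if (!is.null(config$seed)) set.seed(config$seed)

  npar <- 2L + J + (J * (J - 1L)) %/% 2L
  par_names <- bias_parameter_names(labels)
  # moment-matched central init, jittered per chain
  sd0 <- if (nrow(beta_hat) >= 2L) sd(rowMeans(beta_hat)) else 0.1
  base_init <- c(log(max(sd0, 0.1, na.rm = TRUE)),
                 rep(log(0.1), J), 0, rep(0, (J * (J - 1L)) %/% 2L))
  draws <- array(NA_real_, c(config$draws, npar, config$chains),
                 dimnames = list(NULL, par_names, NULL))
  evals <- numeric(config$chains)
  for (ch in seq_len(config$chains)) {
    init <- base_init + rnorm(npar, 0, 0.3)
    res <- bias_mcmc_cpp(beta_hat, se, init, config$warmup, config$draws,
                         config$thin, config$prior_sd_shape,
                         config$prior_sd_scale, config$prior_on == "variance",
                         config$lambda_shape, config$lambda_rate,
                         config$lkj_eta, config$target_accept)
    draws[, , ch] <- res$draws
    evals[ch] <- res$evals_per_iter
  }
  diag <- data.frame(parameter = par_names,
                     rhat = apply(draws, 2L, function(x) split_rhat(x)),
                     ess = apply(draws, 2L, function(x) ess_mean(x)),
                     row.names = NULL, stringsAsFactors = FALSE)
  fit <- structure(list(draws = draws, labels = labels, n = nrow(beta_hat),
                        diagnostics = list(parameters = diag,
                                           evals_per_iter = evals),
                        config = config,
                        data = list(beta_hat = beta_hat, se = se),
                        call = match.call()),
                   class = "bias_model")
  fit$summary <- posterior_report(fit)
  if (any(is.finite(diag$rhat) & diag$rhat > 1.01))
    db_warn("ConvergenceWarning",
            paste0("split-Rhat > 1.01 for: ",
                   paste(diag$parameter[is.finite(diag$rhat) &
                                        diag$rhat > 1.01], collapse = ", ")))
  fit
}

# pooled draws across chains as a single vector
pool_draws <- function(fit, parameter) {
  as.vector(fit$draws[, parameter, ])
}

#' Posterior summary table of a fitted bias model
#'
#' One row per model parameter — \eqn{\sigma_\beta}, the per-design bias
#' standard deviations \eqn{\sigma_j}, the standard-error scaling
#' \eqn{\lambda}, and the pairwise error correlations
#' \eqn{\Omega[a, b]} — with posterior mean, central 95% credible interval
#' and sampler diagnostics. Larger \eqn{\sigma_j} means a more biased
#' design.
#'
#' @param fit a [fit_bias_model()] result.
#' @param prob credible-interval mass.
#' @return Data frame with columns `parameter`, `mean`, `ci_low`,
#'   `ci_high`, `rhat`, `ess`.
#' @export
posterior_report <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "bias_model"))
  a <- (1 - prob) / 2
  pars <- dimnames(fit$draws)[[2L]]
  stats <- t(vapply(pars, function(p) {
    x <- pool_draws(fit, p)
    c(mean(x), quantile(x, c(a, 1 - a), names = FALSE))
  }, numeric(3L)))
  out <- data.frame(parameter = pars, mean = stats[, 1L],
                    ci_low = stats[, 2L], ci_high = stats[, 3L],
                    rhat = fit$diagnostics$parameters$rhat,
                    ess = fit$diagnostics$parameters$ess,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Per-response true-effect posterior given hyperparameters
#'
#' Conditional on hyperparameter values (posterior means by default), the
#' true effect of each response has a conjugate normal posterior:
#' with \eqn{V_i = \mathrm{diag}(\sigma_j^2) + \lambda D_i \Omega D_i},
#' precision \eqn{1/\sigma_\beta^2 + 1' V_i^{-1} 1} and mean
#' \eqn{(1' V_i^{-1} \hat\beta_i)} over that precision. This is the
#' generalised-least-squares pooling of the four design estimates that the
#' bias-adjusted meta-analysis applies across studies.
#'
#' @param fit a [fit_bias_model()] result.
#' @param sigma_beta,sigma,lambda,Omega optional hyperparameter overrides.
#'
#' @return Data frame with `response_id`, posterior `mean` and `sd`.
#' @export
posterior_true_effects <- function(fit, sigma_beta = NULL, sigma = NULL,
                                   lambda = NULL, Omega = NULL) {
  stopifnot(inherits(fit, "bias_model"))
  co <- coef(fit)
  J <- length(fit$labels)
  if (is.null(sigma_beta)) sigma_beta <- co[["sigma_beta"]]
  if (is.null(sigma)) sigma <- unname(co[paste0("sigma[", fit$labels, "]")])
  if (is.null(lambda)) lambda <- co[["lambda"]]
  if (is.null(Omega)) {
    Omega <- diag(J)
    pairs <- utils::combn(J, 2L)
    vals <- co[paste0("Omega[", fit$labels[pairs[1L, ]], ",",
                      fit$labels[pairs[2L, ]], "]")]
    Omega[t(pairs)] <- vals
    Omega[t(pairs)[, 2:1, drop = FALSE]] <- vals
  }
  bh <- fit$data$beta_hat
  se <- fit$data$se
  one <- rep(1, J)
  res <- t(vapply(seq_len(nrow(bh)), function(i) {
    V <- diag(sigma^2, J) + lambda * (se[i, ] %o% se[i, ]) * Omega
    Vi1 <- solve(V, one)
    prec <- 1 / sigma_beta^2 + sum(Vi1)
    c(sum(Vi1 * bh[i, ]) / prec, sqrt(1 / prec))
  }, numeric(2L)))
  data.frame(response_id = rownames(bh) %||% seq_len(nrow(bh)),
             mean = res[, 1L], sd = res[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.bias_model <- function(x, digits = 3, ...) {
  cat("Hierarchical Bayesian model of study-design bias\n")
  cat("  responses: ", x$n, "   designs: ", length(x$labels),
      " (", paste(x$labels, collapse = ", "), ")\n", sep = "")
  cat(sprintf("  chains: %d  draws/chain: %d (thin %d, +%d warmup sweeps)\n",
              x$config$chains, x$config$draws, x$config$thin, x$config$warmup))
  s <- x$summary
  s$mean <- signif(s$mean, digits)
  s$ci_low <- signif(s$ci_low, digits)
  s$ci_high <- signif(s$ci_high, digits)
  s$rhat <- round(s$rhat, 3)
  s$ess <- round(s$ess)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
summary.bias_model <- function(object, prob = 0.95, ...) {
  posterior_report(object, prob = prob)
}

#' @export
coef.bias_model <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' Trace and density plots for a fitted bias model
#'
#' @param x a `bias_model`.
#' @param parameters which parameters to show (default: the bias standard
#'   deviations and lambda).
#' @param ... unused.
#' @export
plot.bias_model <- function(x, parameters = NULL, ...) {
  if (is.null(parameters))
    parameters <- c(paste0("sigma[", x$labels, "]"), "lambda")
  old <- graphics::par(mfrow = c(length(parameters), 2),
                       mar = c(2.5, 2.5, 1.5, 0.5), mgp = c(1.5, 0.5, 0))
  on.exit(graphics::par(old))
  for (p in parameters) {
    d <- x$draws[, p, , drop = FALSE]
    graphics::matplot(d[, 1L, ], type = "l", lty = 1, xlab = "iteration",
                      ylab = p, main = p, cex.main = 0.9)
    graphics::plot(stats::density(as.vector(d)), main = "", xlab = p)
  }
  invisible(x)
}

#' Simulate estimate matrices from a fitted bias model
#'
#' Draws replicate data sets from the generative model at the posterior-mean
#' hyperparameters, using the observed standard-error matrix — the basis of
#' posterior-predictive checks.
#'
#' @param object a `bias_model`.
#' @param nsim number of replicate matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of `nsim` results of [simulate_estimates()].
#' @export
simulate.bias_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  co <- coef(object)
  J <- length(object$labels)
  Omega <- diag(J)
  pairs <- utils::combn(J, 2L)
  vals <- co[paste0("Omega[", object$labels[pairs[1L, ]], ",",
                    object$labels[pairs[2L, ]], "]")]
  Omega[t(pairs)] <- vals
  Omega[t(pairs)[, 2:1, drop = FALSE]] <- vals
  lapply(seq_len(nsim), function(k)
    simulate_estimates(nrow(object$data$beta_hat), co[["sigma_beta"]],
                       unname(co[paste0("sigma[", object$labels, "]")]),
                       co[["lambda"]], Omega, object$data$se,
                       labels = object$labels))
}

## ---- MCMC diagnostics -----------------------------------------------------

# split-Rhat (each chain halved) on an iterations x chains matrix
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- n %/% 2L
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(xs)
  w <- mean(apply(xs, 2L, var))
  if (w == 0) return(1)
  b <- half * var(colMeans(xs))
  vhat <- (half - 1) / half * w + b / half
  sqrt(vhat / w)
}

# effective sample size via chain-averaged autocorrelations, truncated at the
# first negative paired sum (Geyer initial positive sequence, simplified)
ess_mean <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4L) return(NA_real_)
  max_lag <- min(n - 2L, 500L)
  rho <- rowMeans(vapply(seq_len(m), function(ch) {
    a <- stats::acf(x[, ch], lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1L]
    as.numeric(a)
  }, numeric(max_lag)))
  s <- 0
  for (k in seq(1L, max_lag - 1L, by = 2L)) {
    pair <- rho[k] + rho[k + 1L]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
  }
  min(n * m / (1 + 2 * s), n * m)
}
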