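test_that("model inputs are complete-case matrices in fixed column order", {
  rows <- list()
  for (id in paste0("r", 1:5)) {
    for (l in estimator_labels()) {
      conv <- !(id == "r5" && l == "BA")  # one failed BA
      rows <- c(rows, list(make_est(rnorm(1), 0.2, response_id = id,
                                    estimator = l, converged = conv)))
    }
  }
  m <- do.call(make_estimates, rows)
  inp <- build_model_inputs(m)
  expect_identical(colnames(inp$beta_hat), estimator_labels())
  expect_identical(inp$n, 4L)
  expect_identical(inp$dropped, "r5")
  expect_identical(dim(inp$se), c(4L, 4L))

  m_bad <- m
  m_bad$converged <- FALSE
  expect_error(build_model_inputs(m_bad), class = "NoCompleteRows")
})

test_that("marginal likelihood agrees with a direct R implementation", {
  # independent oracle: dense MVN density via determinant() and solve()
  r_loglik <- function(bh, se, sb, sig, lam, Om) {
    J <- ncol(bh)
    ll <- 0
    for (i in seq_len(nrow(bh))) {
      S <- sb^2 * matrix(1, J, J) + diag(sig^2, J) +
        lam * (se[i, ] %o% se[i, ]) * Om
      ll <- ll + as.numeric(-0.5 * J * log(2 * pi) -
        0.5 * determinant(S)$modulus -
        0.5 * t(bh[i, ]) %*% solve(S) %*% bh[i, ])
    }
    ll
  }
  set.seed(17)
  for (k in 1:5) {
    Om <- designbias:::vine_corr_cpp(tanh(rnorm(6, 0, 0.7)), 4L)
    sig <- exp(rnorm(4, -2, 1))
    sb <- exp(rnorm(1, -0.5, 0.5))
    lam <- exp(rnorm(1, 0, 0.3))
    se <- matrix(runif(15 * 4, 0.05, 0.4), 15, 4)
    sim <- simulate_estimates(15, sb, sig, lam, Om, se)
    expect_equal(designbias:::bias_loglik_cpp(sim$beta_hat, se, sb, sig, lam, Om),
                 r_loglik(sim$beta_hat, se, sb, sig, lam, Om),
                 tolerance = 1e-10)
  }
})

test_that("vine construction always yields valid correlation matrices", {
  set.seed(18)
  for (k in 1:30) {
    Om <- designbias:::vine_corr_cpp(tanh(rnorm(6, 0, 1.5)), 4L)
    expect_equal(Om, t(Om), tolerance = 1e-12)
    expect_equal(diag(Om), rep(1, 4), tolerance = 1e-12)
    expect_gt(min(eigen(Om, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("with no data the posterior reproduces the prior", {
  f0 <- suppressWarnings(fit_bias_model(matrix(0, 0, 4), matrix(0, 0, 4),
    bias_model_config(seed = 4, draws = 1500, warmup = 300, thin = 2)))
  lam <- designbias:::pool_draws(f0, "lambda")
  expect_equal(mean(lam), 1, tolerance = 0.1)          # Gamma(2,2) mean
  expect_equal(var(lam), 0.5, tolerance = 0.2)         # Gamma(2,2) variance
  # Inv-Gamma(1, 0.02) prior median of a bias SD: 0.02 / log 2
  sb <- designbias:::pool_draws(f0, "sigma_beta")
  expect_equal(median(sb), 0.02 / log(2), tolerance = 0.2)
  # LKJ(1) marginal in d = 4: 2 * Beta(2, 2) - 1, variance 1/5
  om <- designbias:::pool_draws(f0, "Omega[BACI_DiD,CI]")
  expect_equal(var(om), 0.2, tolerance = 0.25)
  expect_lt(abs(mean(om)), 0.06)
})

test_that("null data drive the bias standard deviations towards zero", {
  sim <- simulate_estimates(200, 0.7, rep(0, 4), 1, diag(4), 0.1, seed = 7)
  f <- quick_fit(sim$beta_hat, sim$se, seed = 8, draws = 600, warmup = 300,
                 thin = 2)
  sig_means <- coef(f)[paste0("sigma[", estimator_labels(), "]")]
  expect_true(all(sig_means < 0.08))
  expect_equal(coef(f)[["sigma_beta"]], 0.7, tolerance = 0.1)
})

test_that("posterior respects column-label equivariance", {
  Om <- diag(4)
  sig <- c(0.03, 0.03, 0.03, 0.7)  # BA strongly biased
  se <- matrix(0.15, 400, 4)
  sim <- simulate_estimates(400, 0.6, sig, 1, Om, se, seed = 9)
  perm <- c(4L, 2L, 3L, 1L)        # swap BACI_DiD and BA columns
  f1 <- quick_fit(sim$beta_hat, se, seed = 10, draws = 500, warmup = 300)
  f2 <- suppressWarnings(fit_bias_model(sim$beta_hat[, perm], se,
    bias_model_config(seed = 10, draws = 500, warmup = 300, thin = 1),
    labels = estimator_labels()[perm]))
  s1 <- coef(f1)[paste0("sigma[", estimator_labels(), "]")]
  s2 <- coef(f2)[paste0("sigma[", estimator_labels(), "]")]
  # the biased design is identified as BA under either column order
  expect_identical(names(which.max(s1)), "sigma[BA]")
  expect_identical(names(which.max(s2)), "sigma[BA]")
  expect_equal(unname(s1), unname(s2), tolerance = 0.1)
})

test_that("pooled per-response effects match the conjugate closed form", {
  sim <- simulate_estimates(30, 0.7, c(0.1, 0.1, 0.1, 0.5), 1, diag(4),
                            0.2, seed = 11)
  f <- quick_fit(sim$beta_hat, sim$se, seed = 12, draws = 100, warmup = 100)
  sig <- c(0.1, 0.1, 0.1, 0.5)
  post <- posterior_true_effects(f, sigma_beta = 0.7, sigma = sig,
                                 lambda = 1, Omega = diag(4))
  # oracle: with Omega = I and lambda = 1 the GLS pooling reduces to
  # independent precision weights 1 / (sigma_j^2 + se_ij^2)
  for (i in c(1L, 17L, 30L)) {
    w <- 1 / (sig^2 + sim$se[i, ]^2)
    prec <- 1 / 0.7^2 + sum(w)
    expect_equal(post$mean[i], sum(w * sim$beta_hat[i, ]) / prec,
                 tolerance = 1e-9)
    expect_equal(post$sd[i], sqrt(1 / prec), tolerance = 1e-9)
  }
})

test_that("fit validates inputs and reports structure", {
  expect_error(fit_bias_model(matrix(c(1, Inf, 0, 1), 1), matrix(0.1, 1, 4)),
               class = "NonFiniteInput")
  expect_error(fit_bias_model(matrix(0, 2, 4), matrix(0.1, 3, 4)),
               class = "DimensionMismatch")
  expect_warning(
    withCallingHandlers(
      fit_bias_model(matrix(rnorm(8), 2, 4), matrix(0.1, 2, 4),
                     bias_model_config(seed = 1, draws = 50, warmup = 50,
                                       thin = 1)),
      ConvergenceWarning = function(w) invokeRestart("muffleWarning")),
    class = "SmallSample")

  sim <- simulate_estimates(40, 0.5, rep(0.1, 4), 1, diag(4), 0.2, seed = 13)
  f <- quick_fit(sim$beta_hat, sim$se, seed = 14, draws = 100, warmup = 100)
  rep <- posterior_report(f)
  expect_identical(nrow(rep), 12L)  # 1 sigma_beta + 4 sigma + 1 lambda + 6 Omega
  expect_true(all(rep$ci_low <= rep$mean & rep$mean <= rep$ci_high))
  expect_true(all(rep$mean[grepl("sigma|lambda", rep$parameter)] > 0))
  om_draws <- f$draws[, grepl("Omega", dimnames(f$draws)[[2L]]), ]
  expect_true(all(abs(om_draws) <= 1))
  expect_identical(dim(f$draws), c(100L, 12L, 2L))
  # methods run
  expect_output(print(f), "Hierarchical Bayesian model")
  expect_identical(nrow(summary(f)), 12L)
  s <- simulate(f, nsim = 2, seed = 1)
  expect_length(s, 2L)
  expect_identical(dim(s[[1L]]$beta_hat), dim(sim$beta_hat[1:40, ]))
})

test_that("severely truncated chains trigger the convergence warning", {
  sim <- simulate_estimates(100, 0.7, rep(0, 4), 1, diag(4), 0.1, seed = 15)
  expect_warning(
    fit_bias_model(sim$beta_hat, sim$se,
                   bias_model_config(seed = 16, draws = 40, warmup = 5,
                                     thin = 1)),
    class = "ConvergenceWarning")
})
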