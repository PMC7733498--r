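#' Exclude responses that cannot support reliable estimates
#'
#' A response is excluded when one or more of its four period x treatment
#' cells (Before-Control, Before-Impact, After-Control, After-Impact) is
#' empty or consists entirely of zero measurements, or when two or more of
#' these cells have more than 90% zero measurements. Responses lacking
#' repeated measurements per site in both periods are flagged in the report
#' but not dropped: standard errors from such data should be treated with
#' caution.
#'
#' @param datasets a list of [response_dataset()] objects (or a single one).
#'
#' @return A list with `retained` and `excluded` (lists of response
#'   datasets) and `report` (a data frame with one row per response: the
#'   exclusion rule that fired, if any, and the repeated-measurement flag).
#' @export
apply_exclusion_filter <- function(datasets) {
  if (inherits(datasets, "response_dataset")) datasets <- list(datasets)
  report <- do.call(rbind, lapply(datasets, function(d) {
    r <- d$records
    cells <- split(r$value, list(r$period, r$treatment), drop = FALSE)
    zero_frac <- vapply(cells, function(v)
      if (length(v) == 0L) 1 else mean(v == 0), numeric(1L))
    all_zero <- vapply(cells, function(v)
      length(v) == 0L || all(v == 0), logical(1L))
    rule <- if (any(all_zero)) "all_zero_subset"
            else if (sum(zero_frac > 0.9) >= 2L) "gt90_zero_subsets"
            else NA_character_
    per_site <- vapply(c("before", "after"), function(p) {
      rp <- r[r$period == p, , drop = FALSE]
      if (nrow(rp) == 0L) 0 else mean(table(rp$site))
    }, numeric(1L))
    data.frame(dataset_id = d$dataset_id, response_id = d$response_id,
               excluded = !is.na(rule), rule = rule,
               repeated_measurements = all(per_site >= 2),
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  list(retained = datasets[!report$excluded],
       excluded = datasets[report$excluded],
       report = report)
}

#' Subset a response dataset to mimic a study design
#'
#' A dataset collected with a (R-)BACI design contains the data an
#' alternative design would have collected: a BA design uses only the impact
#' group (both periods) and a CI design uses only the after-period (both
#' groups). Both BACI estimators use the full dataset.
#'
#' @param d a [response_dataset()].
#' @param estimator one of [estimator_labels()].
#'
#' @return A [response_dataset()] restricted to the records the design
#'   would have collected.
#' @export
subset_for_design <- function(d, estimator) {
  estimator <- match.arg(estimator, estimator_labels())
  r <- d$records
  keep <- switch(estimator,
                 BA = r$treatment == "impact",
                 CI = r$period == "after",
                 BACI_DiD = , BACI_CA = rep(TRUE, nrow(r)))
  required <- switch(estimator,
                     BA = c("before.impact", "after.impact"),
                     CI = c("after.control", "after.impact"),
                     BACI_DiD = , BACI_CA = c("before.control", "before.impact",
                                              "after.control", "after.impact"))
  cnt <- subset_counts(d)
  missing_cell <- required[cnt[required] == 0L]
  if (length(missing_cell))
    db_stop("EmptySubset",
            paste0(estimator, " requires non-empty cell(s): ",
                   paste(missing_cell, collapse = ", ")))
  out <- d
  out$records <- r[keep, , drop = FALSE]
  out
}

#' Choose the regression structure for a response
#'
#' The error family follows the measure: count -> poisson, density ->
#' quasipoisson (density data tend to be overdispersed), percentage ->
#' quasibinomial, size -> gaussian. The log link is used for every family so
#' that the focal coefficient is a log response ratio. A mixed model with
#' subsample-nested-in-site random intercepts is used when the data have at
#' least ten sites (independent sampling units) and at least two
#' measurements per site on average; otherwise a fixed-effects GLM is
#' fitted.
#'
#' @param d a [response_dataset()] (typically the design-specific subset
#'   actually being modelled).
#'
#' @return An object of class `model_spec`: list with `family`, `link`
#'   (always `"log"`), `mixed`, `random_terms` and `quasi`.
#' @export
choose_model_structure <- function(d) {
  stopifnot(inherits(d, "response_dataset"))
  family <- switch(d$measure,
                   count = "poisson", density = "quasipoisson",
                   percentage = "quasibinomial", size = "gaussian",
                   db_stop("UnknownMeasure", paste0("unknown measure: ", d$measure)))
  n_sites <- length(unique(d$records$site))
  per_site <- nrow(d$records) / n_sites
  mixed <- n_sites >= 10L && per_site >= 2
  structure(list(family = family, link = "log", mixed = mixed,
                 random_terms = if (mixed) "(1 | site/subsample)" else character(0),
                 quasi = family %in% c("quasipoisson", "quasibinomial")),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$family, "(link=log) ",
      if (x$mixed) paste0("GLMM ", x$random_terms) else "GLM", "\n", sep = "")
  invisible(x)
}

# lagged covariate for covariance adjustment: per-site before-period mean,
# log(mean + c) with c = half the smallest positive before-period value for
# the non-negative families, raw mean for gaussian
ca_lag_covariate <- function(records, measure) {
  before <- records[records$period == "before", , drop = FALSE]
  site_mean <- tapply(before$value, before$site, mean)
  if (measure == "gaussian" || measure == "size") return(site_mean)
  pos <- before$value[before$value > 0]
  c0 <- if (length(pos)) min(pos) / 2 else 0.5
  log(site_mean + c0)
}

glm_family <- function(family) {
  switch(family,
         poisson = stats::poisson(link = "log"),
         quasipoisson = stats::quasipoisson(link = "log"),
         quasibinomial = stats::quasibinomial(link = "log"),
         gaussian = stats::gaussian(link = "log"))
}

# family used inside glmer: quasi families via observation-level random effect
glmm_family <- function(family) {
  switch(family,
         poisson = , quasipoisson = stats::poisson(link = "log"),
         quasibinomial = stats::binomial(link = "log"),
         gaussian = stats::gaussian(link = "log"))
}

#' Fit one design estimator to a response dataset
#'
#' Applies the requested design to the appropriate subset of the data and
#' extracts the log response ratio: BA fits the period effect on impact-only
#' data; CI the treatment effect on after-only data; the BACI
#' difference-in-differences (DiD) estimator the period x treatment
#' interaction on the full data; and the BACI covariance-adjustment (CA)
#' estimator the treatment effect in an after-period model with a lagged
#' covariate built from each site's before-period mean. Each year/season
#' enters as an independent observation. The two-sided p-value uses a t
#' reference with residual degrees of freedom for GLMs and a normal (large
#' df) reference for mixed models; 95% confidence limits are fixed at
#' point +/- 1.96 se for cross-design comparability.
#'
#' @param d a [response_dataset()].
#' @param estimator one of [estimator_labels()].
#' @param spec optional [choose_model_structure()] result; by default the
#'   structure is chosen on the design-specific subset being fitted.
#'
#' @return One-row data frame (class `design_estimate`): `response_id`,
#'   `arm`, `estimator`, `point`, `se`, `df`, `p_value`, `ci_low`,
#'   `ci_high`, `family`, `mixed`, `converged`, `note`.
#' @export
fit_design_estimate <- function(d, estimator, spec = NULL) {
  estimator <- match.arg(estimator, estimator_labels())
  sub <- subset_for_design(d, estimator)
  if (is.null(spec)) spec <- choose_model_structure(sub)

  df <- sub$records
  df$period <- factor(df$period, levels = c("before", "after"))
  df$treatment <- factor(df$treatment, levels = c("control", "impact"))

  # a zero cell mean makes the log-link estimand infinite (separation)
  cells <- split(df$value, interaction(df$period, df$treatment, drop = TRUE))
  if (any(vapply(cells, mean, numeric(1L)) == 0))
    db_stop("SeparationOrZeroCell",
            paste0("cell(s) with zero mean in ", estimator, " subset"))

  if (estimator == "BACI_CA") {
    lag <- ca_lag_covariate(df, d$measure)
    df <- df[df$period == "after", , drop = FALSE]
    df$lag_cov <- as.numeric(lag[as.character(df$site)])
    dropped <- sum(is.na(df$lag_cov))
    if (dropped > 0L) df <- df[!is.na(df$lag_cov), , drop = FALSE]
    if (length(unique(df$treatment[!is.na(df$value)])) < 2L)
      db_stop("EmptySubset", "covariance adjustment lost a treatment arm (no before-period data)")
  }

  binom <- spec$family == "quasibinomial"
  df$y <- if (binom) df$value / 100 else df$value
  wts <- if (binom) rep(100, nrow(df)) else NULL

  rhs <- switch(estimator, BA = "period", CI = "treatment",
                BACI_DiD = "period * treatment",
                BACI_CA = "treatment + lag_cov")
  target <- switch(estimator, BA = "periodafter",
                   CI = , BACI_CA = "treatmentimpact",
                   BACI_DiD = "periodafter:treatmentimpact")

  # starting values keep the log link inside its domain
  mustart <- if (binom) pmin(pmax(df$y, 0.01), 1 - 1e-8)
             else pmax(df$y, max(min(df$y[df$y > 0], na.rm = TRUE) / 2, 1e-6))

  converged <- TRUE
  note <- ""
  handler <- function(w) {
    if (grepl("converge|Hessian|singular|unable to evaluate",
              conditionMessage(w), ignore.case = TRUE)) {
      converged <<- FALSE
      note <<- conditionMessage(w)
    }
    invokeRestart("muffleWarning")
  }

  if (spec$mixed) {
    rterms <- "(1 | site/subsample)"
    if (spec$quasi) {
      df$obs_id <- factor(seq_len(nrow(df)))  # observation-level RE for overdispersion
      rterms <- paste(rterms, "+ (1 | obs_id)")
    }
    form <- as.formula(paste("y ~", rhs, "+", rterms))
    fit <- withCallingHandlers(
      lme4::glmer(form, data = df, family = glmm_family(spec$family),
                  weights = wts, mustart = mustart),
      warning = handler)
    cf <- summary(fit)$coefficients
    if (!target %in% rownames(cf))
      db_stop("SeparationOrZeroCell", paste0("coefficient ", target, " not estimable"))
    point <- cf[target, "Estimate"]
    se <- cf[target, "Std. Error"]
    dof <- Inf  # Wald normal reference treated as t with large df
  } else {
    form <- as.formula(paste("y ~", rhs))
    fit <- withCallingHandlers(
      stats::glm(form, data = df, family = glm_family(spec$family),
                 weights = wts, mustart = mustart,
                 control = stats::glm.control(maxit = 100)),
      warning = handler)
    if (!fit$converged) converged <- FALSE
    cf <- summary(fit)$coefficients
    if (!target %in% rownames(cf) || is.na(cf[target, 2L]))
      db_stop("SeparationOrZeroCell", paste0("coefficient ", target, " not estimable"))
    point <- cf[target, 1L]
    se <- cf[target, 2L]
    dof <- fit$df.residual
  }
  tval <- point / se
  p <- 2 * pt(-abs(tval), df = dof)
  out <- data.frame(response_id = d$response_id,
                    arm = if (d$randomised) "randomised" else "non-randomised",
                    estimator = estimator, point = point, se = se, df = dof,
                    p_value = p, ci_low = point - 1.96 * se,
                    ci_high = point + 1.96 * se, family = spec$family,
                    mixed = spec$mixed, converged = converged, note = note,
                    stringsAsFactors = FALSE)
  class(out) <- c("design_estimate", class(out))
  rownames(out) <- NULL
  out
}

#' Fit all four design estimators to every response
#'
#' Runs [fit_design_estimate()] for BACI_DiD, BACI_CA, CI and BA on each
#' response. Per-response failures (empty subsets, zero cells,
#' non-convergence) are recorded as flagged rows; the batch never aborts.
#'
#' @param datasets a list of [response_dataset()] objects (or one), normally
#'   after [apply_exclusion_filter()].
#'
#' @return A data frame of class `estimate_matrix` with one row per
#'   (response, estimator): the columns of [fit_design_estimate()]. Failed
#'   fits have `NA` point/se and `converged = FALSE` with the reason in
#'   `note`.
#' @export
estimate_all <- function(datasets) {
  if (inherits(datasets, "response_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    do.call(rbind, lapply(estimator_labels(), function(est) {
      tryCatch(fit_design_estimate(d, est), error = function(e) {
        data.frame(response_id = d$response_id,
                   arm = if (d$randomised) "randomised" else "non-randomised",
                   estimator = est, point = NA_real_, se = NA_real_,
                   df = NA_real_, p_value = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, family = NA_character_, mixed = NA,
                   converged = FALSE, note = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("estimate_matrix", "data.frame")
  out
}

# reshape an estimate_matrix into response x design matrices of one column
estimate_wide <- function(m, column) {
  stopifnot(is.data.frame(m))
  labs <- estimator_labels()
  ids <- unique(m$response_id)
  out <- matrix(NA_real_, length(ids), length(labs),
                dimnames = list(ids, labs))
  keep <- m$estimator %in% labs
  out[cbind(match(m$response_id[keep], ids), match(m$estimator[keep], labs))] <-
    m[[column]][keep]
  out
}
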