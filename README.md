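# designbias

Estimates of the effect of an environmental impact or intervention depend
on how the data were collected. Uncontrolled Before-After (BA)
comparisons confuse the impact with background trends; after-only
Control-Impact (CI) comparisons confuse it with pre-existing differences
between groups; Before-After-Control-Impact (BACI) designs — and above
all their randomised counterparts — protect against both. `designbias`
is an R package for quantifying exactly how much each design's choice
costs: it mimics the simpler designs inside (R-)BACI monitoring
datasets, compares their effect estimates, fits a hierarchical Bayesian
model of per-design bias, and uses the fitted bias variances to pool
heterogeneous studies in a bias-adjusted meta-analysis. It is aimed at
ecologists and evidence-synthesis practitioners working with
before-after-control-impact monitoring data, and ships a synthetic-data
generator with known truth so the whole pipeline is testable end to end.

## The model

Each monitoring *response* (one response variable in one dataset) is fitted
under four estimators — the BACI difference-in-differences (DiD) and
covariance-adjustment (CA) estimators, CI, and BA — as GLM(M)s with a log
link, so every point estimate is a log response ratio. For response *i*
and design *j*, with estimate β̂ᵢⱼ and reported standard error σ̂ᵢⱼ:

    β̂ᵢⱼ = βᵢ + γᵢⱼ + εᵢⱼ
    βᵢ  ~ N(0, σ_β²)          true effects across responses
    γᵢⱼ ~ N(0, σⱼ²)           design bias (the quantity of interest)
    εᵢ  ~ N(0, λ·diag(σ̂ᵢ) Ω diag(σ̂ᵢ))

σⱼ is the standard deviation of design *j*'s bias across responses (larger
= more biased design), λ calibrates the reported standard errors (λ > 1:
underestimated), and Ω is the within-response correlation of the four
estimators' errors. Priors: Inv-Gamma(1, 0.02) on the σ's, Gamma(2, 2) on
λ, LKJ(1) on Ω. The per-response βᵢ and γᵢⱼ are marginalised analytically
and the 12 remaining hyperparameters are sampled with a covariance-adaptive
slice sampler written in C++ (see the methods vignette,
`vignettes/design-bias.Rmd`).

The fitted σⱼ then drive a bias-adjusted meta-analysis: a study of design
*j* gets precision weight 1/(σⱼ² + se²) instead of the classical 1/se², so
a precise-but-biased design no longer dominates the pooled effect.

## Worked example

Simulate one non-randomised monitoring response whose true effect is
θ = 0.5 on the log scale, contaminated by a confound δ = 0.4 and a trend
τ = 0.2, and fit all four designs:

```r
library(designbias)

scn <- monitoring_scenario(n_sites_per_arm = 6, n_subsamples = 2,
                           theta = 0.5, delta = 0.4, tau = 0.2, seed = 42)
sim <- simulate_monitoring_dataset(scn)
estimate_all(sim$dataset)[, c("estimator", "point", "se", "p_value")]
#>   estimator point     se  p_value
#> 1  BACI_DiD 0.473 0.0551 9.17e-18
#> 2   BACI_CA 0.475 0.0689 5.39e-12
#> 3        CI 0.615 0.1832 7.84e-04
#> 4        BA 0.697 0.0361 9.45e-30
```

Both BACI estimators sit near the true 0.5. BA converges tightly on 0.7 —
the true effect *plus the trend* — and CI drifts towards the confounded
value: precisely the design biases the package measures. Now estimate the
bias structure from 500 responses drawn from the hierarchical model with
known parameters (σ_β = 0.7, σ = (0.03, 0.005, 0.005, 0.77), λ = 1.2,
Ω[CA,CI] = 0.95):

```r
set.seed(1)
Om <- diag(4); Om[2, 3] <- Om[3, 2] <- 0.95
se_mat <- matrix(exp(rnorm(500 * 4, log(0.2), 0.5)), 500, 4)
est <- simulate_estimates(500, 0.7, c(0.03, 0.005, 0.005, 0.77), 1.2, Om,
                          se_mat, seed = 2)
fit <- fit_bias_model(est$beta_hat, est$se, bias_model_config(seed = 3))
fit
#>                parameter     mean   ci_low ci_high  rhat  ess
#>               sigma_beta  0.72400  0.67900  0.7700 0.999 2000
#>          sigma[BACI_DiD]  0.02870  0.00548  0.0778 1.001 1763
#>           sigma[BACI_CA]  0.01270  0.00423  0.0275 0.999 2000
#>                sigma[CI]  0.01480  0.00449  0.0319 0.999 2000
#>                sigma[BA]  0.79800  0.74400  0.8560 1.000 2000
#>                   lambda  1.20000  1.06000  1.3600 1.000 1777
#>  ...
#>        Omega[BACI_CA,CI]  0.95100  0.93500  0.9660 1.000 1851
```

Every generating value is recovered inside its 95% credible interval: BA
is identified as the heavily biased design (σ ≈ 0.8), the BACI/CI family
as nearly unbiased, and the CA–CI error correlation as ≈ 0.95. Finally,
pool two hypothetical studies of the same effect — a precise BA study
reporting 0.0 and a BACI study reporting 1.0 — using those bias SDs:

```r
studies <- data.frame(point = c(0, 1), se = c(0.1, 0.1),
                      design = c("BA", "BACI_DiD"))
sig <- setNames(coef(fit)[c("sigma[BA]", "sigma[BACI_DiD]")],
                c("BA", "BACI_DiD"))
bias_adjusted_pool(studies, sig)
#> Pooled effect (bias_adjusted, closed_form)
#>   mu = 0.984  se = 0.103  95% interval [0.781, 1.186]  (k = 2 studies)
#>   weights: 0.016 0.984
inverse_variance_pool(studies)
#> Pooled effect (inverse_variance, closed_form)
#>   mu = 0.500  se = 0.071  95% interval [0.361, 0.639]  (k = 2 studies)
```

Classical inverse-variance pooling splits the difference (0.5); the
bias-adjusted estimate (0.98) discounts the BA study to a 1.6% weight
because its design, not its standard error, is the dominant uncertainty.

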