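# Shared fixtures: a one-exposure world small enough to fit in ~2 s,
# plus an independent dense multivariate-normal log-likelihood oracle.

small_schedule <- function() {
  exposure_schedule("e1", "2020-01-01", "2020-01-08")
}

small_meta <- function() {
  province_meta(data.frame(
    province = c("A1", "A2", "B1", "B2", "C1", "C2"),
    hdi_category = rep(c("low", "middle", "high"), each = 2),
    hdi = c(0.62, 0.64, 0.70, 0.72, 0.80, 0.82),
    gnppp = c(30, 32, 50, 52, 80, 82) * 1000,
    education_years = c(8, 8.2, 9.5, 9.7, 11, 11.2),
    life_expectancy = c(71, 71.5, 74, 74.5, 77, 77.5)
  ))
}

small_truth <- function() {
  c(`(Intercept)` = log(150), hdi_middle = 0.2, hdi_high = 0.4,
    T = log(1.1) / 365, T_hdi_middle = 0, T_hdi_high = 0,
    step_e1_low = log(1.5), step_e1_middle = log(1.7),
    step_e1_high = log(1.6),
    slope_e1_low = log(0.9) / 7, slope_e1_middle = log(0.9) / 7,
    slope_e1_high = log(0.92) / 7)
}

# 13-month window so month dummies repeat and the design is full rank.
small_config <- function(seed, sigma2 = 0.04, rho = 0.6,
                         G = diag(c(0.01, (5e-5)^2)), ...) {
  simulation_config(
    n_provinces_per_category = c(low = 2, middle = 2, high = 2),
    date_range = c("2019-06-01", "2020-06-30"),
    true_coefficients = small_truth(),
    sigma2 = sigma2, rho = rho, G = G, seed = seed, ...)
}

small_sim <- function(seed, ...) {
  simulate_panel(small_config(seed, ...), small_schedule(), small_meta())
}

small_fit <- function(seed, ...) {
  sim <- small_sim(seed, ...)
  des <- build_design(sim$panel, small_meta(), small_schedule(),
                      study_start = "2019-06-01")
  list(fit = fit_model(des, n_starts = 1, control = list(maxit = 400)),
       sim = sim, design = des)
}

# Brute-force dense MVN log-density: builds V elementwise and uses the
# generic quadratic-form formula, independent of the package's
# tridiagonal/Woodbury path.
dense_block_loglik <- function(e, t, sigma2, rho, G) {
  n <- length(e)
  Z <- cbind(1, t)
  V <- sigma2 * rho^abs(outer(t, t, "-")) + Z %*% G %*% t(Z)
  -0.5 * (n * log(2 * pi) + as.numeric(determinant(V)$modulus) +
            drop(t(e) %*% solve(V, e)))
}

# A tiny fake fit for closed-form effect arithmetic.
fake_fit <- function(beta, se = NULL, cov = NULL, hdi_mode = "categorical",
                     schedule = NULL) {
  p <- length(beta)
  if (is.null(cov)) {
    se <- se %||% rep(0.1, p)
    cov <- diag(se^2, p)
  }
  dimnames(cov) <- list(names(beta), names(beta))
  structure(list(beta = beta, cov_beta = cov, hdi_mode = hdi_mode,
                 schedule = schedule), class = "its_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
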