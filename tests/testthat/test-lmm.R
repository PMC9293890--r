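test_that("ar1_corr matches the closed form, with and without gaps", {
  expect_equal(ar1_corr(3, 0.5),
               matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3))
  expect_equal(ar1_corr(4, 0), diag(4))
  expect_equal(ar1_corr(2, 0.5, gaps = c(0, 2))[1, 2], 0.25)
  expect_error(ar1_corr(3, 1), class = "its_config_error")
})

test_that("marginal_loglik equals a dense MVN oracle on small blocks", {
  set.seed(99)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(1:6, 1)
    t1 <- sort(sample(0:12, n1)); t2 <- sort(sample(0:12, n2))
    X <- cbind(1, rnorm(n1 + n2), rnorm(n1 + n2))
    beta <- rnorm(3)
    y <- rnorm(n1 + n2, sd = 2)
    s2 <- runif(1, 0.2, 2); rho <- runif(1, -0.8, 0.9)
    a <- runif(1, 0.01, 0.5); d <- runif(1, 0.001, 0.05)
    cv <- runif(1, -1, 1) * sqrt(a * d) * 0.9
    G <- matrix(c(a, cv, cv, d), 2)
    prov <- rep(c("p1", "p2"), c(n1, n2))
    e <- y - drop(X %*% beta)
    oracle <- dense_block_loglik(e[1:n1], t1, s2, rho, G) +
      dense_block_loglik(e[(n1 + 1):(n1 + n2)], t2, s2, rho, G)
    expect_equal(marginal_loglik(beta, s2, rho, G, X, y, prov, c(t1, t2)),
                 oracle, tolerance = 1e-10)
  }
})

test_that("single-observation residual-0 loglik is the standard normal density", {
  ll <- marginal_loglik(beta = 0, sigma2 = 1, rho = 0.5,
                        G = matrix(0, 2, 2), X = matrix(0), y = 0,
                        province = "a", tdays = 0)
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("doubling sigma2 at zero residuals lowers the loglik by n/2 * ln 2", {
  n <- 8
  X <- matrix(1, n)
  y <- rep(2, n)
  args <- list(beta = 2, rho = 0.4, G = matrix(0, 2, 2), X = X, y = y,
               province = rep("a", n), tdays = 0:(n - 1))
  l1 <- do.call(marginal_loglik, c(args, sigma2 = 1))
  l2 <- do.call(marginal_loglik, c(args, sigma2 = 2))
  expect_equal(l1 - l2, 0.5 * n * log(2), tolerance = 1e-10)
})

test_that("with rho = 0 and G = 0 the profiled GLS reduces to OLS", {
  set.seed(3)
  n <- 120
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- drop(X %*% c(1, 0.5, -0.2)) + rnorm(n, sd = 0.3)
  prov <- rep(c("a", "b"), each = n / 2)
  td <- rep(0:(n / 2 - 1), 2)
  ols <- stats::lm(y ~ X - 1)
  # GLS normal equations at the null variance structure
  bd <- searchits:::make_blocks(X, y, prov, td)
  acc <- searchits:::gls_accumulate(bd$blocks, rho = 0,
                                    L = matrix(0, 2, 2))
  beta_gls <- solve(acc$A, acc$b)
  expect_equal(unname(beta_gls), unname(coef(ols)), tolerance = 1e-8)
  # and the marginal loglik at the OLS solution equals lm's ML loglik
  s2_ml <- sum(resid(ols)^2) / n
  ll <- marginal_loglik(coef(ols), s2_ml, 0, matrix(0, 2, 2),
                        bd$X, bd$y, bd$province, bd$tdays)
  expect_equal(ll, as.numeric(stats::logLik(ols)), tolerance = 1e-8)
})

test_that("information criteria are the stated closed forms", {
  ic <- information_criteria(0, 3, exp(2))
  expect_equal(ic$aic, 6)
  expect_equal(ic$bic, 6)
  ic <- information_criteria(-100, 10, 100)
  expect_equal(ic$aic, 220)
  expect_equal(ic$bic, 246.0517, tolerance = 1e-4)
  # aic < bic iff n > e^2
  expect_true(information_criteria(-5, 4, 8)$aic <
                information_criteria(-5, 4, 8)$bic)
  expect_true(information_criteria(-5, 4, 7)$aic >
                information_criteria(-5, 4, 7)$bic)
})

test_that("fit recovers a small simulated world and is a likelihood optimum", {
  res <- small_fit(17)
  fit <- res$fit
  expect_true(fit$converged)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  expect_equal(fit$bic, -2 * fit$loglik + fit$n_params * log(fit$n_obs))
  expect_equal(dim(fit$cov_beta), rep(length(fit$beta), 2))
  expect_true(all(diag(fit$cov_beta) > 0))

  # profiled-GLS optimality: perturbing beta coordinates cannot improve
  # the marginal likelihood at the fitted variance components
  ll0 <- marginal_loglik(fit$beta, fit$vc$sigma2, fit$vc$rho, fit$vc$G,
                         fit$X, fit$y, fit$province, fit$tdays)
  for (j in c(1, 4, 7)) {
    for (d in c(-1e-4, 1e-4)) {
      b <- fit$beta
      b[j] <- b[j] + d
      ll <- marginal_loglik(b, fit$vc$sigma2, fit$vc$rho, fit$vc$G,
                            fit$X, fit$y, fit$province, fit$tdays)
      expect_lte(ll, ll0 + 1e-9)
    }
  }
})

test_that("fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  # appreciable random effects so both implementations estimate an
  # interior optimum for G
  res <- small_fit(29, G = diag(c(0.04, (3e-4)^2)))
  des <- res$design
  df <- data.frame(y = des$y, prov = des$province, tdays = des$tdays,
                   t365 = des$tdays / 365)
  df$Xm <- des$X
  ctrl <- nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                           returnObject = TRUE)
  ref <- nlme::lme(y ~ Xm - 1, data = df,
                   random = ~ 1 + t365 | prov,
                   correlation = nlme::corAR1(form = ~ tdays | prov),
                   method = "ML", control = ctrl)
  expect_gte(res$fit$loglik, as.numeric(stats::logLik(ref)) - 0.01)
  expect_lt(max(abs(res$fit$beta - nlme::fixef(ref))), 1e-3)
  expect_equal(res$fit$vc$rho,
               as.numeric(stats::coef(ref$modelStruct$corStruct,
                                      unconstrained = FALSE)),
               tolerance = 1e-3)
})

test_that("rank-deficient designs fail with the collinear column named", {
  X <- cbind(a = rep(1, 20), b = rep(2, 20), t = 1:20)
  y <- rnorm(20)
  expect_error(fit_lnlmm(X, y, rep(c("p", "q"), each = 10),
                         rep(0:9, 2)),
               "collinear column\\(s\\): b")
})

test_that("whitening an exact AR(1) series and diagnostics behave", {
  res <- small_fit(31)
  d <- residual_diagnostics(res$fit)
  expect_gt(d$lag1_raw, 0.3)            # raw residuals are autocorrelated
  expect_lt(abs(d$lag1_whitened), 0.05) # whitened ones are not
  expect_lt(abs(d$skewness), 0.2)
  expect_lt(abs(d$excess_kurtosis), 0.4)

  # heteroscedastic noise injection is flagged by the variance slope
  sim <- small_sim(33)
  des <- build_design(sim$panel, small_meta(), small_schedule(),
                      study_start = "2019-06-01")
  lp <- des$y
  set.seed(33)
  extra <- stats::rnorm(length(lp), sd = 0.3 * (lp > log(400)))
  des2 <- des
  des2$y <- lp + extra
  fit2 <- fit_lnlmm(des2$X, des2$y, des2$province, des2$tdays,
                    n_starts = 1, control = list(maxit = 300))
  fit2$hdi_mode <- "categorical"
  d2 <- residual_diagnostics(fit2)
  expect_gt(d2$variance_slope_z, 2)
})
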