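#' AR(1) correlation matrix
#'
#' Entry (s, t) is `rho^|d_s - d_t|` where `d` are day offsets; with no
#' gaps supplied, `rho^|s - t|`. Missing days are therefore handled by
#' the continuous-time AR(1) embedding: correlation decays with the
#' calendar-day distance, not the row distance.
#'
#' @param n series length (>= 1).
#' @param rho AR(1) coefficient, `|rho| < 1`.
#' @param gaps optional numeric day offsets (length `n`).
#' @return `n` x `n` correlation matrix.
#' @export
ar1_corr <- function(n, rho, gaps = NULL) {
  if (!is_count(n)) config_error("n must be a positive integer")
  if (!is.numeric(rho) || abs(rho) >= 1) config_error("|rho| must be < 1")
  d <- if (is.null(gaps)) seq_len(n) else {
    if (length(gaps) != n) config_error("gaps must have length n")
    as.numeric(gaps)
  }
  rho^abs(outer(d, d, "-"))
}

# --- internal machinery -----------------------------------------------------
# Per-province block b with sorted days d_1..d_n and adjacent correlations
# r_k = rho^(d_{k+1} - d_k), the AR(1) correlation matrix R has a tridiagonal
# precision P: diag_k = 1/(1 - r_{k-1}^2) + 1/(1 - r_k^2) - 1 (edge terms
# drop), offdiag_k = -r_k/(1 - r_k^2), and log det R = sum log(1 - r_k^2).
# All likelihood work uses P applied to tall matrices, O(n) per column,
# plus 2x2 Woodbury corrections for the random effects, so each likelihood
# evaluation is linear in the panel size.

YEAR_DAYS <- 365  # random-slope column is tdays / YEAR_DAYS for conditioning

ar1_precision_apply <- function(M, r) {
  n <- nrow(M)
  if (n == 1L) return(M)
  a <- 1 / (1 - r^2)                     # length n-1
  dg <- c(1, a) + c(a, 1) - 1
  off <- -r * a
  PM <- dg * M
  PM[1:(n - 1), ] <- PM[1:(n - 1), , drop = FALSE] + off * M[2:n, , drop = FALSE]
  PM[2:n, ] <- PM[2:n, , drop = FALSE] + off * M[1:(n - 1), , drop = FALSE]
  PM
}

make_blocks <- function(X, y, province, tdays) {
  province <- as.factor(province)
  ord <- order(province, tdays)
  X <- X[ord, , drop = FALSE]; y <- y[ord]; tdays <- tdays[ord]
  province <- province[ord]
  idx <- split(seq_along(y), province)
  blocks <- lapply(idx, function(i) {
    list(X = X[i, , drop = FALSE], y = y[i], t = tdays[i],
         Z = cbind(1, tdays[i] / YEAR_DAYS))
  })
  list(blocks = blocks, order = ord, X = X, y = y, tdays = tdays,
       province = province)
}

# Accumulate GLS quantities under W = R + U U' (V = sigma2 * W), where
# U = Z %*% L and L is the relative (G/sigma2) Cholesky in year units.
gls_accumulate <- function(blocks, rho, L) {
  p <- ncol(blocks[[1]]$X)
  A <- matrix(0, p, p); b <- numeric(p); cc <- 0; ld <- 0
  for (bl in blocks) {
    n <- length(bl$y)
    U <- bl$Z %*% L
    W <- cbind(bl$X, bl$y, U)
    if (n > 1L) {
      r <- rho^diff(bl$t)
      PW <- ar1_precision_apply(W, r)
      ld <- ld + sum(log1p(-r^2))
    } else {
      PW <- W
    }
    C <- crossprod(W, PW)
    ix <- 1:p; iy <- p + 1L; iu <- (p + 2L):(p + 3L)
    M <- diag(2) + C[iu, iu]
    ch <- chol(M)
    ld <- ld + 2 * sum(log(diag(ch)))
    Minv <- chol2inv(ch)
    UtPX <- C[iu, ix, drop = FALSE]; UtPy <- C[iu, iy]
    A <- A + C[ix, ix] - crossprod(UtPX, Minv %*% UtPX)
    b <- b + C[ix, iy] - drop(crossprod(UtPX, Minv %*% UtPy))
    cc <- cc + C[iy, iy] - drop(crossprod(UtPy, Minv %*% UtPy))
  }
  list(A = A, b = b, c = cc, ld = ld)
}

theta_unpack <- function(theta) {
  th <- pmin(pmax(theta, c(-6, -12, -60, -12)), c(6, 6, 60, 6))
  rho <- tanh(th[1])
  L <- matrix(c(exp(th[2]), th[3], 0, exp(th[4])), 2, 2)
  list(rho = rho, L = L)
}

profiled_nll <- function(theta, blocks, N, p, reml) {
  tp <- theta_unpack(theta)
  acc <- tryCatch(gls_accumulate(blocks, tp$rho, tp$L),
                  error = function(e) NULL)
  if (is.null(acc) || !all(is.finite(acc$A))) return(1e10)
  sol <- tryCatch({
    ch <- chol(acc$A)
    beta <- backsolve(ch, forwardsolve(t(ch), acc$b))
    list(beta = beta, ldA = 2 * sum(log(diag(ch))))
  }, error = function(e) NULL)
  if (is.null(sol)) return(1e10)
  Q <- acc$c - sum(acc$b * sol$beta)
  if (!is.finite(Q) || Q <= 0) return(1e10)
  if (reml) {
    s2 <- Q / (N - p)
    0.5 * ((N - p) * (log(2 * pi * s2) + 1) + acc$ld + sol$ldA)
  } else {
    s2 <- Q / N
    0.5 * (N * (log(2 * pi * s2) + 1) + acc$ld)
  }
}

#' Marginal log-likelihood of the AR(1) log-normal mixed model
#'
#' Sum over province blocks of the multivariate-normal log-density with
#' mean `X beta` and covariance `V_i = Z_i G Z_i' + sigma2 R_i(rho)`,
#' where `Z_i = (1, T_i)` (intercept and study day) and `R_i` is the
#' AR(1) correlation over calendar days. Uses the tridiagonal AR(1)
#' precision plus rank-2 Woodbury corrections, so the cost is linear in
#' the panel size.
#'
#' @param beta fixed-effect vector (length `ncol(X)`).
#' @param sigma2 residual marginal variance (> 0).
#' @param rho AR(1) coefficient, `|rho| < 1`.
#' @param G 2x2 PSD covariance of (intercept, slope-per-day) random
#'   effects.
#' @param X fixed-effect design matrix.
#' @param y response (log index).
#' @param province blocking factor.
#' @param tdays study day per row.
#' @return the log-likelihood (scalar).
#' @export
marginal_loglik <- function(beta, sigma2, rho, G, X, y, province, tdays) {
  if (!is.numeric(sigma2) || sigma2 <= 0) config_error("sigma2 must be > 0")
  if (abs(rho) >= 1) config_error("|rho| must be < 1")
  G <- as.matrix(G)
  eg <- eigen(G, symmetric = TRUE)
  if (any(eg$values < -1e-10)) config_error("G must be PSD")
  Fm <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 2)
  bd <- make_blocks(X, y, province, tdays)
  e_all <- bd$y - drop(bd$X %*% beta)
  ll <- 0
  pos <- 0
  for (bl in bd$blocks) {
    n <- length(bl$y)
    e <- e_all[(pos + 1):(pos + n)]; pos <- pos + n
    U <- cbind(1, bl$t) %*% Fm                    # per-day Z here
    W <- cbind(e, U)
    if (n > 1L) {
      r <- rho^diff(bl$t)
      PW <- ar1_precision_apply(W, r)
      ldR <- sum(log1p(-r^2))
    } else {
      PW <- W; ldR <- 0
    }
    C <- crossprod(W, PW)
    M <- diag(2) + C[2:3, 2:3] / sigma2
    ch <- chol(M)
    Minv <- chol2inv(ch)
    q <- C[1, 1] / sigma2 -
      drop(crossprod(C[2:3, 1], Minv %*% C[2:3, 1])) / sigma2^2
    ldV <- n * log(sigma2) + ldR + 2 * sum(log(diag(ch)))
    ll <- ll - 0.5 * (n * log(2 * pi) + ldV + q)
  }
  ll
}

#' Fit the segmented log-normal mixed model
#'
#' Maximum (restricted) likelihood over `(rho, sigma2, G)` with the
#' fixed effects profiled out by generalized least squares at every
#' step; `sigma2` is itself profiled analytically, leaving a 4-parameter
#' optimization over `atanh(rho)` and the log-Cholesky of the relative
#' random-effect covariance. Nelder-Mead with multiple starts guards
#' against local optima. The random-effect design is a per-province
#' intercept and study time (internally scaled to years for
#' conditioning; `G` is reported on the per-day scale).
#'
#' @param X full-column-rank fixed-effect design matrix with column
#'   names.
#' @param y log search index.
#' @param province blocking factor (>= 2 provinces).
#' @param tdays study day per row.
#' @param method `"ml"` (default, so AIC/BIC comparisons across
#'   fixed-effect structures are valid) or `"reml"`.
#' @param n_starts number of optimizer starts (default 3).
#' @param control list: `maxit` (default 600), `reltol` (default 1e-9).
#' @return an object of class `its_fit`: `beta`, `cov_beta`, `vc`
#'   (`sigma2`, `rho`, `G` per-day), `loglik`, `aic`, `bic`, `n_obs`,
#'   `n_params`, `converged`, `method`, optimizer trace, and the data
#'   needed for diagnostics.
#' @export
fit_lnlmm <- function(X, y, province, tdays, method = c("ml", "reml"),
                      n_starts = 3, control = list()) {
  method <- match.arg(method)
  maxit <- control$maxit %||% 600
  reltol <- control$reltol %||% 1e-9
  X <- as.matrix(X)
  p <- ncol(X); N <- length(y)
  if (nrow(X) != N) config_error("X and y dimensions differ")
  if (length(unique(province)) < 2L) config_error("need >= 2 provinces")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    validation_error(sprintf("X is rank deficient; collinear column(s): %s",
                             paste(bad, collapse = ", ")))
  }
  bd <- make_blocks(X, y, province, tdays)
  reml <- method == "reml"
  obj <- function(th) profiled_nll(th, bd$blocks, N, p, reml)

  starts <- list(c(atanh(0.3), log(0.5), 0, log(0.5)),
                 c(atanh(0.7), log(1.5), 0, log(0.05)),
                 c(0, log(0.05), 0, log(1)))
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  fits <- lapply(starts, function(s) {
    stats::optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  refine <- stats::optim(best$par, obj, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = reltol))
  if (refine$value > best$value) refine <- best

  tp <- theta_unpack(refine$par)
  acc <- gls_accumulate(bd$blocks, tp$rho, tp$L)
  ch <- chol(acc$A)
  beta <- drop(backsolve(ch, forwardsolve(t(ch), acc$b)))
  names(beta) <- colnames(X)
  Q <- acc$c - sum(acc$b * beta)
  s2 <- if (reml) Q / (N - p) else Q / N
  cov_beta <- s2 * chol2inv(ch)
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  G_rel_yr <- tcrossprod(tp$L)
  D <- diag(c(1, 1 / YEAR_DAYS))
  G_day <- s2 * D %*% G_rel_yr %*% D
  dimnames(G_day) <- list(c("intercept", "slope_day"),
                          c("intercept", "slope_day"))
  loglik <- -refine$value
  n_params <- p + 5L  # sigma2, rho, 3 free G parameters
  icrit <- information_criteria(loglik, n_params, N)
  structure(list(
    beta = beta, cov_beta = cov_beta,
    vc = list(sigma2 = s2, rho = tp$rho, G = G_day),
    loglik = loglik, aic = icrit$aic, bic = icrit$bic,
    n_obs = N, n_params = n_params,
    converged = refine$convergence == 0 && is.finite(refine$value),
    method = method,
    optim = list(theta = refine$par, value = refine$value,
                 start_values = vapply(fits, `[[`, 0, "value"),
                 counts = refine$counts),
    X = bd$X, y = bd$y, province = bd$province, tdays = bd$tdays
  ), class = "its_fit")
}

#' Fit the model from a built design
#'
#' Thin wrapper around [fit_lnlmm()] that carries the design's mode and
#' schedule into the fit object so effect summaries know how to find
#' coefficients.
#'
#' @param design an `its_design` from [build_design()].
#' @inheritParams fit_lnlmm
#' @return an `its_fit` with `hdi_mode` and `schedule` attached.
#' @export
fit_model <- function(design, method = c("ml", "reml"), n_starts = 3,
                      control = list()) {
  fit <- fit_lnlmm(design$X, design$y, design$province, design$tdays,
                   method = method, n_starts = n_starts, control = control)
  fit$hdi_mode <- design$hdi_mode
  fit$schedule <- design$schedule
  fit
}

#' Akaike and Bayesian information criteria
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of estimated parameters.
#' @param n_obs number of observations (>= 1).
#' @return list with `aic = -2*loglik + 2*n_params` and
#'   `bic = -2*loglik + n_params*log(n_obs)`.
#' @export
information_criteria <- function(loglik, n_params, n_obs) {
  if (!is.numeric(n_obs) || n_obs < 1) config_error("n_obs must be >= 1")
  list(aic = -2 * loglik + 2 * n_params,
       bic = -2 * loglik + n_params * log(n_obs))
}

#' Residual diagnostics for a fitted model
#'
#' Returns standardized marginal residuals, the pooled lag-1
#' autocorrelation of within-province residuals before and after full
#' whitening by the fitted marginal covariance, moment-based normality
#' statistics (skewness and excess kurtosis of the whitened residuals),
#' and the slope of squared standardized residuals on fitted values (a
#' heteroscedasticity probe) with its Wald z.
#'
#' @param fit an `its_fit`.
#' @return list of class `its_diagnostics`.
#' @export
residual_diagnostics <- function(fit) {
  beta <- fit$beta
  fitted <- drop(fit$X %*% beta)
  r <- fit$y - fitted
  vc <- fit$vc
  idx <- split(seq_along(r), fit$province)
  white <- numeric(length(r))
  std <- numeric(length(r))
  num_raw <- den_raw <- num_w <- den_w <- 0
  for (i in idx) {
    t_i <- fit$tdays[i]
    n <- length(i)
    Z <- cbind(1, t_i)
    V <- vc$sigma2 * ar1_corr(n, vc$rho, gaps = t_i) +
      Z %*% vc$G %*% t(Z)
    ch <- chol(V)
    w <- forwardsolve(t(ch), r[i])
    white[i] <- w
    std[i] <- r[i] / sqrt(diag(V))
    if (n > 1) {
      adj <- which(diff(t_i) == 1)
      num_raw <- num_raw + sum(r[i][adj] * r[i][adj + 1])
      den_raw <- den_raw + sum(r[i]^2)
      num_w <- num_w + sum(w[-n] * w[-1])
      den_w <- den_w + sum(w^2)
    }
  }
  sk <- mean((white - mean(white))^3) / stats::sd(white)^3
  ku <- mean((white - mean(white))^4) / stats::sd(white)^4 - 3
  vs <- stats::lm(I(std^2) ~ fitted)
  sl <- summary(vs)$coefficients["fitted", ]
  structure(list(
    residuals = r, std_residuals = std, whitened = white, fitted = fitted,
    lag1_raw = num_raw / den_raw, lag1_whitened = num_w / den_w,
    skewness = sk, excess_kurtosis = ku,
    variance_slope = unname(sl["Estimate"]),
    variance_slope_z = unname(sl["t value"])
  ), class = "its_diagnostics")
}

#' @export
print.its_fit <- function(x, ...) {
  cat("Segmented log-normal mixed model (", toupper(x$method), ")\n", sep = "")
  cat(sprintf("  n = %d obs, %d provinces, %d fixed effects; converged: %s\n",
              x$n_obs, nlevels(x$province), length(x$beta), x$converged))
  cat(sprintf("  logLik %.2f | AIC %.2f | BIC %.2f\n", x$loglik, x$aic, x$bic))
  cat(sprintf("  sigma2 %.4g | rho %.3f | RE sd (intercept %.3g, slope/day %.3g)\n",
              x$vc$sigma2, x$vc$rho, sqrt(x$vc$G[1, 1]), sqrt(x$vc$G[2, 2])))
  invisible(x)
}

#' @export
print.its_diagnostics <- function(x, ...) {
  cat("Residual diagnostics\n")
  cat(sprintf("  lag-1 autocorrelation: raw %.3f, whitened %.3f\n",
              x$lag1_raw, x$lag1_whitened))
  cat(sprintf("  whitened skewness %.3f, excess kurtosis %.3f\n",
              x$skewness, x$excess_kurtosis))
  cat(sprintf("  variance-vs-fitted slope %.4g (z = %.2f)\n",
              x$variance_slope, x$variance_slope_z))
  invisible(x)
}
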