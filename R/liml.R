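#' Parameters of the joint limited-information likelihood
#'
#' The LIML model couples a normal linear exposure equation
#' \eqn{T_i = \gamma_0 + Z_i\gamma + \gamma_x X_i + V_i},
#' \eqn{V_i \sim N(0, \sigma_v^2)}, with a latent-index probit outcome
#' \eqn{Y_i = 1\{\beta_0 + \beta_T T_i + \beta_x X_i + U_i \ge 0\}},
#' where \eqn{(V_i, U_i)} are bivariate normal with correlation
#' \eqn{\rho_{uv}} and \eqn{U_i} has unit variance.  `beta_t` is directly
#' comparable to the generating latent-scale effect when the model is
#' correctly specified.
#'
#' @param gamma0 Exposure-equation intercept.
#' @param gamma Instrument slopes (length = number of analysis instruments).
#' @param gamma_x Optional exposure-equation covariate slope.
#' @param sigma_v Exposure error standard deviation (> 0).
#' @param beta0 Latent outcome intercept.
#' @param beta_t Latent outcome exposure coefficient.
#' @param beta_x Optional latent outcome covariate coefficient.
#' @param rho_uv Correlation of the structural errors, in (-1, 1).
#' @return An object of class `liml_params`.
#' @export
liml_params <- function(gamma0, gamma, gamma_x = NULL, sigma_v,
                        beta0, beta_t, beta_x = NULL, rho_uv) {
  if (!is.numeric(sigma_v) || sigma_v <= 0)
    stop("'sigma_v' must be > 0", call. = FALSE)
  if (!is.numeric(rho_uv) || abs(rho_uv) >= 1)
    stop("'rho_uv' must lie in (-1, 1)", call. = FALSE)
  if (is.null(gamma_x) != is.null(beta_x))
    stop("supply both 'gamma_x' and 'beta_x' or neither", call. = FALSE)
  structure(list(gamma0 = gamma0, gamma = gamma, gamma_x = gamma_x,
                 sigma_v = sigma_v, beta0 = beta0, beta_t = beta_t,
                 beta_x = beta_x, rho_uv = rho_uv),
            class = "liml_params")
}

#' Joint log-likelihood of exposure and outcome
#'
#' Evaluates
#' \deqn{\sum_i \log\phi\!\left(\frac{T_i-\mu_i}{\sigma_v}\right) - \log\sigma_v
#'   + Y_i\log\Phi(m_i) + (1-Y_i)\log(1-\Phi(m_i)),}
#' where \eqn{\mu_i = \gamma_0 + Z_i\gamma + \gamma_x X_i} and
#' \eqn{m_i = (\beta_0 + \beta_T T_i + \beta_x X_i +
#' \rho (T_i-\mu_i)/\sigma_v)/\sqrt{1-\rho^2}}.  Tail log-probabilities use
#' `pnorm(..., log.p = TRUE)` for numerical stability.  With \eqn{\rho = 0}
#' the likelihood separates exactly into a normal linear regression plus a
#' plain probit.
#'
#' @param params A [liml_params()] object.
#' @param T,Y Exposure and binary outcome vectors.
#' @param Z_sel n x p matrix of analysis instruments.
#' @param X Optional covariate vector.
#' @param include_x Whether the covariate enters both equations (default:
#'   inferred from `params`).
#' @return The scalar log-likelihood.
#' @export
liml_loglik <- function(params, T, Y, Z_sel, X = NULL,
                        include_x = !is.null(params$gamma_x)) {
  stopifnot(inherits(params, "liml_params"))
  Z_sel <- as.matrix(Z_sel)
  storage.mode(Z_sel) <- "double"
  stopifnot(length(T) == length(Y), nrow(Z_sel) == length(T),
            ncol(Z_sel) == length(params$gamma))
  if (include_x && (is.null(X) || is.null(params$gamma_x)))
    stop("covariate requested but 'X' or covariate coefficients missing",
         call. = FALSE)
  mu <- params$gamma0 + drop(Z_sel %*% params$gamma) +
    if (include_x) params$gamma_x * X else 0
  eta <- params$beta0 + params$beta_t * T +
    if (include_x) params$beta_x * X else 0
  .liml_loglik_core(T, Y, mu, eta, params$sigma_v, params$rho_uv)
}

.liml_loglik_core <- function(T, Y, mu, eta, sigma_v, rho) {
  e <- (T - mu) / sigma_v
  m <- (eta + rho * e) / sqrt(1 - rho^2)
  sum(stats::dnorm(e, log = TRUE)) - length(T) * log(sigma_v) +
    sum(Y * stats::pnorm(m, log.p = TRUE) +
        (1 - Y) * stats::pnorm(m, lower.tail = FALSE, log.p = TRUE))
}

# Objective/gradient over the unconstrained parameter vector
# theta = c(beta0, beta_t, [beta_x], gamma0, gamma_1..p, [gamma_x],
#           log sigma_v, atanh rho).
# D_out = (1, T, X?), D_exp = (1, Z_sel, X?).  Returns negative log-likelihood
# (and its gradient) for optim.
.liml_unpack <- function(theta, p, include_x) {
  nb <- 2L + include_x
  ng <- 1L + p + include_x
  list(beta = theta[seq_len(nb)],
       gamma = theta[nb + seq_len(ng)],
       sigma_v = exp(theta[nb + ng + 1L]),
       rho = tanh(theta[nb + ng + 2L]))
}

# Negative mean log-likelihood (scaled by 1/n so gradients are O(1) and the
# BFGS line search behaves across cohort sizes).
.liml_negloglik <- function(theta, D_out, D_exp, T, Y) {
  p <- ncol(D_exp) - 1L - (ncol(D_out) == 3L)
  include_x <- ncol(D_out) == 3L
  pp <- .liml_unpack(theta, p, include_x)
  mu <- drop(D_exp %*% pp$gamma)
  eta <- drop(D_out %*% pp$beta)
  -.liml_loglik_core(T, Y, mu, eta, pp$sigma_v, pp$rho) / length(T)
}

.liml_neggrad <- function(theta, D_out, D_exp, T, Y) {
  include_x <- ncol(D_out) == 3L
  p <- ncol(D_exp) - 1L - include_x
  pp <- .liml_unpack(theta, p, include_x)
  s <- pp$sigma_v; r <- pp$rho; cc <- sqrt(1 - r^2)
  mu <- drop(D_exp %*% pp$gamma)
  eta <- drop(D_out %*% pp$beta)
  e <- (T - mu) / s
  m <- (eta + r * e) / cc
  # probit score dlogL/dm, computed on the log scale for tail stability
  lam1 <- exp(stats::dnorm(m, log = TRUE) - stats::pnorm(m, log.p = TRUE))
  lam0 <- exp(stats::dnorm(m, log = TRUE) -
              stats::pnorm(m, lower.tail = FALSE, log.p = TRUE))
  g <- ifelse(Y == 1, lam1, -lam0)
  grad_beta <- drop(crossprod(D_out, g)) / cc
  grad_gamma <- drop(crossprod(D_exp, e / s - g * (r / (s * cc))))
  grad_s <- sum(-1 / s + e^2 / s) - sum(g * (r * e / (s * cc)))
  grad_r <- sum(g * ((e / cc) + m * r / (1 - r^2)))
  # chain rule to the unconstrained scale
  -c(grad_beta, grad_gamma, grad_s * s, grad_r * (1 - r^2)) / length(T)
}

#' Fit LIML by maximizing the joint likelihood
#'
#' One-step maximum likelihood over all exposure- and outcome-equation
#' coefficients plus \eqn{(\sigma_v, \rho)}, on the unconstrained
#' reparameterization \eqn{(\log\sigma_v, \mathrm{atanh}\,\rho)} with analytic
#' gradients and BFGS.  The default start combines the first-stage OLS fit
#' (exposure equation) with a 2SRI probit fit rescaled by
#' \eqn{\sqrt{1-\tilde\rho^2}} (outcome equation), \eqn{\tilde\rho} recovered
#' from the 2SRI residual coefficient; this is cheap, consistent under correct
#' specification, and keeps the optimizer away from the \eqn{|\rho| = 1}
#' boundary.  On optimizer failure one restart from a deterministically
#' perturbed start is attempted; the best found parameters are always
#' returned with `converged = FALSE` if both attempts fail.
#'
#' @param T,Y Exposure and binary outcome vectors.
#' @param Z_sel n x p matrix of analysis instruments.
#' @param X Optional covariate vector.
#' @param include_x Include the covariate in both equations.
#' @param init Optional [liml_params()] starting point.
#' @param reltol Relative convergence tolerance passed to [stats::optim()]
#'   (default `1e-8`).
#' @param maxit Maximum BFGS iterations per attempt.
#' @return An `iv_estimate` record with method `"LIML"`; `aux` carries
#'   `rho`, `sigma_v`, the achieved `loglik`, and a `boundary` flag set when
#'   \eqn{|\hat\rho| > 0.99}.
#' @export
fit_liml <- function(T, Y, Z_sel, X = NULL, include_x = !is.null(X),
                     init = NULL, reltol = 1e-8, maxit = 500L) {
  Z_sel <- as.matrix(Z_sel)
  storage.mode(Z_sel) <- "double"
  n <- length(T)
  stopifnot(length(Y) == n, nrow(Z_sel) == n, all(Y %in% c(0, 1)))
  if (include_x && is.null(X))
    stop("include_x = TRUE but no covariate supplied", call. = FALSE)
  p <- ncol(Z_sel)

  # Optimize on internally standardized data (centred instruments, unit-scale
  # exposure and covariate): same likelihood up to a constant, far better
  # conditioned for BFGS.  Estimates are mapped back exactly afterwards.
  mT <- mean(T); sT <- stats::sd(T)
  if (!is.finite(sT) || sT <= 0) sT <- 1
  zbar <- colMeans(Z_sel)
  Zc <- sweep(Z_sel, 2L, zbar)
  Ts <- (T - mT) / sT
  if (include_x) {
    mX <- mean(X); sX <- stats::sd(X)
    Xs <- (X - mX) / sX
  } else Xs <- NULL
  D_exp <- cbind(1, Zc, if (include_x) Xs)
  D_out <- cbind(1, Ts, if (include_x) Xs)

  if (is.null(init)) {
    fs <- fit_first_stage(Ts, Zc, Xs, include_x)
    sigma0 <- sqrt(sum(fs$residuals^2) / (n - length(fs$coefficients)))
    sri <- fit_2sri(Y, Ts, fs, Xs, include_x, link = "probit")
    cres <- sri$aux$residual_coef
    if (!is.finite(cres)) cres <- 0
    d <- cres * sigma0
    rho0 <- max(min(d / sqrt(1 + d^2), 0.95), -0.95)
    shrink <- sqrt(1 - rho0^2)
    beta0v <- c(sri$intercept, sri$beta_t,
                if (include_x) sri$covariate_coef) * shrink
    gamma0v <- fs$coefficients
    theta0 <- c(beta0v, gamma0v, log(sigma0), atanh(rho0))
  } else {
    stopifnot(inherits(init, "liml_params"), length(init$gamma) == p)
    # map a user start (original scale) into the standardized coordinates
    bx_s <- if (include_x) init$beta_x * sX
    gx_s <- if (include_x) init$gamma_x * sX / sT
    b0_s <- init$beta0 + init$beta_t * mT +
      (if (include_x) init$beta_x * mX else 0)
    g0_s <- (init$gamma0 + sum(init$gamma * zbar) +
               (if (include_x) init$gamma_x * mX else 0) - mT) / sT
    theta0 <- c(b0_s, init$beta_t * sT, bx_s,
                g0_s, init$gamma / sT, gx_s,
                log(init$sigma_v / sT), atanh(init$rho_uv))
  }

  run <- function(th0) {
    stats::optim(th0, .liml_negloglik, .liml_neggrad,
                 D_out = D_out, D_exp = D_exp, T = Ts, Y = Y,
                 method = "BFGS",
                 control = list(maxit = maxit, reltol = reltol))
  }
  opt <- run(theta0)
  if (opt$convergence != 0) {
    bump <- 1e-2 * (1 + abs(theta0)) * rep_len(c(1, -1), length(theta0))
    opt2 <- run(theta0 + bump)
    if (opt2$value < opt$value) opt <- opt2
  }
  pp <- .liml_unpack(opt$par, p, include_x)
  converged <- opt$convergence == 0

  # back-transform to the original scale
  beta_t <- pp$beta[2L] / sT
  beta_x <- if (include_x) pp$beta[3L] / sX
  beta0 <- pp$beta[1L] - beta_t * mT - (if (include_x) beta_x * mX else 0)
  gamma <- pp$gamma[2:(p + 1L)] * sT
  gamma_x <- if (include_x) pp$gamma[p + 2L] * sT / sX
  gamma0 <- mT + sT * pp$gamma[1L] - sum(gamma * zbar) -
    (if (include_x) gamma_x * mX else 0)
  sigma_v <- pp$sigma_v * sT
  loglik <- -opt$value * n - n * log(sT)

  estimate_record("LIML",
                  beta_t = beta_t,
                  intercept = beta0,
                  covariate_coef = beta_x,
                  aux = list(rho = pp$rho, sigma_v = sigma_v,
                             loglik = loglik,
                             gamma0 = gamma0, gamma = gamma,
                             gamma_x = gamma_x,
                             boundary = abs(pp$rho) > 0.99,
                             optim_convergence = opt$convergence),
                  converged = converged, n_used = n)
}
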