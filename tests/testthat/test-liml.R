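test_that("liml_params validates the variance and correlation domains", {
  expect_error(liml_params(0, rep(0, 3), NULL, sigma_v = -1,
                           beta0 = 0, beta_t = 0, rho_uv = 0), "sigma_v")
  expect_error(liml_params(0, rep(0, 3), NULL, sigma_v = 1,
                           beta0 = 0, beta_t = 0, rho_uv = 1.5), "rho_uv")
  expect_error(liml_params(0, rep(0, 3), gamma_x = 0.1, sigma_v = 1,
                           beta0 = 0, beta_t = 0, beta_x = NULL, rho_uv = 0),
               "both")
})

test_that("rho = 0 separates the likelihood into linear-normal + probit parts", {
  set.seed(301)
  w <- liml_world(200, p = 4)
  par <- liml_params(gamma0 = 19, gamma = runif(4, 0, 0.1), gamma_x = 0.2,
                     sigma_v = 1.3, beta0 = -7, beta_t = 0.12, beta_x = 0.04,
                     rho_uv = 0)
  ll <- liml_loglik(par, w$T, w$Y, w$Z, w$X)
  mu <- par$gamma0 + drop(w$Z %*% par$gamma) + par$gamma_x * w$X
  eta <- par$beta0 + par$beta_t * w$T + par$beta_x * w$X
  ll_lin <- sum(dnorm(w$T, mu, par$sigma_v, log = TRUE))
  ll_probit <- sum(w$Y * pnorm(eta, log.p = TRUE) +
                     (1 - w$Y) * pnorm(-eta, log.p = TRUE))
  expect_equal(ll, ll_lin + ll_probit, tolerance = 1e-10)
})

test_that("all-zero coefficients give the symmetric-probit hand value", {
  # 3 subjects, all coefficients 0, sigma_v = 1:
  # logL = sum log phi(T_i) + 3 log(0.5)
  T <- c(-0.3, 0.1, 0.7); Y <- c(0L, 1L, 1L)
  Z <- matrix(0, 3, 2)
  par <- liml_params(gamma0 = 0, gamma = c(0, 0), sigma_v = 1,
                     beta0 = 0, beta_t = 0, rho_uv = 0)
  expect_equal(liml_loglik(par, T, Y, Z),
               sum(dnorm(T, log = TRUE)) + 3 * log(0.5), tolerance = 1e-12)
})

test_that("log-likelihood matches a direct per-subject summation oracle", {
  set.seed(311)
  w <- liml_world(20, p = 3)
  par <- liml_params(gamma0 = rnorm(1, 20), gamma = rnorm(3, 0, 0.1),
                     gamma_x = rnorm(1, 0.2, 0.05), sigma_v = runif(1, 0.5, 2),
                     beta0 = rnorm(1, -7), beta_t = rnorm(1, 0.1, 0.05),
                     beta_x = rnorm(1, 0.05, 0.02), rho_uv = runif(1, -0.9, 0.9))
  # brute-force oracle: scalar density/cdf calls subject by subject
  oracle <- 0
  for (i in 1:20) {
    mu_i <- par$gamma0 + sum(w$Z[i, ] * par$gamma) + par$gamma_x * w$X[i]
    m_i <- (par$beta0 + par$beta_t * w$T[i] + par$beta_x * w$X[i] +
              par$rho_uv * (w$T[i] - mu_i) / par$sigma_v) /
      sqrt(1 - par$rho_uv^2)
    oracle <- oracle + log(dnorm((w$T[i] - mu_i) / par$sigma_v)) -
      log(par$sigma_v) +
      if (w$Y[i] == 1) log(pnorm(m_i)) else log(1 - pnorm(m_i))
  }
  expect_equal(liml_loglik(par, w$T, w$Y, w$Z, w$X), oracle,
               tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(321)
  w <- liml_world(300, p = 4)
  D_out <- cbind(1, w$T, w$X)
  D_exp <- cbind(1, w$Z, w$X)
  theta <- c(-6.5, 0.09, 0.05, 19, runif(4, 0, 0.1), 0.2, log(1.2), atanh(0.4))
  g <- ivbin:::.liml_neggrad(theta, D_out, D_exp, w$T, w$Y)
  h <- 1e-6
  gnum <- vapply(seq_along(theta), function(j) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (ivbin:::.liml_negloglik(tp, D_out, D_exp, w$T, w$Y) -
       ivbin:::.liml_negloglik(tm, D_out, D_exp, w$T, w$Y)) / (2 * h)
  }, numeric(1))
  expect_equal(g, gnum, tolerance = 1e-4)
})

test_that("likelihood is invariant to instrument column order", {
  set.seed(331)
  w <- liml_world(100, p = 5)
  par <- liml_params(gamma0 = 20, gamma = runif(5, 0, 0.1), gamma_x = 0.2,
                     sigma_v = 1, beta0 = -7.5, beta_t = 0.1, beta_x = 0.05,
                     rho_uv = 0.5)
  perm <- c(3, 1, 5, 2, 4)
  par2 <- par; par2$gamma <- par$gamma[perm]
  expect_equal(liml_loglik(par, w$T, w$Y, w$Z, w$X),
               liml_loglik(par2, w$T, w$Y, w$Z[, perm], w$X),
               tolerance = 1e-12)
})

test_that("optimizer improves on its starting point and fits the no-confounding case", {
  set.seed(341)
  # strong instruments so the instrumented direction is well identified in a
  # single run (its sampling SE scales as 1 / sd(Z alpha) / sqrt(n))
  w <- liml_world(20000, p = 20, rho = 0, alpha_mu = 0.15)
  rec <- fit_liml(w$T, w$Y, w$Z, w$X, include_x = TRUE)
  expect_true(rec$converged)
  # no-confounding recovery at ~3 single-run SEs of the instrumented slope
  expect_lt(abs(rec$beta_t - 0.1), 0.13)
  expect_lt(abs(rec$aux$rho), 0.25)
  # monotonicity: achieved log-likelihood beats the 2SRI-derived start
  fs <- fit_first_stage(w$T, w$Z, w$X, include_x = TRUE)
  sri <- fit_2sri(w$Y, w$T, fs, w$X, link = "probit")
  cres <- sri$aux$residual_coef
  sig0 <- sqrt(mean(fs$residuals^2))
  d <- cres * sig0; rho0 <- d / sqrt(1 + d^2)
  start <- liml_params(gamma0 = fs$coefficients[1],
                       gamma = fs$coefficients[2:21],
                       gamma_x = fs$coefficients[22], sigma_v = sig0,
                       beta0 = sri$intercept * sqrt(1 - rho0^2),
                       beta_t = sri$beta_t * sqrt(1 - rho0^2),
                       beta_x = sri$covariate_coef * sqrt(1 - rho0^2),
                       rho_uv = rho0)
  expect_gte(rec$aux$loglik,
             liml_loglik(start, w$T, w$Y, w$Z, w$X) - 1e-6)
})

test_that("fit is invariant to instrument column order", {
  set.seed(351)
  w <- liml_world(5000, p = 10)
  rec1 <- fit_liml(w$T, w$Y, w$Z, w$X, include_x = TRUE)
  perm <- sample(10)
  rec2 <- fit_liml(w$T, w$Y, w$Z[, perm], w$X, include_x = TRUE)
  expect_equal(rec1$beta_t, rec2$beta_t, tolerance = 1e-5)
  expect_equal(rec1$aux$loglik, rec2$aux$loglik, tolerance = 1e-7)
})

test_that("works without a covariate", {
  set.seed(361)
  w <- liml_world(8000, p = 10, rho = 0.5)
  rec <- fit_liml(w$T, w$Y, w$Z, include_x = FALSE)
  expect_true(is.finite(rec$beta_t))
  expect_null(rec$covariate_coef)
})
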