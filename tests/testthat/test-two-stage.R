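test_that("first stage reproduces hand-computed OLS on a toy design", {
  # 4 subjects, 1 instrument: Z = 0,1,1,2; T = 1,2,2,3 -> slope 1, intercept 1
  toy <- toy_iv_data()
  fs <- fit_first_stage(toy$T, cbind(toy$Z))
  expect_equal(unname(fs$coefficients), c(1, 1), tolerance = 1e-12)
  expect_equal(fs$fitted_values + fs$residuals, toy$T, tolerance = 1e-12)
  # perfect fit: zero residuals, R^2 = 1
  expect_equal(fs$residuals, rep(0, 4), tolerance = 1e-12)
  expect_equal(fs$r_squared, 1, tolerance = 1e-12)
})

test_that("first-stage residuals are orthogonal to the design", {
  set.seed(201)
  w <- liml_world(400, p = 10)
  fs <- fit_first_stage(w$T, w$Z, w$X, include_x = TRUE)
  D <- cbind(1, w$Z, w$X)
  expect_lt(max(abs(crossprod(D, fs$residuals))), 1e-7)
  expect_equal(fs$fitted_values + fs$residuals, w$T, tolerance = 1e-10)
})

test_that("first stage rejects rank-deficient designs, naming the columns", {
  set.seed(211)
  Z <- cbind(A = rnorm(100), B = rnorm(100))
  Z <- cbind(Z, C = Z[, 1] + Z[, 2])
  expect_error(fit_first_stage(rnorm(100), Z), "C")
})

test_that("2SLS equals the closed-form instrumental-variable estimator", {
  set.seed(221)
  w <- liml_world(2000, p = 10)
  fs <- fit_first_stage(w$T, w$Z, w$X, include_x = TRUE)
  rec <- fit_2sls(w$Y, fs, w$X)
  # oracle: (W'D)^{-1} W'Y with W = (1, That, X), D = (1, T, X)
  W <- cbind(1, fs$fitted_values, w$X)
  D <- cbind(1, w$T, w$X)
  bet <- solve(crossprod(W, D), crossprod(W, w$Y))
  expect_equal(rec$beta_t, bet[2], tolerance = 1e-8)
})

test_that("just-identified 2SLS equals the Wald ratio", {
  set.seed(231)
  z <- rbinom(300, 2, 0.4)
  T <- 1 + 0.5 * z + rnorm(300)
  Y <- rbinom(300, 1, 0.2 + 0.1 * T / max(T))
  fs <- fit_first_stage(T, cbind(z))
  rec <- fit_2sls(Y, fs)
  expect_equal(rec$beta_t, cov(z, Y) / cov(z, T), tolerance = 1e-10)
})

test_that("noiseless linear outcome is recovered exactly by 2SLS", {
  # fitted exposure takes values {1, 3}; Y = -0.5 + 0.5 * fitted is binary
  # and exactly linear, so the second stage must return slope 0.5.
  fs <- fit_first_stage(c(1, 1, 3, 3), cbind(c(0, 0, 1, 1)))
  Y <- round(-0.5 + 0.5 * fs$fitted_values)  # exact up to float residue
  expect_true(all(Y %in% c(0, 1)))
  rec <- fit_2sls(Y, fs)
  expect_equal(rec$beta_t, 0.5, tolerance = 1e-8)
  expect_equal(rec$intercept, -0.5, tolerance = 1e-8)
})

test_that("identity-link predictor substitution reproduces 2SLS", {
  set.seed(241)
  w <- liml_world(1500, p = 8)
  fs <- fit_first_stage(w$T, w$Z, w$X, include_x = TRUE)
  a <- fit_2sls(w$Y, fs, w$X)
  b <- fit_2sps(w$Y, fs, w$X, link = "identity")
  expect_equal(a$beta_t, b$beta_t, tolerance = 1e-12)
  expect_equal(a$intercept, b$intercept, tolerance = 1e-12)
})

test_that("probit second stage matches a direct maximum-likelihood oracle", {
  set.seed(251)
  w <- liml_world(800, p = 5)
  fs <- fit_first_stage(w$T, w$Z, w$X, include_x = TRUE)
  rec <- fit_2sps(w$Y, fs, w$X, link = "probit")
  # independent oracle: Newton-Raphson on the probit log-likelihood with
  # analytic score and Fisher information, run to machine precision
  D <- cbind(1, fs$fitted_values, w$X)
  bb <- c(qnorm(mean(w$Y)), 0, 0)
  for (i in 1:50) {
    eta <- drop(D %*% bb)
    lam1 <- exp(dnorm(eta, log = TRUE) - pnorm(eta, log.p = TRUE))
    lam0 <- exp(dnorm(eta, log = TRUE) -
                  pnorm(eta, lower.tail = FALSE, log.p = TRUE))
    score <- drop(crossprod(D, ifelse(w$Y == 1, lam1, -lam0)))
    wgt <- lam1 * lam0
    H <- crossprod(D * sqrt(wgt))
    step <- solve(H, score)
    bb <- bb + step
    if (max(abs(step)) < 1e-12) break
  }
  expect_equal(rec$beta_t, bb[2], tolerance = 1e-6)
  expect_equal(rec$intercept, bb[1], tolerance = 1e-5)
})

test_that("degenerate control function reduces 2SRI to an ordinary GLM", {
  toy <- toy_iv_data()
  fs <- fit_first_stage(toy$T, cbind(toy$Z))  # perfect fit: residuals 0
  set.seed(261)
  w <- liml_world(1000, p = 5)
  fs0 <- fit_first_stage(w$T, w$Z, w$X, include_x = TRUE)
  fs0$residuals <- rep(0, length(w$T))
  rec <- fit_2sri(w$Y, w$T, fs0, w$X, link = "probit")
  ref <- glm(w$Y ~ w$T + w$X, family = binomial("probit"))
  expect_true(rec$aux$residual_dropped)
  expect_equal(rec$beta_t, unname(coef(ref)[2]), tolerance = 1e-6)
})

test_that("2SRI stores the residual (control-function) coefficient", {
  set.seed(271)
  w <- liml_world(5000, p = 10, rho = 0.5)
  fs <- fit_first_stage(w$T, w$Z, w$X, include_x = TRUE)
  rec <- fit_2sri(w$Y, w$T, fs, w$X, link = "probit")
  expect_true(is.finite(rec$aux$residual_coef))
  # positive confounding -> positive residual coefficient
  expect_gt(rec$aux$residual_coef, 0)
  ref <- glm(w$Y ~ w$T + fs$residuals + w$X, family = binomial("probit"))
  expect_equal(rec$beta_t, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(rec$aux$residual_coef, unname(coef(ref)[3]), tolerance = 1e-6)
})

test_that("probit two-stage estimators recover the effect without confounding", {
  # rho = 0: no unmeasured confounding, both 2SPS_PR and 2SRI_PR consistent
  set.seed(281)
  R <- 10
  est <- matrix(NA_real_, R, 2)
  for (r in 1:R) {
    w <- liml_world(20000, p = 20, rho = 0)
    fs <- fit_first_stage(w$T, w$Z, w$X, include_x = TRUE)
    est[r, 1] <- fit_2sps(w$Y, fs, w$X, link = "probit")$beta_t
    est[r, 2] <- fit_2sri(w$Y, w$T, fs, w$X, link = "probit")$beta_t
  }
  for (j in 1:2)
    expect_lt(abs(mean(est[, j]) - 0.1), 3 * sd(est[, j]) / sqrt(R))
})

test_that("log-link fallback is flagged, not fatal", {
  set.seed(291)
  w <- liml_world(3000, p = 5)
  fs <- fit_first_stage(w$T, w$Z, w$X, include_x = TRUE)
  rec <- fit_2sps(w$Y, fs, w$X, link = "log")
  expect_true(is.finite(rec$beta_t))
  if (!rec$converged) expect_identical(rec$aux$fallback, "poisson")
})
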