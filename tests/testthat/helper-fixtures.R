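# Shared fixtures, all generated in code at test time.

# Small-but-valid cohort parameters: enough instruments for both analysis
# sets (>= 75 columns) but desk-sized n.
small_params <- function(n = 2000, K = 80, rho = 0.5, family = "gaussian",
                         margin_scale_v = 1, ...) {
  dgm_params(n = n, K = K, n_strong = 25,
             copula = copula_spec(family, rho,
                                  margin_scale_v = margin_scale_v, ...))
}

# A correctly-specified LIML world: the exposure depends on exactly the
# p instruments handed to the estimators, so (beta_t, rho, sigma_v) are
# recoverable.  Returns the cohort pieces the fitters need.
liml_world <- function(n, p = 50, rho = 0.5, sigma_v = 1, beta_t = 0.1,
                       alpha_mu = 0.02, alpha_sigma = 0.07) {
  q <- runif(p, 0.1, 0.9)
  Z <- matrix(rbinom(n * p, 2L, rep(q, each = n)), n, p)
  storage.mode(Z) <- "double"
  alpha <- abs(rnorm(p, alpha_mu, alpha_sigma))
  X <- rnorm(n, 55, 7)
  vu <- sample_confounders(n, copula_spec("gaussian", rho,
                                          margin_scale_v = sigma_v))
  T <- 20 + drop(Z %*% alpha) + 0.2 * X + vu[, 1]
  Y <- as.integer(-7.5 + beta_t * T + 0.05 * X + vu[, 2] >= 0)
  list(Z = Z, X = X, T = T, Y = Y, alpha = alpha)
}

# Tiny deterministic design for closed-form regression checks.
toy_iv_data <- function() {
  list(Z = c(0, 1, 1, 2), T = c(1, 2, 2, 3), Y = c(0, 0, 1, 1))
}
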