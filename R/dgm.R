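#' Parameters of the cohort data-generating mechanism
#'
#' Describes the generative model for one simulated cohort in the
#' many-instrument setting: `K` genetic instruments \eqn{Z_k \sim
#' \mathrm{Bin}(2, q_k)} with \eqn{q_k \sim U(q_{low}, q_{high})}, folded-normal
#' instrument effects (a strong block and a weak block), a normal covariate
#' \eqn{X} (age), copula-coupled unmeasured confounders \eqn{(V, U)}, a linear
#' exposure model
#' \deqn{T = b_0 + \sum_k Z_k \alpha_k + b_x X + V}
#' and a probit-threshold binary outcome
#' \deqn{Y = 1\{c_0 + \beta_T T + c_x X + U \ge 0\}.}
#'
#' With the defaults the exposure plays the role of BMI, the outcome of
#' incident diabetes, and the instruments of SNPs: n = 100,000 subjects,
#' 500 instruments of which 25 are strong
#' (\eqn{\alpha_k \sim |N(0.02, 0.07^2)|}) and 475 weak
#' (\eqn{\alpha_k \sim |N(0.001, 0.01^2)|}), age \eqn{X \sim N(55, 7^2)},
#' exposure intercept 20 with age coefficient 0.2, outcome index
#' \eqn{-7.5 + 0.1\,T + 0.05\,X + U}, giving an event rate of roughly 15%.
#' `beta_t_true = 0.1` is the latent-probit-scale estimand that every
#' estimator targets.
#'
#' @param n Cohort size.
#' @param K Number of instruments.
#' @param n_strong Number of strong instruments (the first `n_strong` columns).
#' @param q_low,q_high Allele-frequency bounds for \eqn{q_k}.
#' @param strong_mu,strong_sigma Folded-normal hyper-parameters of the strong
#'   instrument effects.
#' @param weak_mu,weak_sigma Folded-normal hyper-parameters of the weak
#'   instrument effects.
#' @param exposure_intercept,covariate_coef_exposure Exposure-model intercept
#'   and age coefficient.
#' @param covariate_mean,covariate_sd Age distribution parameters.
#' @param outcome_intercept,beta_t_true,covariate_coef_outcome Latent outcome
#'   index coefficients.
#' @param copula A [copula_spec()] for the unmeasured confounders.
#' @return An object of class `dgm_params`.
#' @export
dgm_params <- function(n = 100000L, K = 500L, n_strong = 25L,
                       q_low = 0.1, q_high = 0.9,
                       strong_mu = 0.02, strong_sigma = 0.07,
                       weak_mu = 0.001, weak_sigma = 0.01,
                       exposure_intercept = 20,
                       covariate_coef_exposure = 0.2,
                       covariate_mean = 55, covariate_sd = 7,
                       outcome_intercept = -7.5,
                       beta_t_true = 0.1,
                       covariate_coef_outcome = 0.05,
                       copula = copula_spec("gaussian", 0.5)) {
  stopifnot(n >= 1, K >= 1, n_strong >= 0, n_strong < K,
            q_low > 0, q_low < q_high, q_high < 1,
            strong_sigma > 0, weak_sigma > 0, covariate_sd > 0)
  if (!inherits(copula, "copula_spec"))
    stop("'copula' must be a copula_spec object", call. = FALSE)
  structure(list(
    n = as.integer(n), K = as.integer(K), n_strong = as.integer(n_strong),
    q_low = q_low, q_high = q_high,
    strong_mu = strong_mu, strong_sigma = strong_sigma,
    weak_mu = weak_mu, weak_sigma = weak_sigma,
    exposure_intercept = exposure_intercept,
    covariate_coef_exposure = covariate_coef_exposure,
    covariate_mean = covariate_mean, covariate_sd = covariate_sd,
    outcome_intercept = outcome_intercept,
    beta_t_true = beta_t_true,
    covariate_coef_outcome = covariate_coef_outcome,
    copula = copula), class = "dgm_params")
}

#' Draw the instrument matrix and allele frequencies
#'
#' \eqn{q_k \sim U(q_{low}, q_{high})} i.i.d., then \eqn{Z_{ik} \sim
#' \mathrm{Bin}(2, q_k)} independently across subjects and instruments.
#' Genotypes are sampled column-wise by inverting the three-point
#' \eqn{\mathrm{Bin}(2, q)} cdf on a single uniform per subject, and stored as
#' an integer matrix (half the memory of a double matrix at 100,000 x 500).
#'
#' @param params A [dgm_params()] object.
#' @param q Optional fixed allele-frequency vector (length `K`), used when
#'   freezing the genetic architecture across Monte-Carlo iterations.
#' @return A list with `Z` (n x K integer matrix, entries 0/1/2) and `q`.
#' @export
draw_instruments <- function(params, q = NULL) {
  stopifnot(inherits(params, "dgm_params"))
  n <- params$n; K <- params$K
  if (is.null(q)) q <- stats::runif(K, params$q_low, params$q_high)
  stopifnot(length(q) == K, all(q > 0 & q < 1))
  Z <- matrix(0L, n, K)
  for (k in seq_len(K)) {
    p0 <- (1 - q[k])^2               # P(Z = 0)
    p01 <- p0 + 2 * q[k] * (1 - q[k])  # P(Z <= 1)
    u <- stats::runif(n)
    Z[, k] <- (u > p0) + (u > p01)
  }
  list(Z = Z, q = q)
}

#' Draw instrument effect sizes
#'
#' The first `n_strong` effects are \eqn{|N(\mu_s, \sigma_s^2)|} draws and the
#' remaining `K - n_strong` are \eqn{|N(\mu_w, \sigma_w^2)|} draws, so all
#' effects are non-negative and the strong block dominates the
#' instrument-exposure signal.
#'
#' @param params A [dgm_params()] object.
#' @return Numeric vector of length `K` (strong block first).
#' @export
draw_effect_sizes <- function(params) {
  stopifnot(inherits(params, "dgm_params"))
  c(abs(stats::rnorm(params$n_strong, params$strong_mu, params$strong_sigma)),
    abs(stats::rnorm(params$K - params$n_strong, params$weak_mu,
                     params$weak_sigma)))
}

#' Mean of a folded-normal distribution
#'
#' \eqn{E|N(\mu, \sigma^2)| = \sigma\sqrt{2/\pi}\,e^{-\mu^2/2\sigma^2} +
#' \mu(1 - 2\Phi(-\mu/\sigma))}; used as a closed-form oracle for the expected
#' instrument dose and hence the expected exposure.
#'
#' @param mu,sigma Parameters of the underlying normal.
#' @return The expectation of the absolute value.
#' @export
folded_normal_mean <- function(mu, sigma) {
  sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sigma))
}

#' Generate one simulated cohort
#'
#' Draws, in fixed order, the allele frequencies, the effect sizes, the
#' genotypes, the covariate, and the confounder pair, then computes the
#' exposure and outcome from the structural equations (see [dgm_params()]).
#' Seed the R stream before calling for reproducibility.  Genotypes and the
#' allele dose \eqn{\sum_k Z_{ik}\alpha_k} are produced in one fused compiled
#' pass over the R random stream (one uniform per genotype, column by
#' column), so the 100,000 x 500 integer matrix is never coerced to double.
#'
#' @param params A [dgm_params()] object.
#' @param q,alpha Optional fixed allele frequencies / effect sizes (both or
#'   neither), for runs that freeze the genetic architecture across
#'   iterations.
#' @return An object of class `iv_cohort`: a list with `Z`, `q`, `alpha`,
#'   `X`, `V`, `U`, `T`, `Y`, and the generating `params`.
#' @examples
#' set.seed(7)
#' co <- generate_cohort(dgm_params(n = 2000, K = 80, n_strong = 10))
#' mean(co$Y)
#' @export
generate_cohort <- function(params, q = NULL, alpha = NULL) {
  stopifnot(inherits(params, "dgm_params"))
  if (is.null(q)) q <- stats::runif(params$K, params$q_low, params$q_high)
  if (is.null(alpha)) alpha <- draw_effect_sizes(params)
  stopifnot(length(q) == params$K, all(q > 0 & q < 1),
            length(alpha) == params$K)
  zd <- .draw_genotypes_dose(params$n, q, alpha)
  X <- stats::rnorm(params$n, params$covariate_mean, params$covariate_sd)
  VU <- sample_confounders(params$n, params$copula)
  TT <- params$exposure_intercept + zd$dose +
    params$covariate_coef_exposure * X + VU[, 1]
  idx <- params$outcome_intercept + params$beta_t_true * TT +
    params$covariate_coef_outcome * X + VU[, 2]
  Y <- as.integer(idx >= 0)
  structure(list(Z = zd$Z, q = q, alpha = alpha, X = X,
                 V = VU[, 1], U = VU[, 2], T = TT, Y = Y, params = params),
            class = "iv_cohort")
}

#' @export
print.iv_cohort <- function(x, ...) {
  cat(sprintf("<iv_cohort> n=%d K=%d prevalence=%.3f mean(T)=%.2f sd(T)=%.2f\n",
              length(x$Y), ncol(x$Z), mean(x$Y), mean(x$T), stats::sd(x$T)))
  invisible(x)
}

#' Select the instrument columns used for estimation
#'
#' The estimation models deliberately use only 50 of the generated
#' instruments, so the fitted exposure model always differs from the true
#' structural equation.  `"mixed"` uses the 25 strong instruments plus the
#' first 25 weak ones (columns 1–50); `"weak_only"` uses the first 50 weak
#' instruments (columns 26–75).  Effect sizes are i.i.d. within each block, so
#' any fixed subset is statistically equivalent; fixing by index keeps runs
#' reproducible.
#'
#' @param cohort An `iv_cohort` (needs at least 75 instrument columns).
#' @param iv_set `"mixed"` or `"weak_only"`.
#' @return Integer vector of 50 column indices.
#' @export
select_analysis_instruments <- function(cohort, iv_set = c("mixed", "weak_only")) {
  iv_set <- match.arg(iv_set)
  stopifnot(inherits(cohort, "iv_cohort"))
  if (ncol(cohort$Z) < 75L)
    stop("cohort must carry at least 75 instruments", call. = FALSE)
  switch(iv_set, mixed = 1:50, weak_only = 26:75)
}

#' Write a cohort to a delimited text file
#'
#' One row per subject with header `Z1..ZK, X, T, Y` (plus `V` and `U` when
#' `include_confounders = TRUE`, e.g. for oracle checks).
#'
#' @param cohort An `iv_cohort`.
#' @param path Output file path.
#' @param include_confounders Also write the latent `V`, `U` columns.
#' @param sep Field separator (default tab).
#' @export
write_cohort <- function(cohort, path, include_confounders = FALSE, sep = "\t") {
  stopifnot(inherits(cohort, "iv_cohort"))
  df <- as.data.frame(cohort$Z)
  names(df) <- paste0("Z", seq_len(ncol(cohort$Z)))
  df$X <- cohort$X; df$T <- cohort$T; df$Y <- cohort$Y
  if (include_confounders) { df$V <- cohort$V; df$U <- cohort$U }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a delimited cohort file written by [write_cohort()]
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return A list with `Z` (integer matrix), `X`, `T`, `Y`, and `V`, `U` when
#'   present in the file.
#' @export
read_cohort <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  zcols <- grep("^Z[0-9]+$", names(df))
  Z <- unname(as.matrix(df[zcols]))
  storage.mode(Z) <- "integer"
  out <- list(Z = Z, X = df$X, T = df$T, Y = as.integer(df$Y))
  if (!is.null(df$V)) out$V <- df$V
  if (!is.null(df$U)) out$U <- df$U
  out
}
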