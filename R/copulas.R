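#' Specify a bivariate dependence family for the unmeasured confounders
#'
#' The simulated cohorts carry a pair of unmeasured confounders \eqn{(V, U)}:
#' \eqn{V} enters the exposure equation and \eqn{U} the latent outcome index.
#' Their joint distribution is built from a copula so that the margins and the
#' dependence structure can be varied independently.  Five families are
#' supported:
#'
#' * `"gaussian"` — bivariate normal (symmetric, light tails);
#' * `"t_copula"` — t copula with normal margins (symmetric, joint heavy tails);
#' * `"clayton"` — Clayton copula with normal margins (lower-tail asymmetric);
#' * `"gumbel"` — Gumbel copula with normal margins (upper-tail asymmetric);
#' * `"gaussian_copula_t_margins"` — Gaussian copula with Student-t margins
#'   (symmetric dependence, heavy-tailed margins).
#'
#' `rho` is the association level on the Gaussian-correlation scale.  For the
#' non-Gaussian families the copula parameter is calibrated so that Kendall's
#' \eqn{\tau} matches that of a Gaussian copula with correlation `rho`
#' (`calibration = "kendall"`, the default): \eqn{\tau = (2/\pi)\arcsin\rho},
#' Clayton \eqn{\theta = 2\tau/(1-\tau)}, Gumbel \eqn{\theta = 1/(1-\tau)}.
#' Rank-based calibration is margin-free; `calibration = "pearson"` instead
#' root-finds the copula parameter so that the simulated Pearson correlation
#' of the transformed margins equals `rho`.
#'
#' Clayton and Gumbel copulas model positive dependence only, so they accept
#' only `rho > 0`.
#'
#' @param family Dependence family, one of the five listed above.
#' @param rho Signed association level in (-1, 1) on the Gaussian scale.
#' @param df Degrees of freedom for the t components (`t_copula` and
#'   `gaussian_copula_t_margins` only).  Must be at least 3 so that the
#'   margins have finite variance.
#' @param margin_scale_v,margin_scale_u Standard deviations of the \eqn{V}
#'   and \eqn{U} margins (default 1; the probit outcome model assumes a
#'   unit-scale \eqn{U}).
#' @param calibration `"kendall"` (default) or `"pearson"`; see Details.
#' @param standardize_t For `gaussian_copula_t_margins`, rescale the t margins
#'   by \eqn{\sqrt{df/(df-2)}} to unit variance (default `TRUE`) so the
#'   outcome threshold keeps a comparable event rate.
#' @return An object of class `copula_spec`.
#' @seealso [sample_confounders()]
#' @examples
#' spec <- copula_spec("clayton", rho = 0.5)
#' spec$param  # Clayton theta = 1 at Kendall tau = 1/3
#' @export
copula_spec <- function(family = c("gaussian", "t_copula", "clayton", "gumbel",
                                   "gaussian_copula_t_margins"),
                        rho = 0.5, df = 3L,
                        margin_scale_v = 1, margin_scale_u = 1,
                        calibration = c("kendall", "pearson"),
                        standardize_t = TRUE) {
  family <- match.arg(family)
  calibration <- match.arg(calibration)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho <= -1 || rho >= 1)
    stop("'rho' must be a single number in (-1, 1)", call. = FALSE)
  if (family %in% c("clayton", "gumbel") && rho <= 0)
    stop("the ", family, " copula models positive dependence only; ",
         "'rho' must be > 0", call. = FALSE)
  if (family %in% c("t_copula", "gaussian_copula_t_margins")) {
    if (!is.numeric(df) || length(df) != 1L || df < 3)
      stop("'df' must be >= 3 for t components (df <= 2 leaves the margin ",
           "variance undefined or unstandardizable)", call. = FALSE)
  }
  if (margin_scale_v <= 0 || margin_scale_u <= 0)
    stop("margin scales must be > 0", call. = FALSE)

  spec <- structure(
    list(family = family, rho = rho, df = df,
         margin_scale_v = margin_scale_v, margin_scale_u = margin_scale_u,
         calibration = calibration, standardize_t = standardize_t,
         param = NA_real_),
    class = "copula_spec")
  spec$param <- switch(calibration,
                       kendall = .kendall_param(family, rho),
                       pearson = .pearson_param(spec))
  spec
}

#' @export
print.copula_spec <- function(x, ...) {
  cat(sprintf("<copula_spec> family=%s rho=%+.3f param=%.4f", x$family,
              x$rho, x$param))
  if (x$family %in% c("t_copula", "gaussian_copula_t_margins"))
    cat(sprintf(" df=%d", as.integer(x$df)))
  cat(sprintf(" scales=(%.3g, %.3g)\n", x$margin_scale_v, x$margin_scale_u))
  invisible(x)
}

# Copula parameter whose Kendall tau matches a Gaussian copula at rho.
.kendall_param <- function(family, rho) {
  tau <- (2 / pi) * asin(rho)
  switch(family,
         gaussian = rho,
         t_copula = rho,                 # elliptical: same tau-rho relation
         gaussian_copula_t_margins = rho,
         clayton = 2 * tau / (1 - tau),
         gumbel = 1 / (1 - tau))
}

# Root-find the copula parameter so the simulated Pearson correlation of the
# (normal- or t-) margins matches rho.  Uses a private RNG substream so the
# caller's stream is untouched.
.pearson_param <- function(spec, n_cal = 2e5, cal_seed = 191919L) {
  if (spec$family == "gaussian") return(spec$rho)  # exact for normal margins
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  probe <- function(param) {
    s <- spec
    s$param <- param
    set.seed(cal_seed)
    vu <- .sample_copula(n_cal, s)
    stats::cor(vu[, 1], vu[, 2]) - spec$rho
  }
  interval <- switch(spec$family,
                     t_copula = c(-0.999, 0.999),
                     gaussian_copula_t_margins = c(-0.999, 0.999),
                     clayton = c(0.05, 20),
                     gumbel = c(1 + 1e-6, 20))
  stats::uniroot(probe, interval, tol = 1e-3)$root
}

#' Sample pairs of unmeasured confounders
#'
#' Draws `n` pairs \eqn{(V_i, U_i)} from the joint distribution described by a
#' [copula_spec()].  Sampling uses the current R random stream (seed with
#' [set.seed()] for reproducibility) and is independent of any instrument or
#' covariate stream because the cohort generator draws the confounders from
#' their own block of the stream.
#'
#' Samplers are exact (no MCMC): Gaussian pairs via the Cholesky construction,
#' the t copula via a chi-square scale mixture, Clayton via its gamma-frailty
#' (Marshall–Olkin) representation, and Gumbel via the positive-stable frailty
#' representation with Chambers–Mallows–Stuck stable draws.
#'
#' @param n Number of pairs (>= 1).
#' @param spec A [copula_spec()].
#' @return An `n` x 2 numeric matrix with columns `V` and `U`.
#' @examples
#' set.seed(1)
#' vu <- sample_confounders(1000, copula_spec("gaussian", 0.5))
#' cor(vu[, 1], vu[, 2])
#' @export
sample_confounders <- function(n, spec) {
  if (!inherits(spec, "copula_spec"))
    stop("'spec' must be a copula_spec object", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  .sample_copula(as.integer(n), spec)
}

.sample_copula <- function(n, spec) {
  out <- switch(spec$family,
    gaussian = {
      z <- .bvn_pair(n, spec$param)
      cbind(z[, 1], z[, 2])
    },
    t_copula = {
      z <- .bvn_pair(n, spec$param)
      w <- stats::rchisq(n, spec$df)
      tt <- z / sqrt(w / spec$df)          # bivariate t, correlation param
      u <- stats::pt(tt, spec$df)
      cbind(stats::qnorm(u[, 1]), stats::qnorm(u[, 2]))
    },
    clayton = {
      theta <- spec$param
      w <- stats::rgamma(n, shape = 1 / theta, rate = 1)
      e1 <- stats::rexp(n); e2 <- stats::rexp(n)
      u1 <- .clamp01((1 + e1 / w)^(-1 / theta))
      u2 <- .clamp01((1 + e2 / w)^(-1 / theta))
      cbind(stats::qnorm(u1), stats::qnorm(u2))
    },
    gumbel = {
      theta <- spec$param
      if (theta <= 1 + 1e-10) {
        cbind(stats::qnorm(stats::runif(n)), stats::qnorm(stats::runif(n)))
      } else {
        a <- 1 / theta
        s <- .rposstable(n, a)
        e1 <- stats::rexp(n); e2 <- stats::rexp(n)
        u1 <- .clamp01(exp(-(e1 / s)^a))
        u2 <- .clamp01(exp(-(e2 / s)^a))
        cbind(stats::qnorm(u1), stats::qnorm(u2))
      }
    },
    gaussian_copula_t_margins = {
      z <- .bvn_pair(n, spec$param)
      u <- stats::pnorm(z)
      tt <- cbind(stats::qt(u[, 1], spec$df), stats::qt(u[, 2], spec$df))
      if (isTRUE(spec$standardize_t)) tt <- tt / sqrt(spec$df / (spec$df - 2))
      tt
    })
  out[, 1] <- out[, 1] * spec$margin_scale_v
  out[, 2] <- out[, 2] * spec$margin_scale_u
  colnames(out) <- c("V", "U")
  out
}

# Keep copula pseudo-observations strictly inside (0, 1) so the normal
# quantile transform stays finite at extreme frailty draws.
.clamp01 <- function(u) pmin(pmax(u, 1e-15), 1 - 1e-15)

# Standard bivariate normal with correlation r (Cholesky construction).
.bvn_pair <- function(n, r) {
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  cbind(z1, z2)
}

# Positive alpha-stable draw with Laplace transform exp(-t^alpha),
# Chambers-Mallows-Stuck form (the Gumbel frailty distribution).
.rposstable <- function(n, alpha) {
  theta <- stats::runif(n, 0, pi)
  w <- stats::rexp(n)
  (sin(alpha * theta) / sin(theta)^(1 / alpha)) *
    (sin((1 - alpha) * theta) / w)^((1 - alpha) / alpha)
}
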