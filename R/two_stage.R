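#' Fit the first-stage exposure model
#'
#' Ordinary least squares of the exposure on an intercept, the 50 analysis
#' instruments, and (optionally) the measured covariate.  All two-stage
#' estimators and the IVW intercept anchoring build on this fit.
#'
#' @param T Numeric exposure vector.
#' @param Z_sel n x p matrix of analysis instruments.
#' @param X Optional covariate vector.
#' @param include_x Include `X` in the design (default: `TRUE` when `X` is
#'   supplied).
#' @return An object of class `first_stage_fit`: coefficients, fitted values,
#'   residuals, `r_squared`, `f_statistic`, `include_x`, `n`.
#' @export
fit_first_stage <- function(T, Z_sel, X = NULL, include_x = !is.null(X)) {
  Z_sel <- as.matrix(Z_sel)
  storage.mode(Z_sel) <- "double"
  n <- length(T)
  stopifnot(nrow(Z_sel) == n, !anyNA(T), !anyNA(Z_sel))
  if (include_x && is.null(X))
    stop("include_x = TRUE but no covariate supplied", call. = FALSE)
  if (is.null(colnames(Z_sel))) colnames(Z_sel) <- paste0("Z", seq_len(ncol(Z_sel)))
  D <- cbind(`(Intercept)` = 1, Z_sel, if (include_x) cbind(X = X))
  if (n <= ncol(D))
    stop("need more subjects than first-stage coefficients", call. = FALSE)
  fit <- .lm.fit(D, T)
  if (fit$rank < ncol(D)) {
    bad <- colnames(D)[fit$pivot[(fit$rank + 1L):ncol(D)]]
    stop("first-stage design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- fit$coefficients[order(fit$pivot)]
  names(coefs) <- colnames(D)
  resid <- fit$residuals
  fitted <- T - resid
  rss <- sum(resid^2)
  tss <- sum((T - mean(T))^2)
  r2 <- 1 - rss / tss
  p <- ncol(D) - 1L
  fstat <- (r2 / p) / ((1 - r2) / (n - p - 1L))
  structure(list(coefficients = coefs, fitted_values = fitted,
                 residuals = resid, r_squared = r2, f_statistic = fstat,
                 include_x = include_x, n = n),
            class = "first_stage_fit")
}

#' @export
print.first_stage_fit <- function(x, ...) {
  cat(sprintf("<first_stage_fit> n=%d p=%d R2=%.4f F=%.1f include_x=%s\n",
              x$n, length(x$coefficients) - 1L, x$r_squared, x$f_statistic,
              x$include_x))
  invisible(x)
}

# Internal constructor for one estimator's output on one cohort.
estimate_record <- function(method, beta_t, intercept,
                            covariate_coef = NULL, aux = list(),
                            converged = TRUE, n_used) {
  structure(list(method = method, beta_t = unname(beta_t),
                 intercept = unname(intercept),
                 covariate_coef = if (is.null(covariate_coef)) NULL
                                  else unname(covariate_coef),
                 aux = aux, converged = converged, n_used = n_used),
            class = "iv_estimate")
}

#' @export
print.iv_estimate <- function(x, ...) {
  cat(sprintf("<iv_estimate> %s beta_t=%.4f converged=%s n=%d\n",
              x$method, x$beta_t, x$converged, x$n_used))
  invisible(x)
}

#' Two-stage least squares
#'
#' OLS of the binary outcome on an intercept, the first-stage fitted exposure,
#' and (optionally) the covariate.  `beta_t` is the fitted-exposure slope on
#' the linear-probability scale.
#'
#' @param Y Binary outcome vector (0/1).
#' @param first_stage A [fit_first_stage()] result.
#' @param X Optional covariate vector.
#' @param include_x Include `X` in the second stage (default: follow the
#'   first stage).
#' @return An `iv_estimate` record with method `"2SLS"`.
#' @export
fit_2sls <- function(Y, first_stage, X = NULL,
                     include_x = first_stage$include_x) {
  stopifnot(inherits(first_stage, "first_stage_fit"),
            all(Y %in% c(0, 1)))
  if (include_x && is.null(X))
    stop("include_x = TRUE but no covariate supplied", call. = FALSE)
  D <- cbind(`(Intercept)` = 1, That = first_stage$fitted_values,
             if (include_x) cbind(X = X))
  coefs <- qr.coef(qr(D), Y)
  estimate_record("2SLS", beta_t = coefs["That"],
                  intercept = coefs["(Intercept)"],
                  covariate_coef = if (include_x) coefs["X"],
                  aux = list(), converged = TRUE, n_used = length(Y))
}

# Binomial GLM with a documented fallback for the unstable log link:
# IRLS via glm.fit (with step-halving built in); on failure or
# non-convergence the log link falls back to a Poisson-family log-link fit
# of the binary outcome, which targets the same log-risk coefficients.
fit_binary_glm <- function(D, Y, link) {
  start <- NULL
  pois <- NULL
  if (identical(link, "log")) {
    # Poisson log-link fit of the binary outcome: fast, always converges,
    # targets the same log-risk coefficients -- used as warm start and as
    # the documented fallback.
    pois <- tryCatch(
      suppressWarnings(stats::glm.fit(D, Y, family = stats::poisson("log"),
                                      control = stats::glm.control(maxit = 100))),
      error = function(e) NULL)
    pois_interior <- !is.null(pois) && all(is.finite(pois$coefficients)) &&
      max(drop(D %*% pois$coefficients)) < -1e-8
    if (!pois_interior && !is.null(pois) &&
        all(is.finite(pois$coefficients))) {
      # the log-risk fit already predicts risks at or above 1, so the
      # log-binomial maximum sits on the parameter-space boundary and its
      # IRLS cannot converge; report the Poisson fallback directly
      return(list(coefficients = pois$coefficients, converged = FALSE,
                  fallback = "poisson"))
    }
    start <- if (pois_interior) pois$coefficients
             else c(log(max(mean(Y), 1e-8)), rep(0, ncol(D) - 1L))
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(D, Y, family = stats::binomial(link),
                                    start = start,
                                    control = stats::glm.control(
                                      maxit = if (identical(link, "log")) 15 else 100))),
    error = function(e) NULL)
  ok <- !is.null(fit) && isTRUE(fit$converged) &&
    all(is.finite(fit$coefficients)) && fit$boundary == FALSE
  if (ok)
    return(list(coefficients = fit$coefficients, converged = TRUE,
                fallback = NA_character_))
  if (identical(link, "log") && !is.null(pois) &&
      all(is.finite(pois$coefficients))) {
    return(list(coefficients = pois$coefficients, converged = FALSE,
                fallback = "poisson"))
  }
  list(coefficients = if (is.null(fit)) rep(NA_real_, ncol(D))
                      else fit$coefficients,
       converged = FALSE, fallback = NA_character_)
}

#' Two-stage predictor substitution
#'
#' Binomial GLM of the outcome on an intercept, the first-stage fitted
#' exposure, and (optionally) the covariate, with a probit or log link.
#' `beta_t` is the fitted-exposure coefficient on the link scale.  The
#' `"identity"` link is an internal test hook that reproduces [fit_2sls()].
#'
#' Log-binomial fits are notoriously unstable; on non-convergence the fit
#' falls back to a Poisson-family log-link regression of the binary outcome
#' (same target coefficients) and flags `converged = FALSE` with
#' `aux$fallback = "poisson"`.
#'
#' @inheritParams fit_2sls
#' @param link `"probit"`, `"log"`, or `"identity"` (test hook).
#' @return An `iv_estimate` record with method `"2SPS_PR"` or `"2SPS_LL"`.
#' @export
fit_2sps <- function(Y, first_stage, X = NULL,
                     include_x = first_stage$include_x,
                     link = c("probit", "log", "identity")) {
  link <- match.arg(link)
  stopifnot(inherits(first_stage, "first_stage_fit"), all(Y %in% c(0, 1)))
  if (include_x && is.null(X))
    stop("include_x = TRUE but no covariate supplied", call. = FALSE)
  if (link == "identity") {
    rec <- fit_2sls(Y, first_stage, X, include_x)
    rec$method <- "2SPS_ID"
    return(rec)
  }
  D <- cbind(`(Intercept)` = 1, That = first_stage$fitted_values,
             if (include_x) cbind(X = X))
  fit <- fit_binary_glm(D, Y, link)
  names(fit$coefficients) <- colnames(D)
  estimate_record(paste0("2SPS_", if (link == "probit") "PR" else "LL"),
                  beta_t = fit$coefficients["That"],
                  intercept = fit$coefficients["(Intercept)"],
                  covariate_coef = if (include_x) fit$coefficients["X"],
                  aux = list(fallback = fit$fallback),
                  converged = fit$converged, n_used = length(Y))
}

#' Two-stage residual inclusion (control function)
#'
#' Binomial GLM of the outcome on an intercept, the observed exposure, the
#' first-stage residual, and (optionally) the covariate.  `beta_t` is the
#' observed-exposure coefficient; the residual (control-function) coefficient
#' is stored in `aux$residual_coef`.  If the supplied residuals are
#' identically zero the residual column is dropped (degenerate control
#' function) and the fit reduces to an ordinary GLM of `Y` on `(1, T, X?)`.
#'
#' @inheritParams fit_2sps
#' @param T Observed exposure vector.
#' @return An `iv_estimate` record with method `"2SRI_PR"` or `"2SRI_LL"`.
#' @export
fit_2sri <- function(Y, T, first_stage, X = NULL,
                     include_x = first_stage$include_x,
                     link = c("probit", "log")) {
  link <- match.arg(link)
  stopifnot(inherits(first_stage, "first_stage_fit"), all(Y %in% c(0, 1)),
            length(T) == length(Y))
  if (include_x && is.null(X))
    stop("include_x = TRUE but no covariate supplied", call. = FALSE)
  res <- first_stage$residuals
  degenerate <- all(abs(res) < 1e-12)
  D <- cbind(`(Intercept)` = 1, T = T,
             if (!degenerate) cbind(resid = res),
             if (include_x) cbind(X = X))
  fit <- fit_binary_glm(D, Y, link)
  names(fit$coefficients) <- colnames(D)
  estimate_record(paste0("2SRI_", if (link == "probit") "PR" else "LL"),
                  beta_t = fit$coefficients["T"],
                  intercept = fit$coefficients["(Intercept)"],
                  covariate_coef = if (include_x) fit$coefficients["X"],
                  aux = list(residual_coef = if (degenerate) NA_real_
                                             else unname(fit$coefficients["resid"]),
                             residual_dropped = degenerate,
                             fallback = fit$fallback),
                  converged = fit$converged, n_used = length(Y))
}
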