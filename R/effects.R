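#' Map an estimator to its risk-function family
#'
#' Probit family: `2SPS_PR`, `2SRI_PR`, `LIML` (latent-scale coefficients in
#' the normal-cdf map).  Log family: `2SPS_LL`, `2SRI_LL`, `IVW_LL`.  Linear
#' family: `2SLS`, `IVW_LI`.
#'
#' @param method Method label.
#' @return `"probit"`, `"log"`, or `"linear"`.
#' @export
method_family <- function(method) {
  switch(method,
         "2SPS_PR" = , "2SRI_PR" = , "LIML" = "probit",
         "2SPS_LL" = , "2SRI_LL" = , "IVW_LL" = "log",
         "2SLS" = , "2SPS_ID" = , "IVW_LI" = "linear",
         stop("unknown method: ", method, call. = FALSE))
}

#' G-formula standardized risk at an exposure value
#'
#' With a covariate in the fitted model the standardized risk is the sample
#' average over the covariate distribution,
#' \eqn{\hat p(t') = n^{-1}\sum_i g(\hat\alpha_0 + t'\hat\alpha_t +
#' x_i\hat\alpha_x)} with \eqn{g = \Phi} (probit family), \eqn{\exp} (log
#' family) or the identity (linear family).  Without a covariate the same
#' maps are evaluated once at \eqn{\hat\alpha_0 + t'\hat\alpha_t}.  Risks are
#' never clipped: linear-family risks may fall outside \eqn{[0, 1]}, and the
#' resulting negative risk ratios are meaningful summaries of that
#' misspecification.
#'
#' @param record An `iv_estimate`.
#' @param t_prime Exposure value(s) at which to evaluate the risk.
#' @param X_sample Covariate vector to standardize over; must be supplied
#'   exactly when the record's model included the covariate.
#' @return Standardized risk(s), same length as `t_prime`.
#' @export
standardized_risk <- function(record, t_prime, X_sample = NULL) {
  stopifnot(inherits(record, "iv_estimate"))
  if (!isTRUE(record$converged))
    warning("standardizing a non-converged ", record$method, " fit")
  fam <- method_family(record$method)
  map <- switch(fam, probit = stats::pnorm, log = exp, linear = identity)
  if (!is.finite(record$beta_t) || !is.finite(record$intercept))
    stop("method ", record$method, ": missing coefficient (intercept/beta_t)",
         call. = FALSE)
  has_x <- !is.null(record$covariate_coef)
  if (has_x && is.null(X_sample))
    stop("method ", record$method,
         " was fitted with a covariate; supply 'X_sample'", call. = FALSE)
  if (!has_x && !is.null(X_sample))
    stop("method ", record$method,
         " has no covariate coefficient; drop 'X_sample'", call. = FALSE)
  vapply(t_prime, function(tp) {
    lin <- record$intercept + tp * record$beta_t
    if (has_x) mean(map(lin + X_sample * record$covariate_coef))
    else map(lin)
  }, numeric(1))
}

#' Default exposure-shift pairs on the BMI grid
#'
#' \eqn{(18.5, 25.0)}, \eqn{(30.5, 37.0)}, \eqn{(41.0, 47.5)},
#' \eqn{(53.0, 59.5)} — four 6.5-unit BMI increments spanning underweight to
#' severe obesity.
#'
#' @return A list of length-2 numeric vectors.
#' @export
default_pairs <- function() {
  list(c(18.5, 25.0), c(30.5, 37.0), c(41.0, 47.5), c(53.0, 59.5))
}

#' Causal risk ratios and differences on an exposure grid
#'
#' Evaluates the standardized risk at every grid point and forms, for each
#' pair \eqn{(t_1, t_2)}, the causal risk ratio
#' \eqn{\mathrm{CRR} = \hat p(t_2)/\hat p(t_1)} and causal risk difference
#' \eqn{\mathrm{CRD} = \hat p(t_2) - \hat p(t_1)}.  A zero \eqn{\hat p(t_1)}
#' yields a signed-infinite CRR with `crr_infinite = TRUE` (the CRD is
#' unaffected); nothing is clipped.
#'
#' @param record An `iv_estimate`.
#' @param pairs List of `(t1, t2)` pairs (default [default_pairs()]).
#' @param X_sample Covariate sample for standardization (see
#'   [standardized_risk()]).
#' @return An object of class `effect_grid`: `method`, `t_values`, `p_hat`,
#'   and a data frame `pairs` with columns `t1, t2, p1, p2, crr, crd,
#'   crr_infinite`.
#' @export
effect_grid <- function(record, pairs = default_pairs(), X_sample = NULL) {
  stopifnot(length(pairs) >= 1L)
  tvals <- sort(unique(unlist(pairs)))
  p_hat <- standardized_risk(record, tvals, X_sample)
  names(p_hat) <- tvals
  rows <- lapply(pairs, function(pr) {
    p1 <- p_hat[[as.character(pr[1])]]
    p2 <- p_hat[[as.character(pr[2])]]
    inf <- p1 == 0
    crr <- if (inf) sign(p2) * Inf else p2 / p1
    data.frame(t1 = pr[1], t2 = pr[2], p1 = p1, p2 = p2,
               crr = crr, crd = p2 - p1, crr_infinite = inf)
  })
  structure(list(method = record$method, t_values = tvals, p_hat = p_hat,
                 pairs = do.call(rbind, rows)),
            class = "effect_grid")
}

#' @export
print.effect_grid <- function(x, ...) {
  cat(sprintf("<effect_grid> %s\n", x$method))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
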