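#' Split a cohort into two random halves
#'
#' Random disjoint halves of equal size, emulating a two-sample Mendelian
#' randomization design inside a single simulated cohort.  Deterministic
#' given the R random stream state.  With an odd number of subjects the extra
#' subject goes to half A with a warning.
#'
#' @param indices Either a single integer `n` (split `1:n`) or an integer
#'   vector of subject indices.
#' @return A list with sorted index vectors `A` and `B`.
#' @export
split_halves <- function(indices) {
  if (length(indices) == 1L) indices <- seq_len(indices)
  n <- length(indices)
  if (n < 2L) stop("need at least 2 subjects to split", call. = FALSE)
  if (n %% 2L == 1L)
    warning("odd number of subjects; extra subject assigned to half A")
  perm <- sample(indices)
  nA <- ceiling(n / 2)
  list(A = sort(perm[seq_len(nA)]), B = sort(perm[(nA + 1L):n]))
}

# Per-SNP simple/adjusted linear regressions, vectorised across SNPs.
# For each column z of Zs fit y ~ 1 + z (+ x) by OLS; return slope and its
# model-based SE.  All variables are centred first (slopes are unchanged,
# conditioning is much better), so the adjusted fit reduces to a 2x2 solve
# done in closed form across all SNPs at once.  Monomorphic columns are
# flagged dropped.
.snp_linear <- function(y, Zs, x = NULL) {
  n <- length(y)
  K <- ncol(Zs)
  Zc <- Zs - rep(.colMeans(Zs, n, K), each = n)
  yc <- y - mean(y)
  Szz <- .colSums(Zc^2, n, K)
  Szy <- .colSums(Zc * yc, n, K)
  Syy <- sum(yc^2)
  dropped <- Szz < 1e-10
  if (is.null(x)) {
    b <- Szy / Szz
    rss <- pmax(Syy - b * Szy, 0)
    se <- sqrt(rss / (n - 2) / Szz)
  } else {
    xc <- x - mean(x)
    Sxx <- sum(xc^2)
    Sxy <- sum(xc * yc)
    Szx <- .colSums(Zc * xc, n, K)
    det <- Szz * Sxx - Szx^2
    dropped <- dropped | det <= 0
    b <- (Szy * Sxx - Szx * Sxy) / det
    cx <- (Szz * Sxy - Szx * Szy) / det
    rss <- pmax(Syy - b * Szy - cx * Sxy, 0)
    se <- sqrt(rss / (n - 3) * Sxx / det)
  }
  b[dropped] <- NA_real_
  se[dropped] <- NA_real_
  list(slope = b, se = se, dropped = dropped)
}

# Per-SNP log-binomial regressions, IRLS vectorised across SNPs.
# For each column z of Zs fit a binomial GLM with log link y ~ 1 + z (+ x);
# return slope and Fisher-information SE.  The instrument and covariate are
# centred (slopes unchanged, conditioning vastly better); the weighted-sum
# accumulation runs in compiled code (.snp_irls_sums) and the per-SNP
# 2x2 / 3x3 normal equations are solved in closed form (Cramer) across all
# SNPs at once.
#
# Log-binomial likelihoods with a continuous covariate often have their
# maximum on the boundary (fitted risks at 1), where IRLS cycles instead of
# converging -- the classic log-binomial pathology.  SNPs whose linear
# predictor hits the risk cap, and SNPs that otherwise fail to converge, are
# refit as Poisson-family log-risk regressions of the binary outcome (the
# modified-Poisson workaround, targeting the same log-risk coefficients);
# they are counted in `fallback`, and only SNPs where even that fails are
# dropped.
.snp_logbinom <- function(y, Zs, x = NULL, maxit = 15L, tol = 1e-10) {
  n <- length(y)
  K <- ncol(Zs)
  has_x <- !is.null(x)
  zbar <- .colMeans(Zs, n, K)
  Zc <- Zs - rep(zbar, each = n)
  dropped <- .colSums(Zc^2, n, K) < 1e-10
  xc <- if (has_x) x - mean(x)
  ybar <- mean(y)
  if (ybar <= 0) {
    return(list(slope = rep(NA_real_, K), se = rep(NA_real_, K),
                dropped = rep(TRUE, K), fallback = integer(0)))
  }
  a <- rep(log(ybar), K); b <- rep(0, K); cx <- rep(0, K)
  converged <- rep(FALSE, K)
  boundary <- rep(FALSE, K)

  # vectorised Cramer solve of the per-SNP weighted normal equations from
  # one .snp_irls_sums pass (columns: S_w, S_wz, S_wzz, S_wx, S_wxx, S_wzx,
  # r_a, r_b, r_x, atcap)
  cramer <- function(s) {
    S_w <- s[, 1]; S_wz <- s[, 2]; S_wzz <- s[, 3]
    if (!has_x) {
      det <- S_w * S_wzz - S_wz^2
      list(a = (s[, 7] * S_wzz - S_wz * s[, 8]) / det,
           b = (S_w * s[, 8] - S_wz * s[, 7]) / det,
           cx = rep(0, K), det = det)
    } else {
      S_wx <- s[, 4]; S_wxx <- s[, 5]; S_wzx <- s[, 6]
      r_a <- s[, 7]; r_b <- s[, 8]; r_x <- s[, 9]
      A11 <- S_wzz * S_wxx - S_wzx^2
      A12 <- S_wz * S_wxx - S_wzx * S_wx
      A13 <- S_wz * S_wzx - S_wzz * S_wx
      det <- S_w * A11 - S_wz * A12 + S_wx * A13
      A22 <- S_w * S_wxx - S_wx^2
      A23 <- S_w * S_wzx - S_wz * S_wx
      A33 <- S_w * S_wzz - S_wz^2
      list(a = (r_a * A11 - r_b * A12 + r_x * A13) / det,
           b = (-r_a * A12 + r_b * A22 - r_x * A23) / det,
           cx = (r_a * A13 - r_b * A23 + r_x * A33) / det,
           det = det)
    }
  }
  info_se <- function(s) {
    if (!has_x) {
      det <- s[, 1] * s[, 3] - s[, 2]^2
      suppressWarnings(sqrt(s[, 1] / det))
    } else {
      A11 <- s[, 3] * s[, 5] - s[, 6]^2
      A12 <- s[, 2] * s[, 5] - s[, 6] * s[, 4]
      A13 <- s[, 2] * s[, 6] - s[, 3] * s[, 4]
      det <- s[, 1] * A11 - s[, 2] * A12 + s[, 4] * A13
      A22 <- s[, 1] * s[, 5] - s[, 4]^2
      suppressWarnings(sqrt(A22 / det))
    }
  }

  for (it in seq_len(maxit)) {
    s <- .snp_irls_sums(y, Zc, xc, a, b, cx, FALSE)
    # a binding risk cap means the likelihood maximum sits on the boundary;
    # such SNPs go straight to the Poisson fallback
    boundary <- boundary | (s[, 10] > 0)
    sol <- cramer(s)
    bad <- !is.finite(sol$a) | !is.finite(sol$b) |
      (has_x & !is.finite(sol$cx)) | sol$det <= 0
    upd <- !converged & !dropped & !bad & !boundary
    del <- pmax(abs(sol$a - a), abs(sol$b - b),
                if (has_x) abs(sol$cx - cx) else 0)
    a[upd] <- sol$a[upd]; b[upd] <- sol$b[upd]
    if (has_x) cx[upd] <- sol$cx[upd]
    converged <- converged | (upd & del < tol * (1 + abs(b)))
    if (all(converged | dropped | boundary)) break
  }
  converged <- converged & !boundary
  se <- rep(NA_real_, K)
  if (any(converged & !dropped)) {
    se_bin <- info_se(.snp_irls_sums(y, Zc, xc, a, b, cx, FALSE))
    se[converged & !dropped] <- se_bin[converged & !dropped]
  }

  fallback <- which(!converged & !dropped)
  if (length(fallback)) {
    a[fallback] <- log(ybar); b[fallback] <- 0; cx[fallback] <- 0
    is_fb <- seq_len(K) %in% fallback
    pconv <- rep(FALSE, K)
    for (it in seq_len(25L)) {
      s <- .snp_irls_sums(y, Zc, xc, a, b, cx, TRUE)
      sol <- cramer(s)
      del <- pmax(abs(sol$a - a), abs(sol$b - b),
                  if (has_x) abs(sol$cx - cx) else 0)
      upd <- is_fb & !pconv & is.finite(sol$b) & sol$det > 0
      a[upd] <- sol$a[upd]; b[upd] <- sol$b[upd]
      if (has_x) cx[upd] <- sol$cx[upd]
      pconv <- pconv | (upd & del < 1e-10 * (1 + abs(b)))
      if (all(pconv[fallback])) break
    }
    se_pois <- info_se(.snp_irls_sums(y, Zc, xc, a, b, cx, TRUE))
    dropped <- dropped | (is_fb & !pconv)
    idx <- setdiff(fallback, which(dropped))
    se[idx] <- se_pois[idx]
  }
  dropped <- dropped | !is.finite(b) | !is.finite(se) | se <= 0
  slope <- b
  slope[dropped] <- NA_real_
  se[dropped] <- NA_real_
  list(slope = slope, se = se, dropped = dropped,
       fallback = setdiff(fallback %||% integer(0), which(dropped)))
}

#' Per-instrument association regressions in disjoint halves
#'
#' For each analysis instrument \eqn{k} separately: the instrument-exposure
#' slope \eqn{\hat\gamma_k} from OLS of `T` on `(1, Z_k, X?)` in half A, and
#' the instrument-outcome slope \eqn{\hat\Gamma_k} from OLS (`link =
#' "linear"`) or a log-link binomial GLM (`link = "log"`) of `Y` on
#' `(1, Z_k, X?)` in half B.  Monomorphic or non-convergent instruments are
#' dropped from pooling with a warning and counted.
#'
#' @param cohort An `iv_cohort`.
#' @param half_A,half_B Disjoint subject index vectors (from
#'   [split_halves()]).
#' @param iv_cols Instrument column indices (the 50 analysis instruments).
#' @param include_x Adjust both association regressions for the covariate.
#' @param link `"linear"` or `"log"` outcome association model.
#' @return An object of class `snp_associations` with `gamma_hat`,
#'   `gamma_se`, `Gamma_hat`, `Gamma_se`, `dropped`, `n_dropped`, `link`.
#' @export
per_snp_regressions <- function(cohort, half_A, half_B, iv_cols,
                                include_x = FALSE,
                                link = c("linear", "log")) {
  link <- match.arg(link)
  stopifnot(inherits(cohort, "iv_cohort"),
            length(intersect(half_A, half_B)) == 0L)
  ZA <- cohort$Z[half_A, iv_cols, drop = FALSE]
  ZB <- cohort$Z[half_B, iv_cols, drop = FALSE]
  storage.mode(ZA) <- "double"; storage.mode(ZB) <- "double"
  xA <- if (include_x) cohort$X[half_A]
  xB <- if (include_x) cohort$X[half_B]
  expo <- .snp_linear(cohort$T[half_A], ZA, xA)
  outc <- if (link == "linear") .snp_linear(cohort$Y[half_B], ZB, xB)
          else .snp_logbinom(cohort$Y[half_B], ZB, xB)
  dropped <- expo$dropped | outc$dropped |
    !is.finite(expo$slope) | !is.finite(outc$slope) | !is.finite(outc$se)
  if (any(dropped))
    warning(sum(dropped), " instrument(s) dropped from IVW pooling")
  fb <- seq_along(iv_cols) %in% (outc$fallback %||% integer(0))
  structure(list(gamma_hat = expo$slope, gamma_se = expo$se,
                 Gamma_hat = outc$slope, Gamma_se = outc$se,
                 dropped = dropped, n_dropped = sum(dropped),
                 fallback = fb, n_fallback = sum(fb),
                 link = link),
            class = "snp_associations")
}

#' Fixed-effect inverse-variance-weighted pooling
#'
#' \deqn{\hat\beta = \frac{\sum_k \hat\gamma_k \hat\Gamma_k / se(\hat\Gamma_k)^2}
#'                        {\sum_k \hat\gamma_k^2 / se(\hat\Gamma_k)^2},}
#' the fixed-effect IVW estimate — identical to weighted least squares of
#' \eqn{\hat\Gamma_k} on \eqn{\hat\gamma_k} through the origin with weights
#' \eqn{1/se(\hat\Gamma_k)^2}.  With a single instrument this reduces to the
#' Wald ratio \eqn{\hat\Gamma_1/\hat\gamma_1}.
#'
#' @param assoc A [per_snp_regressions()] result.
#' @return The pooled scalar estimate.
#' @export
ivw_pool <- function(assoc) {
  stopifnot(inherits(assoc, "snp_associations"))
  use <- !assoc$dropped & is.finite(assoc$Gamma_se) & assoc$Gamma_se > 0
  if (!any(use)) stop("no usable instruments for IVW pooling", call. = FALSE)
  g <- assoc$gamma_hat[use]; G <- assoc$Gamma_hat[use]
  w <- 1 / assoc$Gamma_se[use]^2
  sum(g * G * w) / sum(g^2 * w)
}

#' Split-sample IVW estimator with cross-fit averaging
#'
#' Splits the cohort into random halves, runs [per_snp_regressions()] with
#' half A estimating the instrument-exposure associations and half B the
#' instrument-outcome associations, pools by [ivw_pool()], repeats with the
#' half roles swapped, and returns the arithmetic mean of the two pooled
#' estimates.  `aux` keeps both directional estimates and the dropped
#' counts.
#'
#' For downstream risk standardization an intercept is attached by anchoring
#' the risk function at the observed prevalence and mean exposure:
#' \eqn{\hat\alpha_0 = g(\bar Y) - \bar T \hat\beta} with \eqn{g = \log}
#' (`link = "log"`) or the identity (`link = "linear"`), using full-sample
#' means.
#'
#' @param cohort An `iv_cohort`.
#' @param iv_cols Instrument column indices.
#' @param include_x Adjust the per-instrument regressions for the covariate.
#' @param link `"linear"` (method `IVW_LI`) or `"log"` (method `IVW_LL`).
#' @return An `iv_estimate` record.
#' @export
fit_ivw <- function(cohort, iv_cols, include_x = FALSE,
                    link = c("linear", "log")) {
  link <- match.arg(link)
  halves <- split_halves(length(cohort$Y))
  a1 <- per_snp_regressions(cohort, halves$A, halves$B, iv_cols,
                            include_x, link)
  a2 <- per_snp_regressions(cohort, halves$B, halves$A, iv_cols,
                            include_x, link)
  b1 <- ivw_pool(a1); b2 <- ivw_pool(a2)
  beta <- (b1 + b2) / 2
  ybar <- mean(cohort$Y); tbar <- mean(cohort$T)
  alpha0 <- if (link == "log") log(ybar) - tbar * beta else ybar - tbar * beta
  estimate_record(if (link == "linear") "IVW_LI" else "IVW_LL",
                  beta_t = beta, intercept = alpha0,
                  covariate_coef = NULL,
                  aux = list(beta_ab = b1, beta_ba = b2,
                             n_dropped = c(a1$n_dropped, a2$n_dropped),
                             n_fallback = c(a1$n_fallback, a2$n_fallback)),
                  converged = TRUE, n_used = length(cohort$Y))
}
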