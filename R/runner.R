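#' All estimator labels, in the conventional reporting order
#' @return Character vector of the eight method labels.
#' @export
all_methods <- function() {
  c("2SRI_PR", "2SRI_LL", "LIML", "2SLS", "2SPS_PR", "2SPS_LL",
    "IVW_LI", "IVW_LL")
}

# Deterministic child seed for (master seed, scenario, iteration).
# Exact in double arithmetic (products stay far below 2^53) and always
# below 2^31 so it is a valid R integer seed.
derive_seed <- function(master_seed, scenario_id = 0L, iteration = 0L) {
  as.integer((1000003 * (master_seed %% 1048576) +
                10007 * scenario_id + 97 * iteration) %% 2147483629)
}

#' Build the 32-scenario simulation grid
#'
#' The full factorial of instrument set (`mixed`, `weak_only`) x covariate
#' inclusion (yes, no) x eight confounder-dependence settings: Gaussian
#' (rho = +0.5, -0.5), t copula with normal margins (+0.5, -0.5), Clayton
#' (+0.5), Gumbel (+0.5), and Gaussian copula with t margins (+0.5, -0.5).
#' Ordering is instrument-set major, then covariate inclusion, then the
#' eight dependence settings; Clayton and Gumbel appear only with positive
#' association.
#'
#' @param df Degrees of freedom for the t components (default 3).
#' @return A list of 32 scenario specifications, each with `scenario_id`,
#'   `iv_set`, `include_x`, `copula`, `copula_label`.
#' @export
build_grid <- function(df = 3L) {
  cops <- list(
    gaussian_p = copula_spec("gaussian", 0.5),
    gaussian_m = copula_spec("gaussian", -0.5),
    t_copula_p = copula_spec("t_copula", 0.5, df = df),
    t_copula_m = copula_spec("t_copula", -0.5, df = df),
    clayton_p = copula_spec("clayton", 0.5),
    gumbel_p = copula_spec("gumbel", 0.5),
    t_margins_p = copula_spec("gaussian_copula_t_margins", 0.5, df = df),
    t_margins_m = copula_spec("gaussian_copula_t_margins", -0.5, df = df))
  grid <- list()
  sid <- 0L
  for (iv_set in c("mixed", "weak_only")) {
    for (include_x in c(TRUE, FALSE)) {
      for (lab in names(cops)) {
        sid <- sid + 1L
        grid[[sid]] <- list(scenario_id = sid, iv_set = iv_set,
                            include_x = include_x, copula = cops[[lab]],
                            copula_label = lab)
      }
    }
  }
  grid
}

#' Run every requested estimator on one cohort
#'
#' Selects the scenario's 50 analysis instruments, fits the shared first
#' stage, dispatches each estimator, and standardizes each fit to the causal
#' risk ratio/difference grid.  Per-fit failures are caught and recorded as
#' non-converged rows, never fatal.
#'
#' @param cohort An `iv_cohort`.
#' @param scenario One element of [build_grid()].
#' @param methods Estimator labels (subset of [all_methods()]).
#' @param pairs Exposure-shift pairs for [effect_grid()].
#' @return A data frame with one row per method: the exposure coefficient,
#'   convergence flag, LIML auxiliaries, and one `crr_*`/`crd_*` column per
#'   pair.
#' @export
run_iteration <- function(cohort, scenario, methods = all_methods(),
                          pairs = default_pairs()) {
  iv_cols <- select_analysis_instruments(cohort, scenario$iv_set)
  include_x <- scenario$include_x
  X <- if (include_x) cohort$X
  Zs <- cohort$Z[, iv_cols, drop = FALSE]
  storage.mode(Zs) <- "double"
  needs_fs <- any(methods %in% c("2SLS", "2SPS_PR", "2SPS_LL",
                                 "2SRI_PR", "2SRI_LL", "LIML"))
  fs <- if (needs_fs) fit_first_stage(cohort$T, Zs, X, include_x)

  one <- function(method) {
    rec <- tryCatch(switch(method,
      "2SLS" = fit_2sls(cohort$Y, fs, X, include_x),
      "2SPS_PR" = fit_2sps(cohort$Y, fs, X, include_x, link = "probit"),
      "2SPS_LL" = fit_2sps(cohort$Y, fs, X, include_x, link = "log"),
      "2SRI_PR" = fit_2sri(cohort$Y, cohort$T, fs, X, include_x, "probit"),
      "2SRI_LL" = fit_2sri(cohort$Y, cohort$T, fs, X, include_x, "log"),
      "LIML" = fit_liml(cohort$T, cohort$Y, Zs, X, include_x),
      "IVW_LI" = fit_ivw(cohort, iv_cols, include_x, link = "linear"),
      "IVW_LL" = fit_ivw(cohort, iv_cols, include_x, link = "log"),
      stop("unknown method: ", method)),
      error = function(e) NULL)
    row <- data.frame(method = method, beta_t = NA_real_, converged = FALSE,
                      rho_hat = NA_real_, sigma_v_hat = NA_real_,
                      error = NA_character_)
    for (j in seq_along(pairs))
      for (col in paste0(c("crr_", "crd_"), j)) row[[col]] <- NA_real_
    if (is.null(rec)) { row$error <- "fit_error"; return(row) }
    row$beta_t <- rec$beta_t
    row$converged <- rec$converged
    if (method == "LIML") {
      row$rho_hat <- rec$aux$rho
      row$sigma_v_hat <- rec$aux$sigma_v
    }
    xs <- if (!is.null(rec$covariate_coef)) cohort$X
    eg <- tryCatch(suppressWarnings(effect_grid(rec, pairs, xs)),
                   error = function(e) NULL)
    for (j in seq_along(pairs)) {
      row[[paste0("crr_", j)]] <-
        if (is.null(eg)) NA_real_ else eg$pairs$crr[j]
      row[[paste0("crd_", j)]] <-
        if (is.null(eg)) NA_real_ else eg$pairs$crd[j]
    }
    row
  }
  do.call(rbind, lapply(methods, one))
}

#' Run the Monte-Carlo study over a scenario grid
#'
#' Iteration `r` of scenario `s` seeds the R stream with a child seed derived
#' from `(master_seed, s, r)`, generates a fresh cohort (allele frequencies
#' and effect sizes redrawn each iteration unless `freeze_genetics = TRUE`,
#' in which case they are drawn once per scenario from the iteration-0
#' stream), and runs every requested estimator on the same cohort, so method
#' comparisons are paired within iteration.  Estimates are never truncated:
#' extreme values (a known behaviour of LIML under confounder
#' misspecification) enter the summaries as-is.
#'
#' @param grid Scenario list from [build_grid()] (or a subset).
#' @param R Number of Monte-Carlo iterations (>= 2).
#' @param n Cohort size.
#' @param methods Estimator labels to run.
#' @param master_seed Master seed (integer).
#' @param params Base [dgm_params()]; its `n` and `copula` are overridden
#'   per scenario.
#' @param pairs Exposure-shift pairs.
#' @param freeze_genetics Freeze `q` and `alpha` across iterations within a
#'   scenario.
#' @param workers Parallel workers via `parallel::mclapply` (results are
#'   reduced in deterministic (scenario, iteration) order regardless).
#' @param progress Print per-scenario progress to stderr.
#' @return An object of class `iv_study`: `estimates` (one row per scenario x
#'   iteration x method), `summary` (see [summarize_study()]), and the run
#'   configuration.
#' @export
run_study <- function(grid = build_grid(), R = 200L, n = 100000L,
                      methods = all_methods(), master_seed = 1L,
                      params = dgm_params(), pairs = default_pairs(),
                      freeze_genetics = FALSE, workers = 1L,
                      progress = FALSE) {
  stopifnot(R >= 2L)
  run_one <- function(scenario, r, q = NULL, alpha = NULL) {
    set.seed(derive_seed(master_seed, scenario$scenario_id, r))
    p <- params
    p$n <- as.integer(n)
    p$copula <- scenario$copula
    cohort <- generate_cohort(p, q = q, alpha = alpha)
    rows <- run_iteration(cohort, scenario, methods, pairs)
    rows$scenario_id <- scenario$scenario_id
    rows$iv_set <- scenario$iv_set
    rows$include_x <- scenario$include_x
    rows$copula_label <- scenario$copula_label
    rows$iteration <- r
    rows
  }
  per_scenario <- lapply(grid, function(scenario) {
    if (progress)
      message(sprintf("scenario %d/%d (%s, include_x=%s, %s)",
                      scenario$scenario_id, length(grid), scenario$iv_set,
                      scenario$include_x, scenario$copula_label))
    q <- NULL; alpha <- NULL
    if (freeze_genetics) {
      set.seed(derive_seed(master_seed, scenario$scenario_id, 0L))
      p <- params; p$copula <- scenario$copula
      q <- stats::runif(p$K, p$q_low, p$q_high)
      alpha <- draw_effect_sizes(p)
    }
    iters <- seq_len(R)
    res <- if (workers > 1L && requireNamespace("parallel", quietly = TRUE)) {
      parallel::mclapply(iters, function(r) run_one(scenario, r, q, alpha),
                         mc.cores = workers)
    } else {
      lapply(iters, function(r) run_one(scenario, r, q, alpha))
    }
    do.call(rbind, res)
  })
  estimates <- do.call(rbind, per_scenario)
  structure(list(estimates = estimates,
                 summary = summarize_study(estimates),
                 pairs = pairs, R = R, n = n, master_seed = master_seed,
                 methods = methods),
            class = "iv_study")
}

#' Summarize per-iteration estimates as mean and empirical standard error
#'
#' The empirical standard error (ESE) is the sample standard deviation across
#' iterations (denominator `R - 1`).  Summaries include every iteration,
#' converged or not, provided the estimate is non-missing; cells where every
#' fit failed are `NA`.
#'
#' @param estimates The `estimates` data frame of an `iv_study` (or any data
#'   frame with `scenario_id`, `method`, `beta_t`, optional `crr_*`/`crd_*`
#'   columns).
#' @return A data frame with one row per scenario x method: `beta_mean`,
#'   `beta_ese`, per-pair `crr_*_mean`/`crr_*_ese`/`crd_*_mean`/`crd_*_ese`,
#'   `n_iter`, `n_converged`.
#' @export
summarize_study <- function(estimates) {
  metric_cols <- c("beta_t",
                   grep("^cr[rd]_[0-9]+$", names(estimates), value = TRUE))
  keys <- unique(estimates[c("scenario_id", "method")])
  keys <- keys[order(keys$scenario_id,
                     match(keys$method, all_methods())), ]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- estimates[estimates$scenario_id == keys$scenario_id[i] &
                       estimates$method == keys$method[i], ]
    out <- data.frame(scenario_id = keys$scenario_id[i],
                      method = keys$method[i])
    for (meta in c("iv_set", "include_x", "copula_label"))
      if (!is.null(sub[[meta]])) out[[meta]] <- sub[[meta]][1]
    for (mc in metric_cols) {
      v <- sub[[mc]][!is.na(sub[[mc]])]
      pre <- sub("^beta_t$", "beta", mc)
      out[[paste0(pre, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(pre, "_ese")]] <- if (length(v) >= 2L) stats::sd(v)
                                    else NA_real_
    }
    out$n_iter <- nrow(sub)
    out$n_converged <- sum(sub$converged, na.rm = TRUE)
    out
  })
  do.call(rbind, rows)
}

#' Format a summary cell as "mean (ESE)"
#'
#' Three decimals; magnitudes above 999 print as `>999` (or `<-999`),
#' matching how extreme unbounded estimates are conventionally tabulated
#' rather than truncated.
#'
#' @param mean,ese Cell mean and empirical standard error.
#' @param digits Decimal places (default 3).
#' @return A character scalar.
#' @export
format_mean_ese <- function(mean, ese, digits = 3) {
  f1 <- function(v) {
    if (is.na(v)) return("NA")
    if (!is.finite(v)) return(if (v > 0) ">999" else "<-999")
    if (v > 999) return(">999")
    if (v < -999) return("<-999")
    sprintf(paste0("%.", digits, "f"), v)
  }
  paste0(f1(mean), " (", f1(ese), ")")
}

#' Render one summary table analogue
#'
#' Methods (in reporting order) x the eight dependence settings, for one
#' instrument set, covariate-inclusion flag, and metric, each cell formatted
#' as `mean (ESE)`.
#'
#' @param study An `iv_study` from [run_study()].
#' @param metric `"beta"` or a pair metric such as `"crr_2"`.
#' @param iv_set `"mixed"` or `"weak_only"`.
#' @param include_x Covariate-inclusion flag of the block to render.
#' @return A character matrix (methods x dependence settings).
#' @export
render_table <- function(study, metric = "beta",
                         iv_set = c("mixed", "weak_only"),
                         include_x = TRUE) {
  iv_set <- match.arg(iv_set)
  s <- study$summary
  s <- s[s$iv_set == iv_set & s$include_x == include_x, ]
  cops <- unique(s$copula_label)
  methods <- intersect(all_methods(), unique(s$method))
  m <- matrix("", length(methods), length(cops),
              dimnames = list(methods, cops))
  for (i in seq_along(methods)) for (j in seq_along(cops)) {
    row <- s[s$method == methods[i] & s$copula_label == cops[j], ]
    if (nrow(row))
      m[i, j] <- format_mean_ese(row[[paste0(metric, "_mean")]],
                                 row[[paste0(metric, "_ese")]])
  }
  m
}

#' @export
print.iv_study <- function(x, ...) {
  cat(sprintf("<iv_study> %d scenario(s) x %d iteration(s), n=%d, %d method(s)\n",
              length(unique(x$estimates$scenario_id)), x$R, x$n,
              length(x$methods)))
  invisible(x)
}
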