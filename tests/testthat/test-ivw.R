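test_that("split_halves produces disjoint, exhaustive, seed-stable halves", {
  set.seed(401)
  h <- split_halves(100000)
  expect_length(h$A, 50000)
  expect_length(h$B, 50000)
  expect_length(intersect(h$A, h$B), 0)
  expect_identical(sort(c(h$A, h$B)), 1:100000)
  set.seed(401)
  h2 <- split_halves(100000)
  expect_identical(h, h2)
  # small even case
  set.seed(402)
  h <- split_halves(10)
  expect_length(h$A, 5); expect_length(h$B, 5)
  # odd n: extra subject to half A, with a warning
  set.seed(403)
  expect_warning(h <- split_halves(11), "odd")
  expect_length(h$A, 6); expect_length(h$B, 5)
})

test_that("per-instrument slopes match refitting each regression directly", {
  set.seed(411)
  co <- generate_cohort(small_params(n = 1200, K = 80))
  set.seed(412)
  h <- split_halves(1200)
  iv_cols <- 1:8
  for (link in c("linear", "log")) {
    for (include_x in c(FALSE, TRUE)) {
      assoc <- per_snp_regressions(co, h$A, h$B, iv_cols, include_x, link)
      for (k in seq_along(iv_cols)) {
        if (assoc$dropped[k]) next
        zA <- co$Z[h$A, iv_cols[k]]; zB <- co$Z[h$B, iv_cols[k]]
        fe <- if (include_x) lm(co$T[h$A] ~ zA + co$X[h$A])
              else lm(co$T[h$A] ~ zA)
        expect_equal(assoc$gamma_hat[k], unname(coef(fe)[2]),
                     tolerance = 1e-8)
        expect_equal(assoc$gamma_se[k],
                     unname(sqrt(diag(vcov(fe)))[2]), tolerance = 1e-8)
        fo <- if (link == "linear") {
          if (include_x) lm(co$Y[h$B] ~ zB + co$X[h$B]) else lm(co$Y[h$B] ~ zB)
        } else {
          fml <- if (include_x) co$Y[h$B] ~ zB + co$X[h$B] else co$Y[h$B] ~ zB
          fam <- if (assoc$fallback[k]) poisson("log") else binomial("log")
          suppressWarnings(
            glm(fml, family = fam,
                start = c(log(mean(co$Y[h$B])), rep(0, 1 + include_x)),
                control = glm.control(epsilon = 1e-12, maxit = 100)))
        }
        expect_lt(abs(assoc$Gamma_hat[k] - unname(coef(fo)[2])), 1e-6)
      }
    }
  }
})

test_that("noiseless outcome association is recovered exactly", {
  set.seed(421)
  co <- generate_cohort(small_params(n = 400, K = 80))
  co$Y <- 0.5 + 0.2 * co$Z[, 3]  # deterministic linear in one instrument
  h <- split_halves(400)
  assoc <- per_snp_regressions(co, h$A, h$B, iv_cols = 3, FALSE, "linear")
  expect_equal(assoc$Gamma_hat[1], 0.2, tolerance = 1e-10)
})

test_that("monomorphic instruments are dropped with a warning", {
  set.seed(431)
  co <- generate_cohort(small_params(n = 400, K = 80))
  co$Z[, 5] <- 0L
  h <- split_halves(400)
  expect_warning(
    assoc <- per_snp_regressions(co, h$A, h$B, iv_cols = c(4, 5, 6),
                                 FALSE, "linear"),
    "dropped")
  expect_true(assoc$dropped[2])
  expect_identical(assoc$n_dropped, 1L)
})

test_that("ivw_pool is the hand-computed inverse-variance formula", {
  mk <- function(g, G, se) structure(
    list(gamma_hat = g, gamma_se = rep(0.1, length(g)), Gamma_hat = G,
         Gamma_se = se, dropped = rep(FALSE, length(g)),
         n_dropped = 0L, link = "linear"), class = "snp_associations")
  # single instrument: Wald ratio
  expect_equal(ivw_pool(mk(2, 0.5, 0.1)), 0.25, tolerance = 1e-12)
  # two instruments, equal SEs: (0.1 + 0.8) / (1 + 4) = 0.18
  expect_equal(ivw_pool(mk(c(1, 2), c(0.1, 0.4), c(1, 1))), 0.18,
               tolerance = 1e-12)
  # all instruments dropped -> error
  bad <- mk(1, 0.1, 0.1); bad$dropped <- TRUE
  expect_error(ivw_pool(bad), "usable")
})

test_that("ivw_pool equals origin-constrained weighted least squares", {
  set.seed(441)
  K <- 50
  g <- rnorm(K, 0.05, 0.02)
  G <- 0.1 * g + rnorm(K, 0, 0.005)
  se <- runif(K, 0.002, 0.01)
  assoc <- structure(
    list(gamma_hat = g, gamma_se = rep(0.01, K), Gamma_hat = G,
         Gamma_se = se, dropped = rep(FALSE, K), n_dropped = 0L,
         link = "linear"), class = "snp_associations")
  wls <- lm(G ~ 0 + g, weights = 1 / se^2)
  expect_equal(ivw_pool(assoc), unname(coef(wls)), tolerance = 1e-10)
})

test_that("pooled estimate is invariant to instrument rescaling", {
  set.seed(451)
  co <- generate_cohort(small_params(n = 2000, K = 80))
  set.seed(452)
  h <- split_halves(2000)
  a1 <- per_snp_regressions(co, h$A, h$B, 1:10, FALSE, "linear")
  b1 <- ivw_pool(a1)
  # rescale: gamma and Gamma both scale by 1/c, beta unchanged
  a2 <- a1
  cc <- rep(c(2, 5), 5)
  a2$gamma_hat <- a1$gamma_hat / cc
  a2$Gamma_hat <- a1$Gamma_hat / cc
  a2$Gamma_se <- a1$Gamma_se / cc
  expect_equal(ivw_pool(a2), b1, tolerance = 1e-8)
})

test_that("cross-fit averaging returns the mean of the two directional estimates", {
  set.seed(461)
  co <- generate_cohort(small_params(n = 3000, K = 80))
  set.seed(462)
  rec <- fit_ivw(co, 1:50, include_x = TRUE, link = "linear")
  expect_equal(rec$beta_t, mean(c(rec$aux$beta_ab, rec$aux$beta_ba)),
               tolerance = 1e-12)
  # intercept anchors the risk function at observed prevalence/mean exposure
  expect_equal(rec$intercept, mean(co$Y) - mean(co$T) * rec$beta_t,
               tolerance = 1e-12)
  set.seed(463)
  rec_ll <- fit_ivw(co, 1:50, include_x = TRUE, link = "log")
  expect_equal(rec_ll$intercept, log(mean(co$Y)) - mean(co$T) * rec_ll$beta_t,
               tolerance = 1e-12)
  expect_identical(rec$method, "IVW_LI")
  expect_identical(rec_ll$method, "IVW_LL")
})

test_that("IVW under strong instruments approaches 2SLS on the same half", {
  set.seed(471)
  p <- small_params(n = 20000, K = 80)
  p$weak_mu <- 0.02; p$weak_sigma <- 0.07  # make all 50 analysis IVs strong
  co <- generate_cohort(p)
  set.seed(472)
  rec <- fit_ivw(co, 1:50, include_x = FALSE, link = "linear")
  Zs <- co$Z[, 1:50]
  fs <- fit_first_stage(co$T, Zs)
  sls <- fit_2sls(co$Y, fs)
  # documented approximate equivalence, loose tolerance
  expect_equal(rec$beta_t, sls$beta_t, tolerance = 0.35)
})
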