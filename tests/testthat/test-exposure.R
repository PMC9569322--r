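test_that("exposure_model matches its closed form and limits", {
  expect_equal(exposure_model(0, 1, 0.72, 2.49), 1)
  expect_equal(exposure_model(1, 1, 0.72, 2.49), 0.72)

  # log-domain evaluation as an independent route
  log_eval <- exp(log(1 - 0.72) + 2.49 * log(1 - 0.30)) + 0.72
  expect_equal(exposure_model(0.30, 1, 0.72, 2.49), log_eval)
  expect_equal(exposure_model(0.30, 1, 0.72, 2.49), 0.8352,
               tolerance = 1e-4)

  expect_error(exposure_model(1.2, 1, 0.5, 2), class = "mq_error")
  expect_error(exposure_model(0.5, 0.7, 0.8, 2), class = "mq_error")
})

test_that("exposure_model is monotone and bounded", {
  # strict decrease checked away from q = 1, where the quenchable term
  # underflows below double precision for large L_n
  q <- seq(0, 0.9, 0.05)
  for (L_n in c(0.5, 2.49, 9)) {
    f <- exposure_model(q, 1, 0.6, L_n)
    expect_true(all(diff(f) < 0))
    f_full <- exposure_model(seq(0, 1, 0.05), 1, 0.6, L_n)
    expect_true(all(diff(f_full) <= 0))
    expect_true(all(f_full <= 1 & f_full >= 0.6))
  }
  # more boundary lipids quench harder at any interior fraction
  q_in <- seq(0.05, 0.95, 0.05)
  f2 <- exposure_model(q_in, 1, 0.6, 2)
  f8 <- exposure_model(q_in, 1, 0.6, 8)
  expect_true(all(f8 < f2))
})

test_that("fit_exposure recovers the published parameter sets exactly", {
  for (scen in stn_scenarios()) {
    e <- scen$exposure
    if (is.null(e)) next
    fit <- fit_exposure(make_quenching_series(e))
    expect_lt(rel_err(coef(fit)[["L_n"]], e$L_n), 0.01)
    expect_lt(rel_err(coef(fit)[["F_min"]], e$F_min), 0.01)
  }
})

test_that("round-trip recovery over random parameter draws is tight", {
  set.seed(11)
  for (i in 1:200) {
    L_n <- runif(1, 0.5, 12)
    F_min <- runif(1, 0.4, 0.95)
    fit <- fit_exposure(make_quenching_series(list(L_n = L_n,
                                                   F_min = F_min)))
    expect_lt(rel_err(coef(fit)[["L_n"]], L_n), 0.005)
    expect_lt(rel_err(coef(fit)[["F_min"]], F_min), 0.005)
  }
})

test_that("noisy recovery degrades with the boundary-lipid count", {
  err_at <- function(L_n, F_min) {
    vapply(1:50, function(s) {
      fit <- fit_exposure(make_quenching_series(list(
        L_n = L_n, F_min = F_min, noise_sd = 0.01, seed = s)))
      rel_err(coef(fit)[["L_n"]], L_n)
    }, numeric(1))
  }
  # the two published extremes: StnI without Chol vs the weakly
  # constrained StnII-W43/110F row that carries a +/- 9.7 uncertainty
  e2 <- err_at(2.38, 0.79)
  e9 <- err_at(9.34, 0.89)
  expect_lt(median(e2), 0.15)
  # precision degrades as L_n grows (the high-L_n rows carry the
  # largest published uncertainties)
  expect_lt(median(e2), median(e9))
})

test_that("flat and non-monotone series are flagged", {
  flat <- quenching_series(seq(0, 0.6, 0.1), rep(1, 7))
  fit <- fit_exposure(flat)
  expect_true(all(c("degenerate", "unidentifiable") %in% fit$flags))
  expect_true(is.na(coef(fit)[["L_n"]]))

  wobble <- quenching_series(c(0, 0.1, 0.2, 0.3), c(1, 0.85, 0.93, 0.8))
  expect_true("non_monotone" %in% fit_exposure(wobble)$flags)
})

test_that("stern_volmer is the pointwise reciprocal and an involution", {
  q <- seq(0, 0.6, 0.1)
  ones <- quenching_series(q, rep(1, 7))
  expect_equal(stern_volmer(ones)$ratio, rep(1, 7))

  s <- quenching_series(c(0, 0.2, 0.4), c(1, 0.8, 0.5))
  sv <- stern_volmer(s)
  expect_equal(sv$ratio, c(1, 1.25, 2))

  back <- stern_volmer(sv)
  expect_equal(back$response, s$response)
  expect_s3_class(back, "quenching_series")
})

test_that("classify_quenching partitions static and dynamic components", {
  q <- seq(0, 0.5, 0.1)
  mk <- function(ratio, kind) {
    s <- quenching_series(q, 1 / ratio, response_kind = kind)
    stern_volmer(s)
  }
  # purely dynamic: F0/F == tau0/tau
  r <- 1 + q
  out <- classify_quenching(mk(r, "intensity"), mk(r, "lifetime"))
  expect_equal(out$static_component, rep(1, length(q)))
  expect_equal(out$static_geomean, 1)

  # purely static: lifetimes untouched
  out2 <- classify_quenching(mk(c(1, rep(1.5, 5)), "intensity"),
                             mk(rep(1, 6), "lifetime"))
  expect_equal(out2$static_component[-1], rep(1.5, 5))

  # product rule: F0/F = static * dynamic
  out3 <- classify_quenching(mk(c(1, rep(2, 5)), "intensity"),
                             mk(c(1, rep(1.25, 5)), "lifetime"))
  expect_equal(out3$static_component[-1], rep(1.6, 5))
  expect_equal(out3$static_geomean, 1.6)

  # same length but a different quencher grid must be rejected
  q_other <- seq(0, 0.25, 0.05)
  mismatch <- stern_volmer(quenching_series(q_other, 1 / (1 + q_other),
                                            response_kind = "lifetime"))
  expect_error(classify_quenching(mk(r, "intensity"), mismatch),
               class = "mq_error")
})

test_that("partial accessibility bends the Stern-Volmer plot downward", {
  q <- seq(0, 0.7, 0.05)
  for (scen in stn_scenarios()) {
    e <- scen$exposure
    if (is.null(e)) next
    sv <- 1 / exposure_model(q, 1, e$F_min, e$L_n)
    # the inaccessible population caps the ratio below 1/F_min and
    # below the fully accessible single-population curve
    expect_true(all(sv <= 1 / e$F_min + 1e-12))
    expect_true(all(sv <= (1 - q)^(-e$L_n) + 1e-12))
    # where several lipids are in contact the curvature is visibly
    # downward over the upper part of the measured range
    if (e$L_n >= 2) {
      d2 <- diff(diff(sv))
      expect_true(all(d2[q[seq_along(d2) + 1] >= 0.35] < 0))
    }
  }
})
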