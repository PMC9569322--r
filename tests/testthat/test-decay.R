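test_that("intensity-weighted average lifetime follows the moment formula", {
  expect_equal(intensity_weighted_tau(8, alpha = 1), 8)
  # hand arithmetic: sum(a t^2) = 16.625, sum(a t) = 3.25
  expect_equal(intensity_weighted_tau(c(8, 3, 1.5),
                                      alpha = c(0.2, 0.3, 0.5)),
               16.625 / 3.25)
  expect_equal(intensity_weighted_tau(c(4, 4, 4),
                                      alpha = c(0.1, 0.4, 0.5)), 4)
})

test_that("intensity-weighted tau dominates the amplitude-weighted mean", {
  set.seed(5)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    tau <- sort(runif(k, 0.5, 12), decreasing = TRUE)
    a <- runif(k); a <- a / sum(a)
    ti <- intensity_weighted_tau(tau, alpha = a)
    ta <- amplitude_weighted_tau(tau, alpha = a)
    expect_gte(ti, ta - 1e-12)
    expect_true(ti >= min(tau) && ti <= max(tau))
  }
  # equality iff one effective component
  expect_equal(intensity_weighted_tau(c(6, 6), alpha = c(0.3, 0.7)),
               amplitude_weighted_tau(c(6, 6), alpha = c(0.3, 0.7)))
})

test_that("reconvolution fitting is exact on noise-free decays", {
  d1 <- make_decay(list(alpha = 1, tau = 4, poisson = FALSE))
  f1 <- fit_decay(d1, 1)
  expect_lt(rel_err(f1$lifetimes, 4), 0.01)

  d3 <- make_decay(list(alpha = c(0.2, 0.3, 0.5), tau = c(8, 3, 1.5),
                        poisson = FALSE))
  f3 <- fit_decay(d3, 3)
  expect_lt(max(rel_err(f3$lifetimes, c(8, 3, 1.5))), 0.005)
  expect_lt(max(abs(f3$amplitudes - c(0.2, 0.3, 0.5))), 0.005)
  expect_equal(sum(f3$amplitudes), 1)
  expect_true(all(diff(f3$lifetimes) < 0))
})

test_that("Poisson-noised lifetimes are recovered at realistic counts", {
  taus <- vapply(1:4, function(s) {
    fit_decay(make_decay(list(alpha = c(0.2, 0.3, 0.5),
                              tau = c(8, 3, 1.5), seed = s)), 3)$lifetimes
  }, numeric(3))
  # single-trace scatter is real; the replicate mean is tight
  expect_lt(max(rel_err(rowMeans(taus), c(8, 3, 1.5))), 0.05)
  f1 <- fit_decay(make_decay(list(alpha = 1, tau = 4, seed = 9)), 1)
  expect_lt(rel_err(f1$lifetimes, 4), 0.01)
})

test_that("degenerate and over-parameterized fits are flagged", {
  # scatter-only trace: lifetime collapses to the channel width
  irf_only <- make_decay(list(alpha = 1, tau = 1e-3, poisson = FALSE))
  expect_true("degenerate" %in% fit_decay(irf_only, 1)$flags)

  # two components closer than 20% advise fewer components
  close <- make_decay(list(alpha = c(0.5, 0.5), tau = c(4, 3.5),
                           poisson = FALSE))
  expect_true("component_collapse" %in% fit_decay(close, 2)$flags)

  expect_error(fit_decay(make_decay(list(alpha = 1, tau = 4,
                                         poisson = FALSE)), 5),
               class = "mq_error")
})

test_that("weighted residuals of a well-specified fit are white", {
  dw <- vapply(1:25, function(s) {
    trace <- make_decay(list(alpha = c(0.2, 0.3, 0.5), tau = c(8, 3, 1.5),
                             seed = s, dt = 0.075))
    fit <- fit_decay(trace, 3, weighting = "neyman")
    r <- (trace$counts - fitted(fit)) / sqrt(pmax(fitted(fit), 1))
    durbin_watson(r)
  }, numeric(1))
  expect_true(all(dw > 1.5 & dw < 2.5))
})

test_that("reduced chi-square sits near one for Poisson data", {
  fit <- fit_decay(make_decay(list(alpha = c(0.2, 0.3, 0.5),
                                   tau = c(8, 3, 1.5), seed = 1)), 3)
  expect_gt(fit$gof$chi2_red, 0.9)
  expect_lt(fit$gof$chi2_red, 1.1)
})
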