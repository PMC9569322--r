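test_that("bound_fraction matches the closed form and its limits", {
  # no lipid, no binding
  expect_identical(bound_fraction(0, 1e-7, 60, 1e8), 0)

  # direct evaluation of the isotherm at a representative point
  expect_equal(bound_fraction(1.2e-5, 1e-7, n = 60, K_a = 1e8),
               0.9155711, tolerance = 1e-6)

  # saturating affinity with sites in excess drives theta to 1
  expect_gt(bound_fraction(2 * 60 * 1e-7, 1e-7, n = 60, K_a = 1e15),
            0.999999)

  # invalid inputs signal structured errors
  expect_error(bound_fraction(-1e-6, 1e-7, 60, 1e8), class = "mq_error")
  expect_error(bound_fraction(1e-6, 1e-7, -60, 1e8), class = "mq_error")
  expect_error(bound_fraction(NaN, 1e-7, 60, 1e8), class = "mq_error")
})

test_that("bound_fraction agrees with an independent mass-action solver", {
  P <- 1e-7
  n <- 58
  for (L in seq(1e-7, 3e-5, length.out = 20)) {
    for (K_a in 10^seq(6, 10, length.out = 20)) {
      expect_lt(abs(bound_fraction(L, P, n, K_a) -
                      theta_mass_action(L, P, n, K_a)), 1e-9)
    }
  }
})

test_that("bound_fraction is monotone in lipid and affinity, bounded", {
  P <- 1e-7
  L_grid <- seq(0, 5e-5, length.out = 60)
  for (K_a in c(1e6, 1e8, 1e10)) {
    th <- bound_fraction(L_grid, P, 55, K_a)
    expect_true(all(diff(th) >= -1e-12))
    expect_true(all(th >= 0 & th <= 1))
  }
  Ka_grid <- 10^seq(5, 12, length.out = 40)
  th_ka <- vapply(Ka_grid, function(k) bound_fraction(8e-6, P, 55, k),
                  numeric(1))
  expect_true(all(diff(th_ka) >= -1e-12))
  # theta -> 1 as lipid -> infinity
  expect_gt(bound_fraction(1, P, 55, 1e8), 0.99999)
})

test_that("correct_dilution conserves protein mass and accumulates lipid", {
  none <- correct_dilution(1e-7, 1000, data.frame(added_volume = numeric(),
                                                  lipid_stock = numeric()))
  expect_equal(none$protein_total, 1e-7)
  expect_equal(none$lipid_total, 0)

  one <- correct_dilution(1e-7, 1000,
                          data.frame(added_volume = 100, lipid_stock = 0.02))
  expect_equal(one$protein_total[2], 1e-7 / 1.1)
  expect_equal(one$lipid_total[2], 0.02 * 100 / 1100)  # ~1.818 mM

  # two equal additions equal one addition of double volume
  two <- correct_dilution(1e-7, 1000,
                          data.frame(added_volume = c(50, 50),
                                     lipid_stock = c(0.02, 0.02)))
  expect_equal(two$lipid_total[3], one$lipid_total[2])
  expect_equal(two$protein_total[3], one$protein_total[2])

  # protein mass conserved at every point
  expect_equal(two$protein_total * two$volume,
               rep(1e-7 * 1000, 3))

  expect_error(correct_dilution(1e-7, -1, data.frame(added_volume = 1,
                                                     lipid_stock = 1)),
               class = "mq_error")
  expect_error(correct_dilution(1e-7, 1000,
                                data.frame(added_volume = 0,
                                           lipid_stock = 0.02)),
               class = "mq_error")
})

test_that("fit_binding recovers generating parameters from clean curves", {
  for (scen in stn_scenarios()) {
    b <- scen$binding
    if (is.null(b)) next
    fit <- fit_binding(make_titration(b))
    expect_lt(rel_err(coef(fit)[["n"]], b$n), 0.01)
    expect_lt(rel_err(coef(fit)[["K_a"]], b$K_a), 0.01)
    expect_lt(rel_err(coef(fit)[["F_b_ratio"]], b$F_b_ratio), 0.01)
    expect_length(residuals(fit), 25)
    expect_gte(fit$gof$rmsd, 0)
  }
})

test_that("fit_binding stoichiometry survives 2% multiplicative noise", {
  b <- stn_scenarios("StnI", "chol")$binding
  errs <- vapply(1:100, function(s) {
    fit <- fit_binding(make_titration(modifyList(b, list(noise_cv = 0.02,
                                                         seed = s))))
    rel_err(coef(fit)[["n"]], b$n)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("degenerate and unsaturated titrations are flagged", {
  flat <- titration_curve(rep(1e-7, 8), seq(0, 2e-5, length.out = 8),
                          rep(5, 8))
  fit <- fit_binding(flat)
  expect_true("degenerate" %in% fit$flags)
  expect_equal(coef(fit)[["F_b_ratio"]], 1)

  # truncate the curve far below saturation
  b <- stn_scenarios("StnI", "chol")$binding
  low <- make_titration(modifyList(b, list(lp_grid = seq(0, 12,
                                                         length.out = 8))))
  fit_low <- fit_binding(low)
  expect_true("no_saturation" %in% fit_low$flags)
})

test_that("saturation_lp_ratio reflects the published saturation behavior", {
  b <- stn_scenarios("StnI", "chol")$binding
  fit <- fit_binding(make_titration(b))

  # emission saturates below L/P = 80: theta there is already > 0.95
  expect_gt(bound_fraction(80 * 1e-7, 1e-7, b$n, b$K_a), 0.95)
  expect_lt(saturation_lp_ratio(fit, 0.95, 1e-7), 80)

  # monotone in threshold
  expect_lte(saturation_lp_ratio(fit, 0.5, 1e-7),
             saturation_lp_ratio(fit, 0.99, 1e-7))

  # stronger affinity can only lower the required lipid, checked
  # against brute-force evaluation over a lipid grid
  hi <- list(n = b$n, K_a = b$K_a * 10)
  expect_lte(saturation_lp_ratio(hi, 0.9, 1e-7),
             saturation_lp_ratio(list(n = b$n, K_a = b$K_a), 0.9, 1e-7))
  L_grid <- seq(1e-8, 5e-5, length.out = 500)
  th_lo <- bound_fraction(L_grid, 1e-7, b$n, b$K_a)
  th_hi <- bound_fraction(L_grid, 1e-7, b$n, b$K_a * 10)
  expect_true(all(th_hi >= th_lo - 1e-12))

  expect_error(saturation_lp_ratio(fit, 1.2, 1e-7), class = "mq_error")
})

test_that("interparticle distances follow the surface-density geometry", {
  mono <- mean_interparticle_distance(180, 50, 1, 11)
  expect_equal(mono$center_to_center, sqrt(180 * 50) / 2)
  expect_equal(mono$edge_to_edge, 25.43, tolerance = 0.01)

  octa <- mean_interparticle_distance(180, 50, 8, 11)
  expect_gt(octa$center_to_center, 100)
  expect_equal(octa$center_to_center, 134.16, tolerance = 0.01)

  # doubling the lipid area scales center-to-center by sqrt(2)
  d1 <- mean_interparticle_distance(100, 35, 1, 11)$center_to_center
  d2 <- mean_interparticle_distance(100, 70, 1, 11)$center_to_center
  expect_equal(d2 / d1, sqrt(2))

  # counting only the binding leaflet halves the area
  half <- mean_interparticle_distance(180, 50, 1, 11, leaflet = "outer")
  expect_equal(half$area_per_particle, mono$area_per_particle / 2)

  expect_error(mean_interparticle_distance(180, 20, 1, 11),
               class = "mq_error")
})
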