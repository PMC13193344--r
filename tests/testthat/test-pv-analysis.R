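make_obs <- function(rwc, psi, sw = 0.12, dw = 0.04, la = 0.001)
  suppressWarnings(pv_curve_observation("t", dw + rwc * (sw - dw), psi,
                                        sw, dw, la))

test_that("relative water content follows (FW - DW)/(SW - DW)", {
  obs <- suppressWarnings(pv_curve_observation(
    "x", fresh_mass = c(0.12, 0.08, 0.04, 0.1, 0.06, 0.11),
    psi = c(0, -0.5, -1, -1.5, -2, -2.5) - 0.01,
    saturated_mass = 0.12, dry_mass = 0.04, leaf_area = 0.001))
  rwc <- compute_rwc(obs)
  expect_equal(rwc[1], 1)    # FW = SW
  expect_equal(rwc[3], 0)    # FW = DW
  expect_equal(rwc[2], 0.5)  # midpoint: linearity
  bad <- obs; bad$saturated_mass <- bad$dry_mass
  expect_error(compute_rwc(bad), "saturated mass")
})

test_that("segmentation finds the osmotic line and degenerate cases", {
  # perfectly linear -1/psi vs RWC: breakpoint at the series start
  rwc <- seq(0.95, 0.55, by = -0.05)
  y <- 0.1 + 0.6 * rwc
  seg <- segment_pv_curve(rwc, -1 / y, pv_fit_config())
  expect_equal(seg$breakpoint, 1)
  expect_equal(seg$slope, 0.6, tolerance = 1e-9)
  expect_equal(seg$intercept, 0.1, tolerance = 1e-9)
  expect_true(any(grepl("no turgid region", seg$flags)))

  # all-equal psi cannot be segmented
  expect_error(segment_pv_curve(rwc, rep(-1, length(rwc))), "equal")

  # breakpoint invariant to appending duplicated final points
  tr <- pv_ground_truth(noise_sd_psi = 0, noise_sd_mass = 0)
  obs <- simulate_pv_curve(tr)
  rwc <- compute_rwc(obs); psi <- obs$psi
  s1 <- segment_pv_curve(rwc, psi, pv_fit_config())
  n <- length(rwc)
  s2 <- segment_pv_curve(c(rwc, rwc[n], rwc[n]), c(psi, psi[n], psi[n]),
                         pv_fit_config())
  expect_equal(rwc[s1$breakpoint], c(rwc, rwc[n], rwc[n])[s2$breakpoint])
  expect_equal(s1$slope, s2$slope, tolerance = 1e-9)
})

test_that("alternative breakpoint methods run and agree on clean curves", {
  tr <- pv_ground_truth(noise_sd_psi = 0, noise_sd_mass = 0)
  obs <- simulate_pv_curve(tr)
  rwc <- compute_rwc(obs); psi <- obs$psi
  s_inc <- segment_pv_curve(rwc, psi,
                            pv_fit_config(breakpoint_method = "incremental_r2"))
  s_rss <- segment_pv_curve(rwc, psi,
                            pv_fit_config(breakpoint_method = "piecewise_rss"))
  s_dry <- segment_pv_curve(rwc, psi, pv_fit_config())
  expect_gt(s_inc$r2, 0.99)
  expect_gt(s_rss$r2, 0.9)
  expect_equal(s_dry$r2, 1, tolerance = 1e-12)
})

test_that("elastic modulus and capacitance arithmetic follow the formulas", {
  # turgor dropping linearly 1.2 -> 0 MPa as RWC goes 1.00 -> 0.88,
  # evaluated at RWC 0.94 gives (1.2 / 0.12) * 0.94 = 9.4 MPa
  slope <- 1.2 / 0.12
  expect_equal(slope * 0.94, 9.4)

  # capacitance: dRWC/dpsi = 0.10 MPa^-1, DW/LA = 40 g m^-2, SW/DW = 3,
  # M = 18.015 -> 0.10 * 40 * 3 / 18.015
  expect_equal(0.10 * 40 * 3 / 18.015, 0.6661116, tolerance = 1e-6)

  # same arithmetic through the estimator: a synthetic drydown with
  # DW/LA = 40 and SW/DW = 3, fixed 4-point initial window, graphical path
  tr <- pv_ground_truth(noise_sd_psi = 0, noise_sd_mass = 0)
  obs <- simulate_pv_curve(tr)
  cfg <- pv_fit_config(estimator = "graphical", initial_slope_points = 4,
                       psi_floor = attr(obs, "psi_floor"))
  p <- derive_pv_parameters(obs, cfg)
  rwc <- compute_rwc(obs)
  secant <- stats::coef(stats::lm(rwc[1:4] ~ obs$psi[1:4]))[2]
  expect_equal(p$c_bulk, unname(secant) * 40 * 3 / 18.015, tolerance = 1e-9)
})

test_that("noiseless forward-model curves are recovered near-exactly", {
  for (eps in c(5, 15)) for (ft in c(-0.8, -1.8)) for (awf in c(0.1, 0.4)) {
    tr <- pv_ground_truth(psi_ft = ft, epsilon = eps, awf = awf,
                          noise_sd_psi = 0, noise_sd_mass = 0)
    obs <- simulate_pv_curve(tr)
    p <- derive_pv_parameters(obs,
                              pv_fit_config(psi_floor = attr(obs, "psi_floor")))
    expect_equal(p$psi_ft, ft, tolerance = 1e-6)
    expect_equal(p$awf, awf, tolerance = 1e-6)
    expect_equal(p$psi_tlp, tr$psi_tlp, tolerance = 1e-6)
    expect_equal(p$rwc_tlp, tr$rwc_tlp, tolerance = 1e-6)
  }
})

test_that("PV parameter invariants hold across noisy simulated leaves", {
  for (i in 1:25) {
    tr <- pv_ground_truth(seed = i)
    obs <- simulate_pv_curve(tr)
    p <- derive_pv_parameters(obs,
                              pv_fit_config(psi_floor = attr(obs, "psi_floor")))
    expect_lt(p$psi_tlp, 0)
    expect_lte(p$psi_tlp, p$psi_ft)
    expect_lt(p$psi_ft, 0)
    expect_gte(p$awf, 0)
    expect_lt(p$awf, p$rwc_tlp)
    expect_lt(p$rwc_tlp, 1)
    expect_gt(p$epsilon, 0)
    expect_gt(p$c_bulk, 0)
  }
})

test_that("recovered elastic modulus is monotone in the generating modulus", {
  rec <- sapply(c(5, 10, 15, 20), function(eps) {
    tr <- pv_ground_truth(epsilon = eps, noise_sd_psi = 0, noise_sd_mass = 0)
    obs <- simulate_pv_curve(tr)
    derive_pv_parameters(obs,
                         pv_fit_config(psi_floor = attr(obs, "psi_floor")))$epsilon
  })
  expect_true(all(diff(rec) > 0))
})

test_that("mass rescaling leaves ratios invariant and scales capacitance", {
  tr <- pv_ground_truth(noise_sd_psi = 0, noise_sd_mass = 0)
  obs <- simulate_pv_curve(tr)
  cfg <- pv_fit_config(psi_floor = attr(obs, "psi_floor"))
  p1 <- derive_pv_parameters(obs, cfg)
  obs2 <- obs
  obs2$fresh_mass <- 2 * obs$fresh_mass
  obs2$saturated_mass <- 2 * obs$saturated_mass
  obs2$dry_mass <- 2 * obs$dry_mass
  p2 <- derive_pv_parameters(obs2, cfg)
  expect_equal(p2$psi_tlp, p1$psi_tlp, tolerance = 1e-9)
  expect_equal(p2$psi_ft, p1$psi_ft, tolerance = 1e-9)
  expect_equal(p2$awf, p1$awf, tolerance = 1e-9)
  expect_equal(p2$epsilon, p1$epsilon, tolerance = 1e-9)
  # doubling all masses doubles DW/LA while SW/DW is unchanged
  expect_equal(p2$c_bulk, 2 * p1$c_bulk, tolerance = 1e-9)
})

test_that("parameter tabulation survives failing records", {
  tr <- pv_ground_truth(noise_sd_psi = 0, noise_sd_mass = 0)
  good <- simulate_pv_curve(tr)
  bad <- good
  bad$psi <- rep(-1, length(bad$psi))  # unsegmentable
  bad$leaf_id <- "bad"
  tab <- pv_parameter_table(list(good, bad),
                            pv_fit_config(psi_floor = attr(good, "psi_floor")))
  expect_equal(nrow(tab), 2)
  expect_false(is.na(tab$psi_tlp[1]))
  expect_true(is.na(tab$psi_tlp[2]))
  expect_match(tab$flags[2], "equal")
})
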