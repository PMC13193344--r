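test_that("generators are bit-reproducible given a seed", {
  t1 <- pv_ground_truth(seed = 3)
  expect_identical(simulate_pv_curve(t1)$psi, simulate_pv_curve(t1)$psi)
  s1 <- simulate_light_curve(0.06, 25, 0.7, 1.5, "assimilation", seed = 4)
  s2 <- simulate_light_curve(0.06, 25, 0.7, 1.5, "assimilation", seed = 4)
  expect_identical(s1$response, s2$response)
  expect_identical(ape::write.tree(simulate_tree(10, seed = 5)),
                   ape::write.tree(simulate_tree(10, seed = 5)))
  tr <- simulate_tree(10, seed = 5)
  expect_identical(simulate_bm_traits(tr, seed = 6),
                   simulate_bm_traits(tr, seed = 6))
  expect_identical(simulate_climate(10, seed = 7),
                   simulate_climate(10, seed = 7))
})

test_that("the noiseless PV forward model honours its closed forms", {
  tr <- pv_ground_truth(noise_sd_psi = 0, noise_sd_mass = 0)
  obs <- simulate_pv_curve(tr)
  rwc <- compute_rwc(obs)
  # psi at full turgor is zero: turgor cancels the osmotic potential
  expect_equal(obs$psi[1], 0)
  expect_equal(rwc[1], 1)
  # below the turgor loss point, -1/psi is exactly linear in RWC
  post <- obs$psi < tr$psi_tlp
  fit <- stats::lm(I(-1 / obs$psi[post]) ~ rwc[post])
  expect_lt(max(abs(stats::residuals(fit))), 1e-10)
  # and the line is the van't Hoff dilution: psi = psi_ft (1-awf)/(rwc-awf)
  expect_equal(obs$psi[post],
               tr$psi_ft * (1 - tr$awf) / (rwc[post] - tr$awf),
               tolerance = 1e-10)
  # successive psi steps follow the protocol spacing
  expect_true(all(abs(diff(obs$psi)) > 0.19 & abs(diff(obs$psi)) < 0.31))
  # generator output passes the reader invariants unmodified
  expect_length(validate_pv_curve_observation(obs), 0)
  # degenerate parameter combinations are rejected
  expect_error(pv_ground_truth(epsilon = 1, psi_ft = -1.2), "epsilon")
  expect_error(pv_ground_truth(awf = 1), "awf")
})

test_that("light-curve generator matches the model at PPFD 0 and in theta", {
  s <- simulate_light_curve(0.06, 25, 0.7, 1.5, "assimilation", noise_sd = 0)
  expect_equal(s$response[s$ppfd == 0], -1.5)
  g <- simulate_light_curve(8e-4, 0.25, 0.7, 0.02, "conductance",
                            noise_sd = 0)
  expect_equal(g$response[g$ppfd == 0], 0.02)
  # increasing curvature raises the response at intermediate light
  mid <- function(th) nrh_response(400, 0.06, 25, th, 1.5, "assimilation")
  expect_true(all(diff(sapply(c(0.3, 0.6, 0.9), mid)) > 0))
  expect_error(simulate_light_curve(0.06, 25, 1.4, 1.5), "theta")
})

test_that("pure-birth trees are ultrametric with unit depth", {
  for (seed in 1:5) {
    tr <- simulate_tree(15, seed = seed)
    expect_true(attr(tr, "ultrametric"))
    expect_equal(attr(tr, "depth"), 1, tolerance = 1e-9)
    expect_equal(ape::Ntip(tr), 15)
  }
})

test_that("BM trait draws have the lambda-structured covariance", {
  tr <- simulate_tree(5, seed = 8)
  # root state shifts add a constant (same substream seed)
  x0 <- simulate_bm_traits(tr, root_state = 0, seed = 9)
  x5 <- simulate_bm_traits(tr, root_state = 5, seed = 9)
  expect_equal(x5, x0 + 5)
  # empirical tip covariance approaches sigma2 * C_lambda entrywise
  lam <- 0.6
  draws <- t(vapply(1:2000,
                    function(i) simulate_bm_traits(tr, sigma2 = 2,
                                                   lambda = lam,
                                                   seed = 10000 + i),
                    numeric(5)))
  emp <- stats::cov(draws)
  theo <- 2 * phylo_covariance(tr, lam)
  expect_lt(max(abs(emp - theo)) / max(theo), 0.1)
})

test_that("climate generator plants a one-factor structure", {
  # zero noise: exactly rank one
  cm0 <- simulate_climate(20, noise_sd = 0, seed = 11)
  expect_equal(qr(cm0)$rank, 1)
  expect_equal(ncol(cm0), 19)
  # permuting variables permutes the signal columns identically
  # (checked without noise, which is drawn per cell)
  l <- c(1, -0.6, 0.4, -0.8, 0.7, 0.5, 0.6, 0.9, 0.3, 0.8,
         0.4, 1, 0.7, -0.7, 0.8, 0.6, 0.9, -0.5, 0.5)
  perm <- rev(seq_along(l))
  cmp <- simulate_climate(20, loadings = l[perm], noise_sd = 0, seed = 11)
  cmo <- simulate_climate(20, loadings = l, noise_sd = 0, seed = 11)
  expect_equal(unname(cmp), unname(cmo)[, perm], ignore_attr = TRUE)
  # expected PC1 share from the analytic variance decomposition
  cm <- simulate_climate(200, seed = 12)
  share_theory <- sum(l^2) / (sum(l^2) + 19 * 0.3^2)
  pc <- climate_pca(cm)
  # compare on the covariance (unstandardised) decomposition implied share
  tot <- sum(apply(cm, 2, stats::var))
  pc1_raw <- max(eigen(stats::cov(cm), only.values = TRUE)$values) / tot
  expect_lt(abs(pc1_raw - share_theory), 0.05)
})

test_that("the simulated study is complete and internally consistent", {
  st <- simulate_study(seed = 2, n_replicates = 2)
  expect_equal(nrow(st$populations), 13)
  expect_equal(sort(unique(st$populations$group)),
               sort(c("C3-2x", "C3-C4-2x", "C4-2x", "C4-6x", "C4-12x")))
  expect_equal(length(st$pv_curves), 13 * 2)
  expect_equal(length(st$light_assim), 13 * 2)
  expect_true(attr(st$tree, "ultrametric"))
  expect_setequal(st$tree$tip.label, rownames(st$populations))
  expect_setequal(rownames(st$climate), rownames(st$populations))
  # C4 populations carry C4-range isotope values
  is_c4 <- grepl("^C4", st$populations$group)
  expect_true(all(st$populations$d13c[is_c4] > -17))
  expect_true(all(st$populations$d13c[!is_c4] < -17))
  # all PV observations validate
  for (o in st$pv_curves) expect_length(validate_pv_curve_observation(o), 0)
})
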