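test_that("lambda transform scales only the shared path lengths", {
  tr <- read_newick("((A:1,B:1):1,C:2);", text = TRUE)
  C0 <- phylo_covariance(tr, 0)
  expect_equal(C0, diag(2, 3, 3), ignore_attr = TRUE)
  C1 <- phylo_covariance(tr, 1)
  expect_equal(C1["A", "B"], 1)
  expect_equal(C1["A", "C"], 0)
  expect_equal(diag(C1), c(A = 2, B = 2, C = 2))
  C5 <- phylo_covariance(tr, 0.5)
  off <- upper.tri(C1)
  expect_equal(C5[off], 0.5 * C1[off])
  expect_equal(diag(C5), diag(C1))
  expect_error(phylo_covariance(tr, 1.2), "lambda")
})

test_that("PGLS on a star tree reproduces ordinary least squares", {
  set.seed(42)
  star <- ape::read.tree(
    text = paste0("(", paste(sprintf("t%d:1", 1:20), collapse = ","), ");"))
  d <- data.frame(x = rnorm(20), row.names = star$tip.label)
  d$y <- 1 + 2 * d$x + rnorm(20)
  ols <- stats::lm(y ~ x, d)
  for (lam in c(0, 0.5, 1)) {
    f <- pgls_fit(y ~ x, d, star, lambda = lam)
    expect_equal(f$coefficients$estimate, unname(stats::coef(ols)),
                 tolerance = 1e-12)
  }
  # and the GLS r^2 equals the OLS r^2 there
  f1 <- pgls_fit(y ~ x, d, star, lambda = 1)
  expect_equal(f1$r2, summary(ols)$r.squared, tolerance = 1e-12)
  expect_equal(f1$adj_r2, summary(ols)$adj.r.squared, tolerance = 1e-12)
})

test_that("lambda = 1 slope equals the independent-contrasts oracle", {
  for (seed in 1:20) {
    tr <- simulate_tree(30, seed = 100 + seed)
    x <- simulate_bm_traits(tr, seed = 200 + seed)
    y <- 0.7 * x + simulate_bm_traits(tr, sigma2 = 0.5, seed = 300 + seed)
    d <- data.frame(x = x, y = y, row.names = names(x))
    f <- pgls_fit(y ~ x, d, tr, lambda = 1)
    expect_equal(f$coefficients["x", "estimate"], pic_slope(tr, y, x),
                 tolerance = 1e-8)
  }
})

test_that("profile likelihood at the ML lambda dominates a grid", {
  tr <- simulate_tree(40, seed = 11)
  x <- simulate_bm_traits(tr, lambda = 0.6, seed = 12)
  y <- 0.5 * x + simulate_bm_traits(tr, sigma2 = 0.3, lambda = 0.6,
                                    seed = 13)
  d <- data.frame(x = x, y = y, row.names = names(x))
  f <- pgls_fit(y ~ x, d, tr, lambda = "ml")
  for (lam in seq(0, 1, by = 0.05)) {
    g <- pgls_fit(y ~ x, d, tr, lambda = lam)
    expect_gte(f$loglik, g$loglik - 1e-7)
  }
  expect_true(f$lambda >= 0 && f$lambda <= 1)
  expect_lte(f$adj_r2, f$r2)
})

test_that("ML lambda agrees with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(40, seed = 5)
  x <- simulate_bm_traits(tr, seed = 6)
  y <- 0.4 * x + simulate_bm_traits(tr, sigma2 = 0.4, lambda = 0.7,
                                    seed = 7)
  d <- data.frame(x = x, y = y, row.names = names(x))
  f <- pgls_fit(y ~ x, d, tr)
  # corPhyl emits an informational note about row ordering; rows are
  # already in tip order here
  g <- suppressWarnings(
    nlme::gls(y ~ x, data = d, method = "ML",
              correlation = ape::corPagel(0.5, tr, form = ~1)))
  lam_nlme <- unname(stats::coef(g$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(f$lambda, lam_nlme, tolerance = 1e-3)
  expect_equal(f$coefficients$estimate, unname(stats::coef(g)),
               tolerance = 1e-4)
})

test_that("GLS-rotated residuals are orthogonal to the rotated design", {
  tr <- simulate_tree(25, seed = 31)
  x <- simulate_bm_traits(tr, seed = 32)
  y <- 1 + x + simulate_bm_traits(tr, sigma2 = 0.2, seed = 33)
  d <- data.frame(x = x, y = y, row.names = names(x))
  f <- pgls_fit(y ~ x, d, tr)
  C <- phylo_covariance(tr, f$lambda)
  R <- chol(C)
  Xr <- backsolve(R, cbind(1, x[tr$tip.label]), transpose = TRUE)
  expect_lt(max(abs(crossprod(Xr, f$residuals))), 1e-8)
})

test_that("BM ancestral states solve the joint likelihood", {
  # two equal branches: the root state is the tip mean
  tt <- read_newick("(A:1,B:1);", text = TRUE)
  a <- ancestral_states_bm(tt, c(A = 0, B = 2))
  expect_equal(a$root_state, 1)
  expect_equal(a$states$lower95, a$states$state - 1.96 * sqrt(a$states$var))
  expect_equal(a$states$upper95, a$states$state + 1.96 * sqrt(a$states$var))

  # brute-force joint-likelihood maximisation oracle on small random trees
  for (seed in 1:25) {
    tr <- simulate_tree(5, seed = 400 + seed)
    x <- simulate_bm_traits(tr, seed = 500 + seed)
    a <- ancestral_states_bm(tr, x)
    expect_equal(a$states$state, asr_brute_force(tr, x), tolerance = 1e-8)
  }
})

test_that("ancestral states match the re-rooting implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(12, seed = 77)
  x <- simulate_bm_traits(tr, seed = 78)
  a <- ancestral_states_bm(tr, x)
  fa <- suppressWarnings(phytools::fastAnc(tr, x))
  expect_equal(a$states$state, unname(as.numeric(fa)), tolerance = 1e-10)
})

test_that("reconstruction is linear in the trait and flags degeneracy", {
  tr <- simulate_tree(10, seed = 55)
  x <- simulate_bm_traits(tr, seed = 56)
  a1 <- ancestral_states_bm(tr, x)
  a2 <- ancestral_states_bm(tr, 3 * x + 2)
  expect_equal(a2$states$state, 3 * a1$states$state + 2, tolerance = 1e-10)
  # states lie within the tip range for BM on a tree without singletons
  expect_true(all(a1$states$state >= min(x) & a1$states$state <= max(x)))
  const <- ancestral_states_bm(tr, stats::setNames(rep(4, 10), tr$tip.label))
  expect_true(const$degenerate)
  expect_equal(const$states$state, rep(4, nrow(const$states)))
  expect_equal(const$sigma2, 0)
})

test_that("incomplete traits and zero branches are rejected", {
  tr <- simulate_tree(6, seed = 9)
  x <- simulate_bm_traits(tr, seed = 10)
  expect_error(ancestral_states_bm(tr, x[-1]), "named|cover")
  xm <- x; xm[2] <- NA
  expect_error(ancestral_states_bm(tr, xm), "complete")
  trz <- tr; trz$edge.length[1] <- 0
  expect_error(ancestral_states_bm(trz, x), "zero-length")
})
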