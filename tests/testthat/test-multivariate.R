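test_that("Kruskal-Wallis H matches the hand-ranked oracle", {
  # ranks 1..9, rank sums 6, 15, 24: H = 12/(9*10)*(12+75+192) - 3*10 = 7.2
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(kw$p_value, stats::pchisq(7.2, 2, lower.tail = FALSE))
  # H is a rank statistic: invariant under strictly monotone transforms
  kw2 <- kruskal_wallis(list(exp(c(1, 2, 3)), exp(c(4, 5, 6)),
                             exp(c(7, 8, 9))))
  expect_equal(kw2$H, kw$H)
  kw3 <- kruskal_wallis(lapply(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)),
                               function(v) atan(v / 2)))
  expect_equal(kw3$H, kw$H)
})

test_that("ties and degenerate groups are handled", {
  # identical groups: equal rank sums, H = 0
  kw <- suppressWarnings(kruskal_wallis(list(c(1, 2), c(1, 2))))
  expect_equal(kw$H, 0, tolerance = 1e-12)
  # all observations identical: tie correction degenerates, defined H = 0
  kw0 <- suppressWarnings(kruskal_wallis(list(c(3, 3), c(3, 3))))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p_value, 1)
  # tie-corrected H agrees with the no-ties closed form on untied data
  x <- list(c(1.1, 5.2, 2.3), c(4.4, 0.5), c(9.1, 3.3, 6.6))
  pooled <- unlist(x); N <- length(pooled)
  rk <- rank(pooled); gl <- rep(seq_along(x), lengths(x))
  Hclosed <- 12 / (N * (N + 1)) *
    sum(tapply(rk, gl, sum)^2 / lengths(x)) - 3 * (N + 1)
  expect_equal(kruskal_wallis(x)$H, Hclosed, tolerance = 1e-12)
  expect_warning(kruskal_wallis(list(1, 2:3)), "fewer than 5")
  expect_error(kruskal_wallis(list(1:3)), "2 non-empty")
})

test_that("Dunn post hoc and letter display encode the significance graph", {
  set.seed(1)
  g <- list(A = rnorm(10, 0), B = rnorm(10, 0.5), C = rnorm(10, 8))
  ph <- dunn_posthoc(g)
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_adj >= ph$p))
  cld <- compact_letter_display(g)
  expect_equal(cld[["A"]], cld[["B"]])     # A,B share a letter
  expect_false(grepl(cld[["C"]], cld[["A"]], fixed = TRUE))

  # no pair significant: everything shares one letter
  g0 <- list(A = rnorm(6), B = rnorm(6), C = rnorm(6))
  expect_equal(unname(compact_letter_display(g0)), rep("a", 3))

  # all pairs significant: distinct letters
  g3 <- list(A = 1:8, B = 101:108, C = 1001:1008)
  expect_equal(unname(compact_letter_display(g3)), c("a", "b", "c"))

  # chain case A != C only: a, ab, b
  gc <- list(A = c(1, 2, 1.5, 2.5, 1.2, 2.2, 1.8, 1.1),
             B = c(4, 5, 4.5, 5.5, 4.2, 5.2, 4.8, 4.1),
             C = c(8, 9, 8.5, 9.5, 8.2, 9.2, 8.8, 8.1))
  ph <- dunn_posthoc(gc)
  sig <- ph$p_adj < 0.05
  if (sum(sig) == 1 && ph$group1[sig] == "A" && ph$group2[sig] == "C") {
    expect_equal(unname(compact_letter_display(gc)), c("a", "ab", "b"))
  }
  # permutation equivariance: relabelling groups permutes the letters
  cldp <- compact_letter_display(g3[c("C", "A", "B")])
  expect_equal(unname(cldp), c("a", "b", "c"))
  expect_equal(names(cldp), c("C", "A", "B"))

  expect_equal(unname(compact_letter_display(list(A = 1:5))), "a")

  # Mann-Whitney alternative runs through the same surface
  cmw <- compact_letter_display(g3, method = "mann_whitney")
  expect_equal(unname(cmw), c("a", "b", "c"))
})

test_that("standardised PCA behaves on planted and degenerate inputs", {
  set.seed(3)
  # two perfectly correlated variables: PC1 explains all variance
  z <- rnorm(30)
  p2 <- climate_pca(cbind(a = z, b = 2 * z))
  expect_equal(p2$prop_var[1], 1, tolerance = 1e-12)

  # proportions always sum to one
  x <- matrix(rnorm(25 * 7), 25, 7,
              dimnames = list(NULL, paste0("v", 1:7)))
  p <- climate_pca(x)
  expect_equal(sum(p$prop_var), 1, tolerance = 1e-12)

  # reconstruction: scores %*% t(loadings) returns the standardised matrix
  xs <- scale(x)
  expect_equal(p$scores %*% t(p$loadings), xs, tolerance = 1e-10,
               ignore_attr = TRUE)

  # deterministic orientation: largest-magnitude loading positive
  expect_true(all(apply(p$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))

  # zero-variance columns are dropped with a warning
  xz <- cbind(x, const = 1)
  expect_warning(pz <- climate_pca(xz), "zero-variance")
  expect_equal(pz$dropped, "const")
  expect_error(climate_pca(x[1:2, ]), "3 sites")
})

test_that("the planted climate factor is recovered by PC1", {
  cm <- simulate_climate(200, seed = 2)
  pc <- climate_pca(cm)
  l <- attr(cm, "loadings")
  # standardisation rescales columns, so compare after mapping the
  # loadings back to the raw scale
  raw <- pc$loadings[, 1] * apply(cm, 2, stats::sd)
  congruence <- abs(sum(raw * l) / sqrt(sum(raw^2) * sum(l^2)))
  expect_gt(congruence, 0.99)
  expect_gt(pc$prop_var[1], pc$prop_var[2])
})
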