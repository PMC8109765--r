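test_that("perfect monotone relationships give rho = +/-1 with exact p", {
  X <- cbind(m1 = c(1, 2, 3, 4, 5))
  Y <- cbind(m1 = c(5, 4, 3, 2, 1))
  tabs <- tables_from_matrices(X, Y)
  net <- spearman_network(tabs$blood, tabs$csf)
  expect_equal(unname(net$rho[1, 1]), -1)
  # two of the 120 permutations of 5 ranks reach |rho| = 1
  expect_equal(unname(net$pvals[1, 1]), 2 / 120)

  self <- tables_from_matrices(X, X)
  net2 <- spearman_network(self$blood, self$csf)
  expect_equal(unname(net2$rho[1, 1]), 1)
})

test_that("exact small-n p-values match brute-force permutation enumeration", {
  set.seed(20)
  for (n in 4:7) {
    for (rep in 1:6) {
      x <- rnorm(n)
      y <- rnorm(n)
      tabs <- tables_from_matrices(cbind(m1 = x), cbind(m1 = y))
      net <- spearman_network(tabs$blood, tabs$csf)
      expect_equal(unname(net$pvals[1, 1]), brute_spearman_p(x, y),
                   tolerance = 1e-12,
                   label = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("exact p-values handle ties through average ranks", {
  x <- c(1, 1, 2, 3, 4)
  y <- c(2, 5, 1, 1, 3)
  tabs <- tables_from_matrices(cbind(m1 = x), cbind(m1 = y))
  net <- spearman_network(tabs$blood, tabs$csf)
  expect_equal(unname(net$rho[1, 1]),
               suppressWarnings(cor(x, y, method = "spearman")))
  expect_equal(unname(net$pvals[1, 1]), brute_spearman_p(x, y),
               tolerance = 1e-12)
})

test_that("large-n p-values use the t approximation", {
  set.seed(21)
  n <- 30
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  tabs <- tables_from_matrices(cbind(m1 = x), cbind(m1 = y))
  net <- spearman_network(tabs$blood, tabs$csf)
  r <- unname(net$rho[1, 1])
  tt <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(unname(net$pvals[1, 1]), 2 * pt(-abs(tt), n - 2),
               tolerance = 1e-12)
})

test_that("rho is invariant under strictly increasing transforms", {
  set.seed(22)
  X <- matrix(rlnorm(8 * 3), 8, dimnames = list(NULL, paste0("m", 1:3)))
  Y <- matrix(rlnorm(8 * 3), 8, dimnames = list(NULL, paste0("m", 1:3)))
  t1 <- tables_from_matrices(X, Y)
  X2 <- X; X2[, 2] <- exp(X2[, 2])          # monotone transform of m2
  t2 <- tables_from_matrices(X2, Y)
  n1 <- spearman_network(t1$blood, t1$csf)
  n2 <- spearman_network(t2$blood, t2$csf)
  expect_equal(n1$rho, n2$rho, tolerance = 1e-12)
  expect_equal(n1$pvals, n2$pvals, tolerance = 1e-12)
})

test_that("the reverse-direction network is the transpose", {
  set.seed(23)
  X <- matrix(rnorm(6 * 4), 6, dimnames = list(NULL, paste0("m", 1:4)))
  Y <- matrix(rnorm(6 * 4), 6, dimnames = list(NULL, paste0("m", 1:4)))
  tabs <- tables_from_matrices(X, Y)
  fwd <- spearman_network(tabs$blood, tabs$csf)
  # swap the roles: CSF-to-blood
  rev <- spearman_network(tabs$csf, tabs$blood)
  expect_equal(rev$rho, t(fwd$rho), tolerance = 1e-12)
  expect_equal(rev$pvals, t(fwd$pvals), tolerance = 1e-12)
})

test_that("degenerate inputs are reported", {
  X <- cbind(m1 = c(2, 2, 2, 2, 2))
  Y <- cbind(m1 = c(1, 3, 2, 5, 4))
  tabs <- tables_from_matrices(X, Y)
  expect_warning(net <- spearman_network(tabs$blood, tabs$csf),
                 "zero-variance")
  expect_equal(unname(net$rho[1, 1]), 0)
  expect_equal(unname(net$pvals[1, 1]), 1)

  bad <- tables_from_matrices(cbind(m1 = 1:5), cbind(m1 = 1:5))
  bad$csf$sample_id <- rev(bad$csf$sample_id)
  expect_error(spearman_network(bad$blood, bad$csf), "same samples")
  two <- tables_from_matrices(cbind(m1 = 1:2), cbind(m1 = 1:2))
  expect_error(spearman_network(two$blood, two$csf), "at least 3")
})

test_that("the significance filter masks the adjacency at alpha", {
  set.seed(24)
  X <- matrix(rnorm(5 * 3), 5, dimnames = list(NULL, paste0("m", 1:3)))
  Y <- matrix(rnorm(5 * 3), 5, dimnames = list(NULL, paste0("m", 1:3)))
  Y[, 1] <- -X[, 1]                       # one perfectly anti-monotone pair
  tabs <- tables_from_matrices(X, Y)
  net <- spearman_network(tabs$blood, tabs$csf)

  f <- significance_filter(net, alpha = 0.05)
  expect_equal(unname(f$A[1, 1]), -1)     # exact p = 1/60 < 0.05 retained
  expect_true(all(f$A[f$pvals > 0.05] == 0))

  all_rho <- significance_filter(net, alpha = 1)
  expect_equal(all_rho$A, net$rho)

  none <- net
  none$pvals[] <- 1
  expect_true(all(significance_filter(none, 0.05)$A == 0))
})

test_that("pair harmonization takes the union and carries each group's rho", {
  set.seed(25)
  X <- matrix(rnorm(5 * 3), 5, dimnames = list(NULL, paste0("m", 1:3)))
  Y <- matrix(rnorm(5 * 3), 5, dimnames = list(NULL, paste0("m", 1:3)))
  Ywt <- Y; Ywt[, 2] <- X[, 1]            # significant only in "WT"
  wt_t <- tables_from_matrices(X, Ywt)
  ap_t <- tables_from_matrices(X, Y, genotype = "APP")
  wt <- significance_filter(spearman_network(wt_t$blood, wt_t$csf))
  ap <- significance_filter(spearman_network(ap_t$blood, ap_t$csf))

  hp <- harmonize_pairs(wt, ap)
  expect_identical(hp$pairs1[, c("blood", "csf")],
                   hp$pairs2[, c("blood", "csf")])
  expect_true(any(hp$pairs1$blood == "m1" & hp$pairs1$csf == "m2"))
  i <- which(hp$pairs2$blood == "m1" & hp$pairs2$csf == "m2")
  expect_equal(hp$pairs2$rho[i], unname(ap$rho["m1", "m2"]))

  # pair significant in both appears exactly once per list
  expect_false(any(duplicated(hp$pairs1[, c("blood", "csf")])))

  # no significant pairs anywhere: both lists empty
  none1 <- wt; none1$A[] <- 0
  none2 <- ap; none2$A[] <- 0
  hp0 <- harmonize_pairs(none1, none2)
  expect_equal(nrow(hp0$pairs1), 0)
  expect_equal(nrow(hp0$pairs2), 0)

  other <- ap
  other$blood_names <- paste0("x", other$blood_names)
  expect_error(harmonize_pairs(wt, other), "name lists")
})

test_that("the Fisher-z differential test matches the closed formula", {
  eq <- differential_correlations(
    data.frame(blood = "a", csf = "b", rho = 0.5),
    data.frame(blood = "a", csf = "b", rho = 0.5), n1 = 10, n2 = 10)
  expect_equal(eq$z_stat, 0)
  expect_equal(eq$p_value, 1)
  expect_false(eq$significant)

  # strongly discordant pair (APP 0.89 vs WT -0.43) at n = 10 per group
  d <- differential_correlations(
    data.frame(blood = "acetate", csf = "taurine", rho = 0.89),
    data.frame(blood = "acetate", csf = "taurine", rho = -0.43),
    n1 = 10, n2 = 10)
  z_expected <- (atanh(0.89) - atanh(-0.43)) / sqrt(1 / 7 + 1 / 7)
  expect_equal(d$z_stat, z_expected, tolerance = 1e-12)
  expect_equal(d$z_stat, 3.5206, tolerance = 1e-4)
  expect_equal(d$p_value, 2 * pnorm(-z_expected), tolerance = 1e-12)
  expect_equal(d$p_value, 4.31e-4, tolerance = 1e-2)
  expect_true(d$significant)

  # small n, small difference: not significant
  s <- differential_correlations(
    data.frame(blood = "a", csf = "b", rho = 0.2),
    data.frame(blood = "a", csf = "b", rho = 0.1), n1 = 4, n2 = 4)
  expect_lt(abs(s$z_stat), 1.96)
  expect_false(s$significant)

  expect_warning(
    differential_correlations(
      data.frame(blood = "a", csf = "b", rho = 1),
      data.frame(blood = "a", csf = "b", rho = 0.3), n1 = 8, n2 = 8),
    "clamped")
  expect_error(
    differential_correlations(
      data.frame(blood = "a", csf = "b", rho = 0.1),
      data.frame(blood = "a", csf = "b", rho = 0.2), n1 = 3, n2 = 10),
    "n >= 4")
})
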