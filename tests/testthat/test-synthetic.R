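test_that("standards are unit-normalized sums of Lorentzians", {
  ax <- seq(-0.2, 9.6, by = 0.002)
  lib <- make_standard_library(list(
    standard_spec("one", data.frame(center = 2, height = 3, width = 0.002))),
    ax)
  expect_equal(sum(lib$matrix[1, ]), 1, tolerance = 1e-12)

  lib2 <- tiny_library(ax)
  # disjoint peak regions: essentially orthogonal on the grid
  expect_lt(sum(lib2$matrix[1, ] * lib2$matrix[2, ]),
            1e-4 * sqrt(sum(lib2$matrix[1, ]^2) * sum(lib2$matrix[2, ]^2)))
})

test_that("a standard with two equal peaks is symmetric about their midpoint", {
  # grid symmetric about the midpoint 3.0 so mirroring lands on grid points
  ax <- seq(1, 5, by = 0.001)
  lib <- make_standard_library(list(
    standard_spec("sym", data.frame(center = c(2.5, 3.5), height = 1,
                                    width = 0.003))), ax)
  y <- lib$matrix[1, ]
  expect_equal(y, rev(y), tolerance = 1e-10)
})

test_that("standard construction is validated", {
  expect_error(standard_spec("bad", data.frame(center = 10, height = 1,
                                               width = 0.002)),
               "outside 0.5-9.5")
  expect_error(standard_spec("bad", data.frame(center = 2, height = 1,
                                               width = 0)), "width")
  ax <- seq(3, 9.4, by = 0.002)
  expect_error(
    make_standard_library(list(
      standard_spec("oops", data.frame(center = 1.2, height = 1,
                                       width = 0.002))), ax),
    "oops")
  expect_error(
    make_standard_library(list(
      standard_spec("a", data.frame(center = 4, height = 1, width = 0.002)),
      standard_spec("a", data.frame(center = 5, height = 1, width = 0.002))),
      ax),
    "duplicate")
})

test_that("mixture synthesis is linear in the concentrations", {
  lib <- tiny_library()
  mx <- synthesize_mixture_spectrum(lib, c(0.3, 0.7), noise_sd = 0,
                                    shift = 0, baseline_offset = 0,
                                    reference_height = 0)
  expect_equal(mx$spectrum$intensity,
               as.numeric(0.3 * lib$matrix[1, ] + 0.7 * lib$matrix[2, ]),
               tolerance = 1e-14)

  flat <- synthesize_mixture_spectrum(lib, c(0, 0), baseline_offset = 5,
                                      reference_height = 0)
  expect_true(all(flat$spectrum$intensity == 5))

  # with the reference peak on, the non-reference part is still the baseline
  withref <- synthesize_mixture_spectrum(lib, c(0, 0), baseline_offset = 5)
  away <- abs(lib$axis) > 1
  expect_equal(withref$spectrum$intensity[away],
               rep(5, sum(away)), tolerance = 1e-4)
  expect_gt(withref$truth$reference_area, 0)

  expect_error(synthesize_mixture_spectrum(lib, c(-0.1, 1)), "negative")
  expect_error(synthesize_mixture_spectrum(lib, 1), "length")
})

test_that("mixture synthesis is reproducible under a fixed seed", {
  lib <- tiny_library()
  a <- synthesize_mixture_spectrum(lib, c(1, 2), noise_sd = 0.05, seed = 11)
  b <- synthesize_mixture_spectrum(lib, c(1, 2), noise_sd = 0.05, seed = 11)
  d <- synthesize_mixture_spectrum(lib, c(1, 2), noise_sd = 0.05, seed = 12)
  expect_identical(a$spectrum$intensity, b$spectrum$intensity)
  expect_false(identical(a$spectrum$intensity, d$spectrum$intensity))
})

test_that("the circular shift moves peaks by the requested amount", {
  lib <- tiny_library()
  mx0 <- synthesize_mixture_spectrum(lib, c(1, 0), reference_height = 0)
  mx1 <- synthesize_mixture_spectrum(lib, c(1, 0), shift = 0.01,
                                     reference_height = 0)
  p0 <- lib$axis[which.max(mx0$spectrum$intensity)]
  p1 <- lib$axis[which.max(mx1$spectrum$intensity)]
  expect_equal(p1 - p0, 0.01, tolerance = 1e-9)
  expect_identical(mx1$truth$shift_points, 5L)
})

test_that("copula simulation hits target Spearman correlations at large n", {
  des <- study_design(n_metabolites_blood = 4, n_metabolites_csf = 4,
                      n_shared = 4, replicates_per_group = 1250, seed = 42)
  # 8 design cells x 1250 = 10,000 samples, no group effects
  ts0 <- matrix(0, 4, 4)
  sim0 <- simulate_concentration_table(des, copula_spec(ts0),
                                       genotype_shift = 0, age_shift = 0)
  mets <- metabolites(sim0$blood)
  emp0 <- cor(as.matrix(as.data.frame(sim0$blood)[, mets]),
              as.matrix(as.data.frame(sim0$csf)[, mets]),
              method = "spearman")
  expect_lt(max(abs(emp0)), 0.05)

  ts <- matrix(0, 4, 4)
  diag(ts) <- c(0.9, 0.5, -0.7, 0)
  sim <- simulate_concentration_table(des, copula_spec(ts),
                                      genotype_shift = 0, age_shift = 0)
  emp <- cor(as.matrix(as.data.frame(sim$blood)[, mets]),
             as.matrix(as.data.frame(sim$csf)[, mets]),
             method = "spearman")
  expect_true(all(abs(emp - ts) < 0.05))
  expect_gt(emp[1, 1], 0.85)
  expect_lt(emp[1, 1], 0.95)
})

test_that("simulated marginals are log-normal", {
  des <- study_design(n_metabolites_blood = 2, n_metabolites_csf = 2,
                      n_shared = 2, replicates_per_group = 1250, seed = 5)
  sim <- simulate_concentration_table(des, copula_spec(matrix(0, 2, 2),
                                                       sdlog_blood = 0.5),
                                      genotype_shift = 0, age_shift = 0)
  x <- as.data.frame(sim$blood)[["met01"]]
  ks <- suppressWarnings(stats::ks.test(x, "plnorm", 0, 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("non-PSD targets are rejected with the offending eigenvalue", {
  des <- study_design(n_metabolites_blood = 2, n_metabolites_csf = 2,
                      n_shared = 2, replicates_per_group = 3, seed = 1)
  # both blood metabolites perfectly correlated with both CSF metabolites
  # is internally inconsistent when the within-fluid latent blocks are
  # identity
  ts <- matrix(1, 2, 2)
  expect_error(simulate_concentration_table(des, copula_spec(ts)),
               "positive semi-definite")
})

test_that("the simulator is deterministic given the design seed", {
  des <- study_design(n_metabolites_blood = 3, n_metabolites_csf = 3,
                      n_shared = 3, replicates_per_group = 3, seed = 99)
  cop <- copula_spec(diag(0.5, 3))
  a <- simulate_concentration_table(des, cop)
  b <- simulate_concentration_table(des, cop)
  expect_identical(as.data.frame(a$blood), as.data.frame(b$blood))
  expect_identical(as.data.frame(a$csf), as.data.frame(b$csf))
})

test_that("group effects shift the log-scale means of affected metabolites", {
  des <- study_design(n_metabolites_blood = 4, n_metabolites_csf = 4,
                      n_shared = 4, replicates_per_group = 500, seed = 8)
  sim <- simulate_concentration_table(des, copula_spec(matrix(0, 4, 4)),
                                      genotype_shift = 0.4, age_shift = 0,
                                      affected_fraction = 0.25)
  b <- as.data.frame(sim$blood)
  dlog <- mean(log(b$met01[b$genotype == "APP"])) -
    mean(log(b$met01[b$genotype == "WT"]))
  expect_equal(dlog, 0.4, tolerance = 0.06)   # MC error at n = 2000/arm
  dlog2 <- mean(log(b$met04[b$genotype == "APP"])) -
    mean(log(b$met04[b$genotype == "WT"]))
  expect_lt(abs(dlog2), 0.06)                  # unaffected metabolite
})

test_that("spectra and tables round-trip through their text formats", {
  lib <- tiny_library()
  dir <- withr::local_tempdir()
  write_standard_library(lib, dir)
  lib2 <- read_standard_library(dir)
  expect_equal(lib2$names, lib$names)
  expect_equal(lib2$matrix, lib$matrix, ignore_attr = TRUE,
               tolerance = 1e-12)

  des <- study_design(n_metabolites_blood = 3, n_metabolites_csf = 3,
                      n_shared = 3, replicates_per_group = 3, seed = 2)
  sim <- simulate_concentration_table(des, copula_spec(diag(0.5, 3)))
  f <- file.path(dir, "blood.csv")
  write_conc_table(sim$blood, f)
  back <- read_conc_table(f)
  expect_equal(as.data.frame(back), as.data.frame(sim$blood),
               tolerance = 1e-12)
})
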