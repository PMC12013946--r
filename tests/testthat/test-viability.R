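test_that("dead/live tables pool embryonic and larval deaths", {
  a <- list(genotype = "mut", laid = 10, dead_embryo = 2, dead_larva = 3, adult = 5)
  b <- list(genotype = "N2", laid = 10, dead_embryo = 0, dead_larva = 0, adult = 10)
  tab <- dead_live_table(a, b)
  expect_equal(unname(tab), matrix(c(5L, 0L, 5L, 10L), 2))
  expect_equal(rownames(tab), c("mut", "N2"))
  expect_equal(unname(dead_live_table(a, a)[1, ]), unname(dead_live_table(a, a)[2, ]))
  bad <- a; bad$adult <- 99
  expect_error(dead_live_table(bad, b), "identity")
})

test_that("simulated viability counts flow into the contingency table", {
  tab <- generate_viability_table(viability_sim_params(
    c("wt", "mut"), 800, p_embryonic = c(0.02, 0.3),
    p_larval = c(0.01, 0.1), seed = 5))
  ct <- dead_live_table(as.list(tab[2, ]), as.list(tab[1, ]))
  expect_equal(ct[1, "dead"], tab$dead_embryo[2] + tab$dead_larva[2])
  expect_equal(ct[2, "live"], tab$adult[1])
  expect_equal(sum(ct), sum(tab$laid))
})

test_that("Fisher's exact test matches known values and degenerate cases", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1.0)
  expect_equal(fisher_exact(matrix(c(0, 0, 7, 9), 2)), 1.0)   # zero margin
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-12)
  expect_error(fisher_exact(matrix(0L, 2, 2)), "zero")
})

test_that("Fisher p-values are invariant under row and column swaps", {
  set.seed(7)
  for (i in 1:25) {
    t <- matrix(rpois(4, 8), 2)
    p <- fisher_exact(t)
    expect_equal(fisher_exact(t[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisher_exact(t[, 2:1]), p, tolerance = 1e-12)
    expect_equal(fisher_exact(t(t)), p, tolerance = 1e-12)
  }
})

test_that("chi-square matches the closed form and transposition symmetry", {
  flat <- chi_square(matrix(25, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  t <- matrix(c(30, 20, 20, 30), 2)
  expect_equal(chi_square(t)$statistic, 4.0, tolerance = 1e-12)
  expect_equal(chi_square(t(t))$statistic, chi_square(t)$statistic)
  # Yates-corrected variant available but off by default
  expect_lt(chi_square(t, correct = TRUE)$statistic, 4.0)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2)), "expected")
})

test_that("type-I error of the Fisher comparison is controlled under the null", {
  set.seed(12)
  rejections <- 0
  n_sims <- 1000
  for (i in seq_len(n_sims)) {
    tab <- generate_viability_table(viability_sim_params(
      c("a", "b"), 300, p_embryonic = 0.08, p_larval = 0.05,
      seed = 20000 + i))
    ct <- dead_live_table(as.list(tab[1, ]), as.list(tab[2, ]))
    if (fisher_exact(ct) < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / n_sims, 0.06)
})

test_that("survival ratios behave as binomial proportions", {
  expect_equal(survival_ratio(300, 300)$ratio, 1.0)
  expect_equal(survival_ratio(0, 300)$ratio, 0.0)
  expect_error(survival_ratio(10, 0), "zero")
  set.seed(3)
  n <- 20000
  on <- rbinom(1, n, 0.5); off <- rbinom(1, n, 1.0)
  expect_lt(abs(survival_ratio(on, off)$ratio - 0.5), 0.05)
})

test_that("brood metrics compute both viability ratios with flags", {
  res <- brood_metrics(100, 90, 81)
  expect_equal(res$embryonic_viability, 0.9)
  expect_equal(res$larval_viability, 0.9)
  expect_equal(brood_metrics(c(40, 60), 90, 81)$total_laid, 100)
  none <- brood_metrics(50, 0, 0)
  expect_false(none$larval_defined)
  expect_true(is.na(none$larval_viability))
  expect_error(brood_metrics(10, 20, 5), "exceeds")
  expect_error(brood_metrics(10, 8, 9), "exceed")
  set.seed(9)
  hatched <- rbinom(1, 10000, 0.95)
  expect_lt(abs(brood_metrics(10000, hatched, hatched)$embryonic_viability - 0.95),
            0.01)
})

test_that("viability test runner pools replicates and tests against reference", {
  dir <- withr::local_tempdir()
  reps <- do.call(rbind, lapply(1:3, function(r)
    generate_viability_table(viability_sim_params(
      c("N2", "mutA", "mutB"), 250,
      p_embryonic = c(0.02, 0.4, 0.02), p_larval = c(0.02, 0.1, 0.02),
      seed = 100 + r))))
  path <- file.path(dir, "viability.csv")
  write.csv(reps, path, row.names = FALSE)
  res <- viability_tests(path, ref = "N2")
  expect_equal(sort(res$genotype), c("mutA", "mutB"))
  expect_lt(res$p_fisher[res$genotype == "mutA"], 1e-6)
  expect_gt(res$p_fisher[res$genotype == "mutB"], 0.01)
  pooled_dead <- sum(reps$dead_embryo[reps$genotype == "mutA"] +
                       reps$dead_larva[reps$genotype == "mutA"])
  expect_equal(res$dead[res$genotype == "mutA"], pooled_dead)
})
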