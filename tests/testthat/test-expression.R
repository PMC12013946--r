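test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 30, 40, 50,
                20, 40, 60, 80, 100), ncol = 2)
  sf <- size_factors(m)
  expect_equal(sf[2] / sf[1], 2.0, tolerance = 1e-12)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_true(all(abs(size_factors(same) - size_factors(same)[1]) < 1e-12))

  # 5-gene toy matrix against the hand-computed median of ratios
  toy <- matrix(c(100, 50, 10, 200, 400,
                  120, 40, 20, 180, 500,
                  80, 60, 5, 260, 300), ncol = 3)
  geo <- exp(rowMeans(log(toy)))
  want <- apply(toy, 2, function(col) median(col / geo))
  expect_equal(unname(size_factors(toy)), unname(want), tolerance = 1e-12)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "positive in all")
})

test_that("size factors agree with the DESeq reference implementation", {
  skip_if_not_installed("DESeq2")
  sim <- generate_count_matrix(count_sim_params(
    n_genes = c(I = 500L, X = 100L), seed = 13))
  ours <- size_factors(sim$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("log2 fold changes are null for identical groups and track spikes", {
  m <- matrix(rpois(600, 50), ncol = 6)
  g <- rep(c("control", "treatment"), each = 3)
  m[, 4:6] <- m[, 1:3]                      # treatment = control
  tab <- log2_fold_changes(m, g, sf = rep(1, 6))
  expect_true(all(tab$log2fc == 0))

  m2 <- matrix(10000, 20, 6)
  m2[7, 4:6] <- 40000                       # one gene 4x up
  tab2 <- log2_fold_changes(m2, g, sf = rep(1, 6))
  expect_lt(abs(tab2$log2fc[7] - 2), 0.001) # pseudocount-limited
  expect_true(all(tab2$log2fc[-7] == 0))
  expect_error(log2_fold_changes(m2, rep("a", 6)), "two groups")
})

test_that("derepression statistic matches its definition", {
  tab <- data.frame(chrom = c("X", "X", "X", "I", "II", "V"),
                    log2fc = c(0.5, 0.5, 0.5, 0, 0, 0))
  res <- derepression(tab)
  expect_equal(res$d, 0.5)
  expect_equal(res$fold, 2^0.5, tolerance = 1e-12)
  expect_equal(res$n_X, 3); expect_equal(res$n_A, 3)
  expect_equal(res$d, res$median_X - res$median_A, tolerance = 1e-12)

  same <- data.frame(chrom = rep(c("X", "I"), each = 4),
                     log2fc = rep(c(0.1, 0.2, 0.3, 0.4), 2))
  rs <- derepression(same)
  expect_equal(rs$d, 0); expect_equal(rs$fold, 1)
  expect_equal(rs$p, 1)
})

test_that("derepression is invariant under a common additive shift", {
  set.seed(21)
  tab <- data.frame(chrom = sample(c("X", "I", "II"), 400, replace = TRUE),
                    log2fc = rnorm(400))
  d0 <- derepression(tab)$d
  for (c_shift in c(-2, 0.7, 13)) {
    shifted <- tab; shifted$log2fc <- tab$log2fc + c_shift
    expect_equal(derepression(shifted)$d, d0, tolerance = 1e-12)
  }
})

test_that("genes outside the chromosome vocabulary are dropped, not fatal", {
  tab <- data.frame(chrom = c("X", "I", "MtDNA", "I"),
                    log2fc = c(0.5, 0, 1000, NaN))
  expect_message(res <- derepression(tab), "dropped")
  expect_equal(res$n_X + res$n_A, 2)
})

test_that("rank-sum test is exact on small samples and approximate on large", {
  w <- wilcoxon_rank_sum(1:3, 4:6)
  expect_equal(w$p, 0.1)                    # 2/20 rank assignments as extreme
  expect_equal(w$method, "exact")
  expect_equal(wilcoxon_rank_sum(c(5, 1, 9), c(5, 1, 9))$p, 1)

  # independent reference on larger samples with ties
  set.seed(31)
  x <- round(rnorm(40), 1); y <- round(rnorm(55, 0.4), 1)
  ours <- wilcoxon_rank_sum(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_lt(abs(ours$p - ref$p.value), 1e-3)   # Edgeworth term is tiny here
  expect_equal(unname(ours$U), unname(ref$statistic))
})

test_that("normal approximation stays within 0.02 of exact enumeration", {
  worst <- 0
  for (nx in 3:6) {
    ny <- 12 - nx
    subsets <- combn(nx + ny, nx)
    for (j in seq_len(ncol(subsets))) {
      x <- subsets[, j]
      y <- setdiff(seq_len(nx + ny), x)
      pa <- wilcoxon_rank_sum(x, y, method = "normal")$p
      pe <- exact_ranksum_p(nx, ny, sum(x))
      worst <- max(worst, abs(pa - pe))
    }
  }
  expect_lt(worst, 0.02)
})

test_that("fold equivalents reproduce printed conversions and round-trip", {
  expect_equal(fold_change_equivalent(0)$fold, 1.0)
  expect_equal(fold_change_equivalent(1)$fold, 2.0)
  expect_equal(fold_change_equivalent(0.435)$fold_rounded, 1.35)
  for (v in c(0.001, 0.5, 1, 3.7, 42))
    expect_equal(fold_change_equivalent(log2(v))$fold, v, tolerance = 1e-12)
  expect_error(fold_change_equivalent(NA), "finite")
})

test_that("chromosome profiles bin genes by coordinate with p filtering", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    chrom = c("I", "I", "X"),
                    start = c(1, 6e5, 2e6),
                    log2fc = c(0.8, -0.2, 0.5),
                    pvalue = c(0.001, 0.5, 0.01))
  prof <- chromosome_profile(tab, bin_size = 5e5)
  i1 <- prof[prof$chrom == "I" & prof$bin_start == 1, ]
  expect_equal(i1$mean_log2fc, 0.8)          # gene b filtered at p >= 0.05
  expect_equal(i1$n_genes, 1L)
  expect_equal(sum(prof$n_genes), 2L)
  # bins tile the chromosomes without overlap
  for (ch in unique(prof$chrom)) {
    sub <- prof[prof$chrom == ch, ]
    expect_equal(sub$bin_start[-1], head(sub$bin_end, -1) + 1)
    expect_equal(sub$bin_end[nrow(sub)], unname(ce_chrom_lengths()[ch]))
  }
  none <- chromosome_profile(transform(tab, pvalue = 1), bin_size = 5e5)
  expect_equal(sum(none$n_genes), 0L)
  expect_error(chromosome_profile(transform(tab, start = 1e9)), "beyond")
})

test_that("profiles of a uniform X shift are flat at d on X and 0 elsewhere", {
  sim <- generate_count_matrix(count_sim_params(d_true = 0.5, seed = 17))
  # true library factors isolate the binning from normalization bias
  # (a chromosome-wide shift inflates median-of-ratios factors slightly,
  # which is exactly why the derepression statistic uses the X - A contrast)
  tab <- log2_fold_changes(sim$counts, sim$groups, genes = sim$genes,
                           sf = sim$truth$lib_factors)
  prof <- chromosome_profile(tab, bin_size = 1e6, p_max = NULL)
  filled <- prof[prof$n_genes >= 50, ]
  on_x <- filled$chrom == "X"
  expect_true(all(abs(filled$mean_log2fc[on_x] - 0.5) < 0.1))
  expect_true(all(abs(filled$mean_log2fc[!on_x]) < 0.1))
})

test_that("DGE tables survive a write/read round trip", {
  dir <- withr::local_tempdir()
  tab <- data.frame(gene_id = c("g1", "g2"), chrom = c("X", "I"),
                    start = c(100L, 200L), log2fc = c(0.4, -0.1),
                    pvalue = c(0.01, 0.2))
  p <- write_dge_table(tab, file.path(dir, "dge.tsv"))
  expect_equal(read_dge_table(p), tab)
  bad <- tab; names(bad)[4] <- "lfc"
  write.table(bad, file.path(dir, "bad.tsv"), sep = "\t", row.names = FALSE)
  expect_error(read_dge_table(file.path(dir, "bad.tsv")), "columns")
})
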