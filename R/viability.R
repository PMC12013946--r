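# Progeny viability statistics: dead/live contingency tables, Fisher's
# exact and chi-square comparisons, survival ratios, brood metrics.

validate_viability_record <- function(rec) {
  need <- c("laid", "dead_embryo", "dead_larva", "adult")
  if (!all(need %in% names(rec)))
    stop("viability record needs fields: ", paste(need, collapse = ", "))
  counts <- unlist(rec[need])
  if (any(counts < 0) || any(counts != round(counts)))
    stop("viability counts must be non-negative integers")
  if (rec$laid != rec$dead_embryo + rec$dead_larva + rec$adult)
    stop("count identity violated: laid != dead_embryo + dead_larva + adult")
  invisible(rec)
}

#' Dead/live contingency table for two genotypes
#'
#' Dead embryos and dead larvae are pooled into a single "dead" category,
#' against surviving adults, giving the 2x2 table tested between genotypes.
#'
#' @param record_a,record_b viability records: lists or one-row data.frames
#'   with `genotype` (optional), `laid`, `dead_embryo`, `dead_larva`,
#'   `adult`, satisfying `laid = dead_embryo + dead_larva + adult`.
#' @return 2x2 integer matrix, rows = genotypes, columns = `dead`, `live`.
#' @examples
#' a <- list(genotype = "mut", laid = 10, dead_embryo = 2, dead_larva = 3, adult = 5)
#' b <- list(genotype = "N2", laid = 10, dead_embryo = 0, dead_larva = 0, adult = 10)
#' dead_live_table(a, b)
#' @export
dead_live_table <- function(record_a, record_b) {
  record_a <- as.list(record_a); record_b <- as.list(record_b)
  validate_viability_record(record_a)
  validate_viability_record(record_b)
  tab <- rbind(c(record_a$dead_embryo + record_a$dead_larva, record_a$adult),
               c(record_b$dead_embryo + record_b$dead_larva, record_b$adult))
  storage.mode(tab) <- "integer"
  rownames(tab) <- c(record_a$genotype %||% "a", record_b$genotype %||% "b")
  colnames(tab) <- c("dead", "live")
  tab
}

#' Fisher's exact test on a 2x2 table (two-sided)
#'
#' Conditional on the margins, sums the hypergeometric probabilities of all
#' admissible tables whose point probability does not exceed that of the
#' observed table (the point-probability rule, the convention of mainstream
#' implementations).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(10, 0, 0, 10), 2, 2))  # ~1.08e-5
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0),
            all(table == round(table)))
  n <- sum(table)
  if (n == 0) stop("table total is zero")
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1])
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(table[1, 1], c1, n - c1, r1)
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction by default (`correct = TRUE` enables Yates'
#' correction). Delegates to [stats::chisq.test()].
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param correct apply Yates' continuity correction (default `FALSE`).
#' @return list with `statistic` (X-squared, df = 1) and `p`.
#' @examples
#' chi_square(matrix(c(30, 20, 20, 30), 2, 2))$statistic  # 4
#' @export
chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) stop("zero expected cell")
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Auxin survival ratio
#'
#' Final survivor counts on auxin relative to off auxin, assuming equal
#' numbers initially plated; may exceed 1 through sampling.
#'
#' @param on_auxin,off_auxin survivor counts (off_auxin > 0).
#' @return list with `ratio`, `on_auxin`, `off_auxin`.
#' @export
survival_ratio <- function(on_auxin, off_auxin) {
  stopifnot(on_auxin >= 0, off_auxin >= 0)
  if (off_auxin == 0) stop("off-auxin survivor count is zero")
  list(ratio = on_auxin / off_auxin, on_auxin = on_auxin, off_auxin = off_auxin)
}

#' Brood viability metrics
#'
#' Embryonic viability = hatched / total embryos laid; larval viability =
#' adults / hatched. Eggs laid may be given per day (per plate); they are
#' summed. When nothing hatched, larval viability is `NA` and flagged.
#'
#' @param laid numeric vector of eggs laid (e.g. per day).
#' @param hatched total hatched embryos (<= sum(laid)).
#' @param adults total surviving adults (<= hatched).
#' @return A `BroodResult`: list with `total_laid`, `hatched`, `adults`,
#'   `embryonic_viability`, `larval_viability`, `larval_defined`.
#' @examples
#' brood_metrics(100, 90, 81)  # 0.90 and 0.90
#' @export
brood_metrics <- function(laid, hatched, adults) {
  total <- sum(laid)
  stopifnot(total >= 0, hatched >= 0, adults >= 0)
  if (hatched > total) stop("hatched exceeds eggs laid")
  if (adults > hatched) stop("adults exceed hatched embryos")
  larval_ok <- hatched > 0
  structure(list(total_laid = total, hatched = hatched, adults = adults,
                 embryonic_viability = if (total > 0) hatched / total else NA_real_,
                 larval_viability = if (larval_ok) adults / hatched else NA_real_,
                 larval_defined = larval_ok),
            class = "BroodResult")
}

#' Pairwise viability tests against a reference genotype
#'
#' Reads (or takes) a viability table, pools replicate rows per genotype
#' and condition by summing counts, and runs Fisher's exact test of each
#' genotype's dead/live counts against the reference genotype within each
#' condition.
#'
#' @param table data.frame with columns `genotype, condition, laid,
#'   dead_embryo, dead_larva, adult` (replicate rows allowed), or a CSV
#'   path to one.
#' @param ref reference genotype label (default `"N2"`).
#' @return data.frame `condition, genotype, dead, live, ref_dead,
#'   ref_live, p_fisher`.
#' @export
viability_tests <- function(table, ref = "N2") {
  if (is.character(table) && length(table) == 1L) table <- read.csv(table)
  need <- c("genotype", "condition", "laid", "dead_embryo", "dead_larva", "adult")
  stopifnot(all(need %in% names(table)))
  pooled <- aggregate(cbind(laid, dead_embryo, dead_larva, adult) ~ genotype + condition,
                      data = table, FUN = sum)
  for (i in seq_len(nrow(pooled))) validate_viability_record(as.list(pooled[i, ]))
  out <- list()
  for (cond in unique(pooled$condition)) {
    sub <- pooled[pooled$condition == cond, , drop = FALSE]
    rref <- sub[sub$genotype == ref, , drop = FALSE]
    if (nrow(rref) != 1) stop("reference genotype '", ref, "' not found once in condition ", cond)
    for (i in seq_len(nrow(sub))) {
      if (sub$genotype[i] == ref) next
      tab <- dead_live_table(as.list(sub[i, ]), as.list(rref))
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, genotype = sub$genotype[i],
        dead = tab[1, 1], live = tab[1, 2],
        ref_dead = tab[2, 1], ref_live = tab[2, 2],
        p_fisher = fisher_exact(tab), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
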