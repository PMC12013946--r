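# X-vs-autosome derepression statistic and supporting expression utilities.

CHROM_LEVELS <- c("I", "II", "III", "IV", "V", "X")

#' Median-of-ratios library-size factors
#'
#' For each sample, the factor is the median over genes (restricted to
#' genes positive in every sample) of that sample's count divided by the
#' gene's geometric mean across samples. This normalizes library depth so
#' synthetic counts can be turned into fold changes without a full
#' differential-expression fit.
#'
#' @param counts numeric matrix, genes x samples (>= 2 columns).
#' @return Positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene is positive in all samples")
  logc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  apply(logc, 2, function(col) exp(median(col - loggeo)))
}

#' Per-gene log2 fold changes from a count matrix
#'
#' Normalizes counts by [size_factors()] (or given factors), averages the
#' normalized counts within each group, and reports
#' `log2((mean_trt + c) / (mean_ctrl + c))` per gene with pseudocount
#' `c`. Optionally attaches a per-gene Wilcoxon rank-sum p-value across
#' samples. This is a deliberately minimal estimator for simulated counts;
#' tables from an external differential-expression tool enter the pipeline
#' through [read_dge_table()] instead.
#'
#' @param counts genes x samples matrix; rownames are gene ids.
#' @param groups factor/character of length `ncol(counts)` with exactly two
#'   levels; the first level is the control group.
#' @param genes optional data.frame with `gene_id`, `chrom`, `start` to
#'   carry through (e.g. from [generate_count_matrix()]).
#' @param sf size factors, or `NULL` to estimate them.
#' @param pseudocount additive constant `c` (default 1).
#' @param pvalues compute per-gene rank-sum p-values (default `FALSE`;
#'   slow for many genes).
#' @return A DGE table data.frame: `gene_id, chrom, start, log2fc`
#'   (+ `pvalue` when requested). `chrom`/`start` are `NA` when `genes` is
#'   not supplied.
#' @export
log2_fold_changes <- function(counts, groups, genes = NULL, sf = NULL,
                              pseudocount = 1, pvalues = FALSE) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) stop("group labels do not match samples")
  if (nlevels(groups) != 2) stop("need exactly two groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, `/`)
  ctrl <- levels(groups)[1]; trt <- levels(groups)[2]
  m0 <- rowMeans(norm[, groups == ctrl, drop = FALSE])
  m1 <- rowMeans(norm[, groups == trt, drop = FALSE])
  lfc <- log2((m1 + pseudocount) / (m0 + pseudocount))
  ids <- rownames(counts) %||% sprintf("gene_%05d", seq_len(nrow(counts)))
  tab <- data.frame(gene_id = ids,
                    chrom = if (is.null(genes)) NA_character_ else genes$chrom,
                    start = if (is.null(genes)) NA_integer_ else genes$start,
                    log2fc = unname(lfc),
                    base_mean = unname((m0 + m1) / 2),
                    stringsAsFactors = FALSE)
  if (pvalues) {
    tab$pvalue <- vapply(seq_len(nrow(norm)), function(i) {
      wilcoxon_rank_sum(norm[i, groups == trt], norm[i, groups == ctrl])$p
    }, numeric(1))
  }
  tab
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Mid-ranks for ties. When the combined sample size is at most 12 and
#' there are no ties, the p-value is exact by full enumeration of rank
#' assignments; otherwise a normal approximation with tie correction,
#' continuity correction, and an Edgeworth kurtosis term (the rank-sum null
#' is symmetric with known negative excess kurtosis) is used — the regime
#' relevant for genome-scale X-vs-autosome comparisons.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param method `"auto"` (exact when possible), `"exact"`, or `"normal"`
#'   to force the approximation.
#' @return list with `W` (rank-sum of `x`), `U` (Mann-Whitney statistic),
#'   `p` (two-sided), `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6)$p  # 0.1, exact
#' @export
wilcoxon_rank_sum <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))

  use_exact <- switch(method,
    auto = n <= 12 && !ties,
    exact = { if (ties) stop("exact method is not defined with ties"); TRUE },
    normal = FALSE)
  if (use_exact) {
    sums <- combn(n, nx, FUN = sum)          # all rank-sum values
    p_le <- mean(sums <= W)
    p_ge <- mean(sums >= W)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(W = W, U = U, p = p, method = "exact"))
  }

  mu <- nx * (n + 1) / 2                     # mean of the rank sum
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(W = W, U = U, p = 1, method = "normal"))
  # excess kurtosis of the no-tie rank-sum null (exact closed form),
  # applied as a one-term Edgeworth correction to the CDF
  g2 <- -6 / 5 * (nx^2 + ny^2 + nx * ny + n) / (nx * ny * (n + 1))
  Fw <- function(w) {                        # P(W <= w), continuity-corrected
    z <- (w + 0.5 - mu) / sqrt(sigma2)
    min(1, max(0, pnorm(z) - dnorm(z) * (g2 / 24) * (z^3 - 3 * z)))
  }
  p <- min(1, 2 * min(Fw(W), 1 - Fw(W - 1)))
  list(W = W, U = U, p = p, method = "normal")
}

#' Fold-change equivalent of a log2 shift
#'
#' @param d log2 shift (finite).
#' @param signif_digits significant digits for the rounded report
#'   (default 3).
#' @return list with `fold` (= `2^d`, exact) and `fold_rounded`.
#' @examples
#' fold_change_equivalent(0.503)$fold_rounded  # 1.42
#' @export
fold_change_equivalent <- function(d, signif_digits = 3) {
  if (!is.finite(d)) stop("d must be finite")
  fold <- 2^d
  list(fold = fold, fold_rounded = signif(fold, signif_digits))
}

#' X-derepression statistic with Wilcoxon significance
#'
#' `d = median(log2FC of X-linked genes) - median(log2FC of autosomal
#' genes)`, its fold-change equivalent `2^d`, and a two-sided Wilcoxon
#' rank-sum comparison of the two log2FC sets. Medians use the mean of the
#' two central order statistics for even n. Genes on chromosomes outside
#' `I-V, X` (mitochondrial, unplaced) are dropped with a message; rows with
#' non-finite log2FC are dropped likewise.
#'
#' @param table a DGE table data.frame with columns `chrom` and `log2fc`
#'   (see [read_dge_table()] or [log2_fold_changes()]).
#' @param min_base_mean optional expression filter: keep genes with
#'   `base_mean >= min_base_mean` when that column is present.
#' @return A `DerepressionResult`: list with `d`, `fold`, `median_X`,
#'   `median_A`, `n_X`, `n_A`, `W`, `p`.
#' @examples
#' tab <- data.frame(chrom = c("X", "X", "X", "I", "I", "I"),
#'                   log2fc = c(0.5, 0.5, 0.5, 0, 0, 0))
#' derepression(tab)$d  # 0.5
#' @export
derepression <- function(table, min_base_mean = NULL) {
  stopifnot(is.data.frame(table), all(c("chrom", "log2fc") %in% names(table)))
  keep <- table$chrom %in% CHROM_LEVELS & is.finite(table$log2fc)
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " gene(s) dropped (chromosome outside I-V/X or non-finite log2fc)")
  tab <- table[keep, , drop = FALSE]
  if (!is.null(min_base_mean) && "base_mean" %in% names(tab))
    tab <- tab[tab$base_mean >= min_base_mean, , drop = FALSE]
  x <- tab$log2fc[tab$chrom == "X"]
  a <- tab$log2fc[tab$chrom != "X"]
  if (length(x) == 0 || length(a) == 0)
    stop("need at least one X-linked and one autosomal gene")
  med_x <- median(x); med_a <- median(a)
  d <- med_x - med_a
  wt <- wilcoxon_rank_sum(x, a)
  structure(list(d = d, fold = 2^d, median_X = med_x, median_A = med_a,
                 n_X = length(x), n_A = length(a), W = wt$W, p = wt$p),
            class = "DerepressionResult")
}

#' @export
print.DerepressionResult <- function(x, ...) {
  cat(sprintf("X derepression d = %.4f (%.3g-fold), median X = %.4f, median A = %.4f\n",
              x$d, signif(x$fold, 3), x$median_X, x$median_A))
  cat(sprintf("Wilcoxon rank-sum: W = %.4g, two-sided p = %.3g (n_X = %d, n_A = %d)\n",
              x$W, x$p, x$n_X, x$n_A))
  invisible(x)
}

#' Binned per-chromosome log2FC profile
#'
#' Filters the table at a p-value threshold (when a `pvalue` column is
#' present), assigns genes to fixed-width bins by start coordinate, and
#' reports per-bin mean log2FC and gene count — the plot-ready form of a
#' chromosome-coordinate fold-change map.
#'
#' @param table DGE table with `chrom`, `start`, `log2fc` (+ optional
#'   `pvalue`).
#' @param chrom_lengths named vector of chromosome lengths (bp); default
#'   [ce_chrom_lengths()].
#' @param bin_size bin width in bp (default 5e5).
#' @param p_max drop genes with `pvalue >= p_max` (default 0.05); ignored
#'   when the table has no p-values.
#' @return data.frame `chrom, bin_start, bin_end, mean_log2fc, n_genes`
#'   tiling each chromosome (1-based inclusive bins); empty bins have
#'   `n_genes = 0` and `NA` mean.
#' @export
chromosome_profile <- function(table, chrom_lengths = ce_chrom_lengths(),
                               bin_size = 5e5, p_max = 0.05) {
  stopifnot(all(c("chrom", "start", "log2fc") %in% names(table)))
  tab <- table[table$chrom %in% names(chrom_lengths), , drop = FALSE]
  bad <- tab$start < 1 | tab$start > chrom_lengths[tab$chrom]
  if (any(bad)) stop("gene coordinate beyond chromosome length")
  filtered <- "pvalue" %in% names(tab) && !is.null(p_max)
  if (filtered) tab <- tab[!is.na(tab$pvalue) & tab$pvalue < p_max, , drop = FALSE]
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    n_bins <- ceiling(len / bin_size)
    starts <- (seq_len(n_bins) - 1) * bin_size + 1
    ends <- pmin(starts + bin_size - 1, len)
    sub <- tab[tab$chrom == ch, , drop = FALSE]
    bin_of <- floor((sub$start - 1) / bin_size) + 1
    mean_fc <- rep(NA_real_, n_bins)
    n_genes <- integer(n_bins)
    if (nrow(sub) > 0) {
      agg_n <- tapply(sub$log2fc, bin_of, length)
      agg_m <- tapply(sub$log2fc, bin_of, mean)
      ii <- as.integer(names(agg_n))
      n_genes[ii] <- as.integer(agg_n)
      mean_fc[ii] <- as.numeric(agg_m)
    }
    data.frame(chrom = ch, bin_start = starts, bin_end = ends,
               mean_log2fc = mean_fc, n_genes = n_genes,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "p_max") <- if (filtered) p_max else NA_real_
  res
}

#' Read / write differential-expression tables
#'
#' TSV with columns `gene_id, chrom, start, log2fc` and optionally
#' `pvalue`, `base_mean` — the entry point for tables produced by an
#' external differential-expression tool.
#'
#' @param path TSV file path.
#' @return `read_dge_table`: the validated data.frame.
#' @export
read_dge_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "log2fc")
  if (!all(need %in% names(tab)))
    stop("DGE table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene ids")
  tab
}

#' @rdname read_dge_table
#' @param table DGE table data.frame.
#' @return `write_dge_table`: `path`, invisibly.
#' @export
write_dge_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
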