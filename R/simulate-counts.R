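#' C. elegans chromosome lengths
#'
#' Approximate lengths (bp) of the six nuclear chromosomes, used to place
#' simulated genes and to bin coordinate profiles.
#'
#' @return Named numeric vector over `I, II, III, IV, V, X`.
#' @export
ce_chrom_lengths <- function() {
  c(I = 15072434, II = 15279421, III = 13783801,
    IV = 17493829, V = 20924180, X = 17718942)
}

#' Parameters for the negative-binomial count simulator
#'
#' Emulates a two-condition mRNA-seq design (control vs treatment, a few
#' replicates each) over ~20,000 genes on chromosomes I-V and X, where the
#' treatment multiplies the expression of every X-linked gene by `2^d_true`
#' — a uniform chromosome-wide shift, the effect the X-derepression
#' statistic is designed to estimate.
#'
#' @param n_genes named integer vector of gene counts per chromosome;
#'   default 3,440 per autosome and 2,800 on X (20,000 total, X = 14%).
#' @param meanlog,sdlog log-normal parameters for baseline gene means.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param reps integer `(n_control, n_treatment)` replicates, each >= 2.
#' @param d_true uniform X shift in log2 units: treatment-group means of
#'   X genes are `2^d_true` times their control means.
#' @param lib_factors per-sample library-size factors (length
#'   `sum(reps)`), or `NULL` to draw them log-uniformly from \[0.7, 1.4\].
#' @param seed integer RNG seed.
#' @return An object of class `CountSimParams`.
#' @export
count_sim_params <- function(n_genes = c(I = 3440L, II = 3440L, III = 3440L,
                                         IV = 3440L, V = 3440L, X = 2800L),
                             meanlog = log(100), sdlog = 1,
                             dispersion = 0.05,
                             reps = c(3L, 3L),
                             d_true = 0,
                             lib_factors = NULL,
                             seed = 1L) {
  chroms <- names(ce_chrom_lengths())
  stopifnot(all(names(n_genes) %in% chroms), all(n_genes >= 1))
  reps <- as.integer(reps)
  if (length(reps) != 2L || any(reps != round(reps)))
    stop("reps must be two integers")
  if (any(reps < 2L)) stop("need >= 2 samples per group")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (!is.finite(d_true)) stop("d_true must be finite")
  if (!is.null(lib_factors)) {
    stopifnot(length(lib_factors) == sum(reps), all(lib_factors > 0))
  }
  structure(list(n_genes = n_genes, meanlog = meanlog, sdlog = sdlog,
                 dispersion = dispersion, reps = reps, d_true = d_true,
                 lib_factors = lib_factors, seed = as.integer(seed)),
            class = "CountSimParams")
}

#' Simulate a negative-binomial count matrix with a known X shift
#'
#' Control-group gene means are drawn once from a log-normal; treatment
#' means equal control means except X-linked genes, which are multiplied by
#' `2^d_true`. Counts are negative-binomial draws around `mean *
#' library-size factor` per sample.
#'
#' @param params a [count_sim_params()] object.
#' @return A list:
#'   \describe{
#'     \item{counts}{integer matrix genes x samples, columns
#'       `ctrl_1..., trt_1...`.}
#'     \item{genes}{data.frame `gene_id, chrom, start` (1-based bp,
#'       increasing within each chromosome).}
#'     \item{groups}{factor of sample group labels (`control`/`treatment`).}
#'     \item{truth}{list: `d_true`, `mu_control`, `mu_treatment`,
#'       `lib_factors`, `seed`.}
#'   }
#' @examples
#' sim <- generate_count_matrix(count_sim_params(
#'   n_genes = c(I = 50L, X = 20L), d_true = 1, seed = 2))
#' dim(sim$counts)
#' @export
generate_count_matrix <- function(params) {
  stopifnot(inherits(params, "CountSimParams"))
  with_seed(params$seed, {
    n_per <- params$n_genes
    chrom <- rep(names(n_per), n_per)
    n <- length(chrom)
    lens <- ce_chrom_lengths()[names(n_per)]
    start <- unlist(lapply(seq_along(n_per), function(i) {
      sort(sample.int(lens[i] - 1L, n_per[i], replace = FALSE))
    }), use.names = FALSE)
    gene_id <- sprintf("gene_%05d", seq_len(n))

    mu0 <- rlnorm(n, meanlog = params$meanlog, sdlog = params$sdlog)
    mu1 <- mu0
    on_x <- chrom == "X"
    mu1[on_x] <- mu0[on_x] * 2^params$d_true

    reps <- params$reps
    sf <- params$lib_factors
    if (is.null(sf)) sf <- exp(runif(sum(reps), log(0.7), log(1.4)))
    groups <- factor(rep(c("control", "treatment"), reps),
                     levels = c("control", "treatment"))
    mu_mat <- cbind(matrix(mu0, n, reps[1]), matrix(mu1, n, reps[2]))
    mu_mat <- sweep(mu_mat, 2, sf, `*`)
    counts <- if (params$dispersion > 0) {
      matrix(rnbinom(length(mu_mat), mu = mu_mat, size = 1 / params$dispersion),
             n, sum(reps))
    } else {
      matrix(rpois(length(mu_mat), lambda = mu_mat), n, sum(reps))
    }
    colnames(counts) <- c(paste0("ctrl_", seq_len(reps[1])),
                          paste0("trt_", seq_len(reps[2])))
    rownames(counts) <- gene_id
    genes <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                        stringsAsFactors = FALSE)
    list(counts = counts, genes = genes, groups = groups,
         truth = list(d_true = params$d_true, mu_control = mu0,
                      mu_treatment = mu1, lib_factors = sf,
                      seed = params$seed))
  })
}

#' Write a simulated count matrix and gene table as TSV
#'
#' The gene table columns (`gene_id`, `chrom`, `start`) are followed by one
#' column per sample.
#'
#' @param sim result of [generate_count_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_sim <- function(sim, path) {
  out <- cbind(sim$genes, as.data.frame(sim$counts))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
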