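#' Parameters for the progeny-viability simulator
#'
#' Emulates egg-laying viability assays: for each genotype a clutch of
#' embryos is laid; each embryo dies during embryogenesis with probability
#' `p_embryonic`, each hatched larva dies before adulthood with probability
#' `p_larval`, and the rest reach adulthood.
#'
#' @param genotype character vector of genotype labels.
#' @param n_embryos integer vector, embryos laid per genotype.
#' @param p_embryonic,p_larval death probabilities in \[0, 1\] (recycled).
#' @param condition condition label(s), e.g. `"auxin"` / `"no-auxin"`
#'   (recycled).
#' @param seed integer RNG seed.
#' @return An object of class `ViabilitySimParams`.
#' @export
viability_sim_params <- function(genotype, n_embryos,
                                 p_embryonic, p_larval,
                                 condition = "no-auxin", seed = 1L) {
  k <- length(genotype)
  n_embryos <- as.integer(rep_len(n_embryos, k))
  p_embryonic <- rep_len(p_embryonic, k)
  p_larval <- rep_len(p_larval, k)
  condition <- rep_len(as.character(condition), k)
  stopifnot(all(n_embryos >= 0),
            all(p_embryonic >= 0 & p_embryonic <= 1),
            all(p_larval >= 0 & p_larval <= 1))
  structure(list(genotype = as.character(genotype), n_embryos = n_embryos,
                 p_embryonic = p_embryonic, p_larval = p_larval,
                 condition = condition, seed = as.integer(seed)),
            class = "ViabilitySimParams")
}

#' Simulate per-genotype progeny viability counts
#'
#' Binomial draws per developmental stage; by construction
#' `laid = dead_embryo + dead_larva + adult` for every row.
#'
#' @param params a [viability_sim_params()] object.
#' @return data.frame with columns `genotype, condition, laid, dead_embryo,
#'   dead_larva, adult`.
#' @examples
#' generate_viability_table(viability_sim_params(
#'   c("N2", "mut"), 500, p_embryonic = c(0.02, 0.4),
#'   p_larval = 0.05, seed = 1))
#' @export
generate_viability_table <- function(params) {
  stopifnot(inherits(params, "ViabilitySimParams"))
  with_seed(params$seed, {
    laid <- params$n_embryos
    dead_embryo <- rbinom(length(laid), laid, params$p_embryonic)
    hatched <- laid - dead_embryo
    dead_larva <- rbinom(length(laid), hatched, params$p_larval)
    adult <- hatched - dead_larva
    data.frame(genotype = params$genotype, condition = params$condition,
               laid = laid, dead_embryo = dead_embryo,
               dead_larva = dead_larva, adult = adult,
               stringsAsFactors = FALSE)
  })
}
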