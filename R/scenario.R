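#' Reference balancing-selection simulation scenario
#'
#' The package's standard five-species test bed for balancing-selection
#' inference: a fixed rooted tree whose branch lengths (in Moran-event
#' units) put the populations deep into the long-term regime where the
#' per-population state distribution is close to stationarity, and a
#' generating parameter set with a GC-bias rate of 0.1 and balancing
#' selection of strength 2 pulling every nucleotide pair toward preferred
#' frequency 2 on an N = 6 grid. Base frequencies are mildly AT-rich
#' (0.3, 0.2, 0.2, 0.3) and all exchangeabilities are 0.04, which puts
#' roughly 9 percent of sites in a polymorphic state - a diversity level
#' typical of multi-individual population samples. Ten alleles are
#' sampled per population.
#'
#' @param n_sites Number of sites to simulate (default 20000).
#' @return List with \code{tree} (\code{phylo}), \code{params}
#'   (\code{pomo_params}), \code{sample_size} and \code{n_sites}.
#' @examples
#' sc <- bs_scenario(1000)
#' sc$params
#' @export
bs_scenario <- function(n_sites = 20000) {
  tree <- ape::read.tree(
    text = "((sp1:60,sp2:60):60,((sp3:60,sp4:60):30,sp5:90):30);")
  params <- pomo_params(N = 6, pi = c(0.3, 0.2, 0.2, 0.3),
                        rho = rep(0.04, 6), sigma = 0.1,
                        beta = 2, B = 2, mode = "balance")
  list(tree = tree, params = params, sample_size = 10, n_sites = n_sites)
}
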