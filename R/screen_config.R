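#' Screen analysis configuration
#'
#' Bundles the tunable parameters of the screen inference.
#'
#' @param pseudocount Added to normalized counts before log2 fold
#'   changes (default 0.5, symmetric).
#' @param alpha_select sgRNA-level p-value threshold below which a guide
#'   is "selected" for robust rank aggregation (default 0.05).
#' @param n_permutations Number of random guide-to-gene reassignments
#'   used for gene-level permutation p-values (default 10000).
#' @param z_cut Gene z-score magnitude required for a hit (default 2).
#' @param fdr_cut BH-adjusted p-value a hit must stay below (default 0.05).
#' @param seed Integer seed fixing every stochastic step.
#' @param nt_reference Reference distribution for gene z-scores:
#'   `"guide"` uses individual non-targeting guide LFCs, `"pseudo_gene"`
#'   uses median LFCs of random groups of `sgrnas_per_gene` NT guides.
#' @param min_nt Minimum usable non-targeting guides for normalization
#'   and the mean-variance fit (default 20).
#' @param floor_variance Floor for the excess-variance term in the
#'   mean-variance regression (default 0.01).
#' @return A `screen_config` list.
#' @export
screen_config <- function(pseudocount = 0.5, alpha_select = 0.05,
                          n_permutations = 10000L, z_cut = 2,
                          fdr_cut = 0.05, seed = 1L,
                          nt_reference = c("guide", "pseudo_gene"),
                          min_nt = 20L, floor_variance = 0.01) {
  stopifnot(pseudocount > 0, alpha_select > 0, alpha_select < 1,
            n_permutations >= 1, z_cut >= 0, fdr_cut > 0, fdr_cut <= 1,
            floor_variance > 0)
  if (n_permutations < 100) {
    warn("n_permutations < 100: gene permutation p-values will be coarse")
  }
  structure(list(pseudocount = pseudocount, alpha_select = alpha_select,
                 n_permutations = as.integer(n_permutations),
                 z_cut = z_cut, fdr_cut = fdr_cut, seed = as.integer(seed),
                 nt_reference = match.arg(nt_reference),
                 min_nt = as.integer(min_nt),
                 floor_variance = floor_variance),
            class = "screen_config")
}
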