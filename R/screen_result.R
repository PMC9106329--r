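#' Run the full screen inference for one comparison
#'
#' Chains the screen statistics end to end: non-targeting-anchored
#' normalization, the NT mean-variance null, per-sgRNA enrichment and
#' depletion tests, alpha robust rank aggregation with permutation
#' gene p-values in each direction independently, BH adjustment within
#' direction, per-gene direction resolution (smaller permutation p,
#' then smaller RRA score, then positive), median same-direction gene
#' LFC with its NT-referenced z-score, and the hit rule.
#'
#' @param counts Count-matrix tibble (`guide_id` + one column/sample).
#' @param lib Guide library.
#' @param control,treatment Sample column names; LFC is
#'   log2(treatment / control).
#' @param config A [screen_config()]; `config$seed` fixes the
#'   permutation draws (and the pseudo-gene reference, if selected).
#' @return A `screen_result` list with elements `sgrna` (per-guide
#'   tibble), `gene` (per-gene tibble), `model`, `size_factors`,
#'   `nt_lfcs`, `control`, `treatment`, `config`.  Supports
#'   [tidy()][generics::tidy], [glance()][generics::glance] and
#'   [autoplot()][ggplot2::autoplot].
#' @examples
#' lib <- make_library(sim_config(n_genes = 20, n_pos_controls = 0,
#'                                n_nt = 50, seed = 1))
#' eff <- tibble::tibble(gene = "RBP0001", expansion_effect = 0,
#'                       accumulation_effect = -2)
#' cm <- simulate_screen_counts(lib, eff,
#'                              sim_config(n_genes = 20, n_pos_controls = 0,
#'                                         n_nt = 50, seed = 1))
#' res <- screen_test(cm, lib, control = "cd138neg",
#'                    treatment = "cd138pos",
#'                    config = screen_config(n_permutations = 200, seed = 1))
#' head(tidy(res))
#' @export
screen_test <- function(counts, lib, control, treatment,
                        config = screen_config()) {
  lib <- validate_guide_library(lib)
  set.seed(config$seed)
  norm <- normalize_counts(counts, lib, config)
  model <- fit_mean_variance(norm, lib, c(control, treatment), config)
  stats <- sgrna_test(norm, model, control, treatment, lib, config)

  nt_guide_lfcs <- stats$lfc[stats$category == "non_targeting"]
  nt_lfcs <- nt_reference_lfcs(nt_guide_lfcs, lib, config)

  per_dir <- lapply(c("positive", "negative"), function(dir) {
    permute_gene_pvalues(stats, dir, config) |>
      mutate(direction = dir, fdr = bh_fdr(.data$p_perm))
  })
  both <- bind_rows(per_dir) |>
    group_by(.data$gene) |>
    arrange(.data$p_perm, .data$rra_score,
            match(.data$direction, c("positive", "negative")),
            .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup()

  lfc_by_gene <- split(stats$lfc[stats$category != "non_targeting"],
                       stats$gene[stats$category != "non_targeting"])
  gz <- purrr::map2(both$gene, both$direction, function(g, dir) {
    gene_lfc_and_z(lfc_by_gene[[g]], dir, nt_lfcs)
  })
  gene <- both |>
    mutate(gene_lfc = purrr::map_dbl(gz, "gene_lfc"),
           z = purrr::map_dbl(gz, "z"),
           flagged = purrr::map_lgl(gz, "flagged")) |>
    call_hits(config) |>
    arrange(.data$p_perm, .data$rra_score, .data$gene) |>
    select("gene", "direction", "n_guides", "rra_score", "p_perm",
           "fdr", "gene_lfc", "z", "flagged", "is_hit")

  structure(list(sgrna = stats, gene = gene, model = model,
                 size_factors = norm$size_factors, nt_lfcs = nt_lfcs,
                 control = control, treatment = treatment,
                 config = config),
            class = "screen_result")
}

# Reference LFC distribution for gene z-scores: either the raw NT guide
# LFCs, or median LFCs of random NT pseudo-genes of 10 guides.
nt_reference_lfcs <- function(nt_guide_lfcs, lib, config) {
  if (config$nt_reference == "guide") return(nt_guide_lfcs)
  m <- 10L
  n_pg <- max(50L, length(nt_guide_lfcs) %/% m)
  vapply(seq_len(n_pg), function(i) {
    median(sample(nt_guide_lfcs, m))
  }, numeric(1))
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", x$treatment, " vs ", x$control, "\n", sep = "")
  cat("  guides: ", nrow(x$sgrna), ", genes: ", nrow(x$gene),
      ", hits: ", sum(x$gene$is_hit), "\n", sep = "")
  cat("  mean-variance null: var(mu) = mu + ",
      signif(x$model$k, 3), " * mu^", signif(x$model$b, 3), "\n", sep = "")
  invisible(x)
}

#' Tidy a screen result
#'
#' @param x A `screen_result`.
#' @param level `"gene"` (default) or `"sgrna"`.
#' @param ... Unused.
#' @return The per-gene (or per-guide) result tibble.
#' @export
tidy.screen_result <- function(x, level = c("gene", "sgrna"), ...) {
  switch(match.arg(level), gene = x$gene, sgrna = x$sgrna)
}

#' One-row summary of a screen result
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @export
glance.screen_result <- function(x, ...) {
  tibble(control = x$control, treatment = x$treatment,
         n_guides = nrow(x$sgrna), n_genes = nrow(x$gene),
         n_hits = sum(x$gene$is_hit),
         n_hits_positive = sum(x$gene$is_hit & x$gene$direction == "positive"),
         n_hits_negative = sum(x$gene$is_hit & x$gene$direction == "negative"),
         mv_k = x$model$k, mv_b = x$model$b,
         nt_lfc_mean = mean(x$nt_lfcs), nt_lfc_sd = sd(x$nt_lfcs))
}

#' Volcano-style plot of a screen result
#'
#' Gene z-score against -log10 FDR, hits highlighted.
#'
#' @param object A `screen_result`.
#' @param ... Unused.
#' @export
autoplot.screen_result <- function(object, ...) {
  cfg <- object$config
  ggplot(object$gene, aes(x = .data$z, y = -log10(pmax(.data$fdr, 1e-12)),
                          colour = .data$is_hit)) +
    geom_point(alpha = 0.7, size = 1.2) +
    geom_vline(xintercept = c(-cfg$z_cut, cfg$z_cut), linetype = "dashed") +
    geom_hline(yintercept = -log10(cfg$fdr_cut), linetype = "dashed") +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                        name = "hit") +
    labs(x = "gene z-score (NT-referenced)", y = "-log10 FDR",
         title = paste(object$treatment, "vs", object$control)) +
    theme_minimal()
}

#' Write the per-sgRNA and per-gene tables of a screen result
#'
#' @param x A `screen_result`.
#' @param prefix Output path prefix; writes `<prefix>.sgrna.tsv` and
#'   `<prefix>.gene.tsv`.
#' @export
write_screen_result <- function(x, prefix) {
  readr::write_tsv(x$sgrna, paste0(prefix, ".sgrna.tsv"))
  readr::write_tsv(x$gene, paste0(prefix, ".gene.tsv"))
  invisible(prefix)
}
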