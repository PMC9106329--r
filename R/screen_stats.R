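#' Normalize a count matrix against non-targeting controls
#'
#' Size factors are median-of-ratios restricted to the non-targeting
#' control guides, which are the screen's designated null set: for each
#' NT guide with a nonzero geometric mean across samples, the ratio of
#' its count to that geometric mean is formed, and the per-sample size
#' factor is the median of those ratios.  Normalized values are counts
#' divided by the sample's size factor.
#'
#' @param counts Count-matrix tibble (`guide_id` + one column/sample).
#' @param lib Guide library the counts were made against.
#' @param config A [screen_config()].
#' @return A list with `matrix` (tibble of normalized values, same shape
#'   as `counts`), `size_factors` (named numeric) and `pseudocount`.
#' @export
normalize_counts <- function(counts, lib, config = screen_config()) {
  lib <- validate_guide_library(lib)
  samples <- setdiff(names(counts), "guide_id")
  if (length(samples) < 2) abort("normalization requires >= 2 samples")
  m <- as.matrix(counts[, samples])
  rownames(m) <- counts$guide_id
  nt_ids <- lib$guide_id[lib$category == "non_targeting"]
  nt <- m[rownames(m) %in% nt_ids, , drop = FALSE]
  geo <- exp(rowMeans(log(nt)))          # 0 (or NaN) if any count is 0
  usable <- is.finite(geo) & geo > 0
  if (sum(usable) < config$min_nt) {
    abort(paste0("only ", sum(usable), " non-targeting guides with ",
                 "nonzero geometric mean; need >= ", config$min_nt,
                 " (consider a total-count fallback)"))
  }
  sf <- apply(nt[usable, , drop = FALSE] / geo[usable], 2, median)
  norm <- sweep(m, 2, sf, "/")
  out <- tibble(guide_id = counts$guide_id)
  for (s in samples) out[[s]] <- unname(norm[, s])
  list(matrix = out, size_factors = sf, pseudocount = config$pseudocount)
}

#' Construct or fit a non-targeting mean-variance null model
#'
#' The null variance of a normalized count with mean `mu` is modelled as
#' `mu + k * mu^b` (Poisson sampling plus a power-law overdispersion
#' term).  `fit_mean_variance()` estimates `k` and `b` from the
#' non-targeting guides of one sample pair: per NT guide the pair mean
#' `mu = (x1 + x2)/2` and the paired variance proxy `v = (x1 - x2)^2/2`
#' are formed, guides are grouped into equal-occupancy bins of `mu`
#' (at least 5 per bin), and `log2(max(mean(v) - mean(mu), floor))` is
#' regressed on `log2(mean(mu))` across bins; the slope is `b` and
#' `2^intercept` is `k`.
#'
#' @param k,b Overdispersion coefficient and exponent.
#' @param fit_n Number of NT guides used in the fit.
#' @param floor_variance Floor applied to the binned excess variance.
#' @return A `mean_var_model` list with a `predict`-style helper
#'   [predict_null_variance()].
#' @export
mean_var_model <- function(k, b, fit_n = 0L, floor_variance = 0.01) {
  stopifnot(k >= 0, floor_variance > 0)
  structure(list(k = k, b = b, fit_n = as.integer(fit_n),
                 floor_variance = floor_variance),
            class = "mean_var_model")
}

#' @rdname mean_var_model
#' @param norm Result of [normalize_counts()].
#' @param lib Guide library.
#' @param pair Character vector of two sample names.
#' @param config A [screen_config()].
#' @export
fit_mean_variance <- function(norm, lib, pair, config = screen_config()) {
  stopifnot(length(pair) == 2)
  if (!all(pair %in% names(norm$matrix))) {
    abort("both samples of `pair` must be columns of the normalized matrix")
  }
  lib <- validate_guide_library(lib)
  nt_ids <- lib$guide_id[lib$category == "non_targeting"]
  nt <- norm$matrix |> filter(.data$guide_id %in% nt_ids)
  x1 <- nt[[pair[1]]]
  x2 <- nt[[pair[2]]]
  mu <- (x1 + x2) / 2
  v <- (x1 - x2)^2 / 2
  keep <- mu > 0
  if (sum(keep) < config$min_nt) {
    abort(paste0("only ", sum(keep), " non-targeting guides with positive ",
                 "mean across the pair; need >= ", config$min_nt))
  }
  mu <- mu[keep]
  v <- v[keep]
  n <- length(mu)
  n_bins <- max(1L, min(20L, n %/% 5L))
  bin <- ceiling(rank(mu, ties.method = "first") / (n / n_bins))
  mu_bar <- tapply(mu, bin, mean)
  v_bar <- tapply(v, bin, mean)
  excess <- pmax(v_bar - mu_bar, config$floor_variance)
  if (n_bins >= 2) {
    fit <- stats::lm.fit(cbind(1, log2(mu_bar)), log2(excess))
    b <- unname(fit$coefficients[2])
    k <- max(0, 2^unname(fit$coefficients[1]))
  } else {
    b <- 0
    k <- max(0, excess[[1]])
  }
  mean_var_model(k = k, b = b, fit_n = n,
                 floor_variance = config$floor_variance)
}

#' @rdname mean_var_model
#' @param model A `mean_var_model`.
#' @param mu Vector of positive null means.
#' @export
predict_null_variance <- function(model, mu) {
  mu + model$k * mu^model$b
}

#' Per-sgRNA enrichment and depletion tests
#'
#' For each guide the log2 fold change of pseudocounted normalized
#' counts between treatment and control is computed, and two one-sided
#' tail probabilities are taken under the null that the treatment count
#' is drawn around the control value: the null mean is the normalized
#' control count (floored at the pseudocount), the null variance comes
#' from the mean-variance model, and the tail distribution is negative
#' binomial with that mean and variance (collapsing to Poisson when the
#' modelled variance does not exceed the mean).  `p_enrich = P(X >=
#' round(t))` and `p_deplete = P(X <= round(t))`.  Guides are ranked
#' ascending by p within each direction; ties break by decreasing |LFC|
#' and then by guide_id.
#'
#' @param norm Result of [normalize_counts()].
#' @param model A [mean_var_model()] fitted on this comparison's
#'   non-targeting guides.
#' @param control_sample,treatment_sample Column names in the matrix.
#' @param lib Guide library (supplies gene and category columns).
#' @param config A [screen_config()].
#' @return A tibble with one row per guide: `guide_id`, `gene`,
#'   `category`, `lfc`, `p_enrich`, `p_deplete`, `rank_enrich`,
#'   `rank_deplete`, `selected_enrich`, `selected_deplete`.
#' @export
sgrna_test <- function(norm, model, control_sample, treatment_sample,
                       lib, config = screen_config()) {
  lib <- validate_guide_library(lib)
  mat <- norm$matrix
  c_val <- mat[[control_sample]]
  t_val <- mat[[treatment_sample]]
  if (is.null(c_val) || is.null(t_val)) {
    abort("control/treatment samples must be columns of the matrix")
  }
  pc <- config$pseudocount
  lfc <- log2((t_val + pc) / (c_val + pc))
  mu <- pmax(c_val, pc)
  sigma2 <- predict_null_variance(model, mu)
  t_round <- round(t_val)
  nb <- sigma2 > mu
  p_enrich <- p_deplete <- numeric(length(mu))
  if (any(nb)) {
    size <- mu[nb]^2 / (sigma2[nb] - mu[nb])
    p_enrich[nb] <- pnbinom(t_round[nb] - 1, size = size, mu = mu[nb],
                            lower.tail = FALSE)
    p_deplete[nb] <- pnbinom(t_round[nb], size = size, mu = mu[nb])
  }
  if (any(!nb)) {
    p_enrich[!nb] <- ppois(t_round[!nb] - 1, lambda = mu[!nb],
                           lower.tail = FALSE)
    p_deplete[!nb] <- ppois(t_round[!nb], lambda = mu[!nb])
  }
  res <- tibble(guide_id = mat$guide_id) |>
    left_join(lib[, c("guide_id", "gene", "category")], by = "guide_id") |>
    mutate(lfc = lfc, p_enrich = p_enrich, p_deplete = p_deplete)
  rank_dir <- function(p, lfc, id) {
    order(order(p, -abs(lfc), id))
  }
  res |>
    mutate(
      rank_enrich = rank_dir(.data$p_enrich, .data$lfc, .data$guide_id),
      rank_deplete = rank_dir(.data$p_deplete, .data$lfc, .data$guide_id),
      selected_enrich = .data$p_enrich < config$alpha_select,
      selected_deplete = .data$p_deplete < config$alpha_select
    )
}

# Core alpha-RRA statistic from normalized ranks of selected guides.
# u_sel: normalized ranks (rank / N_total) of the gene's selected
# guides; m: total guides for the gene.  Score is the minimum over the
# leading order statistics of the Beta(k, m - k + 1) CDF; 1 if nothing
# is selected.
rra_from_u <- function(u_sel, m) {
  j <- length(u_sel)
  if (j == 0) return(1)
  u <- sort(u_sel)
  k <- seq_len(j)
  min(pbeta(u, k, m - k + 1))
}

#' Alpha robust rank aggregation score for one gene
#'
#' Guides with a direction p-value below `alpha_select` are "selected";
#' their ranks among all `n_total` guides are converted to normalized
#' order statistics `u = rank / n_total`, and the score is the smallest
#' Beta(k, m - k + 1) CDF value over the leading order statistics — the
#' probability that the k-th best of m uniform ranks would be at least
#' this extreme.  A gene with no selected guide scores 1.
#'
#' @param p Direction p-values for the gene's guides.
#' @param rank Direction ranks for the same guides (over all guides).
#' @param n_total Total number of ranked guides.
#' @param alpha_select Selection threshold.
#' @return The RRA score in (0, 1].
#' @export
alpha_rra_score <- function(p, rank, n_total, alpha_select = 0.05) {
  m <- length(p)
  if (m == 0) abort("gene must have at least one guide")
  stopifnot(length(rank) == m, all(rank >= 1), all(rank <= n_total))
  rra_from_u(rank[p < alpha_select] / n_total, m)
}

#' Gene-level permutation p-values for RRA scores
#'
#' Null scores are generated by randomizing the sgRNA-to-gene
#' allocation: for each gene size class m, `n_permutations` random sets
#' of m guides are drawn from all targeting guides and scored; draws are
#' pooled across genes of identical size.  The permutation p-value is
#' `(1 + #(null <= observed)) / (1 + n_permutations)`.
#'
#' @param stats sgRNA stat tibble from [sgrna_test()].
#' @param direction `"positive"` (enrichment) or `"negative"` (depletion).
#' @param config A [screen_config()]; the RNG must already be seeded by
#'   the caller (see [screen_test()]).
#' @return A tibble `gene`, `n_guides`, `rra_score`, `p_perm`.
#' @export
permute_gene_pvalues <- function(stats, direction = c("positive", "negative"),
                                 config = screen_config()) {
  direction <- match.arg(direction)
  p_col <- if (direction == "positive") "p_enrich" else "p_deplete"
  r_col <- if (direction == "positive") "rank_enrich" else "rank_deplete"
  n_total <- nrow(stats)
  targeting <- stats |> filter(.data$category != "non_targeting")
  u_all <- targeting[[r_col]] / n_total
  sel_all <- targeting[[p_col]] < config$alpha_select
  obs <- targeting |>
    group_by(.data$gene) |>
    summarise(n_guides = dplyr::n(),
              rra_score = rra_from_u(
                (.data[[r_col]][.data[[p_col]] < config$alpha_select]) /
                  n_total,
                dplyr::n()),
              .groups = "drop")
  n_t <- nrow(targeting)
  null_by_m <- lapply(unique(obs$n_guides), function(m) {
    vapply(seq_len(config$n_permutations), function(i) {
      idx <- sample.int(n_t, m)
      rra_from_u(u_all[idx][sel_all[idx]], m)
    }, numeric(1))
  })
  names(null_by_m) <- as.character(unique(obs$n_guides))
  obs |>
    mutate(p_perm = purrr::map2_dbl(
      .data$rra_score, .data$n_guides,
      function(s, m) {
        null <- null_by_m[[as.character(m)]]
        (1 + sum(null <= s)) / (1 + length(null))
      }))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validating wrapper around the standard step-up adjustment
#' (`stats::p.adjust(method = "BH")`); output order matches input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Gene log2 fold change and non-targeting-referenced z-score
#'
#' The gene LFC is the median of the LFCs of the gene's guides whose
#' sign matches the direction (positive direction: lfc > 0; negative:
#' lfc < 0).  The z-score expresses that median in standard deviations
#' of the non-targeting control LFC distribution.  If no guide matches
#' the direction, both are 0 and the gene is flagged.
#'
#' @param guide_lfcs LFCs of one gene's guides.
#' @param direction `"positive"` or `"negative"`.
#' @param nt_lfcs Reference LFCs of non-targeting controls.
#' @return A list `gene_lfc`, `z`, `flagged`.
#' @export
gene_lfc_and_z <- function(guide_lfcs, direction = c("positive", "negative"),
                           nt_lfcs) {
  direction <- match.arg(direction)
  nt_sd <- sd(nt_lfcs)
  if (!is.finite(nt_sd) || nt_sd == 0) {
    abort("non-targeting LFC reference has zero standard deviation")
  }
  same <- if (direction == "positive") guide_lfcs > 0 else guide_lfcs < 0
  if (!any(same)) {
    return(list(gene_lfc = 0, z = 0, flagged = TRUE))
  }
  gene_lfc <- median(guide_lfcs[same])
  list(gene_lfc = gene_lfc,
       z = (gene_lfc - mean(nt_lfcs)) / nt_sd,
       flagged = FALSE)
}

#' Apply the hit rule to a gene result table
#'
#' A gene is a hit when its z-score magnitude reaches `z_cut` (boundary
#' inclusive) and its BH-adjusted permutation p-value is below
#' `fdr_cut`: the defaults encode |Z| >= 2 and FDR < 0.05.
#'
#' @param results Gene result tibble with `z` and `fdr` columns.
#' @param config A [screen_config()].
#' @return The tibble with `is_hit` (re)computed.
#' @export
call_hits <- function(results, config = screen_config()) {
  results |>
    mutate(is_hit = abs(.data$z) >= config$z_cut &
             .data$fdr < config$fdr_cut)
}
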