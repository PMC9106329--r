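#' Metagene profile of cluster occupancy over scaled CDS regions
#'
#' One representative transcript per gene (the longest total CDS,
#' ties broken by transcript_id) contributes a row: its genomic CDS
#' span is scaled into `n_bins_body` bins and flanked by
#' `flank_bp / bin_bp` fixed-width bins up- and downstream, oriented
#' 5' to 3'.  A bin scores 1 if any same-strand cluster overlaps its
#' genomic interval and 0 otherwise (the maximum of an indicator,
#' without skipping zeros), and the profile is the per-bin mean over
#' genes — the fraction of genes with a cluster in that bin.
#'
#' @param clusters Cluster tibble (`chrom`, `start`, `end` 0-based
#'   half-open, `strand`).
#' @param models Transcript models from [parse_annotation()].
#' @param n_bins_body Bins across the scaled CDS (default 100).
#' @param flank_bp Flank size in bp (default 1000).
#' @param bin_bp Flank bin width in bp (default 10).
#' @return A `metagene_profile` tibble: `bin` (1..total), `region`
#'   (`upstream`/`body`/`downstream`), `position` (-flank_bins..),
#'   `value` in [0, 1]; attribute `n_genes`.
#' @export
compute_metagene <- function(clusters, models, n_bins_body = 100L,
                             flank_bp = 1000L, bin_bp = 10L) {
  stopifnot(flank_bp %% bin_bp == 0)
  coding <- models |>
    filter(purrr::map_int(.data$cds, nrow) > 0) |>
    mutate(cds_len = purrr::map_int(
      .data$cds, function(m) sum(m[, 2] - m[, 1] + 1L)))
  if (nrow(coding) == 0) abort("no coding transcripts in the annotation")
  rep_tx <- coding |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$cds_len), .data$transcript_id,
            .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup()

  flank_bins <- as.integer(flank_bp / bin_bp)
  total_bins <- flank_bins + n_bins_body + flank_bins

  bin_tbl <- bind_rows(lapply(seq_len(nrow(rep_tx)), function(i) {
    cdsm <- rep_tx$cds[[i]]
    span <- c(min(cdsm[, 1]), max(cdsm[, 2]))   # 1-based closed
    gene_bins(span, rep_tx$strand[i], rep_tx$chrom[i],
              n_bins_body, flank_bins, bin_bp) |>
      mutate(gene_id = rep_tx$gene_id[i])
  }))

  q <- GenomicRanges::GRanges(bin_tbl$chrom,
                              IRanges::IRanges(pmax(bin_tbl$start, 1L),
                                               pmax(bin_tbl$end, 1L)),
                              strand = bin_tbl$strand)
  s <- GenomicRanges::GRanges(clusters$chrom,
                              IRanges::IRanges(clusters$start + 1L,
                                               clusters$end),
                              strand = clusters$strand)
  hit <- GenomicRanges::countOverlaps(q, s) > 0
  hit[bin_tbl$end < 1] <- FALSE          # bins off the chromosome start

  profile <- bin_tbl |>
    mutate(hit = as.numeric(hit)) |>
    group_by(.data$bin) |>
    summarise(value = mean(.data$hit), .groups = "drop") |>
    mutate(region = dplyr::case_when(
      .data$bin <= flank_bins ~ "upstream",
      .data$bin <= flank_bins + n_bins_body ~ "body",
      TRUE ~ "downstream"),
      position = .data$bin - flank_bins) |>
    select("bin", "region", "position", "value")
  structure(profile,
            class = c("metagene_profile", class(profile)),
            n_genes = nrow(rep_tx), n_bins_body = n_bins_body,
            flank_bins = flank_bins, bin_bp = bin_bp)
}

# Genomic bin intervals (1-based closed) for one gene in 5'->3' order:
# flank_bins upstream bins, n_body scaled body bins, flank_bins
# downstream.  For minus-strand genes the genomic layout is mirrored.
gene_bins <- function(span, strand, chrom, n_body, flank_bins, bin_bp) {
  L <- span[2] - span[1] + 1
  edges <- span[1] - 1 + round(seq(0, L, length.out = n_body + 1))
  body <- tibble(start = as.integer(edges[-(n_body + 1)] + 1),
                 end = as.integer(edges[-1]))
  # degenerate rounding can make empty bins; clamp to at least 1 bp
  body$end <- pmax(body$end, body$start)
  up_edges <- span[1] - bin_bp * (flank_bins:0)
  up <- tibble(start = as.integer(up_edges[-(flank_bins + 1)]),
               end = as.integer(up_edges[-1] - 1))
  down_edges <- span[2] + bin_bp * (0:flank_bins)
  down <- tibble(start = as.integer(down_edges[-(flank_bins + 1)] + 1),
                 end = as.integer(down_edges[-1]))
  out <- bind_rows(up, body, down)
  if (strand == "-") out <- out[rev(seq_len(nrow(out))), ]
  out |>
    mutate(bin = dplyr::row_number(), chrom = chrom, strand = strand)
}

#' Plot a metagene profile
#'
#' @param profile A `metagene_profile` from [compute_metagene()].
#' @export
plot_metagene <- function(profile) {
  flank_bins <- attr(profile, "flank_bins")
  n_body <- attr(profile, "n_bins_body")
  ggplot(profile, aes(x = .data$bin, y = .data$value)) +
    geom_line(colour = "steelblue") +
    geom_vline(xintercept = c(flank_bins + 0.5, flank_bins + n_body + 0.5),
               linetype = "dashed", colour = "grey50") +
    labs(x = "bin (upstream flank | scaled CDS | downstream flank)",
         y = "fraction of genes with a cluster",
         title = "m6A cluster metagene profile") +
    theme_minimal()
}

#' @rdname plot_metagene
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @export
autoplot.metagene_profile <- function(object, ...) plot_metagene(object)
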