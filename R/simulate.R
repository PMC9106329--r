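#' Simulation configuration for synthetic screens
#'
#' Defaults encode the screen library design: 1213 RBP genes and 72
#' positive-control genes at 10 sgRNAs per gene plus 500 non-targeting
#' controls (13,350 guides), a log-normal plasmid distribution whose
#' spread keeps more than 98.8% of guides within a 16-fold abundance
#' range (`plasmid_sigma = 0.75` log2 units gives 99.2% central mass,
#' so the realized library clears the 98.8% QC bound at any seed), a
#' mean depth of 500 reads per guide, and negative-binomial counting
#' noise with dispersion 0.05.
#'
#' @param n_genes Number of target genes (default 1213).
#' @param sgrnas_per_gene Guides per gene (default 10).
#' @param n_pos_controls Positive-control genes (default 72).
#' @param n_nt Non-targeting guides (default 500).
#' @param plasmid_sigma SD of log2 plasmid abundance (default 0.75).
#' @param depth Mean reads per guide (default 500).
#' @param nb_dispersion Negative-binomial dispersion; 0 gives Poisson
#'   (default 0.05).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1213L, sgrnas_per_gene = 10L,
                       n_pos_controls = 72L, n_nt = 500L,
                       plasmid_sigma = 0.75, depth = 500,
                       nb_dispersion = 0.05, seed = 1L) {
  stopifnot(n_genes >= 1, sgrnas_per_gene >= 1, n_pos_controls >= 0,
            n_nt >= 0, plasmid_sigma > 0, depth > 0, nb_dispersion >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 sgrnas_per_gene = as.integer(sgrnas_per_gene),
                 n_pos_controls = as.integer(n_pos_controls),
                 n_nt = as.integer(n_nt),
                 plasmid_sigma = plasmid_sigma, depth = depth,
                 nb_dispersion = nb_dispersion, seed = as.integer(seed)),
            class = "sim_config")
}

random_kmers <- function(n, k) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE),
              nrow = n)
  apply(m, 1, paste0, collapse = "")
}

#' Generate a synthetic guide library
#'
#' Random distinct 19-mer protospacers for
#' `(n_genes + n_pos_controls) * sgrnas_per_gene` targeting guides plus
#' `n_nt` non-targeting controls; deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A validated guide-library tibble.
#' @export
make_library <- function(config = sim_config()) {
  n_target_genes <- config$n_genes + config$n_pos_controls
  n_total <- n_target_genes * config$sgrnas_per_gene + config$n_nt
  if (n_total > 1e6) {
    abort("requested library exceeds the protospacer uniqueness budget")
  }
  set.seed(config$seed)
  proto <- unique(random_kmers(ceiling(n_total * 1.05), PROTOSPACER_LEN))
  while (length(proto) < n_total) {
    proto <- unique(c(proto, random_kmers(n_total, PROTOSPACER_LEN)))
  }
  proto <- proto[seq_len(n_total)]
  genes <- c(sprintf("RBP%04d", seq_len(config$n_genes)),
             if (config$n_pos_controls > 0)
               sprintf("POS%03d", seq_len(config$n_pos_controls)))
  tgt_gene <- rep(genes, each = config$sgrnas_per_gene)
  tgt_cat <- rep(c(rep("rbp_target", config$n_genes),
                   rep("positive_control", config$n_pos_controls)),
                 each = config$sgrnas_per_gene)
  guide_library(
    guide_id = c(paste0(tgt_gene, "_sg",
                        rep(seq_len(config$sgrnas_per_gene),
                            times = n_target_genes)),
                 if (config$n_nt > 0) sprintf("NT_%04d", seq_len(config$n_nt))),
    protospacer = proto,
    gene = c(tgt_gene, rep(NA_character_, config$n_nt)),
    category = c(tgt_cat, rep("non_targeting", config$n_nt)))
}

#' Simulate screen counts with planted effects
#'
#' Each guide receives a log-normal baseline abundance (shared across
#' populations, emulating the plasmid library).  Expected counts are
#' `depth * abundance` at day4; day8 multiplies effect-carrying guides
#' of a gene by `2^expansion_effect`; the CD138- population inherits
#' the day8 expectation and CD138+ multiplies it by
#' `2^accumulation_effect`, so the planted accumulation LFC equals the
#' effect.  Counts are drawn negative-binomial with the configured
#' dispersion (Poisson when 0).  Non-targeting guides never carry
#' effects.
#'
#' @param lib Guide library (typically [make_library()]).
#' @param effects Tibble `gene`, `expansion_effect`,
#'   `accumulation_effect` (log2 multipliers); genes not listed have no
#'   effect.  May be `NULL` for a fully null screen.
#' @param config A [sim_config()].
#' @param guide_penetrance Fraction of a gene's guides carrying its
#'   effect (default 1).
#' @return A count-matrix tibble with samples `day4`, `day8`,
#'   `cd138neg`, `cd138pos`; attribute `baseline` carries the realized
#'   per-guide plasmid abundance.
#' @export
simulate_screen_counts <- function(lib, effects = NULL,
                                   config = sim_config(),
                                   guide_penetrance = 1) {
  lib <- validate_guide_library(lib)
  stopifnot(guide_penetrance > 0, guide_penetrance <= 1)
  if (!is.null(effects)) {
    bad <- setdiff(effects$gene, lib$gene)
    if (length(bad) > 0) {
      abort(paste0("effects reference genes absent from the library: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  set.seed(config$seed + 1L)
  n <- nrow(lib)
  abundance <- 2^rnorm(n, 0, config$plasmid_sigma)
  abundance <- abundance / mean(abundance)

  exp_eff <- acc_eff <- numeric(n)
  if (!is.null(effects) && nrow(effects) > 0) {
    for (i in seq_len(nrow(effects))) {
      g_idx <- which(lib$gene %in% effects$gene[i])
      m <- length(g_idx)
      carriers <- sample(g_idx, max(1L, round(guide_penetrance * m)))
      exp_eff[carriers] <- effects$expansion_effect[i]
      acc_eff[carriers] <- effects$accumulation_effect[i]
    }
  }
  mu_day4 <- config$depth * abundance
  mu_day8 <- mu_day4 * 2^exp_eff
  mu_neg <- mu_day8
  mu_pos <- mu_day8 * 2^acc_eff

  draw <- function(mu) {
    if (config$nb_dispersion == 0) return(rpois(n, mu))
    rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
  }
  out <- tibble(guide_id = lib$guide_id,
                day4 = as.integer(draw(mu_day4)),
                day8 = as.integer(draw(mu_day8)),
                cd138neg = as.integer(draw(mu_neg)),
                cd138pos = as.integer(draw(mu_pos)))
  attr(out, "baseline") <- abundance
  out
}

#' Fraction of guides within a fold-range window
#'
#' The guide-representation QC statistic: the largest fraction of
#' guides whose abundances fit inside any window of `fold`-fold width
#' (4 log2 units for the default 16-fold).
#'
#' @param abundance Positive abundances.
#' @param fold Window width as a fold change (default 16).
#' @return A fraction in (0, 1].
#' @export
fraction_within_fold <- function(abundance, fold = 16) {
  x <- sort(log2(abundance))
  w <- log2(fold)
  # two-pointer sweep for the densest width-w window
  j <- 1L
  best <- 0L
  for (i in seq_along(x)) {
    while (x[i] - x[j] > w) j <- j + 1L
    best <- max(best, i - j + 1L)
  }
  best / length(x)
}

#' Write simulated reads for one sample as FASTQ
#'
#' For each guide, `count` reads of the form random prefix (0-6 nt) +
#' protospacer + scaffold anchor + random suffix (fixed 50 nt total),
#' constant quality, in shuffled order.  A `.gz` suffix on `path`
#' writes gzip.
#'
#' @param counts Tibble `guide_id`, `count` (e.g. one sample's column
#'   of a count matrix).
#' @param lib Guide library.
#' @param path Output FASTQ path.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
simulate_fastq <- function(counts, lib, path, seed = 1L) {
  lib <- validate_guide_library(lib)
  stopifnot(all(counts$guide_id %in% lib$guide_id))
  set.seed(seed)
  counts <- counts |> filter(.data$count > 0)
  n_reads <- sum(counts$count)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (n_reads == 0) return(invisible(path))
  proto <- lib$protospacer[match(counts$guide_id, lib$guide_id)]
  proto_rep <- rep(proto, counts$count)
  prefix_len <- sample(0:6, n_reads, replace = TRUE)
  read_len <- 50L
  core_len <- PROTOSPACER_LEN + nchar(SCAFFOLD_ANCHOR)
  reads <- vapply(seq_len(n_reads), function(i) {
    pre <- paste0(sample(c("A", "C", "G", "T"), prefix_len[i],
                         replace = TRUE), collapse = "")
    suf_len <- read_len - prefix_len[i] - core_len
    suf <- paste0(sample(c("A", "C", "G", "T"), suf_len, replace = TRUE),
                  collapse = "")
    paste0(pre, proto_rep[i], SCAFFOLD_ANCHOR, suf)
  }, character(1))
  ord <- sample.int(n_reads)
  qual <- strrep("I", read_len)
  writeLines(paste0("@read", seq_len(n_reads), "\n", reads[ord], "\n+\n",
                    qual), con)
  invisible(path)
}

#' Generate a toy annotated transcriptome
#'
#' Random chromosome sequences carrying a mixture of coding genes (2-5
#' exons, 5' and 3' UTRs, varying transcript support levels and CCDS
#' flags, both strands) and non-coding genes, plus a GTF serialization
#' that [parse_annotation()] round-trips.
#'
#' @param n_genes Number of genes (default 20).
#' @param seed Integer seed.
#' @param coding_fraction Fraction of genes that are protein coding
#'   (default 0.75; at least one coding gene is always produced).
#' @return A list `genome` ([Biostrings::DNAStringSet]), `models`
#'   (transcript-model tibble in [parse_annotation()] layout) and
#'   `gtf_lines` (character vector; see [write_toy_annotation()]).
#' @export
make_toy_annotation <- function(n_genes = 20L, seed = 1L,
                                coding_fraction = 0.75) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  margin <- 1500L            # room for 1 kb metagene flanks
  gap <- function() sample(300:800, 1)
  n_chrom <- max(2L, ceiling(n_genes / 6))
  chrom_of <- rep(sprintf("chr%d", seq_len(n_chrom)), length.out = n_genes)
  strand_of <- sample(rep(c("+", "-"), length.out = n_genes))
  coding <- runif(n_genes) < coding_fraction
  coding[1] <- TRUE

  cursor <- setNames(rep(margin, n_chrom), sprintf("chr%d", seq_len(n_chrom)))
  rows <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    ch <- chrom_of[g]
    n_ex <- sample(2:5, 1)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(80:300, n_ex - 1, replace = TRUE) else integer(0)
    start <- cursor[ch] + gap()
    ex_start <- start + c(0, cumsum(ex_len[-n_ex] + in_len))
    ex_end <- ex_start + ex_len - 1L
    cursor[ch] <- ex_end[n_ex]
    exons <- cbind(start = as.integer(ex_start), end = as.integer(ex_end))
    exonic_len <- sum(ex_len)
    if (coding[g]) {
      utr5 <- sample(30:120, 1)
      utr3 <- sample(150:400, 1)
      cds_len <- exonic_len - utr5 - utr3
      cds_len <- cds_len - cds_len %% 3
      if (cds_len < 90) { utr3 <- max(60L, exonic_len - utr5 - 90L)
        cds_len <- exonic_len - utr5 - utr3
        cds_len <- cds_len - cds_len %% 3 }
      # exonic coordinates are 5'->3'; convert to genomic per strand
      if (strand_of[g] == "+") {
        cds_ex <- c(utr5 + 1L, utr5 + cds_len)
      } else {
        cds_ex <- c(exonic_len - utr5 - cds_len + 1L, exonic_len - utr5)
      }
      cds <- exonic_to_genomic_ivs(exons, cds_ex[1], cds_ex[2])
      tsl <- sample(c(1:5, NA_integer_), 1)
      has_ccds <- runif(1) < 0.5
      biotype <- "protein_coding"
    } else {
      cds <- cbind(start = integer(0), end = integer(0))
      tsl <- sample(c(1:5, NA_integer_), 1)
      has_ccds <- FALSE
      biotype <- "lincRNA"
    }
    rows[[g]] <- tibble(
      transcript_id = sprintf("TX%04d", g),
      gene_id = sprintf("GENE%04d", g),
      chrom = ch, strand = strand_of[g], biotype = biotype,
      tsl = as.integer(tsl), has_ccds = has_ccds,
      exons = list(exons), cds = list(cds))
  }
  models <- bind_rows(rows) |> arrange(.data$transcript_id)
  class(models) <- c("transcript_models", class(models))

  chrom_len <- cursor + margin
  genome <- Biostrings::DNAStringSet(vapply(names(chrom_len), function(ch) {
    paste0(sample(c("A", "C", "G", "T"), chrom_len[ch], replace = TRUE),
           collapse = "")
  }, character(1)))
  list(genome = genome, models = models, gtf_lines = models_to_gtf(models))
}

# Map an exonic-coordinate interval (1-based along the spliced, genomic
# left-to-right exon order) to genomic intervals.
exonic_to_genomic_ivs <- function(exons, from, to) {
  widths <- exons[, 2] - exons[, 1] + 1L
  cum <- cumsum(widths)
  offs <- c(0L, cum[-length(cum)])
  out <- list()
  for (i in seq_len(nrow(exons))) {
    lo <- max(from, offs[i] + 1L)
    hi <- min(to, cum[i])
    if (lo <= hi) {
      out[[length(out) + 1]] <- c(exons[i, 1] + (lo - offs[i]) - 1L,
                                  exons[i, 1] + (hi - offs[i]) - 1L)
    }
  }
  m <- do.call(rbind, out)
  cbind(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

# Genomic position (1-based) of the j-th exonic base counting 5'->3'
# along the transcript.
exonic_pos_to_genomic <- function(exons, strand, j) {
  widths <- exons[, 2] - exons[, 1] + 1L
  total <- sum(widths)
  jj <- if (strand == "+") j else total - j + 1L   # genomic left-to-right
  cum <- cumsum(widths)
  i <- findInterval(jj - 1L, c(0L, cum))           # exon index
  off <- jj - c(0L, cum)[i]
  exons[i, 1] + off - 1L
}

models_to_gtf <- function(models) {
  lines <- character(0)
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    exons <- m$exons[[1]]
    cds <- m$cds[[1]]
    attrs <- paste0('gene_id "', m$gene_id, '"; transcript_id "',
                    m$transcript_id, '"; transcript_biotype "',
                    m$biotype, '";',
                    if (!is.na(m$tsl))
                      paste0(' transcript_support_level "', m$tsl, '";')
                    else "",
                    if (m$has_ccds)
                      paste0(' ccds_id "CCDS', i, '";') else "")
    row <- function(type, s, e) {
      paste(m$chrom, "toy", type, s, e, ".", m$strand, ".", attrs,
            sep = "\t")
    }
    lines <- c(lines,
               row("transcript", min(exons[, 1]), max(exons[, 2])),
               vapply(seq_len(nrow(exons)), function(j)
                 row("exon", exons[j, 1], exons[j, 2]), character(1)),
               if (nrow(cds) > 0)
                 vapply(seq_len(nrow(cds)), function(j)
                   row("CDS", cds[j, 1], cds[j, 2]), character(1)))
  }
  lines
}

#' @rdname make_toy_annotation
#' @param toy Result of [make_toy_annotation()].
#' @param gtf_path,fasta_path Output paths.
#' @export
write_toy_annotation <- function(toy, gtf_path, fasta_path) {
  writeLines(toy$gtf_lines, gtf_path)
  Biostrings::writeXStringSet(toy$genome, fasta_path)
  invisible(list(gtf = gtf_path, fasta = fasta_path))
}

#' Plant m6A-like crosslink sites and clusters on a toy transcriptome
#'
#' Sites are placed on the exonic territory of one representative
#' coding transcript per gene: a `stop_bias` fraction within 100 nt of
#' the stop codon (in transcript coordinates) and the remainder
#' uniformly over the transcript.  A `motif_fraction` of all sites has
#' the genome edited so the 5 bases centred on the site spell `motif`
#' in transcript orientation.  Clusters are +/-20 nt windows around
#' sites.  Placements whose motif window would leave the chromosome or
#' collide with an already-planted window are resampled (logged).
#'
#' @param toy Result of [make_toy_annotation()].
#' @param n_sites Number of sites.
#' @param motif 5-mer planted at motif sites (default "GGACT", a DRACH
#'   instance).
#' @param motif_fraction Fraction of sites carrying the motif.
#' @param stop_bias Fraction of sites placed near stop codons.
#' @param seed Integer seed.
#' @return A list `genome` (edited [Biostrings::DNAStringSet]), `sites`
#'   and `clusters` tibbles.
#' @export
plant_crosslink_sites <- function(toy, n_sites, motif = "GGACT",
                                  motif_fraction = 0.6, stop_bias = 0.5,
                                  seed = 1L) {
  stopifnot(nchar(motif) == 5, motif_fraction >= 0, motif_fraction <= 1,
            stop_bias >= 0, stop_bias <= 1)
  set.seed(seed)
  models <- toy$models
  coding <- models |>
    filter(purrr::map_int(.data$cds, nrow) > 0) |>
    mutate(cds_len = purrr::map_int(
      .data$cds, function(m) sum(m[, 2] - m[, 1] + 1L))) |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$cds_len), .data$transcript_id,
            .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup()
  if (nrow(coding) == 0) abort("toy annotation has no coding transcripts")
  if (n_sites == 0) {
    empty_sites <- tibble(chrom = character(0), pos = integer(0),
                          strand = character(0), site_id = character(0),
                          score = numeric(0))
    empty_clusters <- tibble(chrom = character(0), start = integer(0),
                             end = integer(0), strand = character(0),
                             cluster_id = character(0), lfc = numeric(0))
    return(list(genome = toy$genome, sites = empty_sites,
                clusters = empty_clusters))
  }

  # transcript-coordinate stop position = last CDS base, 5'->3'
  tx_info <- lapply(seq_len(nrow(coding)), function(i) {
    exons <- coding$exons[[i]]
    strand <- coding$strand[i]
    exonic_len <- sum(exons[, 2] - exons[, 1] + 1L)
    cds <- coding$cds[[i]]
    cds_gen <- if (strand == "+") max(cds[, 2]) else min(cds[, 1])
    # exonic index of the stop-codon-side CDS boundary
    widths <- exons[, 2] - exons[, 1] + 1L
    cum <- cumsum(widths)
    offs <- c(0L, cum[-length(cum)])
    ex_i <- which(cds_gen >= exons[, 1] & cds_gen <= exons[, 2])
    j_left <- offs[ex_i] + (cds_gen - exons[ex_i, 1]) + 1L
    stop_tc <- if (strand == "+") j_left else exonic_len - j_left + 1L
    list(exons = exons, strand = strand, chrom = coding$chrom[i],
         exonic_len = exonic_len, stop_tc = stop_tc)
  })

  gene_idx <- sample.int(nrow(coding), n_sites, replace = TRUE)
  near_stop <- seq_len(n_sites) <= round(stop_bias * n_sites)
  with_motif <- sample(seq_len(n_sites)) <= round(motif_fraction * n_sites)

  genome_chr <- setNames(as.character(toy$genome), names(toy$genome))
  used_windows <- list()
  window_free <- function(ch, lo, hi) {
    prev <- used_windows[[ch]]
    if (is.null(prev)) return(TRUE)
    !any(lo <= prev[, 2] & hi >= prev[, 1])
  }
  n_resampled <- 0L
  pos <- integer(n_sites)
  chrom <- character(n_sites)
  strand <- character(n_sites)
  for (s in seq_len(n_sites)) {
    info <- tx_info[[gene_idx[s]]]
    repeat {
      tc <- if (near_stop[s]) {
        lo_tc <- max(3L, info$stop_tc - 100L)
        hi_tc <- min(info$exonic_len - 2L, info$stop_tc + 100L)
        lo_tc + sample.int(hi_tc - lo_tc + 1L, 1) - 1L
      } else {
        2L + sample.int(info$exonic_len - 4L, 1)
      }
      gpos <- exonic_pos_to_genomic(info$exons, info$strand, tc)
      lo <- gpos - 2L
      hi <- gpos + 2L
      if (lo >= 1 && hi <= nchar(genome_chr[[info$chrom]]) &&
          window_free(info$chrom, lo - 4L, hi + 4L)) break
      n_resampled <- n_resampled + 1L
    }
    used_windows[[info$chrom]] <- rbind(used_windows[[info$chrom]],
                                        c(lo, hi))
    if (with_motif[s]) {
      planted <- if (info$strand == "+") motif else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(motif)))
      substr(genome_chr[[info$chrom]], lo, hi) <- planted
    }
    pos[s] <- gpos - 1L            # 0-based
    chrom[s] <- info$chrom
    strand[s] <- info$strand
  }
  if (n_resampled > 0) {
    inform(paste0(n_resampled, " site placement(s) resampled (bounds or ",
                  "window collisions)"))
  }
  sites <- tibble(chrom = chrom, pos = pos, strand = strand,
                  site_id = sprintf("site_%05d", seq_len(n_sites)),
                  score = round(runif(n_sites, 1, 10), 3))
  clusters <- tibble(chrom = chrom,
                     start = pmax(pos - 20L, 0L),
                     end = pos + 21L,
                     strand = strand,
                     cluster_id = sprintf("cluster_%05d", seq_len(n_sites)),
                     lfc = round(runif(n_sites, 1, 6), 3))
  list(genome = Biostrings::DNAStringSet(genome_chr), sites = sites,
       clusters = clusters)
}
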