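#' Extract the k-mer centred on each crosslink site
#'
#' Returns the `k` genomic bases centred on each site (positions
#' `pos - 2 .. pos + 2` for the default `k = 5`), reverse-complemented
#' for minus-strand sites so the k-mer reads in transcript orientation.
#' Windows that run off the chromosome or contain a non-ACGT base give
#' `NA`.
#'
#' @param sites Site tibble (`chrom`, `pos` 0-based, `strand`).
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome.
#' @param k Odd window size (default 5).
#' @return Character vector of k-mers (`NA` where unscorable).
#' @export
extract_kmer <- function(sites, genome, k = 5L) {
  stopifnot(k %% 2 == 1)
  half <- (k - 1L) %/% 2L
  unknown <- setdiff(unique(sites$chrom), names(genome))
  if (length(unknown) > 0) {
    abort(paste0("chromosome(s) absent from genome: ",
                 paste(unknown, collapse = ", ")))
  }
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  # 1-based window: site pos is 0-based, so centre base is pos + 1
  w_start <- sites$pos + 1L - half
  w_end <- sites$pos + 1L + half
  ok <- w_start >= 1L & w_end <= chrom_len[sites$chrom]
  out <- rep(NA_character_, nrow(sites))
  if (any(ok)) {
    seqs <- Biostrings::subseq(genome[sites$chrom[ok]],
                               start = w_start[ok], end = w_end[ok])
    minus <- sites$strand[ok] == "-"
    if (any(minus)) {
      seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    }
    km <- as.character(seqs)
    km[grepl("[^ACGT]", km)] <- NA_character_
    out[ok] <- km
  }
  unname(out)
}

#' Randomize crosslink sites into feature-matched control sets
#'
#' For each observed site assigned to feature F, a control position is
#' drawn uniformly (by length) from the pooled feature-F territory of
#' the genes that contain at least one observed site, so every control
#' set reproduces the observed feature distribution exactly.  Territory
#' is the per-gene reduced union of feature-F intervals over the gene's
#' transcripts.  A feature with no territory among eligible genes falls
#' back to all genes (logged); intergenic sites are re-drawn uniformly
#' over the genome with random strand.
#'
#' @param assignments Output of [assign_features()] for the observed
#'   sites (must carry `feature` and `gene_id`).
#' @param models Transcript models from [parse_annotation()].
#' @param genome [Biostrings::DNAStringSet] (only needed when
#'   intergenic sites are present).
#' @param n_sets Number of control sets (default 100).
#' @param seed Integer seed.
#' @return A tibble of control sites with columns `set_index`, `chrom`,
#'   `pos`, `strand`, `feature`.
#' @export
randomize_control_sites <- function(assignments, models, genome = NULL,
                                    n_sets = 100L, seed = 1L) {
  set.seed(seed)
  eligible <- unique(assignments$gene_id[!is.na(assignments$gene_id)])
  feat <- transcript_features(models)
  territory_for <- function(feature, genes) {
    fd <- feat |> filter(.data$feature == !!feature,
                         .data$gene_id %in% genes)
    if (nrow(fd) == 0) return(NULL)
    # reduce within gene so overlapping isoforms do not double-weight
    fd |>
      group_by(.data$gene_id, .data$chrom, .data$strand) |>
      group_modify(function(d, key) {
        r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
        tibble(start = IRanges::start(r), end = IRanges::end(r))
      }) |>
      ungroup()
  }
  obs_features <- assignments$feature
  n_obs <- length(obs_features)
  draws_per_feature <- table(obs_features) * n_sets

  sampled <- lapply(names(draws_per_feature), function(f) {
    n_draw <- as.integer(draws_per_feature[[f]])
    if (f == "intergenic") {
      if (is.null(genome)) {
        abort("intergenic observed sites require `genome` for controls")
      }
      lens <- setNames(Biostrings::width(genome), names(genome))
      ch <- sample(names(genome), n_draw, replace = TRUE,
                   prob = lens / sum(lens))
      return(tibble(feature = f, chrom = ch,
                    pos = as.integer(floor(runif(n_draw) * lens[ch])),
                    strand = sample(c("+", "-"), n_draw, replace = TRUE)))
    }
    terr <- territory_for(f, eligible)
    if (is.null(terr)) {
      inform(paste0("feature ", f, " has no territory among genes with ",
                    "observed sites; falling back to all genes"))
      terr <- territory_for(f, unique(feat$gene_id))
    }
    if (is.null(terr)) {
      abort(paste0("feature ", f, " has no territory in the annotation"))
    }
    w <- terr$end - terr$start + 1L
    iv <- sample.int(nrow(terr), n_draw, replace = TRUE, prob = w / sum(w))
    offset <- floor(runif(n_draw) * w[iv])
    tibble(feature = f, chrom = terr$chrom[iv],
           pos = as.integer(terr$start[iv] - 1L + offset),  # back to 0-based
           strand = terr$strand[iv])
  })
  pool <- bind_rows(sampled)
  # deal draws out feature-wise so each set's feature tally matches
  pool |>
    group_by(.data$feature) |>
    mutate(set_index = rep(seq_len(n_sets),
                           each = dplyr::n() / n_sets)) |>
    ungroup() |>
    arrange(.data$set_index) |>
    select("set_index", "chrom", "pos", "strand", "feature")
}

#' 5-mer enrichment z-scores against randomized control sites
#'
#' Counts each k-mer among the observed site k-mers and among each
#' control set's k-mers, then scores
#' `z = (obs - mean(ctrl)) / sd(ctrl)` with the sample (n-1) standard
#' deviation over control sets.  When the control sd is 0, z is 0 if
#' the observed count equals the control mean and a signed-infinity
#' sentinel (flagged in `degenerate`) otherwise.
#'
#' @param observed_kmers Character vector of observed k-mers (`NA`s are
#'   dropped; they are unscorable sites).
#' @param control_sites Control-site tibble from
#'   [randomize_control_sites()].
#' @param genome [Biostrings::DNAStringSet] used to extract control
#'   k-mers.
#' @param k Window size (default 5).
#' @return A `motif_table` tibble: `kmer`, `obs_count`, `ctrl_mean`,
#'   `ctrl_sd`, `z`, `degenerate`, sorted by `z` descending.
#' @export
motif_zscores <- function(observed_kmers, control_sites, genome, k = 5L) {
  obs <- observed_kmers[!is.na(observed_kmers)]
  if (length(obs) == 0) abort("no scorable observed k-mers")
  n_sets <- length(unique(control_sites$set_index))
  if (n_sets < 2) abort("need >= 2 control sets")
  ctrl_km <- control_sites |>
    mutate(kmer = extract_kmer(control_sites, genome, k)) |>
    filter(!is.na(.data$kmer))
  kmers <- sort(unique(c(obs, ctrl_km$kmer)))
  obs_count <- as.integer(table(factor(obs, levels = kmers)))
  ctrl_mat <- matrix(vapply(seq_len(n_sets), function(s) {
    as.integer(table(factor(ctrl_km$kmer[ctrl_km$set_index == s],
                            levels = kmers)))
  }, integer(length(kmers))), nrow = length(kmers))
  ctrl_mean <- rowMeans(ctrl_mat)
  ctrl_sd <- apply(ctrl_mat, 1, sd)
  z <- ifelse(ctrl_sd > 0, (obs_count - ctrl_mean) / ctrl_sd,
              ifelse(obs_count == ctrl_mean, 0,
                     sign(obs_count - ctrl_mean) * Inf))
  out <- tibble(kmer = kmers, obs_count = obs_count,
                ctrl_mean = ctrl_mean, ctrl_sd = ctrl_sd, z = z,
                degenerate = ctrl_sd == 0 & obs_count != ctrl_mean) |>
    arrange(dplyr::desc(.data$z), .data$kmer)
  class(out) <- c("motif_table", class(out))
  out
}

#' Top-enriched k-mers bar plot
#'
#' @param motifs A `motif_table` from [motif_zscores()].
#' @param n Number of top k-mers to show (default 15).
#' @export
plot_motif_table <- function(motifs, n = 15) {
  top <- motifs |> filter(is.finite(.data$z)) |> slice_head(n = n)
  ggplot(top, aes(x = stats::reorder(.data$kmer, .data$z), y = .data$z)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "z-score vs randomized control sites",
         title = "5-mer enrichment at crosslink sites") +
    theme_minimal()
}

#' @rdname plot_motif_table
#' @param object A `motif_table`.
#' @param ... Unused.
#' @export
autoplot.motif_table <- function(object, ...) plot_motif_table(object)

#' Does a 5-mer match the DRACH consensus?
#'
#' DRACH is D = A/G/T, R = A/G, A, C, H = A/C/T — the degenerate
#' consensus around methylated adenosines.
#'
#' @param kmer Character vector of 5-mers.
#' @return Logical vector.
#' @export
is_drach <- function(kmer) {
  grepl("^[AGT][AG]AC[ACT]$", kmer)
}
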