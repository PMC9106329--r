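#' Parse an Ensembl-dialect GTF into transcript models
#'
#' Builds one model per transcript from the exon and CDS features of an
#' Ensembl-style GTF.  Untranslated regions are derived as exonic
#' sequence outside the CDS (5' vs 3' resolved by strand) and introns
#' as the gaps between sorted exons, so only exon and CDS rows are
#' required.  The attributes `transcript_biotype`,
#' `transcript_support_level` and `ccds_id` are honoured where present;
#' a missing support level is stored as `NA` and a missing `ccds_id` as
#' `has_ccds = FALSE`.
#'
#' Coordinates are held 1-based closed (the GRanges convention); BED
#' input/output converts at the boundary.
#'
#' @param gtf_path Path to a GTF file.
#' @return A `transcript_models` tibble with one row per transcript:
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `biotype`, `tsl`,
#'   `has_ccds`, and list-columns `exons` / `cds` of two-column
#'   (start, end) integer matrices, sorted and non-overlapping.
#' @export
parse_annotation <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  md <- as.data.frame(S4Vectors::mcols(gr))
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    transcript_id = if ("transcript_id" %in% names(md))
      as.character(md$transcript_id) else NA_character_,
    biotype = if ("transcript_biotype" %in% names(md))
      as.character(md$transcript_biotype) else NA_character_,
    tsl_raw = if ("transcript_support_level" %in% names(md))
      as.character(md$transcript_support_level) else NA_character_,
    ccds_id = if ("ccds_id" %in% names(md))
      as.character(md$ccds_id) else NA_character_
  )
  ex <- df |> filter(.data$type == "exon", !is.na(.data$transcript_id))
  if (nrow(ex) == 0) abort("GTF contains no exon features")
  cds <- df |> filter(.data$type == "CDS", !is.na(.data$transcript_id))

  tx_meta <- df |>
    filter(!is.na(.data$transcript_id)) |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = .data$gene_id[1],
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      biotype = first_non_na(.data$biotype),
      tsl = parse_tsl(first_non_na(.data$tsl_raw)),
      has_ccds = any(!is.na(.data$ccds_id)),
      .groups = "drop")

  sort_ivs <- function(s, e) {
    o <- order(s)
    cbind(start = as.integer(s[o]), end = as.integer(e[o]))
  }
  exon_list <- ex |>
    group_by(.data$transcript_id) |>
    summarise(ivs = list(sort_ivs(.data$start, .data$end)), .groups = "drop")
  cds_list <- cds |>
    group_by(.data$transcript_id) |>
    summarise(cds_ivs = list(sort_ivs(.data$start, .data$end)),
              .groups = "drop")

  models <- tx_meta |>
    inner_join(exon_list, by = "transcript_id") |>
    left_join(cds_list, by = "transcript_id") |>
    mutate(
      cds_ivs = purrr::map(.data$cds_ivs, function(m) {
        if (is.null(m)) cbind(start = integer(0), end = integer(0)) else m
      }),
      biotype = dplyr::coalesce(
        .data$biotype,
        ifelse(purrr::map_int(.data$cds_ivs, nrow) > 0,
               "protein_coding", "non_coding"))) |>
    rename(exons = "ivs", cds = "cds_ivs") |>
    arrange(.data$transcript_id)

  # CDS must lie within the exonic union
  for (i in seq_len(nrow(models))) {
    cdsm <- models$cds[[i]]
    if (nrow(cdsm) == 0) next
    exr <- IRanges::IRanges(models$exons[[i]][, 1], models$exons[[i]][, 2])
    cdr <- IRanges::IRanges(cdsm[, 1], cdsm[, 2])
    if (sum(IRanges::width(IRanges::intersect(cdr, exr))) !=
        sum(IRanges::width(cdr))) {
      abort(paste0("CDS outside exons for transcript ",
                   models$transcript_id[i]))
    }
  }
  class(models) <- c("transcript_models", class(models))
  models
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_character_ else x[1]
}

# Ensembl writes support levels like "1" or "5 (assigned to previous
# version)"; keep the leading integer, anything else is NA.
parse_tsl <- function(x) {
  if (is.na(x)) return(NA_integer_)
  v <- suppressWarnings(as.integer(stringr::str_extract(x, "^[0-9]+")))
  if (!is.na(v) && v >= 1 && v <= 5) v else NA_integer_
}

# Derive the (transcript, feature) interval table used for hierarchical
# assignment and for control-site territory.  Coding transcripts yield
# CDS / UTR5 / UTR3 / intron; non-coding yield nc_exon / nc_intron.
transcript_features <- function(models) {
  one <- function(i) {
    exm <- models$exons[[i]]
    cdsm <- models$cds[[i]]
    strand <- models$strand[i]
    exr <- IRanges::reduce(IRanges::IRanges(exm[, 1], exm[, 2]))
    introns <- IRanges::setdiff(range(exr), exr)
    coding <- nrow(cdsm) > 0
    rows <- list()
    add <- function(ir, feature) {
      if (length(ir) == 0) return()
      rows[[length(rows) + 1]] <<- tibble(
        feature = feature, start = IRanges::start(ir),
        end = IRanges::end(ir))
    }
    if (coding) {
      cdr <- IRanges::reduce(IRanges::IRanges(cdsm[, 1], cdsm[, 2]))
      utr <- IRanges::setdiff(exr, cdr)
      left <- utr[IRanges::end(utr) < min(IRanges::start(cdr))]
      right <- utr[IRanges::start(utr) > max(IRanges::end(cdr))]
      add(cdr, "CDS")
      add(if (strand == "+") right else left, "UTR3")
      add(if (strand == "+") left else right, "UTR5")
      add(introns, "intron")
    } else {
      add(exr, "nc_exon")
      add(introns, "nc_intron")
    }
    bind_rows(rows) |>
      mutate(transcript_id = models$transcript_id[i],
              gene_id = models$gene_id[i],
              chrom = models$chrom[i], strand = strand,
              coding = coding, tsl = models$tsl[i],
              has_ccds = models$has_ccds[i])
  }
  bind_rows(lapply(seq_len(nrow(models)), one))
}

# Priority keys of the hierarchical assignment, smaller = preferred:
# coding first; support level < 4 first; feature hierarchy
# CDS > UTR3 > UTR5 > intron > nc_exon > nc_intron; then lower TSL
# (absent last), CCDS-flagged first, transcript_id ascending.
feature_priority_keys <- function(feat) {
  feat |>
    mutate(
      key_coding = ifelse(.data$coding, 0L, 1L),
      key_tsl_lt4 = ifelse(!is.na(.data$tsl) & .data$tsl < 4, 0L, 1L),
      key_feature = match(.data$feature, FEATURE_LEVELS),
      key_tsl = ifelse(is.na(.data$tsl), 99L, .data$tsl),
      key_ccds = ifelse(.data$has_ccds, 0L, 1L))
}

#' Hierarchically assign crosslink sites (or clusters) to features
#'
#' Each site is matched against all same-strand transcript feature
#' intervals it overlaps; the candidate (transcript, feature) pairs are
#' ordered by the priority hierarchy — protein-coding isoforms first,
#' then isoforms with transcript support level < 4, then the feature
#' hierarchy CDS > 3'UTR > 5'UTR > intron > non-coding exon >
#' non-coding intron, then higher-confidence isoforms (lower support
#' level, absent last, then CCDS-flagged), with transcript_id as the
#' final deterministic tie-break — and the best candidate is kept.
#' Sites overlapping nothing are `intergenic` with no gene.
#'
#' @param x A crosslink-site tibble (`chrom`, `pos` 0-based, `strand`,
#'   optionally `site_id`/`score`) or a cluster tibble (`chrom`,
#'   `start`/`end` 0-based half-open, `strand`); clusters are assigned
#'   by any overlap.
#' @param models A `transcript_models` tibble from [parse_annotation()].
#' @return `x` with `gene_id`, `transcript_id` and `feature` columns
#'   appended (`NA` gene/transcript for intergenic).
#' @export
assign_features <- function(x, models) {
  is_site <- "pos" %in% names(x)
  if (!is_site && !all(c("start", "end") %in% names(x))) {
    abort("x must have a `pos` column (sites) or `start`/`end` (clusters)")
  }
  x <- as_tibble(x)
  if (!"site_id" %in% names(x)) {
    x$site_id <- sprintf("site_%05d", seq_len(nrow(x)))
  }
  q_start <- if (is_site) x$pos + 1L else x$start + 1L
  q_end <- if (is_site) x$pos + 1L else x$end
  query <- GenomicRanges::GRanges(x$chrom,
                                  IRanges::IRanges(q_start, q_end),
                                  strand = x$strand)
  feat <- feature_priority_keys(transcript_features(models))
  subject <- GenomicRanges::GRanges(feat$chrom,
                                    IRanges::IRanges(feat$start, feat$end),
                                    strand = feat$strand)
  ov <- GenomicRanges::findOverlaps(query, subject)  # strand-aware
  cand <- tibble(q = S4Vectors::queryHits(ov), s = S4Vectors::subjectHits(ov))
  best <- cand |>
    mutate(key_coding = feat$key_coding[.data$s],
           key_tsl_lt4 = feat$key_tsl_lt4[.data$s],
           key_feature = feat$key_feature[.data$s],
           key_tsl = feat$key_tsl[.data$s],
           key_ccds = feat$key_ccds[.data$s],
           transcript_id = feat$transcript_id[.data$s],
           gene_id = feat$gene_id[.data$s],
           feature = feat$feature[.data$s]) |>
    arrange(.data$q, .data$key_coding, .data$key_tsl_lt4,
            .data$key_feature, .data$key_tsl, .data$key_ccds,
            .data$transcript_id) |>
    group_by(.data$q) |>
    slice_head(n = 1) |>
    ungroup()
  x$gene_id <- NA_character_
  x$transcript_id <- NA_character_
  x$feature <- "intergenic"
  x$gene_id[best$q] <- best$gene_id
  x$transcript_id[best$q] <- best$transcript_id
  x$feature[best$q] <- best$feature
  x
}

#' Classify transcripts by where their m6A sites fall
#'
#' Transcripts whose assigned sites are all in the 3'UTR are `utr3`,
#' all in the CDS are `cds`, at least one of each are `both`, and any
#' other combination is `other`; transcripts with no assigned site do
#' not appear (unmethylated).
#'
#' @param assignments Output of [assign_features()] for sites.
#' @return A tibble `transcript_id`, `methylation` over
#'   `{utr3, cds, both, other}`.
#' @export
classify_transcript_methylation <- function(assignments) {
  assignments |>
    filter(!is.na(.data$transcript_id)) |>
    group_by(.data$transcript_id) |>
    summarise(
      n_utr3 = sum(.data$feature == "UTR3"),
      n_cds = sum(.data$feature == "CDS"),
      n_other = sum(!.data$feature %in% c("UTR3", "CDS")),
      .groups = "drop") |>
    mutate(methylation = dplyr::case_when(
      .data$n_utr3 > 0 & .data$n_cds > 0 ~ "both",
      .data$n_utr3 > 0 & .data$n_other == 0 ~ "utr3",
      .data$n_cds > 0 & .data$n_other == 0 ~ "cds",
      TRUE ~ "other")) |>
    select("transcript_id", "methylation")
}
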