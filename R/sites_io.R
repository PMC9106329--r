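#' Read / write crosslink sites and clusters as 6-column BED
#'
#' Sites are single-nucleotide BED intervals (`end = start + 1`) whose
#' name column carries the site id and whose score carries the
#' enrichment; clusters are ordinary stranded intervals.  BED is
#' 0-based half-open on disk; site tibbles keep the BED-style 0-based
#' `pos`, cluster tibbles keep 0-based half-open `start`/`end`.
#'
#' @param path Path to a BED file.
#' @return `read_sites_bed()`: tibble `chrom`, `pos`, `strand`,
#'   `site_id`, `score`; `read_clusters_bed()`: tibble `chrom`,
#'   `start`, `end`, `strand`, `cluster_id`, `lfc`.
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         pos = GenomicRanges::start(gr) - 1L,
         strand = as.character(GenomicRanges::strand(gr)),
         site_id = if (is.null(gr$name))
           sprintf("site_%05d", seq_along(gr)) else as.character(gr$name),
         score = if (is.null(gr$score)) NA_real_ else as.numeric(gr$score))
}

#' @rdname read_sites_bed
#' @param sites A site tibble.
#' @export
write_sites_bed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos + 1L, width = 1L),
    strand = sites$strand,
    name = sites$site_id %||% sprintf("site_%05d", seq_len(nrow(sites))),
    score = sites$score %||% rep(0, nrow(sites)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname read_sites_bed
#' @export
read_clusters_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)),
         cluster_id = if (is.null(gr$name))
           sprintf("cluster_%05d", seq_along(gr)) else as.character(gr$name),
         lfc = if (is.null(gr$score)) NA_real_ else as.numeric(gr$score))
}

#' @rdname read_sites_bed
#' @param clusters A cluster tibble.
#' @export
write_clusters_bed <- function(clusters, path) {
  gr <- GenomicRanges::GRanges(
    clusters$chrom, IRanges::IRanges(clusters$start + 1L, clusters$end),
    strand = clusters$strand,
    name = clusters$cluster_id %||%
      sprintf("cluster_%05d", seq_len(nrow(clusters))),
    score = clusters$lfc %||% rep(0, nrow(clusters)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
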