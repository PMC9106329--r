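# Shared fixtures and independent oracles, built in code at test time.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

SCAFFOLD <- "GTTTAAGAGCTAT"

# A tiny three-guide library with hand-chosen protospacers.
tiny_library <- function() {
  guide_library(
    guide_id = c("G1", "G2", "NT1"),
    protospacer = c("ACGTACGTACGTACGTACG",
                    "TTTTCCCCGGGGAAAATTT",
                    "GACGACGACGACGACGACG"),
    gene = c("GeneA", "GeneB", NA),
    category = c("rbp_target", "rbp_target", "non_targeting"))
}

write_fastq <- function(seqs, path) {
  if (length(seqs) == 0) {
    file.create(path)
    return(path)
  }
  writeLines(paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n",
                    strrep("I", max(nchar(seqs)))), path)
  path
}

# Independent alpha-RRA oracle: P(U_(k) <= u) for m uniforms via the
# binomial identity P(Binom(m, u) >= k), minimised over the leading
# selected order statistics.
rra_bruteforce <- function(p, rank, n_total, alpha = 0.05) {
  m <- length(p)
  u <- sort(rank[p < alpha] / n_total)
  if (length(u) == 0) return(1)
  min(vapply(seq_along(u), function(k) {
    stats::pbinom(k - 1, m, u[k], lower.tail = FALSE)
  }, numeric(1)))
}

# Brute-force hierarchical assignment: per site, loop over every
# transcript feature interval with base-R overlap tests, order the
# candidates by the priority keys with base order(), and return the
# best (or intergenic).
assign_bruteforce <- function(sites, models) {
  feat <- plasmascreen:::transcript_features(models)
  feature_rank <- c(CDS = 1, UTR3 = 2, UTR5 = 3, intron = 4,
                    nc_exon = 5, nc_intron = 6)
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    p1 <- sites$pos[i] + 1            # 1-based
    cand <- feat[feat$chrom == sites$chrom[i] &
                   feat$strand == sites$strand[i] &
                   feat$start <= p1 & feat$end >= p1, ]
    if (nrow(cand) == 0) {
      out[[i]] <- tibble(site_id = sites$site_id[i],
                         gene_id = NA_character_,
                         transcript_id = NA_character_,
                         feature = "intergenic")
      next
    }
    o <- order(ifelse(cand$coding, 0, 1),
               ifelse(!is.na(cand$tsl) & cand$tsl < 4, 0, 1),
               feature_rank[cand$feature],
               ifelse(is.na(cand$tsl), 99, cand$tsl),
               ifelse(cand$has_ccds, 0, 1),
               cand$transcript_id)
    best <- cand[o[1], ]
    out[[i]] <- tibble(site_id = sites$site_id[i],
                       gene_id = best$gene_id,
                       transcript_id = best$transcript_id,
                       feature = best$feature)
  }
  bind_rows(out)
}

# A hand-built locus with overlapping isoforms designed to exercise
# every rung of the assignment hierarchy:
#  TXA1 coding TSL1+CCDS, TXA2 coding TSL5, TXB1 lncRNA TSL1 spanning
#  both, TXC1 coding TSL NA on the minus strand, TXD1 coding TSL2
#  overlapping TXA1's UTR3 with its CDS.
overlap_annotation_gtf <- function(path) {
  attr_str <- function(g, t, bio, tsl, ccds) {
    paste0('gene_id "', g, '"; transcript_id "', t,
           '"; transcript_biotype "', bio, '";',
           if (!is.na(tsl)) paste0(' transcript_support_level "', tsl, '";')
           else "",
           if (ccds) paste0(' ccds_id "CCDS_', t, '";') else "")
  }
  row <- function(ch, type, s, e, strand, at) {
    paste(ch, "test", type, s, e, ".", strand, ".", at, sep = "\t")
  }
  a1 <- attr_str("GA", "TXA1", "protein_coding", 1, TRUE)
  a2 <- attr_str("GA", "TXA2", "protein_coding", 5, FALSE)
  b1 <- attr_str("GB", "TXB1", "lincRNA", 1, FALSE)
  c1 <- attr_str("GC", "TXC1", "protein_coding", NA, FALSE)
  d1 <- attr_str("GD", "TXD1", "protein_coding", 2, FALSE)
  lines <- c(
    row("chr1", "transcript", 101, 700, "+", a1),
    row("chr1", "exon", 101, 300, "+", a1),
    row("chr1", "exon", 401, 700, "+", a1),
    row("chr1", "CDS", 151, 300, "+", a1),
    row("chr1", "CDS", 401, 600, "+", a1),
    row("chr1", "transcript", 101, 700, "+", a2),
    row("chr1", "exon", 101, 250, "+", a2),
    row("chr1", "exon", 451, 700, "+", a2),
    row("chr1", "CDS", 121, 250, "+", a2),
    row("chr1", "CDS", 451, 500, "+", a2),
    row("chr1", "transcript", 1, 800, "+", b1),
    row("chr1", "exon", 1, 350, "+", b1),
    row("chr1", "exon", 500, 800, "+", b1),
    row("chr1", "transcript", 150, 650, "-", c1),
    row("chr1", "exon", 150, 400, "-", c1),
    row("chr1", "exon", 480, 650, "-", c1),
    row("chr1", "CDS", 200, 400, "-", c1),
    row("chr1", "CDS", 480, 560, "-", c1),
    row("chr1", "transcript", 580, 900, "+", d1),
    row("chr1", "exon", 580, 900, "+", d1),
    row("chr1", "CDS", 620, 820, "+", d1))
  writeLines(lines, path)
  path
}
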