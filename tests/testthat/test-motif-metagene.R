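test_that("k-mer extraction is centred and strand-aware", {
  genome <- Biostrings::DNAStringSet(c(chrA = "TTGGACTCC"))
  # centre on the A of GGACT: 0-based pos 4 -> window GGACT
  sites <- tibble(chrom = "chrA", pos = 4L, strand = "+")
  expect_equal(extract_kmer(sites, genome), "GGACT")
  sites_m <- tibble(chrom = "chrA", pos = 4L, strand = "-")
  expect_equal(extract_kmer(sites_m, genome), "AGTCC")
  # a site one base into the chromosome has no full window
  edge <- tibble(chrom = "chrA", pos = 1L, strand = "+")
  expect_true(is.na(extract_kmer(edge, genome)))
  # windows containing non-ACGT are unscorable
  genome_n <- Biostrings::DNAStringSet(c(chrA = "TTGGNCTCC"))
  expect_true(is.na(extract_kmer(sites, genome_n)))
  expect_error(extract_kmer(tibble(chrom = "chrZ", pos = 4L, strand = "+"),
                            genome), "chrZ")
})

test_that("motif z-scores follow the (obs - mean) / sd definition", {
  # an all-A and an all-C chromosome make control k-mers fully
  # predictable from position
  genome <- Biostrings::DNAStringSet(c(A = strrep("A", 100),
                                       C = strrep("C", 100)))
  ctrl_set <- function(set, nA, nC) {
    tibble(set_index = set,
           chrom = c(rep("A", nA), rep("C", nC)),
           pos = 10L + seq_len(nA + nC),
           strand = "+")
  }
  ctrl <- bind_rows(ctrl_set(1, 8, 4), ctrl_set(2, 10, 2),
                    ctrl_set(3, 12, 0))
  obs <- rep("AAAAA", 30)
  mt <- motif_zscores(obs, ctrl, genome)
  a <- mt[mt$kmer == "AAAAA", ]
  expect_equal(a$ctrl_mean, 10)
  expect_equal(a$ctrl_sd, 2)           # sample sd of (8, 10, 12)
  expect_equal(a$z, (30 - 10) / 2)
  # sd = 0 with obs equal to the mean -> z = 0; unequal -> flagged Inf
  cc <- mt[mt$kmer == "CCCCC", ]
  expect_equal(cc$ctrl_sd, 2)
  ctrl_const <- bind_rows(ctrl_set(1, 5, 0), ctrl_set(2, 5, 0))
  mt2 <- motif_zscores(rep("AAAAA", 5), ctrl_const, genome)
  expect_equal(mt2$z[mt2$kmer == "AAAAA"], 0)
  mt3 <- motif_zscores(rep("AAAAA", 9), ctrl_const, genome)
  expect_true(is.infinite(mt3$z[mt3$kmer == "AAAAA"]))
  expect_true(mt3$degenerate[mt3$kmer == "AAAAA"])
  expect_error(motif_zscores(character(0), ctrl, genome), "scorable")
  expect_error(motif_zscores(obs, ctrl_set(1, 5, 0), genome), "2 control")
})

test_that("control sets preserve the observed feature distribution", {
  toy <- make_toy_annotation(n_genes = 12, seed = 3)
  planted <- plant_crosslink_sites(toy, n_sites = 40, motif_fraction = 0,
                                   stop_bias = 0.3, seed = 5)
  asg <- assign_features(planted$sites, toy$models)
  ctrl <- randomize_control_sites(asg, toy$models, planted$genome,
                                  n_sets = 25, seed = 7)
  expect_equal(length(unique(ctrl$set_index)), 25L)
  obs_tally <- sort(c(table(asg$feature)))
  per_set <- split(ctrl$feature, ctrl$set_index)
  for (s in per_set) expect_equal(sort(c(table(s))), obs_tally)
  # same seed reproduces the sets byte for byte
  ctrl2 <- randomize_control_sites(asg, toy$models, planted$genome,
                                   n_sets = 25, seed = 7)
  expect_identical(ctrl, ctrl2)
  # control sites land in territory of genes that carry observed sites
  ctrl_asg <- assign_features(
    ctrl |> filter(.data$set_index == 1) |> select(-"feature"),
    toy$models)
  expect_true(all(ctrl_asg$gene_id %in% asg$gene_id))
})

test_that("per-set k-mer counts conserve the number of scorable sites", {
  toy <- make_toy_annotation(n_genes = 10, seed = 23)
  planted <- plant_crosslink_sites(toy, n_sites = 30, motif_fraction = 0.5,
                                   stop_bias = 0.5, seed = 2)
  asg <- assign_features(planted$sites, toy$models)
  ctrl <- randomize_control_sites(asg, toy$models, planted$genome,
                                  n_sets = 10, seed = 4)
  obs_km <- extract_kmer(planted$sites, planted$genome)
  mt <- motif_zscores(obs_km, ctrl, planted$genome)
  expect_equal(sum(mt$obs_count), sum(!is.na(obs_km)))
  # summed control means equal the average number of scorable control
  # sites per set, so each set's k-mer counts add up to its sites
  scorable_per_set <- vapply(1:10, function(s) {
    sum(!is.na(extract_kmer(ctrl |> filter(.data$set_index == s),
                            planted$genome)))
  }, numeric(1))
  expect_equal(sum(mt$ctrl_mean), mean(scorable_per_set))
})

test_that("motif table is invariant under genome reverse-complement", {
  toy <- make_toy_annotation(n_genes = 8, seed = 17)
  planted <- plant_crosslink_sites(toy, n_sites = 25, motif_fraction = 0.8,
                                   stop_bias = 0, seed = 6)
  km_fwd <- extract_kmer(planted$sites, planted$genome)
  # reverse-complement every chromosome and mirror site coordinates
  lens <- setNames(Biostrings::width(planted$genome),
                   names(planted$genome))
  genome_rc <- Biostrings::reverseComplement(planted$genome)
  sites_rc <- planted$sites |>
    mutate(pos = lens[.data$chrom] - 1L - .data$pos,
           strand = ifelse(.data$strand == "+", "-", "+"))
  km_rc <- extract_kmer(sites_rc, genome_rc)
  expect_equal(km_rc, km_fwd)
})

test_that("metagene bins score indicator overlap and average over genes", {
  one_tx <- function(id, gene, chrom, start, end, strand = "+") {
    tibble(transcript_id = id, gene_id = gene, chrom = chrom,
           strand = strand, biotype = "protein_coding",
           tsl = 1L, has_ccds = TRUE,
           exons = list(cbind(start = start, end = end)),
           cds = list(cbind(start = start, end = end)))
  }
  models <- bind_rows(one_tx("t1", "g1", "chr1", 2001L, 3000L),
                      one_tx("t2", "g2", "chr1", 6001L, 7000L))
  # one cluster covering exactly the middle tenth of g1's CDS
  clusters <- tibble(chrom = "chr1", start = 2450L, end = 2550L,
                     strand = "+", cluster_id = "c", lfc = 1)
  prof <- compute_metagene(clusters, models)
  expect_equal(nrow(prof), 300)
  expect_true(all(prof$value >= 0 & prof$value <= 1))
  body <- prof[prof$region == "body", ]
  covered <- body$value > 0
  # covered body bins are the middle tenth, at gene-average value 0.5
  expect_equal(which(covered), 46:55)
  expect_equal(unique(body$value[covered]), 0.5)
  expect_true(all(prof$value[prof$region != "body"] == 0))
  # no clusters anywhere -> an all-zero profile
  empty <- compute_metagene(clusters[0, ], models)
  expect_true(all(empty$value == 0))
  # non-coding-only annotations are rejected
  nc <- models |> mutate(cds = list(cbind(start = integer(0),
                                          end = integer(0))))
  expect_error(compute_metagene(clusters, nc), "coding")
})

test_that("minus-strand genes contribute in transcript orientation", {
  tx <- tibble(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
               strand = "-", biotype = "protein_coding", tsl = 1L,
               has_ccds = TRUE,
               exons = list(cbind(start = 2001L, end = 3000L)),
               cds = list(cbind(start = 2001L, end = 3000L)))
  # cluster at the genomic START of the CDS = transcript 3' end
  clusters <- tibble(chrom = "chr1", start = 2000L, end = 2050L,
                     strand = "-", cluster_id = "c", lfc = 1)
  prof <- compute_metagene(clusters, tx)
  body_hits <- prof$bin[prof$region == "body" & prof$value > 0]
  expect_true(all(body_hits > 190))      # lands at the transcript 3' end
  # opposite-strand clusters never count
  clusters_plus <- clusters |> mutate(strand = "+")
  expect_true(all(compute_metagene(clusters_plus, tx)$value == 0))
})
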