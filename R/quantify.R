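#' Extract the protospacer from a screen read
#'
#' Screen reads carry the 19-nt protospacer immediately 5' of the
#' constant iCRISPR scaffold.  The first occurrence of the scaffold
#' anchor `GTTTAAGAGCTAT` is located in each read and the 19 bases
#' immediately preceding it are returned.  Reads without the anchor, or
#' where the anchor starts fewer than 19 bases into the read, yield
#' `NA`.
#'
#' @param reads Character vector of read sequences over `{A,C,G,T,N}`.
#' @return Character vector of 19-mers, `NA` where extraction failed.
#' @examples
#' extract_protospacer(paste0(strrep("ACGT", 5), "GTTTAAGAGCTATCGG"))
#' @export
extract_protospacer <- function(reads) {
  reads <- toupper(reads)
  hit <- stringr::str_locate(reads, stringr::fixed(SCAFFOLD_ANCHOR))[, "start"]
  out <- rep(NA_character_, length(reads))
  ok <- !is.na(hit) & hit > PROTOSPACER_LEN
  out[ok] <- substr(reads[ok], hit[ok] - PROTOSPACER_LEN, hit[ok] - 1L)
  out
}

# Read a (possibly gzipped) FASTQ into a character vector of sequences.
# gzfile() auto-detects compression from magic bytes, so one connection
# type serves both plain and gzip files.  Malformed records are reported
# by record number.
read_fastq_sequences <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0) return(character(0))
  if (length(lines) %% 4 != 0) {
    abort(paste0("malformed FASTQ '", path, "': truncated record ",
                 length(lines) %/% 4 + 1))
  }
  headers <- lines[seq(1, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  bad <- which(!startsWith(headers, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0) {
    abort(paste0("malformed FASTQ '", path, "': bad record ", bad[1]))
  }
  lines[seq(2, length(lines), by = 4)]
}

#' Count sgRNA reads for one sample
#'
#' Extracts the protospacer from every read and assigns it to a library
#' guide by exact (zero-mismatch) string equality of the 19-mer.  Reads
#' whose extracted 19-mer contains `N` or is absent from the library are
#' left unassigned; each read contributes to at most one guide.
#'
#' @param fastq_path Path to a FASTQ file (plain or gzip).
#' @param lib A guide-library tibble (see [guide_library()]).
#' @param sample_id Sample name attached to the result.
#' @return A `sample_counts` tibble (`guide_id`, `count`, one row per
#'   library guide) with attributes `sample_id`, `n_reads_total`,
#'   `n_reads_with_scaffold`, `n_reads_assigned`.
#' @export
count_reads <- function(fastq_path, lib, sample_id) {
  lib <- validate_guide_library(lib)
  seqs <- read_fastq_sequences(fastq_path)
  proto <- extract_protospacer(seqs)
  idx <- match(proto, lib$protospacer)
  tab <- table(factor(lib$guide_id[idx[!is.na(idx)]], levels = lib$guide_id))
  out <- tibble(guide_id = lib$guide_id, count = as.integer(tab))
  structure(out,
            class = c("sample_counts", class(out)),
            sample_id = sample_id,
            n_reads_total = length(seqs),
            n_reads_with_scaffold = sum(!is.na(proto)),
            n_reads_assigned = sum(!is.na(idx)))
}

#' @rdname count_reads
#' @param x A `sample_counts` object.
#' @export
sample_tallies <- function(x) {
  tibble(sample_id = attr(x, "sample_id"),
         n_reads_total = attr(x, "n_reads_total"),
         n_reads_with_scaffold = attr(x, "n_reads_with_scaffold"),
         n_reads_assigned = attr(x, "n_reads_assigned"))
}

#' Assemble per-sample counts into a guide-by-sample count matrix
#'
#' @param samples A list of `sample_counts` objects from [count_reads()]
#'   (or tibbles with `guide_id`/`count` plus a `sample_id` attribute).
#' @param lib The guide library all samples were counted against.
#' @return A tibble with `guide_id` and one integer column per sample,
#'   one row per library guide in library order (zero-filled where a
#'   guide was unseen).
#' @export
build_count_matrix <- function(samples, lib) {
  lib <- validate_guide_library(lib)
  if (length(samples) == 0) abort("at least one sample is required")
  ids <- vapply(samples, function(s) as.character(attr(s, "sample_id")),
                character(1))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sample_id: ", ids[duplicated(ids)][1]))
  }
  cols <- lapply(samples, function(s) {
    if (!setequal(s$guide_id, lib$guide_id)) {
      abort("sample was counted against a different guide library")
    }
    as.integer(s$count[match(lib$guide_id, s$guide_id)])
  })
  out <- tibble(guide_id = lib$guide_id)
  for (i in seq_along(cols)) out[[ids[i]]] <- cols[[i]]
  out
}

#' Read / write a count matrix TSV (guides in rows, samples in columns)
#'
#' @param path Path to the TSV.
#' @export
read_count_matrix <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    guide_id = "c", .default = "i"))
}

#' @rdname read_count_matrix
#' @param counts A count-matrix tibble.
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}
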