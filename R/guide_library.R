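#' Construct and validate an sgRNA guide library
#'
#' A guide library is a tibble with one row per sgRNA and columns
#' `guide_id`, `protospacer` (19-nt, ACGT), `gene` (`NA` for
#' non-targeting controls) and `category` (one of `rbp_target`,
#' `positive_control`, `non_targeting`).  Protospacers must be unique:
#' read assignment is by exact 19-mer lookup, so a collision would make
#' counting ambiguous and is treated as a load error.
#'
#' @param guide_id Character vector of unique guide identifiers.
#' @param protospacer Character vector of 19-nt ACGT protospacers.
#' @param gene Character vector of target genes; `NA` for non-targeting.
#' @param category Character vector over `rbp_target`,
#'   `positive_control`, `non_targeting`.
#' @return A validated `guide_library` tibble.
#' @examples
#' guide_library(
#'   guide_id = c("g1", "nt1"),
#'   protospacer = c(strrep("A", 19), strrep("C", 19)),
#'   gene = c("Prdm1", NA),
#'   category = c("rbp_target", "non_targeting")
#' )
#' @export
guide_library <- function(guide_id, protospacer, gene, category) {
  lib <- tibble(
    guide_id = as.character(guide_id),
    protospacer = toupper(as.character(protospacer)),
    gene = as.character(gene),
    category = as.character(category)
  )
  validate_guide_library(lib)
}

#' @rdname guide_library
#' @param lib A candidate guide-library tibble.
#' @export
validate_guide_library <- function(lib) {
  req <- c("guide_id", "protospacer", "gene", "category")
  missing_cols <- setdiff(req, names(lib))
  if (length(missing_cols) > 0) {
    abort(paste0("guide library is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(lib) == 0) abort("guide library is empty")
  if (anyDuplicated(lib$guide_id)) {
    abort("guide_id values must be unique within a library")
  }
  dup <- duplicated(lib$protospacer)
  if (any(dup)) {
    abort(paste0("protospacer collision in library: ",
                 paste(unique(lib$protospacer[dup]), collapse = ", ")))
  }
  bad_len <- nchar(lib$protospacer) != PROTOSPACER_LEN
  if (any(bad_len)) {
    abort(paste0("protospacers must be exactly ", PROTOSPACER_LEN,
                 " nt; offending guide(s): ",
                 paste(head(lib$guide_id[bad_len], 5), collapse = ", ")))
  }
  if (any(grepl("[^ACGT]", lib$protospacer))) {
    abort("protospacers must be over the alphabet {A,C,G,T}")
  }
  if (!all(lib$category %in% GUIDE_CATEGORIES)) {
    abort(paste0("category must be one of: ",
                 paste(GUIDE_CATEGORIES, collapse = ", ")))
  }
  nt <- lib$category == "non_targeting"
  if (any(nt & !is.na(lib$gene)) || any(!nt & is.na(lib$gene))) {
    abort("gene must be NA exactly for non_targeting guides")
  }
  as_tibble(lib[, req])
}

#' Read / write a guide library TSV
#'
#' The on-disk format is a four-column TSV with header
#' `guide_id<TAB>protospacer<TAB>gene<TAB>category`; an empty `gene`
#' field denotes a non-targeting control.
#'
#' @param path Path to a library TSV.
#' @return `read_guide_library()`: a validated `guide_library` tibble.
#' @export
read_guide_library <- function(path) {
  lib <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"))
  validate_guide_library(lib)
}

#' @rdname read_guide_library
#' @param lib A guide-library tibble.
#' @export
write_guide_library <- function(lib, path) {
  readr::write_tsv(validate_guide_library(lib), path)
  invisible(path)
}

#' Tally guides by category
#'
#' @param lib A guide-library tibble.
#' @return A tibble with one row per category (`n_guides`, `n_genes`).
#' @export
library_composition <- function(lib) {
  lib <- validate_guide_library(lib)
  lib |>
    group_by(category = factor(.data$category, levels = GUIDE_CATEGORIES)) |>
    summarise(n_guides = dplyr::n(),
              n_genes = dplyr::n_distinct(.data$gene[!is.na(.data$gene)]),
              .groups = "drop") |>
    tidyr::complete(category, fill = list(n_guides = 0L, n_genes = 0L)) |>
    mutate(category = as.character(.data$category))
}
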