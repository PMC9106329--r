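#' Intersect two screens into accumulation / expansion classes
#'
#' Reproduces the two-screen intersection that separates regulators of
#' CD138+ plasma-cell accumulation from regulators of B-cell expansion.
#' With accumulation LFC defined as CD138+ over CD138-, knocking out a
#' differentiation promoter depletes its guides from the CD138+ gate,
#' so an accumulation-only hit with `z <= -z_cut` is classed
#' `accumulation_promote` and one with `z >= z_cut` is
#' `accumulation_limit` (set `flip_sign = TRUE` for the opposite
#' orientation).  Genes hitting only the expansion screen are
#' `expansion_only`; genes hitting both are `both`; the rest are `none`.
#'
#' @param expansion,accumulation Per-gene tibbles (from
#'   [screen_test()]'s `gene` element or equivalent TSVs) with columns
#'   `gene`, `z`, `fdr`, `is_hit`.
#' @param config A [screen_config()] (supplies `z_cut`).
#' @param flip_sign Flip the promote/limit sign convention.
#' @return A tibble `gene`, `z_expansion`, `z_accumulation`,
#'   `fdr_expansion`, `fdr_accumulation`, `class`.
#' @export
classify_genes <- function(expansion, accumulation,
                           config = screen_config(), flip_sign = FALSE) {
  check_gene_table <- function(tbl, name) {
    req <- c("gene", "z", "fdr", "is_hit")
    if (!all(req %in% names(tbl))) {
      abort(paste0(name, " must have columns: ", paste(req, collapse = ", ")))
    }
    if (anyDuplicated(tbl$gene)) {
      dup <- tbl$gene[duplicated(tbl$gene)][1]
      conflict <- tbl |> filter(.data$gene == dup) |> distinct()
      if (nrow(conflict) > 1) {
        abort(paste0("gene '", dup, "' appears with conflicting rows in ",
                     name))
      }
      tbl <- tbl |> distinct()
    }
    tbl
  }
  exp_tbl <- check_gene_table(expansion, "expansion") |>
    select("gene", z_expansion = "z", fdr_expansion = "fdr",
           hit_expansion = "is_hit")
  acc_tbl <- check_gene_table(accumulation, "accumulation") |>
    select("gene", z_accumulation = "z", fdr_accumulation = "fdr",
           hit_accumulation = "is_hit")
  sign_mult <- if (flip_sign) -1 else 1
  full_join(exp_tbl, acc_tbl, by = "gene") |>
    mutate(hit_expansion = dplyr::coalesce(.data$hit_expansion, FALSE),
           hit_accumulation = dplyr::coalesce(.data$hit_accumulation, FALSE),
           class = dplyr::case_when(
             .data$hit_accumulation & .data$hit_expansion ~ "both",
             .data$hit_accumulation &
               sign_mult * .data$z_accumulation <= -config$z_cut ~
               "accumulation_promote",
             .data$hit_accumulation ~ "accumulation_limit",
             .data$hit_expansion ~ "expansion_only",
             TRUE ~ "none")) |>
    select("gene", "z_expansion", "z_accumulation", "fdr_expansion",
           "fdr_accumulation", "class")
}

#' Tally gene classifications
#'
#' @param classifications Output of [classify_genes()].
#' @return A tibble `class`, `n` with one zero-filled row per class plus
#'   a `total` row.
#' @export
summarize_classes <- function(classifications) {
  if (nrow(classifications) == 0) abort("classifications are empty")
  tab <- classifications |>
    count(class = factor(.data$class, levels = CLASS_LEVELS)) |>
    tidyr::complete(class, fill = list(n = 0L)) |>
    mutate(class = as.character(class))
  bind_rows(tab, tibble(class = "total", n = sum(tab$n)))
}

#' Two-screen classification scatter
#'
#' Accumulation z-score against expansion z-score, coloured by class,
#' with the hit cutoffs drawn.
#'
#' @param classifications Output of [classify_genes()].
#' @param z_cut Cutoff lines to draw (default 2).
#' @export
plot_classification <- function(classifications, z_cut = 2) {
  ggplot(classifications,
         aes(x = .data$z_accumulation, y = .data$z_expansion,
             colour = .data$class)) +
    geom_point(alpha = 0.7, size = 1.2, na.rm = TRUE) +
    geom_vline(xintercept = c(-z_cut, z_cut), linetype = "dashed") +
    geom_hline(yintercept = c(-z_cut, z_cut), linetype = "dashed") +
    labs(x = "z-score, CD138+ accumulation (CD138+ / CD138-)",
         y = "z-score, B cell expansion (day8 / day4)") +
    theme_minimal()
}
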