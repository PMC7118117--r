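#' Library-level coverage report
#'
#' Summarises what a designed library can reach: per isoform, the fraction
#' of residues targetable (a residue counts as targetable when at least one
#' outcome changes its amino acid, i.e. missense or nonsense; set
#' `include_silent = TRUE` to also count silent-only residues) and the
#' fraction of covered loci hit by more than one sgRNA; library-wide, the
#' fraction of guides producing each combination of mutation types; and,
#' given a clinical-variant table, the fraction of variants exactly
#' producible by some outcome.
#'
#' @param outcomes tibble from [enumerate_outcomes()].
#' @param models tibble from [load_gene_models()].
#' @param variants optional tibble with columns `gene`, `residue`, `ref_aa`,
#'   `alt_aa`. Rows naming genes absent from the outcomes are skipped (their
#'   count is reported and a warning raised).
#' @param include_silent count residues reachable only by silent outcomes as
#'   targetable.
#' @return An object of class `coverage_report`: a list with `by_isoform`
#'   (tibble: `tx_id`, `gene_id`, `n_residues`, `n_targetable`,
#'   `frac_targetable`, `n_covered_loci`, `n_multi_guide_loci`,
#'   `frac_multi_guide`), `mutation_types` (tibble of guide fractions per
#'   class combination), `variant_coverage`, `n_variants`,
#'   `n_variants_skipped`.
#' @export
coverage_stats <- function(outcomes, models, variants = NULL,
                           include_silent = FALSE) {
  ml <- models_as_list(models)
  allowed <- c("missense", "nonsense", if (include_silent) "silent")
  per_res <- if (nrow(outcomes)) {
    outcomes |>
      filter(.data$class %in% CLASS_LEVELS) |>
      tidyr::unnest("changes", names_sep = "_") |>
      select(
        "guide_id", "tx_id", "gene_id",
        residue = "changes_residue", res_class = "changes_class",
        res_ref_aa = "changes_ref_aa", res_alt_aa = "changes_alt_aa"
      ) |>
      filter(.data$res_class %in% CLASS_LEVELS)
  } else {
    tibble(
      guide_id = character(), tx_id = character(), gene_id = character(),
      residue = integer(), res_class = character(),
      res_ref_aa = character(), res_alt_aa = character()
    )
  }
  by_isoform <- tibble(
    tx_id = unname(names(ml)),
    gene_id = unname(map_chr(ml, "gene_id")),
    n_residues = unname(map_int(ml, ~ length(.x$genomic_pos) %/% 3L))
  ) |>
    left_join(
      per_res |>
        group_by(.data$tx_id) |>
        summarise(
          n_targetable = dplyr::n_distinct(.data$residue[.data$res_class %in% allowed]),
          n_covered_loci = dplyr::n_distinct(.data$residue),
          n_multi_guide_loci = {
            d <- dplyr::distinct(dplyr::pick("residue", "guide_id"))
            sum(table(d$residue) >= 2L)
          },
          .groups = "drop"
        ),
      by = "tx_id"
    ) |>
    mutate(
      across(c("n_targetable", "n_covered_loci", "n_multi_guide_loci"),
             ~ tidyr::replace_na(.x, 0L)),
      frac_targetable = ifelse(.data$n_residues > 0,
                               .data$n_targetable / .data$n_residues, 0),
      frac_multi_guide = ifelse(.data$n_covered_loci > 0,
                                .data$n_multi_guide_loci / .data$n_covered_loci, 0)
    )
  mutation_types <- outcomes |>
    filter(.data$class %in% CLASS_LEVELS) |>
    group_by(.data$guide_id) |>
    summarise(
      type_combo = paste(sort(unique(.data$class)), collapse = "+"),
      .groups = "drop"
    ) |>
    count(.data$type_combo, name = "n_guides") |>
    mutate(fraction = if (sum(.data$n_guides) > 0) {
      .data$n_guides / sum(.data$n_guides)
    } else {
      numeric(length(.data$n_guides))
    })
  variant_coverage <- NA_real_
  n_variants <- 0L
  n_skipped <- 0L
  if (!is.null(variants) && nrow(variants)) {
    known_genes <- unique(per_res$gene_id)
    unknown <- !variants$gene %in% known_genes
    n_skipped <- sum(unknown)
    if (n_skipped > 0) {
      warn(sprintf("%d variant row(s) reference unknown genes; skipped", n_skipped))
    }
    v <- variants[!unknown, , drop = FALSE]
    n_variants <- nrow(v)
    if (n_variants > 0) {
      producible <- per_res |>
        distinct(.data$gene_id, .data$residue, .data$res_ref_aa, .data$res_alt_aa)
      hit <- v |>
        left_join(producible,
          by = c(gene = "gene_id", residue = "residue",
                 ref_aa = "res_ref_aa", alt_aa = "res_alt_aa"),
          keep = TRUE
        )
      covered <- !is.na(hit$gene_id)
      variant_coverage <- sum(covered) / n_variants
    }
  }
  structure(
    list(
      by_isoform = by_isoform,
      mutation_types = mutation_types,
      variant_coverage = variant_coverage,
      n_variants = n_variants,
      n_variants_skipped = n_skipped
    ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report>\n")
  cat(sprintf(
    "  %d isoform(s); mean targetable-residue fraction %.3f\n",
    nrow(x$by_isoform), mean(x$by_isoform$frac_targetable)
  ))
  cat(sprintf(
    "  mean fraction of covered loci with >1 sgRNA %.3f\n",
    mean(x$by_isoform$frac_multi_guide)
  ))
  if (!is.na(x$variant_coverage)) {
    cat(sprintf(
      "  variant coverage %.3f (%d rows, %d skipped)\n",
      x$variant_coverage, x$n_variants, x$n_variants_skipped
    ))
  }
  invisible(x)
}

#' @rdname coverage_stats
#' @param x a `coverage_report`.
#' @param ... unused.
#' @method tidy coverage_report
#' @export
tidy.coverage_report <- function(x, ...) {
  x$by_isoform
}
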