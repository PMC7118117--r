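#' Count sgRNA spacers in pooled-screen reads
#'
#' A read increments a guide exactly when it contains the guide's 20-nt
#' spacer as an exact substring (forward orientation by default;
#' `revcomp = TRUE` also matches the reverse complement). Reads matching
#' spacers of more than one guide are ambiguous and excluded; reads
#' matching none are tallied as unassigned.
#'
#' @param reads character vector of read sequences, a tibble with `seq`, or
#'   a FASTQ path.
#' @param library tibble with `guide_id` and 20-nt `spacer` columns
#'   (optionally `gene`). Spacers must be unique.
#' @param sample_id label stored on the result.
#' @param revcomp also match reverse-complemented spacers.
#' @param chunk_size reads per matching block (memory control).
#' @return A `guide_count_table` tibble: `guide_id`, `gene`, `count`, with
#'   attributes `sample_id`, `total_reads`, `n_assigned`, `n_ambiguous`,
#'   `n_unassigned`.
#' @export
count_spacers <- function(reads, library, sample_id = "sample",
                          revcomp = FALSE, chunk_size = 20000L) {
  if (!nrow(library)) abort("empty guide library")
  if (anyDuplicated(library$spacer)) {
    abort("library spacers must be unique (flag duplicates upstream)")
  }
  if (any(nchar(library$spacer) != 20L)) abort("spacers must be 20 nt")
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)$seq
  } else if (is.data.frame(reads)) {
    reads <- reads$seq
  }
  n_guides <- nrow(library)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(library$spacer))
  pd_rc <- if (revcomp) {
    Biostrings::PDict(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(library$spacer)
    ))
  }
  counts <- integer(n_guides)
  n_ambiguous <- 0L
  n_unassigned <- 0L
  for (chunk in split(reads, ceiling(seq_along(reads) / chunk_size))) {
    ss <- Biostrings::DNAStringSet(chunk)
    hit <- Biostrings::vcountPDict(pd, ss) > 0L
    if (revcomp) hit <- hit | (Biostrings::vcountPDict(pd_rc, ss) > 0L)
    per_read <- colSums(hit)
    n_ambiguous <- n_ambiguous + sum(per_read > 1L)
    n_unassigned <- n_unassigned + sum(per_read == 0L)
    ok <- per_read == 1L
    if (any(ok)) counts <- counts + rowSums(hit[, ok, drop = FALSE])
  }
  out <- tibble(
    guide_id = library$guide_id,
    gene = if ("gene" %in% names(library)) library$gene else NA_character_,
    count = counts
  )
  attr(out, "sample_id") <- sample_id
  attr(out, "total_reads") <- length(reads)
  attr(out, "n_assigned") <- sum(counts)
  attr(out, "n_ambiguous") <- n_ambiguous
  attr(out, "n_unassigned") <- n_unassigned
  class(out) <- c("guide_count_table", class(out))
  out
}

#' Build a count table from pre-counted data
#'
#' @param counts tibble with `guide_id`, `count` (optionally `gene`).
#' @param sample_id label stored on the result.
#' @return A `guide_count_table` tibble.
#' @export
guide_count_table <- function(counts, sample_id = "sample") {
  stopifnot(all(c("guide_id", "count") %in% names(counts)))
  out <- as_tibble(counts)
  if (!"gene" %in% names(out)) out$gene <- NA_character_
  if (any(out$count < 0) || any(out$count != round(out$count))) {
    abort("counts must be non-negative integers")
  }
  attr(out, "sample_id") <- sample_id
  attr(out, "total_reads") <- sum(out$count)
  attr(out, "n_assigned") <- sum(out$count)
  class(out) <- c("guide_count_table", class(out))
  out
}

#' Normalize sgRNA counts to a fixed scale plus pseudocount
#'
#' `normalized = raw / total assigned x scale + pseudocount`. The formula is
#' the reads-per-scale convention of earlier pooled-screen work, with scale
#' and pseudocount exposed.
#'
#' @param table a `guide_count_table` (or tibble with `guide_id`, `count`).
#' @param scale scale factor (default 1e6).
#' @param pseudocount added after scaling (default 1; keeps log2
#'   fold-changes finite).
#' @return The table with a `norm` column added.
#' @export
normalize_counts <- function(table, scale = 1e6, pseudocount = 1) {
  total <- sum(table$count)
  if (total <= 0) abort("total counted reads is zero; cannot normalize")
  mutate(table, norm = .data$count / total * scale + pseudocount)
}

#' Per-guide log2 fold-change between two samples
#'
#' `l2fc = log2(norm_treatment / norm_control)` on counts normalized within
#' each sample. A guide missing from one table is treated as raw count 0
#' (so its normalized value is the pseudocount).
#'
#' @param treatment,control `guide_count_table`s.
#' @param scale,pseudocount passed to [normalize_counts()].
#' @return A tibble: `guide_id`, `gene`, `count_treat`, `count_ctrl`,
#'   `norm_treat`, `norm_ctrl`, `l2fc`.
#' @export
log2_fold_change <- function(treatment, control, scale = 1e6, pseudocount = 1) {
  uni <- dplyr::full_join(
    select(as_tibble(treatment), "guide_id", "gene", count_treat = "count"),
    select(as_tibble(control), "guide_id", count_ctrl = "count"),
    by = "guide_id"
  ) |>
    mutate(across(c("count_treat", "count_ctrl"), ~ tidyr::replace_na(.x, 0L)))
  tot_t <- sum(uni$count_treat)
  tot_c <- sum(uni$count_ctrl)
  if (tot_t <= 0 || tot_c <= 0) abort("zero total counts in one sample")
  uni |>
    mutate(
      norm_treat = .data$count_treat / tot_t * scale + pseudocount,
      norm_ctrl = .data$count_ctrl / tot_c * scale + pseudocount,
      l2fc = log2(.data$norm_treat / .data$norm_ctrl)
    )
}

#' Representation summary across screen samples
#'
#' Distribution statistics of guide counts per sample: quartiles, fraction
#' of zero-count guides and the top guide's share of assigned reads. Under
#' selection the representation collapses (median falls, top share rises).
#'
#' @param tables a named list of `guide_count_table`s, or a long tibble with
#'   `sample`, `guide_id`, `count`.
#' @return A tibble with one row per sample.
#' @export
representation_summary <- function(tables) {
  long <- if (is.data.frame(tables)) {
    as_tibble(tables)
  } else {
    bind_rows(imap(tables, function(t, nm) {
      sid <- if (is.character(nm) && nzchar(nm)) {
        nm
      } else {
        attr(t, "sample_id") %||% as.character(nm)
      }
      tibble(sample = sid, guide_id = t$guide_id, count = t$count)
    }))
  }
  stopifnot(all(c("sample", "guide_id", "count") %in% names(long)))
  long |>
    group_by(.data$sample) |>
    summarise(
      n_guides = dplyr::n(),
      q25 = unname(quantile(.data$count, 0.25)),
      median = unname(median(.data$count)),
      q75 = unname(quantile(.data$count, 0.75)),
      frac_zero = mean(.data$count == 0),
      top_share = if (sum(.data$count) > 0) max(.data$count) / sum(.data$count) else NA_real_,
      .groups = "drop"
    )
}
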