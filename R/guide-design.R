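#' Scan a genome for base-editor sgRNA candidates
#'
#' Finds every 20-mer protospacer followed by an allowed PAM on both strands
#' (5'-N20-PAM-3'). No editability filtering is applied here; see
#' [filter_editable()]. Protospacer positions are numbered 1-20 with 1 at the
#' PAM-distal end, and the activity window is positions 4-8. Each candidate is
#' annotated with all protospacer cytosines and a TC-motif flag per C (APOBEC1
#' prefers TC, which drives out-of-window editing at e.g. positions 13-15).
#'
#' @param genome tibble from [load_genome()] or named character vector.
#' @param pam_classes subset of `c("NGG", "NAG")`. NAG is the lower-activity
#'   alternative PAM, off by default.
#' @param window activity-window positions (1 = PAM-distal end).
#' @return A tibble with one row per candidate: `guide_id`, `contig`,
#'   `start`, `end` (0-based half-open protospacer interval), `strand`
#'   (target strand carrying protospacer+PAM), `spacer`, `pam`, `pam_class`,
#'   and list-columns `proto_c_pos` (protospacer positions of all Cs),
#'   `window_c_pos` (Cs inside the window) and `tc_pos` (Cs preceded by T).
#' @export
scan_candidates <- function(genome, pam_classes = "NGG", window = 4:8) {
  pam_classes <- match.arg(pam_classes, c("NGG", "NAG"), several.ok = TRUE)
  seqs <- genome_as_vector(genome)
  one_strand <- function(s, contig, strand) {
    L <- nchar(s)
    if (L < 23L) return(NULL)
    chars <- strsplit(s, "")[[1]]
    i0 <- 0:(L - 23L) # 0-based protospacer starts in scanned orientation
    p2 <- chars[i0 + 22L]
    p3 <- chars[i0 + 23L]
    cls <- ifelse(p2 == "G" & p3 == "G", "NGG",
      ifelse(p2 == "A" & p3 == "G", "NAG", NA_character_)
    )
    keep <- !is.na(cls) & cls %in% pam_classes
    i0 <- i0[keep]
    if (!length(i0)) return(NULL)
    spacer <- substring(s, i0 + 1L, i0 + 20L)
    pam <- substring(s, i0 + 21L, i0 + 23L)
    ok <- !grepl("N", paste0(spacer, pam))
    i0 <- i0[ok]
    if (!length(i0)) return(NULL)
    tibble(
      contig = contig,
      start = if (strand == "+") i0 else L - (i0 + 20L),
      end = if (strand == "+") i0 + 20L else L - i0,
      strand = strand,
      spacer = spacer[ok],
      pam = pam[ok],
      pam_class = cls[keep][ok]
    )
  }
  out <- purrr::imap(seqs, function(s, contig) {
    bind_rows(
      one_strand(s, contig, "+"),
      one_strand(revcomp(s), contig, "-")
    )
  }) |> bind_rows()
  if (!nrow(out)) {
    return(tibble(
      guide_id = character(), contig = character(), start = integer(),
      end = integer(), strand = character(), spacer = character(),
      pam = character(), pam_class = character(),
      proto_c_pos = list(), window_c_pos = list(), tc_pos = list()
    ))
  }
  out <- out |>
    arrange(.data$contig, .data$start, .data$strand) |>
    mutate(guide_id = sprintf("sg%04d", row_number()), .before = 1)
  cpos <- lapply(strsplit(out$spacer, ""), function(b) which(b == "C"))
  tpos <- map2(strsplit(out$spacer, ""), cpos, function(b, cp) {
    cp[cp > 1L & b[pmax(cp - 1L, 1L)] == "T"]
  })
  out |>
    mutate(
      proto_c_pos = cpos,
      window_c_pos = map(cpos, ~ .x[.x %in% window]),
      tc_pos = tpos
    )
}

#' Genomic position of a protospacer position
#'
#' Position 1 is the PAM-distal end of the protospacer on the target strand.
#' @noRd
proto_genomic_pos <- function(start, end, strand, p) {
  if (strand == "+") start + p - 1L else end - p
}

#' Keep candidates with an editable cytosine in coding sequence
#'
#' A candidate is retained when at least one window C (target strand,
#' positions 4-8) falls inside the CDS of at least one isoform. The editable
#' sites are recorded per isoform in the `editable_sites` list-column
#' (tibble of `tx_id`, `proto_pos`, `gpos`).
#'
#' @param candidates tibble from [scan_candidates()].
#' @param models tibble from [load_gene_models()] (or list of [gene_model()]).
#' @return Filtered candidate tibble with `editable_sites` added.
#' @export
filter_editable <- function(candidates, models) {
  ml <- models_as_list(models)
  sites <- pmap(
    list(candidates$contig, candidates$start, candidates$end,
         candidates$strand, candidates$window_c_pos),
    function(contig, start, end, strand, wc) {
      if (!length(wc)) return(NULL)
      gp <- proto_genomic_pos(start, end, strand, wc)
      bind_rows(lapply(ml, function(m) {
        if (m$contig != contig) return(NULL)
        in_cds <- gp %in% m$genomic_pos
        if (!any(in_cds)) return(NULL)
        tibble(tx_id = m$tx_id, proto_pos = wc[in_cds], gpos = gp[in_cds])
      }))
    }
  )
  keep <- map_lgl(sites, ~ !is.null(.x) && nrow(.x) > 0)
  candidates |>
    mutate(editable_sites = sites) |>
    filter(keep)
}

#' Classify a codon change as silent, missense or nonsense
#'
#' Nonsense iff the alternative codon translates to stop and the reference
#' does not; silent iff both translate to the same amino acid; otherwise
#' missense. Codons containing N are classified `"unknown"` and excluded
#' from coverage statistics.
#'
#' @param ref_codon,alt_codon character vectors of 3-mers.
#' @return Character vector in `c("silent", "missense", "nonsense", "unknown")`.
#' @export
classify_outcome <- function(ref_codon, alt_codon) {
  stopifnot(length(ref_codon) == length(alt_codon))
  has_n <- grepl("N", ref_codon) | grepl("N", alt_codon)
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  out <- ifelse(
    alt_aa == "*" & ref_aa != "*", "nonsense",
    ifelse(alt_aa == ref_aa, "silent", "missense")
  )
  out[has_n | is.na(out)] <- "unknown"
  out
}

#' Enumerate every introducible mutation for editable candidates
#'
#' For each candidate x isoform, all non-empty subsets of the candidate's
#' editable window cytosines are edited on the target strand (C->T, which
#' appears as G->A on the coding strand when the strands differ), the
#' affected codons are reconstructed via the gene model, and each outcome is
#' classified. Outcomes spanning two codons report both changes, the overall
#' class being the most severe (nonsense > missense > silent).
#'
#' @param candidates tibble from [filter_editable()] (must carry
#'   `editable_sites`).
#' @param models tibble from [load_gene_models()] (or list of models).
#' @return A tibble with one row per (guide, isoform, edit subset):
#'   `guide_id`, `gene_id`, `tx_id`, `edited_pos` (list of protospacer
#'   positions), `edit` (e.g. `"4+6"`), `n_edits`, `changes` (nested tibble
#'   of per-codon changes), `class`, `notation` (e.g. `"E203K"`, two-codon
#'   outcomes joined by `"/"`).
#' @export
enumerate_outcomes <- function(candidates, models) {
  if (!"editable_sites" %in% names(candidates)) {
    abort("candidates must come from filter_editable()")
  }
  ml <- models_as_list(models)
  rows <- pmap(
    list(candidates$guide_id, candidates$strand, candidates$editable_sites),
    function(gid, gstrand, sites) {
      if (is.null(sites) || !nrow(sites)) return(NULL)
      bind_rows(lapply(split(sites, sites$tx_id), function(ss) {
        m <- ml[[ss$tx_id[1]]]
        enumerate_for_model(gid, gstrand, ss, m)
      }))
    }
  )
  out <- bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(
      guide_id = character(), gene_id = character(), tx_id = character(),
      edited_pos = list(), edit = character(), n_edits = integer(),
      changes = list(), class = character(), notation = character()
    ))
  }
  out
}

enumerate_for_model <- function(gid, gstrand, sites, model) {
  same_strand <- gstrand == model$strand
  cds_idx <- match(sites$gpos, model$genomic_pos)
  stopifnot(!any(is.na(cds_idx)))
  n_codons <- length(model$genomic_pos) %/% 3L
  subsets <- nonempty_subsets(seq_len(nrow(sites)))
  bind_rows(lapply(subsets, function(sel) {
    idx <- cds_idx[sel]
    residues <- sort(unique((idx - 1L) %/% 3L + 1L))
    residues <- residues[residues <= n_codons] # drop trailing partial codon
    chg <- bind_rows(lapply(residues, function(r) {
      span <- (3L * r - 2L):(3L * r)
      ref <- substr(model$cds, span[1], span[3])
      b <- strsplit(ref, "")[[1]]
      off <- idx[idx %in% span] - span[1] + 1L
      # target-strand C->T is coding-strand C->T (same strand) or G->A
      b[off] <- if (same_strand) "T" else "A"
      alt <- paste(b, collapse = "")
      tibble(
        residue = r, ref_codon = ref, alt_codon = alt,
        ref_aa = translate_codon(ref), alt_aa = translate_codon(alt),
        class = classify_outcome(ref, alt)
      )
    }))
    if (!nrow(chg)) return(NULL)
    tibble(
      guide_id = gid, gene_id = model$gene_id, tx_id = model$tx_id,
      edited_pos = list(sort(sites$proto_pos[sel])),
      edit = paste(sort(sites$proto_pos[sel]), collapse = "+"),
      n_edits = length(sel),
      changes = list(chg),
      class = most_severe_class(chg$class),
      notation = paste(
        paste0(chg$ref_aa, chg$residue, chg$alt_aa),
        collapse = "/"
      )
    )
  }))
}

#' Amino-acid conversion matrix of a C-to-T base editor
#'
#' Pure codon-table computation: for each canonical amino acid, the union
#' over its codons of the translations reachable by editing any non-empty
#' subset of same-strand target bases -- C->T edits only, or G->A edits only
#' (the coding-strand image of editing the opposite strand), never mixed
#' within one outcome, since one deamination event acts on one strand.
#'
#' @return A tibble with one row per amino acid: `aa`, `reachable`
#'   (list-column of reachable translations incl. `"*"`), `reachable_aas`
#'   (collapsed string), `convertible` (some different non-stop amino acid is
#'   reachable), `silent_or_nonsense_only`. Attributes `n_convertible` and
#'   `n_silent_or_nonsense_only` hold the two headline counts.
#' @export
aa_conversion_matrix <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  edit_set <- function(codon, from, to) {
    b <- strsplit(codon, "")[[1]]
    vapply(nonempty_subsets(which(b == from)), function(s) {
      bb <- b
      bb[s] <- to
      paste(bb, collapse = "")
    }, character(1))
  }
  aas <- sort(setdiff(unique(gc), "*"))
  out <- tibble(aa = aas) |>
    mutate(
      reachable = map(.data$aa, function(a) {
        alts <- unlist(lapply(codons[gc == a], function(cd) {
          c(edit_set(cd, "C", "T"), edit_set(cd, "G", "A"))
        }))
        sort(unique(unname(gc[alts])))
      }),
      reachable_aas = map_chr(.data$reachable, paste, collapse = ","),
      convertible = map2(.data$reachable, .data$aa, ~ any(.x != .y & .x != "*")) |>
        unlist(),
      silent_or_nonsense_only = !.data$convertible
    )
  attr(out, "n_convertible") <- sum(out$convertible)
  attr(out, "n_silent_or_nonsense_only") <- sum(out$silent_or_nonsense_only)
  out
}

#' Group candidates that target the same locus
#'
#' Two candidates target the same position when their target strands are
#' identical and their protospacer intervals overlap by at least one base;
#' groups are the transitive closure of that relation.
#'
#' @param candidates candidate tibble with `contig`, `start`, `end`, `strand`.
#' @return The input with an integer `target_group` column added.
#' @export
group_by_target_overlap <- function(candidates) {
  if (!nrow(candidates)) {
    return(mutate(candidates, target_group = integer()))
  }
  ord <- order(candidates$contig, candidates$strand, candidates$start)
  grp <- integer(nrow(candidates))
  gid <- 0L
  cur_contig <- ""
  cur_strand <- ""
  cur_end <- -1L
  for (k in ord) {
    if (candidates$contig[k] != cur_contig || candidates$strand[k] != cur_strand ||
        candidates$start[k] >= cur_end) {
      gid <- gid + 1L
      cur_contig <- candidates$contig[k]
      cur_strand <- candidates$strand[k]
      cur_end <- candidates$end[k]
    } else {
      cur_end <- max(cur_end, candidates$end[k])
    }
    grp[k] <- gid
  }
  mutate(candidates, target_group = grp)
}

#' Export an sgRNA library as a flat table
#'
#' One row per candidate with its best (most severe, then fewest-edit)
#' outcome notation and the set of outcome classes it can produce.
#' Duplicate spacer sequences are emitted with a `duplicate_spacer` flag.
#' Ordering is deterministic (contig, start, strand).
#'
#' @param candidates tibble from [filter_editable()].
#' @param outcomes tibble from [enumerate_outcomes()].
#' @param path optional output TSV path.
#' @return The export tibble (invisibly when `path` is given).
#' @export
export_library <- function(candidates, outcomes, path = NULL) {
  sev <- function(cl) match(cl, CLASS_LEVELS)
  best <- outcomes |>
    filter(.data$class %in% CLASS_LEVELS) |>
    group_by(.data$guide_id) |>
    summarise(
      gene = paste(sort(unique(.data$gene_id)), collapse = ","),
      best_outcome = {
        o <- pick(dplyr::everything())
        o <- o[order(-sev(o$class), o$n_edits, o$notation), ]
        o$notation[1]
      },
      outcome_classes = paste(sort(unique(.data$class)), collapse = "+"),
      .groups = "drop"
    )
  out <- candidates |>
    left_join(best, by = "guide_id") |>
    mutate(
      window_c = map_chr(.data$window_c_pos, paste, collapse = ","),
      duplicate_spacer = duplicated(.data$spacer) | duplicated(.data$spacer, fromLast = TRUE)
    ) |>
    arrange(.data$contig, .data$start, .data$strand) |>
    select(
      "guide_id", "gene", "spacer", "pam", "pam_class", "contig", "start",
      "end", "strand", "window_c", "best_outcome", "outcome_classes",
      "duplicate_spacer"
    )
  if (!is.null(path)) {
    readr::write_tsv(out, path)
    return(invisible(out))
  }
  out
}
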