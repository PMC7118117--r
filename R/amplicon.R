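#' Describe an amplicon around one protospacer
#'
#' The reference is the amplicon sequence; the protospacer+PAM (23 nt)
#' starts at `proto_start` (0-based) on the given strand of the amplicon.
#' Internally the spec is normalised to "target orientation": the reference
#' is stored so the protospacer+PAM reads forward, and all positions below
#' are 1-23 in that orientation (1 = PAM-distal end of the protospacer,
#' 21-23 = PAM). The 10-nt flanks on both sides of the protospacer+PAM are
#' extracted from the reference and later used to identify the segment in
#' reads. `coding_strand` records whether the protein-coding strand is the
#' target strand or its opposite; reporting mirrors accordingly (a target
#' C-to-T appears as G-to-A on an opposite coding strand).
#'
#' @param id amplicon identifier.
#' @param reference amplicon sequence (A/C/G/T).
#' @param proto_start 0-based start of the protospacer within `reference`
#'   (on `target_strand`).
#' @param target_strand `"+"` if protospacer+PAM reads forward on
#'   `reference`, `"-"` if on its reverse complement. For `"-"`,
#'   `proto_start` refers to the reverse-complemented sequence.
#' @param coding_strand `"target"` or `"opposite"`.
#' @param codon_map optional tibble with `residue` and `offset` (0-based
#'   start of the codon within the 23-nt segment, coding-strand reading
#'   direction); reference codons and amino acids are derived.
#' @param window activity-window protospacer positions.
#' @return An object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(id, reference, proto_start,
                          target_strand = c("+", "-"),
                          coding_strand = c("target", "opposite"),
                          codon_map = NULL, window = 4:8) {
  target_strand <- match.arg(target_strand)
  coding_strand <- match.arg(coding_strand)
  reference <- toupper(reference)
  assert_dna(reference, "amplicon reference", allow_n = FALSE)
  ref_t <- if (target_strand == "-") revcomp(reference) else reference
  if (proto_start < 10L || proto_start + 23L + 10L > nchar(ref_t)) {
    abort("amplicon must leave >= 10 nt of flank on both sides of protospacer+PAM")
  }
  segment <- substr(ref_t, proto_start + 1L, proto_start + 23L)
  flank5 <- substr(ref_t, proto_start - 9L, proto_start)
  flank3 <- substr(ref_t, proto_start + 24L, proto_start + 33L)
  seg_b <- strsplit(segment, "")[[1]]
  window_c <- window[seg_b[window] == "C"]
  cm <- NULL
  if (!is.null(codon_map)) {
    cm <- as_tibble(codon_map)
    stopifnot(all(c("residue", "offset") %in% names(cm)))
    if (any(cm$offset < 0L | cm$offset + 3L > 23L)) {
      abort("codon_map offsets must lie within the 23-nt segment")
    }
    cm <- cm |>
      mutate(
        ref_codon = map_chr(.data$offset, function(o) {
          cd <- substr(segment, o + 1L, o + 3L)
          if (coding_strand == "opposite") revcomp(cd) else cd
        }),
        ref_aa = translate_codon(.data$ref_codon)
      )
  }
  structure(
    list(
      id = id, reference = ref_t, proto_start = proto_start,
      segment = segment, flank5 = flank5, flank3 = flank3,
      target_strand = target_strand, coding_strand = coding_strand,
      window = window, window_c = window_c, codon_map = cm
    ),
    class = "amplicon_spec"
  )
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat(sprintf(
    "<amplicon_spec> %s: %d nt reference, protospacer+PAM %s, coding strand = %s\n",
    x$id, nchar(x$reference), x$segment, x$coding_strand
  ))
  invisible(x)
}

#' Quality-control amplicon reads
#'
#' Reads with more than 50\% of bases below Q30 are discarded (exactly half
#' is kept); in surviving reads every base below Q30 is masked to N.
#'
#' @param fastq path to a Phred+33 FASTQ file, or a tibble with columns
#'   `id`, `seq`, `qual`.
#' @param min_q quality threshold (default Q30).
#' @param max_low_frac discard reads whose low-quality fraction exceeds this.
#' @return A list: `reads` (tibble `id`, `seq` with masked bases),
#'   `n_total`, `n_failed`.
#' @export
qc_reads <- function(fastq, min_q = 30, max_low_frac = 0.5) {
  if (is.character(fastq) && length(fastq) == 1L) {
    reads <- read_fastq(fastq)
  } else {
    reads <- as_tibble(fastq)
    stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  }
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    bad <- which(nchar(reads$seq) != nchar(reads$qual))[1]
    abort(sprintf("FASTQ record %d: sequence and quality lengths differ", bad))
  }
  qs <- lapply(reads$qual, function(q) utf8ToInt(q) - 33L)
  low_frac <- map_dbl(qs, ~ mean(.x < min_q))
  keep <- low_frac <= max_low_frac
  masked <- map2_chr(reads$seq[keep], qs[keep], function(s, q) {
    if (all(q >= min_q)) return(s)
    b <- strsplit(s, "")[[1]]
    b[q < min_q] <- "N"
    paste(b, collapse = "")
  })
  list(
    reads = tibble(id = reads$id[keep], seq = masked),
    n_total = nrow(reads),
    n_failed = sum(!keep)
  )
}

read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) abort(sprintf("malformed FASTQ '%s': %s", path, conditionMessage(e)))
  )
  tibble(
    id = names(x),
    seq = toupper(as.character(x)),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' Extract the protospacer segment from reads by flank matching
#'
#' Both 10-nt flanks must be found in order (first occurrence of the 5'
#' flank, then the 3' flank downstream of it); the between-flank segment is
#' returned. Read orientation is auto-detected by retrying on the reverse
#' complement. Matching is exact by default; `max_flank_mm = 1` allows one
#' mismatch per flank.
#'
#' @param reads character vector of read sequences, or tibble with `seq`.
#' @param spec an [amplicon_spec()].
#' @param max_flank_mm allowed mismatches per flank (0 or 1).
#' @return A tibble: `seq`, `segment` (NA when unmatched), `orientation`
#'   (`"fwd"`, `"rev"` or NA).
#' @export
locate_protospacer <- function(reads, spec, max_flank_mm = 0) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  find_seg <- function(s) {
    i5 <- flank_match(s, spec$flank5, max_flank_mm)
    if (is.na(i5)) return(NA_character_)
    rest_start <- i5 + nchar(spec$flank5)
    i3 <- flank_match(substr(s, rest_start, nchar(s)), spec$flank3, max_flank_mm)
    if (is.na(i3)) return(NA_character_)
    substr(s, rest_start, rest_start + i3 - 2L)
  }
  seg <- character(length(seqs))
  ori <- character(length(seqs))
  for (k in seq_along(seqs)) {
    v <- find_seg(seqs[k])
    if (!is.na(v)) {
      seg[k] <- v
      ori[k] <- "fwd"
    } else {
      v <- find_seg(revcomp(seqs[k]))
      if (!is.na(v)) {
        seg[k] <- v
        ori[k] <- "rev"
      } else {
        seg[k] <- NA_character_
        ori[k] <- NA_character_
      }
    }
  }
  tibble(seq = seqs, segment = seg, orientation = ori)
}

# first match position (1-based) of flank in s, N in read treated as mismatch
flank_match <- function(s, flank, max_mm) {
  if (max_mm == 0) {
    i <- regexpr(flank, s, fixed = TRUE)[1]
    return(if (i < 0) NA_integer_ else i)
  }
  m <- Biostrings::matchPattern(flank, Biostrings::DNAString(s),
    max.mismatch = max_mm, fixed = TRUE
  )
  if (!length(m)) NA_integer_ else BiocGenerics::start(m)[1]
}

#' Classify a segment as carrying an indel
#'
#' A flank-delimited protospacer+PAM segment is an indel read exactly when
#' its length differs from 23 nt; no other heuristic is applied.
#'
#' @param segment character vector of segments.
#' @return Logical vector.
#' @export
classify_indel <- function(segment) {
  nchar(segment) != 23L
}

#' Per-position base counts over indel-free segments
#'
#' Counts A/C/G/T/N at each of the 23 segment positions (target
#' orientation). `n_covered` excludes N (a masked base removes the read from
#' that position's denominator only). Coding-strand reporting columns are
#' added: when the coding strand is the opposite strand, `coding_position`
#' mirrors the position and `coding_ref`/`coding_alt_base` complement the
#' bases, so a target-strand C-to-T reads as G-to-A.
#'
#' @param segments character vector of 23-nt segments (N allowed).
#' @param spec an [amplicon_spec()].
#' @return A tibble with one row per position 1-23: `position`, `ref_base`,
#'   `A`, `C`, `G`, `T`, `N`, `n_covered`, `in_window`, `coding_position`,
#'   `coding_ref`.
#' @export
base_frequency_table <- function(segments, spec) {
  stopifnot(all(nchar(segments) == 23L))
  ref_b <- strsplit(spec$segment, "")[[1]]
  m <- if (length(segments)) {
    matrix(unlist(strsplit(segments, "")), nrow = 23L)
  } else {
    matrix(character(0), nrow = 23L)
  }
  counts <- vapply(seq_len(23L), function(p) {
    tabulate(factor(m[p, ], levels = DNA_ALPHABET_STRICT), nbins = 5L)
  }, integer(5))
  out <- tibble(
    position = 1:23,
    ref_base = ref_b,
    A = counts[1, ], C = counts[2, ], G = counts[3, ], T = counts[4, ],
    N = counts[5, ]
  ) |>
    mutate(
      n_covered = .data$A + .data$C + .data$G + .data$T,
      in_window = .data$position %in% spec$window
    )
  if (spec$coding_strand == "opposite") {
    out <- out |>
      mutate(
        coding_position = 24L - .data$position,
        coding_ref = complement_base(.data$ref_base)
      )
  } else {
    out <- out |>
      mutate(coding_position = .data$position, coding_ref = .data$ref_base)
  }
  out
}

#' Per-position substitution efficiency
#'
#' `efficiency(pos) = (reads with C-to-T at pos / indel-free reads covering
#' pos) x (1 - fraction of reads with indels)`. Only target-strand C-to-T is
#' folded into the efficiency (reported as G-to-A on an opposite coding
#' strand); positions whose reference base is not C get `NA`, as do
#' positions with zero coverage.
#'
#' @param base_table tibble from [base_frequency_table()].
#' @param indel_fraction scalar in \[0, 1\].
#' @return `base_table` with `substitution` (label like `"C>T"` on the
#'   coding strand) and `efficiency` columns added.
#' @export
substitution_efficiency <- function(base_table, indel_fraction) {
  stopifnot(indel_fraction >= 0, indel_fraction <= 1)
  base_table |>
    mutate(
      substitution = ifelse(
        .data$ref_base == "C",
        ifelse(.data$coding_ref == "C", "C>T", "G>A"),
        NA_character_
      ),
      efficiency = ifelse(
        .data$ref_base == "C" & .data$n_covered > 0,
        .data$T / .data$n_covered * (1 - indel_fraction),
        NA_real_
      )
    )
}

#' Codon-level amino-acid allele fractions
#'
#' Translates every indel-free segment at each mapped codon (on the coding
#' strand) and reports allele fractions per residue. Segments with an N
#' inside a codon are excluded from that residue's denominator.
#'
#' @param segments character vector of 23-nt segments.
#' @param spec an [amplicon_spec()] with a `codon_map`.
#' @return A tibble: `residue`, `ref_aa`, `codon`, `aa`, `notation`
#'   (e.g. `"E203K"`), `n`, `fraction`.
#' @export
codon_allele_frequencies <- function(segments, spec) {
  if (is.null(spec$codon_map)) abort("amplicon_spec has no codon_map")
  stopifnot(all(nchar(segments) == 23L))
  bind_rows(lapply(seq_len(nrow(spec$codon_map)), function(i) {
    res <- spec$codon_map$residue[i]
    off <- spec$codon_map$offset[i]
    ref_aa <- spec$codon_map$ref_aa[i]
    cods <- substr(segments, off + 1L, off + 3L)
    if (spec$coding_strand == "opposite" && length(cods)) cods <- revcomp(cods)
    cods <- cods[!grepl("N", cods)]
    if (!length(cods)) {
      return(tibble(
        residue = res, ref_aa = ref_aa, codon = character(0),
        aa = character(0), notation = character(0), n = integer(0),
        fraction = numeric(0)
      ))
    }
    tab <- table(cods)
    tibble(
      residue = res, ref_aa = ref_aa,
      codon = names(tab), n = as.integer(tab)
    ) |>
      mutate(
        aa = translate_codon(.data$codon),
        notation = paste0(ref_aa, res, .data$aa),
        fraction = .data$n / sum(.data$n)
      ) |>
      group_by(.data$residue, .data$ref_aa, .data$aa, .data$notation) |>
      summarise(
        codon = paste(.data$codon, collapse = ","),
        n = sum(.data$n), fraction = sum(.data$fraction),
        .groups = "drop"
      ) |>
      select("residue", "ref_aa", "codon", "aa", "notation", "n", "fraction") |>
      arrange(dplyr::desc(.data$n))
  }))
}

#' Joint base patterns across the window cytosines
#'
#' Counts the joint pattern of bases at the given positions across
#' indel-free segments (reads with an N at any of the positions are
#' excluded). With a single position this degenerates to the marginal base
#' counts; under processive deamination only all-reference and all-edited
#' patterns appear.
#'
#' @param segments character vector of 23-nt segments.
#' @param positions target-orientation positions to track; defaults to the
#'   reference window cytosines of `spec`.
#' @param spec optional [amplicon_spec()] used for the default positions.
#' @return A tibble: `pattern`, `n`, `fraction`.
#' @export
haplotype_patterns <- function(segments, positions = NULL, spec = NULL) {
  if (is.null(positions)) {
    if (is.null(spec)) abort("supply positions or an amplicon_spec")
    positions <- spec$window_c
  }
  if (!length(positions)) abort("no window cytosines to track")
  stopifnot(all(nchar(segments) == 23L))
  pats <- vapply(strsplit(segments, ""), function(b) {
    paste(b[positions], collapse = "")
  }, character(1))
  pats <- pats[!grepl("N", pats)]
  if (!length(pats)) {
    return(tibble(pattern = character(0), n = integer(0), fraction = numeric(0)))
  }
  tab <- sort(table(pats), decreasing = TRUE)
  tibble(
    pattern = names(tab), n = as.integer(tab),
    fraction = as.integer(tab) / sum(tab)
  )
}

#' Quantify base-editing outcomes for one amplicon
#'
#' Full pipeline: read QC (Q30 masking and discard rule), flank-based
#' protospacer extraction with orientation auto-detection, length-based
#' indel classification, per-position base counts and substitution
#' efficiencies, codon-level allele fractions (when a codon map is given)
#' and window co-conversion haplotypes.
#'
#' @param fastq FASTQ path or tibble (`id`, `seq`, `qual`).
#' @param spec an [amplicon_spec()].
#' @param max_flank_mm allowed mismatches per flank.
#' @return An object of class `amplicon_edit_table`: list with `counts`
#'   (tibble of read-fate tallies), `indel_fraction`, `base_table`,
#'   `efficiency` (rows of the base table at reference-C positions),
#'   `codon_alleles`, `haplotypes`, `spec`.
#' @export
quantify_amplicon <- function(fastq, spec, max_flank_mm = 0) {
  qc <- qc_reads(fastq)
  loc <- locate_protospacer(qc$reads, spec, max_flank_mm = max_flank_mm)
  matched <- loc |> filter(!is.na(.data$segment))
  n_unmatched <- sum(is.na(loc$segment))
  is_indel <- classify_indel(matched$segment)
  segments <- matched$segment[!is_indel]
  n_flank <- nrow(matched)
  indel_fraction <- if (n_flank > 0) sum(is_indel) / n_flank else NA_real_
  bt <- base_frequency_table(segments, spec) |>
    substitution_efficiency(ifelse(is.na(indel_fraction), 0, indel_fraction))
  counts <- tibble(
    total = qc$n_total,
    qc_failed = qc$n_failed,
    flank_unmatched = n_unmatched,
    flank_matched = n_flank,
    indel = sum(is_indel),
    indel_free = length(segments)
  )
  structure(
    list(
      counts = counts,
      indel_fraction = indel_fraction,
      base_table = bt,
      efficiency = bt |> filter(.data$ref_base == "C"),
      codon_alleles = if (!is.null(spec$codon_map)) {
        codon_allele_frequencies(segments, spec)
      },
      haplotypes = if (length(spec$window_c)) {
        haplotype_patterns(segments, spec = spec)
      },
      spec = spec
    ),
    class = "amplicon_edit_table"
  )
}

#' @export
print.amplicon_edit_table <- function(x, ...) {
  cat(sprintf(
    "<amplicon_edit_table> %s: %d reads (%d QC-failed, %d unmatched, %d indel, %d indel-free); indel fraction %.4f\n",
    x$spec$id, x$counts$total, x$counts$qc_failed, x$counts$flank_unmatched,
    x$counts$indel, x$counts$indel_free,
    ifelse(is.na(x$indel_fraction), 0, x$indel_fraction)
  ))
  eff <- x$efficiency |> filter(.data$in_window, !is.na(.data$efficiency))
  if (nrow(eff)) {
    cat(sprintf(
      "  window substitution efficiency: %s\n",
      paste(sprintf("pos %d %.3f", eff$position, eff$efficiency), collapse = ", ")
    ))
  }
  invisible(x)
}

#' @rdname quantify_amplicon
#' @param x an `amplicon_edit_table`.
#' @param ... unused.
#' @method tidy amplicon_edit_table
#' @export
tidy.amplicon_edit_table <- function(x, ...) {
  x$base_table |>
    mutate(amplicon = x$spec$id, .before = 1)
}

#' @rdname quantify_amplicon
#' @method glance amplicon_edit_table
#' @export
glance.amplicon_edit_table <- function(x, ...) {
  dplyr::bind_cols(tibble(amplicon = x$spec$id), x$counts,
                   tibble(indel_fraction = x$indel_fraction))
}
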