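# Independent brute-force oracles. These deliberately avoid the package's
# internal gene-model and search machinery: splicing is done with substr on
# raw sequence, editing by mutating the whole contig and re-reading every
# codon, off-target search by exhaustive sliding-window comparison.

# Spliced CDS of a gene directly from a 1-based-inclusive GTF tibble.
oracle_splice <- function(gtf_rows, contig_seq) {
  rows <- gtf_rows[order(gtf_rows$start), ]
  cds <- paste(substring(contig_seq, rows$start, rows$end), collapse = "")
  if (rows$strand[1] == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    first <- rows$frame[nrow(rows)]
  } else {
    first <- rows$frame[1]
  }
  substr(cds, first + 1, nchar(cds))
}

# Codon-level diff between two equal-length CDS strings.
oracle_codon_diff <- function(ref_cds, alt_cds) {
  n <- nchar(ref_cds) %/% 3
  gc <- Biostrings::GENETIC_CODE
  out <- list()
  for (r in seq_len(n)) {
    rc <- substr(ref_cds, 3 * r - 2, 3 * r)
    ac <- substr(alt_cds, 3 * r - 2, 3 * r)
    if (rc != ac) {
      ra <- unname(gc[rc])
      aa <- unname(gc[ac])
      cls <- if (aa == "*" && ra != "*") "nonsense" else if (aa == ra) "silent" else "missense"
      out[[length(out) + 1]] <- data.frame(
        residue = r, ref_aa = ra, alt_aa = aa, class = cls,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, list(data.frame(
    residue = integer(0), ref_aa = character(0), alt_aa = character(0),
    class = character(0)
  ))))
}

# Mutate-and-retranslate oracle for one candidate against one gene's GTF rows:
# for every non-empty subset of the candidate's window Cs, edit the contig
# (C->T on the target strand; G->A on the plus strand when the guide is on
# minus), re-splice, and report per-codon changes.
oracle_outcomes <- function(contig_seq, gtf_rows, start, end, strand,
                            window_c_pos) {
  ref_cds <- oracle_splice(gtf_rows, contig_seq)
  gpos <- if (strand == "+") start + window_c_pos - 1L else end - window_c_pos
  # restrict to coding positions (1-based contig coords inside any interval)
  coding <- unlist(Map(seq, gtf_rows$start, gtf_rows$end))
  in_cds <- (gpos + 1L) %in% coding
  gpos <- gpos[in_cds]
  ppos <- window_c_pos[in_cds]
  if (!length(gpos)) return(NULL)
  subsets <- lapply(seq_len(2^length(gpos) - 1), function(m) {
    which(bitwAnd(m, bitwShiftL(1L, seq_along(gpos) - 1L)) > 0L)
  })
  lapply(subsets, function(sel) {
    b <- strsplit(contig_seq, "")[[1]]
    for (g in gpos[sel]) {
      b[g + 1L] <- if (strand == "+") "T" else "A" # target-strand C->T
    }
    alt_cds <- oracle_splice(gtf_rows, paste(b, collapse = ""))
    list(
      edit = paste(sort(ppos[sel]), collapse = "+"),
      changes = oracle_codon_diff(ref_cds, alt_cds)
    )
  })
}

# Exhaustive sliding-window off-target search (both strands, <= max_mm over
# the 20-mer, PAM class in pam_classes).
oracle_offtargets <- function(spacer, seqs, max_mm = 3,
                              pam_classes = c("NGG", "NAG")) {
  sp <- strsplit(spacer, "")[[1]]
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  rows <- list()
  for (contig in names(seqs)) {
    s <- seqs[[contig]]
    L <- nchar(s)
    chars <- strsplit(s, "")[[1]]
    rchars <- strsplit(rc(s), "")[[1]]
    for (strand in c("+", "-")) {
      cc <- if (strand == "+") chars else rchars
      if (L < 23) next
      for (i in 0:(L - 23)) {
        win <- cc[(i + 1):(i + 20)]
        mm <- sum(win != sp)
        if (mm > max_mm) next
        pam <- paste(cc[(i + 21):(i + 23)], collapse = "")
        cls <- if (substr(pam, 2, 3) == "GG") "NGG" else if (substr(pam, 2, 3) == "AG") "NAG" else "other"
        if (!cls %in% pam_classes) next
        g_start <- if (strand == "+") i else L - (i + 20L)
        rows[[length(rows) + 1]] <- data.frame(
          contig = contig, start = g_start, strand = strand, n_mm = mm,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(contig = character(0), start = integer(0),
                      strand = character(0), n_mm = integer(0))
  }
  out[order(out$contig, out$strand, out$start), , drop = FALSE]
}

# Vectorised variant of the sliding-window search used where many spacers are
# checked: mismatch counts come from 20 shifted whole-vector comparisons.
oracle_offtargets_fast <- function(spacer, seqs, max_mm = 3,
                                   pam_classes = c("NGG", "NAG")) {
  sp <- strsplit(spacer, "")[[1]]
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  out <- list()
  for (contig in names(seqs)) {
    s <- seqs[[contig]]
    L <- nchar(s)
    if (L < 23) next
    for (strand in c("+", "-")) {
      cc <- strsplit(if (strand == "+") s else rc(s), "")[[1]]
      i0 <- 0:(L - 23L)
      mm <- integer(length(i0))
      for (j in 1:20) mm <- mm + (cc[i0 + j] != sp[j])
      p2 <- cc[i0 + 22L]
      p3 <- cc[i0 + 23L]
      cls <- ifelse(p2 == "G" & p3 == "G", "NGG",
                    ifelse(p2 == "A" & p3 == "G", "NAG", "other"))
      keep <- mm <= max_mm & cls %in% pam_classes
      if (!any(keep)) next
      out[[length(out) + 1]] <- data.frame(
        contig = contig,
        start = if (strand == "+") i0[keep] else L - (i0[keep] + 20L),
        strand = strand, n_mm = mm[keep], stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(contig = character(0), start = integer(0),
                      strand = character(0), n_mm = integer(0))
  }
  res[order(res$contig, res$strand, res$start), , drop = FALSE]
}
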