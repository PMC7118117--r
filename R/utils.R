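#' DNA helpers shared across the package
#'
#' Thin wrappers around Biostrings kept internal so all modules use one
#' convention: plain uppercase character vectors over {A,C,G,T,N}, 0-based
#' half-open genomic coordinates.
#' @noRd
NULL

DNA_ALPHABET_STRICT <- c("A", "C", "G", "T", "N")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

#' Translate codons with the standard genetic code ("*" for stop)
#' @noRd
translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  out <- unname(gc[codon])
  out[is.na(out)] <- NA_character_
  out
}

#' Translate a full coding sequence (length divisible by 3)
#' @noRd
translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  paste(translate_codon(codons), collapse = "")
}

#' All non-empty subsets of an index vector
#'
#' `combn()` treats a length-one numeric as `seq_len(n)`, so subsets are
#' enumerated by bitmask instead.
#' @noRd
nonempty_subsets <- function(pos) {
  n <- length(pos)
  if (n == 0L) return(list())
  lapply(seq_len(2^n - 1L), function(m) {
    pos[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) > 0L]
  })
}

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- which(!grepl(pat, x))
  if (length(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,T%s} (first offender: element %d)",
      what, if (allow_n) ",N" else "", bad[1]
    ))
  }
  invisible(x)
}

#' Severity ordering for outcome classes
#' @noRd
CLASS_LEVELS <- c("silent", "missense", "nonsense")

most_severe_class <- function(classes) {
  classes <- classes[!is.na(classes) & classes != "unknown"]
  if (!length(classes)) return("unknown")
  CLASS_LEVELS[max(match(classes, CLASS_LEVELS))]
}

#' PAM classification: first base is the "N"
#' @noRd
pam_class_of <- function(pam) {
  tail2 <- substr(pam, 2, 3)
  dplyr::case_when(
    tail2 == "GG" ~ "NGG",
    tail2 == "AG" ~ "NAG",
    TRUE ~ paste0("N", tail2)
  )
}
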