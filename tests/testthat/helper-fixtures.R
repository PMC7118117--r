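# Fixture builders shared across test files. Everything is generated in code;
# no binary or downloaded data.

write_temp_fasta <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(unlist(Map(function(n, s) c(paste0(">", n), s), names(seqs), seqs)),
             path)
  path
}

write_temp_gtf <- function(gtf) {
  path <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  bescreen::write_gtf(gtf, path)
  path
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# quality characters: Phred+33
qchar <- function(q, n = 1) strrep(intToUtf8(q + 33), n)

# a minimal 43-nt amplicon: 10-nt flanks around protospacer+PAM, with C at
# chosen window positions of the protospacer (target orientation)
make_amplicon <- function(window_c = c(4, 6), coding_strand = "target",
                          codon_map = NULL, seed = 42) {
  withr::with_seed(seed, {
    seg <- strsplit(paste0(rand_dna(20), "AGG"), "")[[1]]
    seg[1:20][!(1:20) %in% window_c & seg[1:20] == "C"] <- "A"
    seg[4:8] <- "A"
    seg[window_c] <- "C"
    reference <- paste0(rand_dna(10), paste(seg, collapse = ""), rand_dna(10))
  })
  amplicon_spec("amp1", reference, 10L, coding_strand = coding_strand,
                codon_map = codon_map)
}

# FASTQ-style read tibble from plain sequences at uniform quality
reads_tbl <- function(seqs, q = 37) {
  tibble::tibble(
    id = sprintf("r%04d", seq_along(seqs)),
    seq = seqs,
    qual = vapply(nchar(seqs), function(L) qchar(q, L), character(1))
  )
}
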