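test_that("qc_reads applies the Q30 discard and masking rules", {
  reads <- tibble::tibble(
    id = c("a", "b", "c"),
    seq = c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC"),
    qual = c(
      paste0(qchar(20, 6), qchar(37, 4)), # 6/10 below Q30 -> discarded
      paste0(qchar(20, 5), qchar(37, 5)), # exactly half -> kept, masked
      qchar(37, 10) # clean -> unchanged
    )
  )
  qc <- qc_reads(reads)
  expect_equal(qc$n_total, 3L)
  expect_equal(qc$n_failed, 1L)
  expect_equal(qc$reads$id, c("b", "c"))
  expect_equal(qc$reads$seq[1], "NNNNNCGTAC")
  expect_equal(qc$reads$seq[2], "ACGTACGTAC")
})

test_that("qc_reads rejects malformed records", {
  bad <- tibble::tibble(id = "a", seq = "ACGT", qual = "II")
  expect_error(qc_reads(bad), "record 1")
})

test_that("locate_protospacer finds the segment between the flanks", {
  spec <- make_amplicon()
  read <- spec$reference
  loc <- locate_protospacer(read, spec)
  expect_equal(loc$segment, spec$segment)
  expect_equal(nchar(loc$segment), 23L)
  expect_equal(loc$orientation, "fwd")

  # only one flank present -> unmatched
  half <- paste0(spec$flank5, substr(spec$segment, 1, 23))
  expect_true(is.na(locate_protospacer(half, spec)$segment))

  # reverse-complement read -> same segment after orientation fix
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spec$reference)
  ))
  loc_rc <- locate_protospacer(rc, spec)
  expect_equal(loc_rc$segment, spec$segment)
  expect_equal(loc_rc$orientation, "rev")
})

test_that("indel classification is exactly length != 23", {
  expect_false(classify_indel(strrep("A", 23)))
  expect_true(classify_indel(strrep("A", 41))) # 23 + 18-nt insertion
  expect_true(classify_indel(strrep("A", 20))) # 3-nt deletion
  expect_equal(classify_indel(c(strrep("A", 23), strrep("A", 22))),
               c(FALSE, TRUE))
})

test_that("base counts, N masking and substitution efficiency are exact", {
  spec <- make_amplicon(window_c = c(4, 6))
  seg_edit <- spec$segment
  substr(seg_edit, 6, 6) <- "T"
  segments <- c(rep(spec$segment, 45), rep(seg_edit, 45))
  bt <- base_frequency_table(segments, spec)
  expect_equal(bt$n_covered, rep(90L, 23))
  expect_equal(bt$T[6], 45L)
  expect_equal(bt$C[6], 45L)
  eff <- substitution_efficiency(bt, 0.10)
  expect_equal(eff$efficiency[6], 45 / 90 * 0.9)
  expect_equal(eff$efficiency[4], 0) # unedited reference C
  expect_true(is.na(eff$efficiency[1])) # non-C position

  # with indel fraction 0 the efficiency is the raw fraction
  eff0 <- substitution_efficiency(bt, 0)
  expect_equal(eff0$efficiency[6], 0.5)

  # an N at a position removes the read from that position's denominator only
  seg_n <- spec$segment
  substr(seg_n, 6, 6) <- "N"
  btn <- base_frequency_table(c(segments, seg_n), spec)
  expect_equal(btn$n_covered[6], 90L)
  expect_equal(btn$n_covered[5], 91L)
})

test_that("opposite coding strand reports mirrored positions and G>A labels", {
  spec <- make_amplicon(window_c = 5, coding_strand = "opposite")
  seg_edit <- spec$segment
  substr(seg_edit, 5, 5) <- "T"
  bt <- base_frequency_table(c(spec$segment, seg_edit), spec)
  eff <- substitution_efficiency(bt, 0)
  row <- eff[eff$position == 5, ]
  expect_equal(row$coding_position, 19L)
  expect_equal(row$coding_ref, "G")
  expect_equal(row$substitution, "G>A")
  expect_equal(row$efficiency, 0.5)
})

test_that("codon allele fractions mirror a 77% edited mixture", {
  # codon map: the protospacer codon at offset 3 (positions 4-6), coding on
  # the target strand; window C on the codon's first base so the edit is
  # amino-acid changing (CAA -> TAA)
  spec <- make_amplicon(window_c = 4)
  seg <- spec$segment
  ref_codon <- substr(seg, 4, 6)
  expect_equal(ref_codon, "CAA")
  spec2 <- amplicon_spec("amp1", spec$reference, 10L,
    codon_map = tibble::tibble(residue = 203L, offset = 3L)
  )
  expect_equal(spec2$codon_map$ref_codon, ref_codon)
  expect_equal(spec2$codon_map$ref_aa, "Q")
  edited <- seg
  substr(edited, 4, 4) <- "T"
  segments <- c(rep(edited, 77), rep(seg, 23))
  ca <- codon_allele_frequencies(segments, spec2)
  expect_equal(ca$fraction[ca$aa == "*"], 0.77)
  expect_equal(ca$notation[ca$aa == "*"], "Q203*")
  # all-reference segments -> reference fraction 1
  ca_ref <- codon_allele_frequencies(rep(seg, 10), spec2)
  expect_equal(ca_ref$fraction, 1.0)
  expect_equal(ca_ref$aa, spec2$codon_map$ref_aa)
  # N in the codon removes the segment from the residue's denominator
  seg_n <- seg
  substr(seg_n, 5, 5) <- "N"
  ca_n <- codon_allele_frequencies(c(rep(seg, 4), seg_n), spec2)
  expect_equal(sum(ca_n$n), 4L)
})

test_that("haplotype patterns capture processive vs independent editing", {
  spec <- make_amplicon(window_c = c(4, 6, 8))
  all_edit <- spec$segment
  for (p in c(4, 6, 8)) substr(all_edit, p, p) <- "T"
  segs <- c(rep(spec$segment, 6), rep(all_edit, 4))
  hp <- haplotype_patterns(segs, spec = spec)
  expect_setequal(hp$pattern, c("CCC", "TTT"))
  expect_equal(hp$n[hp$pattern == "CCC"], 6L)
  # single window C degenerates to marginal counts
  spec1 <- make_amplicon(window_c = 5)
  e1 <- spec1$segment
  substr(e1, 5, 5) <- "T"
  hp1 <- haplotype_patterns(c(rep(spec1$segment, 3), e1), spec = spec1)
  expect_equal(hp1$pattern, c("C", "T"))
  expect_equal(hp1$n, c(3L, 1L))
})

test_that("read fates are conserved through quantify_amplicon", {
  spec <- make_amplicon(window_c = c(4, 6))
  sim <- sim_amplicon_reads(spec, n = 400, edit_rates = c(`4` = 0.3, `6` = 0.5),
                            indel_rate = 0.1, lowq_frac = 0.02, seed = 5)
  reads <- sim$reads
  # add reads that cannot match the flanks and reads that fail QC
  junk <- tibble::tibble(
    id = c("junk1", "junk2"),
    seq = c(strrep("ACGT", 12), strrep("GA", 24)),
    qual = c(qchar(37, 48), qchar(37, 48))
  )
  lowq <- tibble::tibble(
    id = "lowq", seq = spec$reference,
    qual = qchar(10, nchar(spec$reference))
  )
  res <- quantify_amplicon(dplyr::bind_rows(reads, junk, lowq), spec)
  cts <- res$counts
  expect_equal(cts$total, 403L)
  expect_equal(
    cts$total,
    cts$qc_failed + cts$flank_unmatched + cts$indel + cts$indel_free
  )
  expect_gte(cts$qc_failed, 1L)
  expect_gte(cts$flank_unmatched, 2L)
})

test_that("simulated editing rates and indel fraction are recovered", {
  spec <- make_amplicon(window_c = c(4, 6))
  rates <- c(`4` = 0.15, `6` = 0.55)
  r_indel <- 0.08
  sim <- sim_amplicon_reads(spec, n = 4000, edit_rates = rates,
                            indel_rate = r_indel, seed = 31)
  res <- quantify_amplicon(sim$reads, spec)
  expect_lt(abs(res$indel_fraction - r_indel), 0.02)
  n_free <- res$counts$indel_free
  for (p in c(4, 6)) {
    e <- rates[as.character(p)]
    est <- res$base_table$T[p] / res$base_table$n_covered[p]
    expect_lt(abs(est - e), 1.96 * sqrt(e * (1 - e) / n_free) + 0.005)
    eff <- substitution_efficiency(res$base_table, res$indel_fraction)
    expect_equal(
      eff$efficiency[p],
      res$base_table$T[p] / res$base_table$n_covered[p] *
        (1 - res$indel_fraction)
    )
  }
})

test_that("an amplicon and its reverse complement quantify identically", {
  spec <- make_amplicon(window_c = c(4, 6))
  sim <- sim_amplicon_reads(spec, n = 300, edit_rates = c(`4` = 0.2, `6` = 0.4),
                            indel_rate = 0.05, seed = 9)
  spec_rc <- amplicon_spec(
    "amp1",
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(spec$reference)
    )),
    10L, target_strand = "-"
  )
  expect_equal(spec_rc$reference, spec$reference)
  reads_rc <- sim$reads |>
    dplyr::mutate(seq = vapply(seq, function(s) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }, character(1)), qual = vapply(qual, function(q) {
      paste(rev(strsplit(q, "")[[1]]), collapse = "")
    }, character(1)))
  a <- quantify_amplicon(sim$reads, spec)
  b <- quantify_amplicon(reads_rc, spec_rc)
  expect_equal(a$base_table, b$base_table)
  expect_equal(a$indel_fraction, b$indel_fraction)
  expect_equal(a$haplotypes, b$haplotypes)
})
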