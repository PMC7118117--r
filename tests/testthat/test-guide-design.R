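test_that("scan_candidates finds N20-PAM sites with the right PAM classes", {
  g <- c(c1 = "TTTCAAAAAAAAAAAAAAAAAGG")
  cand <- scan_candidates(g)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$spacer, "TTTCAAAAAAAAAAAAAAAA")
  expect_equal(cand$pam, "AGG")
  expect_equal(cand$pam_class, "NGG")
  expect_equal(cand$strand, "+")
  expect_equal(cand$start, 0L)
  expect_equal(cand$end, 20L)
  expect_equal(cand$window_c_pos[[1]], 4L)

  # NAG-only scan finds nothing on the plus strand of this sequence
  expect_equal(nrow(scan_candidates(g, pam_classes = "NAG")), 0L)

  # shorter than 23 nt: empty result, not an error
  expect_equal(nrow(scan_candidates(c(c1 = "ACGTACGT"))), 0L)
})

test_that("scanning a sequence and its reverse complement is symmetric", {
  withr::with_seed(21, s <- rand_dna(300))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a <- scan_candidates(c(c1 = s), pam_classes = c("NGG", "NAG"))
  b <- scan_candidates(c(c1 = rc), pam_classes = c("NGG", "NAG"))
  expect_equal(nrow(a), nrow(b))
  # candidates map onto each other with strands swapped and coordinates mirrored
  L <- nchar(s)
  key <- function(d, flip) {
    strand <- if (flip) ifelse(d$strand == "+", "-", "+") else d$strand
    start <- if (flip) L - d$end else d$start
    sort(paste(d$spacer, d$pam, strand, start))
  }
  expect_equal(key(a, FALSE), key(b, TRUE))
})

test_that("filter_editable applies the window-C and CDS rules", {
  # C at protospacer position 4, whole contig is CDS -> retained
  g1 <- c(c1 = "AAACCAAAAAAAAAAAAAAAAGGA")
  genome1 <- tibble::tibble(contig = "c1", sequence = g1[[1]],
                            length = nchar(g1[[1]]))
  gtf1 <- tibble::tibble(contig = "c1", start = 1L, end = 24L, strand = "+",
                         frame = 0L, gene_id = "g", tx_id = "t")
  models1 <- load_gene_models(write_temp_gtf(gtf1), genome1)
  cand1 <- scan_candidates(genome1)
  kept <- filter_editable(cand1, models1)
  expect_true(any(kept$start == 0L))
  k <- kept[kept$start == 0L, ]
  expect_equal(k$editable_sites[[1]]$proto_pos, c(4L, 5L))

  # Cs only outside the window -> removed
  g2 <- c(c1 = "CCCAAAAACCCCCCCCCCCCAGGA")
  genome2 <- tibble::tibble(contig = "c1", sequence = g2[[1]],
                            length = nchar(g2[[1]]))
  models2 <- load_gene_models(write_temp_gtf(gtf1), genome2)
  cand2 <- scan_candidates(genome2)
  expect_true(any(cand2$start == 0L))
  kept2 <- filter_editable(cand2, models2)
  expect_false(any(kept2$start == 0L))
})

test_that("a window C that is intronic for all isoforms removes the candidate", {
  # protospacer at 0-based 6..26; window positions (genomic 9..13) fall in the
  # intron between CDS 1..9 and CDS 16..24 (1-based)
  base <- strsplit(strrep("A", 30), "")[[1]]
  base[12] <- "C" # genomic 0-based 11 -> protospacer position 6 (window)
  base[28:29] <- c("G", "G") # PAM at 0-based 27-28 preceded by any base
  seqs <- paste(base, collapse = "")
  genome <- tibble::tibble(contig = "c1", sequence = seqs, length = 30L)
  gtf <- tibble::tibble(
    contig = "c1", start = c(1L, 16L), end = c(9L, 24L), strand = "+",
    frame = 0L, gene_id = "g", tx_id = "t"
  )
  models <- load_gene_models(write_temp_gtf(gtf), genome)
  cand <- scan_candidates(genome)
  target <- cand[cand$start == 6L & cand$strand == "+", ]
  expect_equal(nrow(target), 1L)
  expect_equal(target$window_c_pos[[1]], 6L)
  kept <- filter_editable(target, models)
  expect_equal(nrow(kept), 0L)
})

test_that("enumerate_outcomes produces the planted E->K change via the opposite strand", {
  sim <- sim_mini_genome(seed = 7)
  genome <- sim$genome
  models <- load_gene_models(write_temp_gtf(sim$gtf), genome)
  cand <- filter_editable(scan_candidates(genome), models)
  planted <- cand[cand$spacer == sim$truth$spacer, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$strand, "-")
  out <- enumerate_outcomes(planted, models)
  expect_setequal(out$edit, c("4", "6", "4+6"))
  expect_equal(out$notation[out$edit == "6"], "E203K")
  expect_equal(out$class[out$edit == "6"], "missense")
  # editing both Gs of the codon still yields lysine (GAG -> AAA)
  expect_equal(out$notation[out$edit == "4+6"], "E203K")
  expect_equal(out$changes[[which(out$edit == "4+6")]]$alt_codon, "AAA")
  expect_equal(out$notation[out$edit == "4"], "E203E")
  expect_equal(out$class[out$edit == "4"], "silent")
})

test_that("a guide with k editable window Cs has exactly 2^k - 1 outcomes", {
  sim <- sim_mini_genome(n_genes = 2, codons_per_gene = 60, plant_ek = FALSE,
                         seed = 13)
  models <- load_gene_models(write_temp_gtf(sim$gtf), sim$genome)
  cand <- filter_editable(scan_candidates(sim$genome), models)
  out <- enumerate_outcomes(cand, models)
  per <- dplyr::count(out, guide_id, tx_id)
  for (i in seq_len(nrow(cand))) {
    es <- cand$editable_sites[[i]]
    for (tx in unique(es$tx_id)) {
      k <- sum(es$tx_id == tx)
      n_out <- per$n[per$guide_id == cand$guide_id[i] & per$tx_id == tx]
      expect_equal(n_out, 2^k - 1)
    }
  }
})

test_that("a window C on the first base of CAA creates a nonsense outcome", {
  cds <- paste0("ATG", "CAA", "TTT", "AAA", "AAA", "AAA", "AAA", "GGA",
                "AAA", "AAA")
  genome <- tibble::tibble(contig = "c1", sequence = cds, length = nchar(cds))
  gtf <- tibble::tibble(contig = "c1", start = 1L, end = 30L, strand = "+",
                        frame = 0L, gene_id = "g", tx_id = "t")
  models <- load_gene_models(write_temp_gtf(gtf), genome)
  cand <- filter_editable(scan_candidates(genome), models)
  first <- cand[cand$start == 0L & cand$strand == "+", ]
  expect_equal(first$window_c_pos[[1]], 4L)
  out <- enumerate_outcomes(first, models)
  expect_equal(out$notation, "Q2*")
  expect_equal(out$class, "nonsense")
  expect_equal(out$changes[[1]]$alt_codon, "TAA")
})

test_that("classify_outcome follows the standard genetic code", {
  expect_equal(classify_outcome("GAG", "AAG"), "missense") # E -> K
  expect_equal(classify_outcome("CTG", "CTA"), "silent") # Leu -> Leu
  expect_equal(classify_outcome("TGG", "TGA"), "nonsense") # Trp -> stop
  expect_equal(classify_outcome("CAN", "TAN"), "unknown")
  expect_equal(
    classify_outcome(c("GAG", "CTG"), c("AAG", "CTA")),
    c("missense", "silent")
  )
})

test_that("enumerate_outcomes matches the mutate-and-retranslate oracle", {
  for (seed in 1:6) {
    sim <- sim_mini_genome(
      n_genes = 2, codons_per_gene = 25, plant_ek = FALSE,
      two_exon = FALSE, pad = 30, seed = seed
    )
    models <- load_gene_models(write_temp_gtf(sim$gtf), sim$genome)
    cand <- filter_editable(scan_candidates(sim$genome), models)
    out <- enumerate_outcomes(cand, models)
    for (i in seq_len(nrow(cand))) {
      ctg <- cand$contig[i]
      seqs <- sim$genome$sequence[sim$genome$contig == ctg]
      gtf_rows <- sim$gtf[sim$gtf$contig == ctg, ]
      es <- cand$editable_sites[[i]]
      orc <- oracle_outcomes(
        seqs, gtf_rows, cand$start[i], cand$end[i], cand$strand[i],
        es$proto_pos
      )
      mine <- out[out$guide_id == cand$guide_id[i], ]
      expect_equal(nrow(mine), length(orc))
      for (o in orc) {
        row <- mine[mine$edit == o$edit, ]
        expect_equal(nrow(row), 1L)
        ch <- row$changes[[1]]
        expect_equal(ch$residue, o$changes$residue)
        expect_equal(ch$ref_aa, o$changes$ref_aa)
        expect_equal(ch$alt_aa, o$changes$alt_aa)
        expect_equal(ch$class, o$changes$class)
      }
    }
  }
})

test_that("designing on the strand-flipped genome yields identical notations", {
  sim <- sim_mini_genome(n_genes = 2, codons_per_gene = 30, plant_ek = FALSE,
                         two_exon = FALSE, pad = 25, seed = 17)
  models <- load_gene_models(write_temp_gtf(sim$gtf), sim$genome)
  cand <- filter_editable(scan_candidates(sim$genome), models)
  out <- enumerate_outcomes(cand, models)

  flip <- sim$genome |>
    dplyr::mutate(sequence = vapply(sequence, function(s) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }, character(1)))
  gtf_f <- sim$gtf |>
    dplyr::left_join(dplyr::select(sim$genome, "contig", "length"),
                     by = "contig") |>
    dplyr::mutate(
      s2 = length - end + 1L,
      e2 = length - start + 1L,
      strand = ifelse(strand == "+", "-", "+"),
      start = s2, end = e2
    ) |>
    dplyr::select("contig", "start", "end", "strand", "frame", "gene_id",
                  "tx_id")
  models_f <- load_gene_models(write_temp_gtf(gtf_f), flip)
  cand_f <- filter_editable(scan_candidates(flip), models_f)
  out_f <- enumerate_outcomes(cand_f, models_f)

  key <- function(cand, out) {
    d <- dplyr::left_join(out,
      dplyr::select(cand, "guide_id", "spacer"), by = "guide_id")
    sort(paste(d$spacer, d$tx_id, d$edit, d$class, d$notation))
  }
  expect_equal(key(cand, out), key(cand_f, out_f))
})

test_that("target-overlap grouping is the transitive closure of same-strand overlap", {
  cand <- tibble::tibble(
    contig = "c1",
    start = c(0L, 5L, 0L, 100L),
    end = c(20L, 25L, 20L, 120L),
    strand = c("+", "+", "-", "+")
  )
  g <- group_by_target_overlap(cand)
  expect_equal(g$target_group[1], g$target_group[2]) # 5-nt offset overlap
  expect_false(g$target_group[1] == g$target_group[3]) # opposite strands
  expect_false(g$target_group[1] == g$target_group[4]) # disjoint
  # chained overlap merges transitively
  chain <- tibble::tibble(
    contig = "c1", start = c(0L, 15L, 30L), end = c(20L, 35L, 50L),
    strand = "+"
  )
  expect_equal(dplyr::n_distinct(group_by_target_overlap(chain)$target_group), 1L)
})

test_that("export_library flattens candidates deterministically and flags duplicates", {
  sim <- sim_mini_genome(seed = 7)
  models <- load_gene_models(write_temp_gtf(sim$gtf), sim$genome)
  cand <- filter_editable(scan_candidates(sim$genome), models)
  out <- enumerate_outcomes(cand, models)
  lib <- export_library(cand, out)
  expect_equal(nrow(lib), nrow(cand))
  expect_false(any(lib$duplicate_spacer))
  expect_true(all(lib$best_outcome != ""))
  # duplicated spacer rows get flagged
  cand2 <- dplyr::bind_rows(cand[1, ], dplyr::mutate(cand[1, ],
    guide_id = "sgDUP", start = start + 1000L,
    end = end + 1000L))
  out2 <- dplyr::bind_rows(out[out$guide_id == cand$guide_id[1], ],
    dplyr::mutate(out[out$guide_id == cand$guide_id[1], ],
                  guide_id = "sgDUP"))
  lib2 <- export_library(cand2, out2)
  expect_true(all(lib2$duplicate_spacer))
  # empty library: header only
  lib0 <- export_library(cand[0, ], out[0, ])
  expect_equal(nrow(lib0), 0L)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_library(cand[0, ], out[0, ], path)
  expect_equal(length(readLines(path)), 1L)
})
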