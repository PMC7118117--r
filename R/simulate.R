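#' Simulators with known ground truth
#'
#' Every generator is deterministic under a fixed seed and returns a
#' machine-readable truth object so downstream estimators can be tested as
#' truth recovery.
#'
#' @name simulators
NULL

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

random_cds <- function(n_codons) {
  paste(c("ATG", sample(SENSE_CODONS, n_codons - 1L, replace = TRUE)),
        collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Plant a minus-strand guide that converts a GAG codon to AAG (E -> K)
#'
#' Overwrites a small deterministic cassette inside a plus-strand CDS so
#' that a guide on the opposite strand carries the codon's G-paired C at
#' protospacer position 6 (and the wobble G at position 4), with a TGG
#' (NGG-class) PAM. Editing position 6 alone, or 4 and 6 together, yields
#' the E->K missense change (the c.607G>A / c.607G>A+c.609G>A patterns);
#' position 4 alone is silent.
#' @noRd
plant_ek_cassette <- function(cds_chars, residue) {
  r <- residue
  stopifnot(r >= 7, 3 * (r + 1) <= length(cds_chars))
  set_codon <- function(x, res, codon) {
    x[(3 * res - 2):(3 * res)] <- strsplit(codon, "")[[1]]
    x
  }
  cds_chars <- set_codon(cds_chars, r, "GAG")
  cds_chars <- set_codon(cds_chars, r - 6L, "ACC") # supplies CC of the PAM source
  cds_chars <- set_codon(cds_chars, r - 5L, "ATT") # supplies the A
  cds_chars <- set_codon(cds_chars, r - 1L, "TTT") # keeps window positions 7-8 C-free
  cds_chars
}

#' Simulate a mini-genome with annotation and planted targets
#'
#' Generates one contig per gene (random CDS of sense codons flanked by
#' `pad` nt of random sequence), mixing plus- and minus-strand genes and an
#' optional two-exon gene whose junction splits a codon. Gene 1 carries a
#' planted E->K target: a GAG codon editable through an opposite-strand
#' window C, mirroring a vemurafenib-resistance codon-203 design.
#'
#' @param n_genes number of genes (>= 1).
#' @param codons_per_gene codons per CDS; must exceed `plant_residue` + 1
#'   when planting.
#' @param plant_ek plant the E->K cassette in gene 1.
#' @param plant_residue residue index of the planted GAG (default 203).
#' @param two_exon give gene 3 (when present) a two-exon structure.
#' @param pad flanking non-coding padding per contig.
#' @param seed integer seed.
#' @param dir optional directory; when given, writes `genome.fa`,
#'   `annotation.gtf` and `truth.tsv` there.
#' @return A list: `genome` (tibble as from [load_genome()]), `gtf` (tibble
#'   of CDS features, 1-based inclusive), `truth` (tibble describing planted
#'   guides), and `paths` when `dir` was given.
#' @export
sim_mini_genome <- function(n_genes = 3, codons_per_gene = 210,
                            plant_ek = TRUE, plant_residue = 203,
                            two_exon = TRUE, pad = 50, seed = 1,
                            dir = NULL) {
  stopifnot(n_genes >= 0)
  if (plant_ek && codons_per_gene < plant_residue + 1) {
    abort("codons_per_gene too small for the planted residue")
  }
  withr::with_seed(seed, {
    genomes <- list()
    gtf <- list()
    truth <- list()
    for (g in seq_len(n_genes)) {
      gene_id <- sprintf("gene%02d", g)
      tx_id <- sprintf("tx%02d", g)
      contig <- sprintf("ctg%02d", g)
      cds_chars <- strsplit(random_cds(codons_per_gene), "")[[1]]
      strand <- if (g %% 2L == 0L) "-" else "+"
      split_exon <- two_exon && g == 3L
      if (g == 1L && plant_ek) {
        strand <- "+"
        split_exon <- FALSE
        cds_chars <- plant_ek_cassette(cds_chars, plant_residue)
      }
      cds <- paste(cds_chars, collapse = "")
      L <- length(cds_chars)
      if (strand == "-") cds_genomic <- revcomp(cds) else cds_genomic <- cds
      if (split_exon) {
        k <- 3L * (codons_per_gene %/% 2L) + 1L # splits a codon 1|2
        intron <- random_dna(20L)
        seq <- paste0(
          random_dna(pad), substr(cds_genomic, 1L, k), intron,
          substr(cds_genomic, k + 1L, L), random_dna(pad)
        )
        gtf[[length(gtf) + 1L]] <- tibble(
          contig = contig,
          start = c(pad + 1L, pad + k + 20L + 1L),
          end = c(pad + k, pad + L + 20L),
          strand = strand,
          frame = c(0L, (3L - (k %% 3L)) %% 3L),
          gene_id = gene_id, tx_id = tx_id
        )
      } else {
        seq <- paste0(random_dna(pad), cds_genomic, random_dna(pad))
        gtf[[length(gtf) + 1L]] <- tibble(
          contig = contig, start = pad + 1L, end = pad + L,
          strand = strand, frame = 0L, gene_id = gene_id, tx_id = tx_id
        )
      }
      genomes[[length(genomes) + 1L]] <- tibble(
        contig = contig, sequence = seq, length = nchar(seq)
      )
      if (g == 1L && plant_ek) {
        r <- plant_residue
        s0 <- pad + 3L * r - 17L # 0-based genomic protospacer start
        spacer <- revcomp(substr(seq, s0 + 1L, s0 + 20L))
        truth[[length(truth) + 1L]] <- tibble(
          contig = contig, gene_id = gene_id, tx_id = tx_id,
          spacer = spacer, strand = "-",
          start = s0, end = s0 + 20L,
          window_c = "4,6",
          residue = r, ref_aa = "E", alt_aa = "K",
          notation = sprintf("E%dK", r)
        )
      }
    }
    out <- list(
      genome = bind_rows(genomes),
      gtf = bind_rows(gtf),
      truth = bind_rows(truth)
    )
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      fa <- file.path(dir, "genome.fa")
      writeLines(
        unlist(Map(function(c, s) c(paste0(">", c), s),
                   out$genome$contig, out$genome$sequence)),
        fa
      )
      gtf_path <- file.path(dir, "annotation.gtf")
      write_gtf(out$gtf, gtf_path)
      truth_path <- file.path(dir, "truth.tsv")
      readr::write_tsv(out$truth, truth_path)
      out$paths <- c(genome = fa, gtf = gtf_path, truth = truth_path)
    }
    out
  })
}

#' Write CDS features as GTF (1-based inclusive)
#'
#' @param gtf tibble with `contig`, `start`, `end`, `strand`, `frame`,
#'   `gene_id`, `tx_id` (start/end already 1-based inclusive).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gtf, path) {
  lines <- sprintf(
    "%s\tbescreen_sim\tCDS\t%d\t%d\t.\t%s\t%d\tgene_id \"%s\"; transcript_id \"%s\";",
    gtf$contig, gtf$start, gtf$end, gtf$strand, gtf$frame,
    gtf$gene_id, gtf$tx_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Simulate edited amplicon reads
#'
#' Each read is the amplicon's 10-nt flanks around a protospacer+PAM
#' segment. With probability `indel_rate` the segment carries an indel
#' (insertion or deletion allele, defaults mirroring an 18-nt in-frame
#' insertion and a 3-nt deletion); otherwise the window cytosines are
#' edited C->T with per-position rates `edit_rates`. Processivity `p` mixes
#' two regimes per read: with probability `p` a single uniform draw drives
#' all window positions jointly (comonotone coupling, preserving the
#' marginal rates; all-or-none when the rates are equal), with probability
#' `1 - p` positions are edited independently. Base qualities are Q37,
#' downgraded to Q14 independently with probability `lowq_frac` (below the
#' Q30 masking threshold).
#'
#' @param spec an [amplicon_spec()].
#' @param n number of reads.
#' @param edit_rates named numeric vector of per-position editing rates
#'   (names = protospacer positions); defaults to 0.2 at every reference
#'   window C.
#' @param processivity mixing coefficient in \[0, 1\].
#' @param indel_rate probability a read carries an indel.
#' @param indel_alleles tibble with `type` (`"ins"`/`"del"`), `seq`
#'   (inserted sequence for ins), `len` (deleted length for del), `at`
#'   (1-based segment position after/from which the event applies),
#'   `weight`.
#' @param lowq_frac fraction of bases dropped below Q30.
#' @param seed integer seed.
#' @param path optional FASTQ output path.
#' @return A list: `reads` (tibble `id`, `seq`, `qual`), `truth` (list of
#'   the simulation parameters), and `path` when written.
#' @export
sim_amplicon_reads <- function(spec, n, edit_rates = NULL, processivity = 0,
                               indel_rate = 0, indel_alleles = NULL,
                               lowq_frac = 0, seed = 1, path = NULL) {
  stopifnot(processivity >= 0, processivity <= 1,
            indel_rate >= 0, indel_rate <= 1)
  if (is.null(edit_rates)) {
    edit_rates <- setNames(rep(0.2, length(spec$window_c)), spec$window_c)
  }
  pos <- as.integer(names(edit_rates))
  if (any(is.na(pos))) abort("edit_rates must be named by protospacer position")
  seg_ref <- strsplit(spec$segment, "")[[1]]
  if (any(seg_ref[pos] != "C")) {
    abort("edit_rates positions must be reference cytosines (target strand)")
  }
  if (is.null(indel_alleles)) {
    indel_alleles <- tibble(
      type = c("ins", "del"),
      seq = c("CTGTTGGATATTCTCGAC", NA),
      len = c(NA_integer_, 3L),
      at = c(10L, 5L),
      weight = c(0.5, 0.5)
    )
  }
  withr::with_seed(seed, {
    is_indel <- runif(n) < indel_rate
    # per-read editing draws: processive reads share one uniform across positions
    proc <- runif(n) < processivity
    segs <- character(n)
    for (i in seq_len(n)) {
      if (is_indel[i]) {
        a <- indel_alleles[sample.int(nrow(indel_alleles), 1,
                                      prob = indel_alleles$weight), ]
        s <- spec$segment
        if (a$type == "ins") {
          segs[i] <- paste0(substr(s, 1, a$at), a$seq,
                            substr(s, a$at + 1L, nchar(s)))
        } else {
          segs[i] <- paste0(substr(s, 1, a$at - 1L),
                            substr(s, a$at + a$len, nchar(s)))
        }
      } else {
        u <- if (proc[i]) rep(runif(1), length(pos)) else runif(length(pos))
        b <- seg_ref
        b[pos[u < edit_rates]] <- "T"
        segs[i] <- paste(b, collapse = "")
      }
    }
    seqs <- paste0(spec$flank5, segs, spec$flank3)
    quals <- vapply(nchar(seqs), function(L) {
      q <- ifelse(runif(L) < lowq_frac, 14L, 37L)
      intToUtf8(q + 33L)
    }, character(1))
    reads <- tibble(
      id = sprintf("read%06d", seq_len(n)),
      seq = seqs, qual = quals
    )
    out <- list(
      reads = reads,
      truth = list(
        edit_rates = edit_rates, processivity = processivity,
        indel_rate = indel_rate, lowq_frac = lowq_frac, n = n,
        is_indel = is_indel
      )
    )
    if (!is.null(path)) {
      writeLines(
        as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)),
        path
      )
      out$path <- path
    }
    out
  })
}

#' Simulate a pooled selection screen
#'
#' Guide abundances start from a common (Dirichlet-like) initial frequency
#' vector and evolve multiplicatively: under treatment, guide g's relative
#' abundance at time t is proportional to `p0[g] * exp(coef[g] * t)`; the
#' control arm is neutral (all coefficients zero). Read counts per sample
#' are multinomial at the given depth.
#'
#' @param library tibble with `guide_id` (order defines the guide universe).
#' @param coefficients named numeric selection coefficients per day
#'   (missing guides default to 0).
#' @param timepoints sampling days (0 = initial).
#' @param depth reads per sample.
#' @param seed integer seed.
#' @param initial_freq optional initial frequencies (default: symmetric
#'   Dirichlet with shape 10).
#' @return A list: `counts` (long tibble `sample`, `condition`, `timepoint`,
#'   `guide_id`, `count`), `truth` (list with `coefficients`, `p0`, expected
#'   terminal treatment shares).
#' @export
sim_screen <- function(library, coefficients = NULL,
                       timepoints = c(0, 7, 14, 21, 28), depth = 1e5,
                       seed = 1, initial_freq = NULL) {
  gids <- library$guide_id
  coef <- setNames(rep(0, length(gids)), gids)
  if (!is.null(coefficients)) {
    unknown <- setdiff(names(coefficients), gids)
    if (length(unknown)) abort(sprintf("unknown guide in coefficients: %s", unknown[1]))
    coef[names(coefficients)] <- coefficients
  }
  withr::with_seed(seed, {
    p0 <- if (is.null(initial_freq)) {
      x <- stats::rgamma(length(gids), shape = 10)
      x / sum(x)
    } else {
      initial_freq / sum(initial_freq)
    }
    draw <- function(p, cond, t) {
      tibble(
        sample = sprintf("%s_D%02d", cond, t),
        condition = cond, timepoint = t, guide_id = gids,
        count = as.integer(rmultinom(1, size = depth, prob = p))
      )
    }
    counts <- bind_rows(lapply(timepoints, function(t) {
      w <- p0 * exp(coef * t)
      bind_rows(
        draw(p0, "control", t),
        draw(w / sum(w), "treatment", t)
      )
    }))
    t_end <- max(timepoints)
    w_end <- p0 * exp(coef * t_end)
    list(
      counts = counts,
      truth = list(
        coefficients = coef, p0 = p0,
        terminal_share = w_end / sum(w_end)
      )
    )
  })
}

#' Simulate single-cell guide capture records
#'
#' Per cell, true integrations K ~ Poisson(lambda) conditioned on K >= 1
#' (selection removes uninfected cells); guides are drawn uniformly with
#' replacement; each integration is detected independently with probability
#' `detection_rate`; each detected integration emits `1 + Poisson(umi_mean
#' - 1)` distinct UMIs.
#'
#' @param lambda MOI (mean integrations before selection), > 0.
#' @param detection_rate probability in (0, 1\].
#' @param n_cells number of (selected) cells.
#' @param n_guides guide library size.
#' @param umi_mean mean UMIs per detected integration (>= 1).
#' @param seed integer seed.
#' @return A list: `records` (tibble `cell_barcode`, `umi`, `guide`),
#'   `cells` (character vector: the cell universe), `truth` (tibble per
#'   cell: `cell_barcode`, `k_true`, `n_detected`).
#' @export
sim_cell_guides <- function(lambda, detection_rate, n_cells,
                            n_guides = 420, umi_mean = 3, seed = 1) {
  stopifnot(lambda > 0, detection_rate > 0, detection_rate <= 1, umi_mean >= 1)
  withr::with_seed(seed, {
    # zero-truncated Poisson by inverse transform
    u <- runif(n_cells, min = exp(-lambda), max = 1)
    k <- stats::qpois(u, lambda)
    cells <- sprintf("cell%06d", seq_len(n_cells))
    recs <- list()
    n_detected <- integer(n_cells)
    umi_counter <- 0L
    for (i in seq_len(n_cells)) {
      guides <- sample.int(n_guides, k[i], replace = TRUE)
      det <- guides[runif(k[i]) < detection_rate]
      n_detected[i] <- length(unique(det))
      if (length(det)) {
        umis_per <- 1L + rpois(length(det), umi_mean - 1)
        total <- sum(umis_per)
        recs[[length(recs) + 1L]] <- tibble(
          cell_barcode = cells[i],
          umi = sprintf("umi%08d", umi_counter + seq_len(total)),
          guide = sprintf("guide%03d", rep(det, umis_per))
        )
        umi_counter <- umi_counter + total
      }
    }
    list(
      records = bind_rows(recs),
      cells = cells,
      truth = tibble(cell_barcode = cells, k_true = k, n_detected = n_detected)
    )
  })
}
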