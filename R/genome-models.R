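#' Read a reference sequence from FASTA
#'
#' Sequences are uppercased and restricted to the alphabet {A,C,G,T,N}.
#' IUPAC ambiguity codes other than N are either rejected (`ambiguity =
#' "strict"`) or converted to N (`ambiguity = "to_n"`).
#'
#' @param path path to a (multi-record) FASTA file.
#' @param ambiguity `"strict"` to error on ambiguity codes other than N,
#'   `"to_n"` to convert them to N.
#' @return A tibble with one row per record: `contig`, `sequence`, `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' load_genome(fa)
#' @export
load_genome <- function(path, ambiguity = c("strict", "to_n")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (!length(seqs)) abort(sprintf("FASTA '%s' contains no records", path))
  x <- toupper(as.character(seqs))
  names(x) <- sub("\\s.*$", "", names(seqs))
  if (ambiguity == "to_n") {
    x <- gsub("[^ACGT]", "N", x)
  } else {
    assert_dna(x, what = sprintf("FASTA '%s'", path), allow_n = TRUE)
  }
  if (any(nchar(x) == 0)) abort("FASTA record with empty sequence")
  tibble(contig = names(x), sequence = unname(x), length = nchar(unname(x)))
}

genome_as_vector <- function(genome) {
  if (is.data.frame(genome)) {
    setNames(genome$sequence, genome$contig)
  } else if (is.character(genome)) {
    if (is.null(names(genome))) abort("genome character vector must be named by contig")
    genome
  } else {
    abort("genome must be a load_genome() tibble or a named character vector")
  }
}

#' Construct a gene model from ordered CDS intervals
#'
#' Internal coordinates are 0-based half-open; the spliced CDS is reported on
#' the coding strand with the first exon's frame already trimmed, alongside
#' the genomic position of every coding base in translation order.
#'
#' @param gene_id,tx_id identifiers.
#' @param contig contig name; must exist in `genome`.
#' @param strand `"+"` or `"-"` (coding strand).
#' @param intervals tibble/data.frame with 0-based half-open `start`, `end`
#'   and `frame` (0/1/2) per CDS interval, in genomic order.
#' @param genome genome tibble or named character vector.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, tx_id, contig, strand, intervals, genome) {
  seqs <- genome_as_vector(genome)
  if (!contig %in% names(seqs)) abort(sprintf("contig '%s' not in genome", contig))
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  iv <- as_tibble(intervals)
  if (!all(c("start", "end", "frame") %in% names(iv))) {
    abort("intervals must have columns start, end, frame")
  }
  if (any(is.na(iv$frame)) || !all(iv$frame %in% 0:2)) {
    abort(sprintf("gene %s/%s: CDS frame missing or not in {0,1,2}", gene_id, tx_id))
  }
  iv <- arrange(iv, .data$start)
  if (any(iv$start < 0) || any(iv$end > nchar(seqs[[contig]]))) {
    abort(sprintf("gene %s/%s: CDS interval outside contig bounds", gene_id, tx_id))
  }
  if (any(iv$end <= iv$start)) abort("empty CDS interval")
  if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)])) {
    abort(sprintf("gene %s/%s: overlapping CDS intervals", gene_id, tx_id))
  }
  # genomic positions of coding bases in translation (5'->3' coding) order
  gpos <- unlist(Map(seq, iv$start, iv$end - 1L), use.names = FALSE)
  contig_chars <- strsplit(seqs[[contig]], "")[[1]]
  if (strand == "-") {
    gpos <- rev(gpos)
    bases <- complement_base(contig_chars[gpos + 1L])
    iv <- arrange(iv, dplyr::desc(.data$start)) # 5'->3' on coding strand
  } else {
    bases <- contig_chars[gpos + 1L]
  }
  # frame of the 5'-most coding interval: bases to skip before the first codon
  f <- iv$frame[1]
  if (f > 0) {
    gpos <- gpos[-seq_len(f)]
    bases <- bases[-seq_len(f)]
  }
  cds <- paste(bases, collapse = "")
  structure(
    list(
      gene_id = gene_id, tx_id = tx_id, contig = contig, strand = strand,
      intervals = iv, cds = cds, genomic_pos = gpos,
      in_frame = (length(gpos) %% 3L) == 0L
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s / %s  %s:%s  %d CDS interval(s), %d coding nt%s\n",
    x$gene_id, x$tx_id, x$contig, x$strand, nrow(x$intervals),
    nchar(x$cds), if (x$in_frame) "" else "  [not divisible by 3]"
  ))
  invisible(x)
}

#' Load gene models from a GTF annotation
#'
#' Reads features typed `CDS` (other types are ignored) carrying `gene_id`
#' and `transcript_id` attributes, converts 1-based inclusive GTF coordinates
#' to internal 0-based half-open, splices and reverse-complements
#' minus-strand CDS, and flags isoforms whose coding length (after frame
#' trimming) is not divisible by 3. Flagged isoforms are kept in the table.
#'
#' @param path path to a GTF file (tab-separated, 1-based inclusive, frame in
#'   column 8).
#' @param genome genome tibble from [load_genome()] or named character vector.
#' @return A tibble with one row per isoform: `gene_id`, `tx_id`, `contig`,
#'   `strand`, `n_intervals`, `cds_length`, `in_frame`, and a list-column
#'   `model` of [gene_model()] objects.
#' @export
load_gene_models <- function(path, genome) {
  if (!file.exists(path)) abort(sprintf("GTF file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- as.character(md$type) == "CDS"
  if (!any(keep)) abort(sprintf("GTF '%s' has no CDS features", path))
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id)) {
    abort("GTF CDS features must carry gene_id and transcript_id attributes")
  }
  if (is.null(md$phase) || any(is.na(md$phase))) {
    abort("GTF CDS features with missing frame")
  }
  cds <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    frame = as.integer(md$phase),
    gene_id = as.character(md$gene_id),
    tx_id = as.character(md$transcript_id)
  )
  if (any(!cds$strand %in% c("+", "-"))) abort("CDS feature without strand")
  models <- cds |>
    group_by(.data$gene_id, .data$tx_id, .data$contig, .data$strand) |>
    tidyr::nest(.key = "iv") |>
    ungroup() |>
    mutate(model = pmap(
      list(.data$gene_id, .data$tx_id, .data$contig, .data$strand, .data$iv),
      function(g, t, c, s, iv) gene_model(g, t, c, s, iv, genome)
    )) |>
    select(-"iv")
  models |>
    mutate(
      n_intervals = map_int(.data$model, ~ nrow(.x$intervals)),
      cds_length = map_int(.data$model, ~ nchar(.x$cds)),
      in_frame = map_lgl(.data$model, "in_frame")
    ) |>
    arrange(.data$gene_id, .data$tx_id)
}

models_as_list <- function(models) {
  if (is.data.frame(models)) {
    setNames(models$model, models$tx_id)
  } else if (inherits(models, "gene_model")) {
    setNames(list(models), models$tx_id)
  } else if (is.list(models)) {
    stopifnot(all(map_lgl(models, inherits, "gene_model")))
    setNames(models, map_chr(models, "tx_id"))
  } else {
    abort("expected a load_gene_models() tibble, a gene_model, or a list of them")
  }
}

#' Codon context at a genomic position
#'
#' Returns the codon containing `position` (internal 0-based coordinates),
#' its 1-based residue index from the start codon, and the genomic positions
#' of all three codon bases (which may span an exon junction). Positions
#' outside the CDS return `NULL`.
#'
#' @param model a [gene_model()].
#' @param position 0-based genomic position.
#' @return A list with `tx_id`, `residue`, `codon`, `aa`, `strand`,
#'   `genomic_pos` (length 3), or `NULL` if the position is not coding.
#' @export
codon_at <- function(model, position) {
  stopifnot(inherits(model, "gene_model"))
  i <- match(position, model$genomic_pos)
  if (is.na(i)) return(NULL)
  res <- (i - 1L) %/% 3L + 1L
  if (3L * res > length(model$genomic_pos)) return(NULL) # trailing partial codon
  idx <- (3L * res - 2L):(3L * res)
  codon <- substr(model$cds, idx[1], idx[3])
  list(
    tx_id = model$tx_id, residue = res, codon = codon,
    aa = translate_codon(codon), strand = model$strand,
    genomic_pos = model$genomic_pos[idx]
  )
}

#' Export gene models as a tidy TSV-ready table
#'
#' One row per isoform with the joined interval list in 1-based inclusive
#' `start-end:frame` notation (the GTF convention), so a re-import of the
#' coordinates reproduces the annotation.
#'
#' @param models tibble from [load_gene_models()].
#' @param path optional path; when given the table is written as TSV.
#' @return The export tibble, invisibly when `path` is given.
#' @export
export_gene_models <- function(models, path = NULL) {
  out <- models |>
    mutate(intervals = map_chr(.data$model, function(m) {
      iv <- arrange(m$intervals, .data$start)
      paste(sprintf("%d-%d:%d", iv$start + 1L, iv$end, iv$frame), collapse = ",")
    })) |>
    select("gene_id", "tx_id", "contig", "strand", "intervals", "cds_length", "in_frame")
  if (!is.null(path)) {
    readr::write_tsv(out, path)
    return(invisible(out))
  }
  out
}
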