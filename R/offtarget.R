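#' Enumerate off-target sites of a spacer
#'
#' Scans a search space (typically coding sequence) on both strands for
#' 20-mers within `max_mm` mismatches of the spacer followed by an allowed
#' PAM. Indels/bulges are not considered. The perfect-match site of the
#' guide itself is excluded from the hit list (it contributes the 1 in the
#' specificity-score denominator): by default the first 0-mismatch site in
#' deterministic (contig, strand, start) order is treated as self; pass
#' `self_site = NULL` explicitly via `exclude_self = FALSE` to keep all.
#'
#' @param spacer 20-mer over {A,C,G,T}.
#' @param search_space tibble from [load_genome()] or named character vector.
#' @param max_mm maximum mismatches over the 20-mer (PAM not counted).
#' @param pam_classes allowed PAM classes for candidate sites.
#' @param exclude_self drop one perfect-match site as the guide's own locus.
#' @return A tibble with one row per hit: `contig`, `start`, `end`, `strand`,
#'   `protospacer`, `pam`, `pam_class`, `n_mm`, and list-column `mismatches`
#'   (tibble of `position`, `spacer_base`, `offtarget_base`).
#' @export
find_offtargets <- function(spacer, search_space, max_mm = 3,
                            pam_classes = c("NGG", "NAG"),
                            exclude_self = TRUE) {
  if (nchar(spacer) != 20L) abort("spacer must be 20 nt")
  if (grepl("N", spacer)) abort("spacer contains N")
  assert_dna(spacer, "spacer", allow_n = FALSE)
  seqs <- genome_as_vector(search_space)
  subj <- Biostrings::DNAStringSet(seqs)
  hit_strand <- function(pattern, strand) {
    m <- Biostrings::vmatchPattern(pattern, subj, max.mismatch = max_mm)
    bind_rows(imap(as.list(m), function(rg, contig) {
      if (!length(rg)) return(NULL)
      s <- seqs[[contig]]
      L <- nchar(s)
      st <- BiocGenerics::start(rg) - 1L # to 0-based
      en <- BiocGenerics::end(rg)
      if (strand == "+") {
        pam_ok <- en + 3L <= L
        st <- st[pam_ok]; en <- en[pam_ok]
        if (!length(st)) return(NULL)
        proto <- substring(s, st + 1L, en)
        pam <- substring(s, en + 1L, en + 3L)
      } else {
        pam_ok <- st >= 3L
        st <- st[pam_ok]; en <- en[pam_ok]
        if (!length(st)) return(NULL)
        proto <- revcomp(substring(s, st + 1L, en))
        pam <- revcomp(substring(s, st - 2L, st))
      }
      tibble(
        contig = contig, start = st, end = en, strand = strand,
        protospacer = proto, pam = pam
      )
    }))
  }
  hits <- bind_rows(
    hit_strand(spacer, "+"),
    hit_strand(revcomp(spacer), "-")
  )
  empty <- tibble(
    contig = character(), start = integer(), end = integer(),
    strand = character(), protospacer = character(), pam = character(),
    pam_class = character(), n_mm = integer(), mismatches = list()
  )
  if (!nrow(hits)) return(empty)
  hits <- hits |>
    mutate(pam_class = pam_class_of(.data$pam)) |>
    filter(.data$pam_class %in% pam_classes, !grepl("N", .data$protospacer))
  if (!nrow(hits)) return(empty)
  sp <- strsplit(spacer, "")[[1]]
  mm <- lapply(strsplit(hits$protospacer, ""), function(ot) {
    p <- which(ot != sp)
    tibble(position = p, spacer_base = sp[p], offtarget_base = ot[p])
  })
  hits <- hits |>
    mutate(mismatches = mm, n_mm = map_int(mm, nrow)) |>
    filter(.data$n_mm <= max_mm) |>
    arrange(.data$contig, .data$strand, .data$start)
  if (exclude_self) {
    self <- which(hits$n_mm == 0L)
    if (length(self)) hits <- hits[-self[1], , drop = FALSE]
  }
  hits
}

#' Remove off-target sites that a base editor cannot act on
#'
#' Mirrors the specificity-score exclusions: off-target protospacers without
#' any C in the activity window (positions 4-8, PAM-distal numbering) are
#' dropped, as are sites whose PAM class is outside {NGG, NAG}.
#'
#' @param hits tibble from [find_offtargets()].
#' @param window activity-window positions.
#' @return Filtered hit tibble.
#' @export
filter_offtargets <- function(hits, window = 4:8) {
  if (!nrow(hits)) return(hits)
  win_c <- map_lgl(strsplit(hits$protospacer, ""), function(b) {
    any(b[window] == "C")
  })
  hits |> filter(win_c, .data$pam_class %in% c("NGG", "NAG"))
}

#' Read a CFD penalty table
#'
#' Two TSV resources define the model: a mismatch table with columns
#' `position` (1-20, PAM-distal numbering), `spacer_base`, `offtarget_base`,
#' `penalty`, and a PAM table with columns `pam_class`, `penalty`. The
#' packaged default (`inst/extdata/cfd_penalties_synthetic.tsv`) is a
#' synthetic stand-in with the qualitative structure of published
#' mismatch-activity data (penalties shrink toward the PAM-proximal end);
#' supply your own tables for calibrated scoring.
#'
#' @param mismatch_path,pam_path TSV paths; `NULL` loads the packaged
#'   synthetic defaults.
#' @return A list with `mismatch` and `pam` tibbles, class `cfd_table`.
#' @export
read_cfd_table <- function(mismatch_path = NULL, pam_path = NULL) {
  if (is.null(mismatch_path)) {
    mismatch_path <- system.file("extdata", "cfd_penalties_synthetic.tsv",
      package = "bescreen", mustWork = TRUE
    )
  }
  if (is.null(pam_path)) {
    pam_path <- system.file("extdata", "cfd_pam_penalties_synthetic.tsv",
      package = "bescreen", mustWork = TRUE
    )
  }
  mm <- readr::read_tsv(mismatch_path, show_col_types = FALSE)
  pam <- readr::read_tsv(pam_path, show_col_types = FALSE)
  stopifnot(
    all(c("position", "spacer_base", "offtarget_base", "penalty") %in% names(mm)),
    all(c("pam_class", "penalty") %in% names(pam))
  )
  structure(list(mismatch = mm, pam = pam), class = "cfd_table")
}

#' CFD score of one off-target hit
#'
#' Product of the per-mismatch penalty factors over the hit's mismatches
#' times the PAM-class factor; a perfect match with canonical PAM scores 1.
#'
#' @param spacer the guide spacer (20-mer).
#' @param hit one row of a [find_offtargets()] tibble (or a list with
#'   `mismatches`, `pam_class`).
#' @param cfd a [read_cfd_table()] object.
#' @return Numeric scalar in \[0, 1\].
#' @export
cfd_score <- function(spacer, hit, cfd = read_cfd_table()) {
  if (is.data.frame(hit)) {
    stopifnot(nrow(hit) == 1L)
    mm <- hit$mismatches[[1]]
    pc <- hit$pam_class
  } else {
    mm <- hit$mismatches
    pc <- hit$pam_class
  }
  pam_pen <- cfd$pam$penalty[match(pc, cfd$pam$pam_class)]
  if (is.na(pam_pen)) {
    abort(sprintf("CFD PAM table has no entry for pam_class '%s'", pc))
  }
  if (is.null(mm) || !nrow(mm)) return(pam_pen)
  key <- paste(mm$position, mm$spacer_base, mm$offtarget_base)
  tkey <- paste(cfd$mismatch$position, cfd$mismatch$spacer_base,
                cfd$mismatch$offtarget_base)
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    miss <- mm[which(is.na(idx))[1], ]
    abort(sprintf(
      "CFD table missing entry: position %d, spacer %s vs off-target %s",
      miss$position, miss$spacer_base, miss$offtarget_base
    ))
  }
  prod(cfd$mismatch$penalty[idx]) * pam_pen
}

#' Aggregate specificity score of a guide
#'
#' `score = 1 / (1 + sum of CFD over off-target hits)`; a guide with no
#' off-targets scores exactly 1, and every added hit strictly decreases the
#' score.
#'
#' @param spacer guide spacer.
#' @param hits filtered hit tibble ([filter_offtargets()]).
#' @param cfd a [read_cfd_table()] object.
#' @return An object of class `specificity_result`: list with `spacer`,
#'   `hits` (with a `cfd` column added), `n_hits`, `sum_cfd`, `score`.
#' @export
specificity_score <- function(spacer, hits, cfd = read_cfd_table()) {
  cfds <- if (nrow(hits)) {
    vapply(seq_len(nrow(hits)), function(i) {
      cfd_score(spacer, hits[i, ], cfd)
    }, numeric(1))
  } else {
    numeric(0)
  }
  hits$cfd <- cfds
  structure(
    list(
      spacer = spacer, hits = hits, n_hits = nrow(hits),
      sum_cfd = sum(cfds), score = 1 / (1 + sum(cfds))
    ),
    class = "specificity_result"
  )
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf(
    "<specificity_result> %s: %d hit(s), sum CFD %.4f, score %.4f\n",
    x$spacer, x$n_hits, x$sum_cfd, x$score
  ))
  invisible(x)
}

#' @rdname specificity_score
#' @param x a `specificity_result`.
#' @param ... unused.
#' @method tidy specificity_result
#' @export
tidy.specificity_result <- function(x, ...) {
  tibble(
    spacer = x$spacer, n_hits = x$n_hits,
    sum_cfd = x$sum_cfd, score = x$score
  )
}

#' Score the specificity of every guide in a library
#'
#' Convenience pipeline over [find_offtargets()], [filter_offtargets()] and
#' [specificity_score()].
#'
#' @param library tibble with `guide_id` and `spacer` columns.
#' @param search_space coding-sequence search space (tibble or named vector).
#' @param cfd a [read_cfd_table()] object.
#' @param max_mm maximum mismatches.
#' @param pam_classes allowed PAM classes for candidate sites.
#' @return A tibble: `guide_id`, `spacer`, `n_hits`, `sum_cfd`, `score`.
#' @export
score_library_specificity <- function(library, search_space,
                                      cfd = read_cfd_table(), max_mm = 3,
                                      pam_classes = c("NGG", "NAG")) {
  library |>
    select("guide_id", "spacer") |>
    mutate(res = map(.data$spacer, function(sp) {
      h <- find_offtargets(sp, search_space, max_mm = max_mm,
                           pam_classes = pam_classes)
      s <- specificity_score(sp, filter_offtargets(h), cfd)
      tibble(n_hits = s$n_hits, sum_cfd = s$sum_cfd, score = s$score)
    })) |>
    tidyr::unnest("res") |>
    select("guide_id", "spacer", "n_hits", "sum_cfd", "score")
}
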