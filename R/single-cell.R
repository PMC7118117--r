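#' Build a per-cell guide UMI-count matrix
#'
#' Collapses duplicate (cell, UMI, guide) triples to one molecule, then
#' counts distinct UMIs per (cell, guide).
#'
#' @param records tibble with columns `cell_barcode`, `umi`, `guide`, or a
#'   path to a TSV with those columns.
#' @return A tibble: `cell_barcode`, `guide`, `umi_count`.
#' @export
build_cell_guide_matrix <- function(records) {
  if (is.character(records) && length(records) == 1L) {
    records <- readr::read_tsv(records, show_col_types = FALSE)
  }
  records <- as_tibble(records)
  need <- c("cell_barcode", "umi", "guide")
  if (!all(need %in% names(records))) {
    abort(sprintf(
      "records must have columns %s", paste(need, collapse = ", ")
    ))
  }
  bad <- which(is.na(records$cell_barcode) | is.na(records$umi) | is.na(records$guide))
  if (length(bad)) {
    abort(sprintf("malformed record at line %d (missing field)", bad[1]))
  }
  records |>
    distinct(.data$cell_barcode, .data$umi, .data$guide) |>
    count(.data$cell_barcode, .data$guide, name = "umi_count") |>
    arrange(.data$cell_barcode, dplyr::desc(.data$umi_count))
}

#' Assign one guide per cell by UMI majority
#'
#' Per cell, the guide with the maximum distinct-UMI count is assigned.
#' Ties leave the cell unassigned and flagged ambiguous by default
#' (`ties = "lexicographic"` breaks ties by guide name for reproducibility
#' studies).
#'
#' @param matrix tibble from [build_cell_guide_matrix()].
#' @param ties `"ambiguous"` (default) or `"lexicographic"`.
#' @return A tibble: `cell_barcode`, `assigned_guide` (NA if ambiguous),
#'   `umi_count`, `n_guides_detected`, `ambiguous`.
#' @export
assign_guides <- function(matrix, ties = c("ambiguous", "lexicographic")) {
  ties <- match.arg(ties)
  matrix |>
    group_by(.data$cell_barcode) |>
    summarise(
      n_guides_detected = dplyr::n(),
      top_count = max(.data$umi_count),
      n_top = sum(.data$umi_count == max(.data$umi_count)),
      top_guide = min(.data$guide[.data$umi_count == max(.data$umi_count)]),
      .groups = "drop"
    ) |>
    mutate(
      ambiguous = .data$n_top > 1L & ties == "ambiguous",
      assigned_guide = ifelse(.data$ambiguous, NA_character_, .data$top_guide),
      umi_count = .data$top_count
    ) |>
    select(
      "cell_barcode", "assigned_guide", "umi_count",
      "n_guides_detected", "ambiguous"
    )
}

#' Detected-guide count histogram over a cell universe
#'
#' @param matrix tibble from [build_cell_guide_matrix()].
#' @param cell_universe character vector of cell barcodes considered (e.g.
#'   cells passing an expression filter). Cells in the universe with no
#'   captured guide contribute a zero. Defaults to the cells present in
#'   `matrix`.
#' @return A tibble: `detected` (number of distinct guides), `n_cells`.
#' @export
detection_histogram <- function(matrix, cell_universe = NULL) {
  per_cell <- matrix |>
    count(.data$cell_barcode, name = "detected")
  if (!is.null(cell_universe)) {
    per_cell <- tibble(cell_barcode = unique(cell_universe)) |>
      left_join(per_cell, by = "cell_barcode") |>
      mutate(detected = tidyr::replace_na(.data$detected, 0L))
  }
  per_cell |>
    count(.data$detected, name = "n_cells") |>
    arrange(.data$detected)
}

#' Zero-truncated-Poisson / binomial-thinning detection likelihood
#'
#' P(D = j | lambda, d) with K ~ Poisson(lambda) conditioned on K >= 1
#' (selection removes uninfected cells) and D | K ~ Binomial(K, d).
#' @noRd
ztp_detection_pmf <- function(j, lambda, d, kmax = NULL) {
  if (is.null(kmax)) {
    kmax <- max(30L, ceiling(lambda + 12 * sqrt(lambda) + max(j)))
  }
  k <- seq_len(kmax)
  ztp <- dpois(k, lambda) / (1 - exp(-lambda))
  vapply(j, function(jj) {
    sum(ztp[k >= max(jj, 1L)] * dbinom(jj, k[k >= max(jj, 1L)], d))
  }, numeric(1))
}

#' Estimate MOI and detection rate from a detected-guide histogram
#'
#' Maximum-likelihood fit of (lambda, d) under the model: true integrations
#' per cell K ~ Poisson(lambda) conditioned on K >= 1 (antibiotic selection
#' keeps only infected cells), detected guides D | K ~ Binomial(K, d). The
#' likelihood is maximised by a coarse grid search over lambda in
#' `lambda_range` and d in `d_range`, refined by Nelder-Mead on transformed
#' coordinates. The fit is deterministic (no randomness).
#'
#' @param histogram tibble from [detection_histogram()] (columns `detected`,
#'   `n_cells`), or an integer vector of per-cell detected counts.
#' @param lambda_range,d_range search bounds.
#' @param grid_n grid points per dimension for the coarse search.
#' @return An object of class `moi_fit`: list with `lambda`,
#'   `detection_rate`, `loglik`, `convergence` (TRUE when the refinement
#'   converged), `n_cells`, `histogram`, `grid`.
#' @export
estimate_moi <- function(histogram, lambda_range = c(0.01, 10),
                         d_range = c(0.01, 1), grid_n = 25) {
  if (!is.data.frame(histogram)) {
    histogram <- tibble(detected = as.integer(histogram)) |>
      count(.data$detected, name = "n_cells")
  }
  stopifnot(all(c("detected", "n_cells") %in% names(histogram)))
  hist <- histogram |> filter(.data$n_cells > 0)
  if (!nrow(hist) || all(hist$detected == 0L)) {
    abort("all cells have zero detected guides; (lambda, d) unidentifiable")
  }
  j <- hist$detected
  w <- hist$n_cells
  nll <- function(lambda, d) {
    p <- ztp_detection_pmf(j, lambda, d)
    if (any(p <= 0)) return(Inf)
    -sum(w * log(p))
  }
  lg <- exp(seq(log(lambda_range[1]), log(lambda_range[2]), length.out = grid_n))
  dg <- seq(d_range[1], d_range[2], length.out = grid_n)
  grid <- expand.grid(lambda = lg, d = dg)
  grid$nll <- mapply(nll, grid$lambda, grid$d)
  best <- grid[which.min(grid$nll), ]
  # refine on unconstrained coordinates (log lambda, logit d)
  tr_nll <- function(par) {
    lambda <- exp(par[1])
    d <- stats::plogis(par[2])
    if (lambda < lambda_range[1] / 10 || lambda > lambda_range[2] * 10) return(Inf)
    nll(lambda, min(d, 1 - 1e-12))
  }
  opt <- optim(
    c(log(best$lambda), stats::qlogis(min(best$d, 1 - 1e-6))),
    tr_nll,
    method = "Nelder-Mead",
    control = list(maxit = 500, reltol = 1e-10)
  )
  structure(
    list(
      lambda = exp(opt$par[1]),
      detection_rate = stats::plogis(opt$par[2]),
      loglik = -opt$value,
      convergence = opt$convergence == 0,
      n_cells = sum(w),
      histogram = hist,
      grid = list(lambda_range = lambda_range, d_range = d_range, grid_n = grid_n)
    ),
    class = "moi_fit"
  )
}

#' @export
print.moi_fit <- function(x, ...) {
  cat(sprintf(
    "<moi_fit> lambda (MOI) = %.3f, detection rate = %.3f  (n = %d cells, logLik = %.1f%s)\n",
    x$lambda, x$detection_rate, x$n_cells, x$loglik,
    if (x$convergence) "" else ", NOT converged"
  ))
  invisible(x)
}

#' @rdname estimate_moi
#' @param x a `moi_fit`.
#' @param ... unused.
#' @method tidy moi_fit
#' @export
tidy.moi_fit <- function(x, ...) {
  tibble(
    term = c("lambda", "detection_rate"),
    estimate = c(x$lambda, x$detection_rate)
  )
}

#' @rdname estimate_moi
#' @method glance moi_fit
#' @export
glance.moi_fit <- function(x, ...) {
  tibble(
    lambda = x$lambda, detection_rate = x$detection_rate,
    logLik = x$loglik, converged = x$convergence, n_cells = x$n_cells
  )
}

#' Fraction of a cell universe with an assigned guide
#'
#' @param assignments tibble from [assign_guides()].
#' @param cell_universe character vector of all cells considered.
#' @return Numeric scalar: assigned / total.
#' @export
assignment_rate <- function(assignments, cell_universe) {
  cell_universe <- unique(cell_universe)
  if (!length(cell_universe)) abort("empty cell universe")
  assigned <- assignments |>
    filter(!is.na(.data$assigned_guide), .data$cell_barcode %in% cell_universe)
  nrow(assigned) / length(cell_universe)
}
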