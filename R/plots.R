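#' Plot per-position substitution efficiency of an amplicon
#'
#' Bar plot of C-to-T (coding-strand G-to-A where applicable) efficiency by
#' protospacer position, activity window shaded.
#'
#' @param object an `amplicon_edit_table` from [quantify_amplicon()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot amplicon_edit_table
#' @export
autoplot.amplicon_edit_table <- function(object, ...) {
  eff <- object$efficiency |> filter(!is.na(.data$efficiency))
  ggplot(eff, aes(x = .data$position, y = .data$efficiency)) +
    annotate("rect",
      xmin = min(object$spec$window) - 0.5, xmax = max(object$spec$window) + 0.5,
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue"
    ) +
    geom_col(fill = "grey30") +
    labs(
      x = "protospacer position (1 = PAM-distal)",
      y = "substitution efficiency",
      title = object$spec$id,
      subtitle = sprintf("indel fraction %.3f", object$indel_fraction)
    ) +
    theme_minimal()
}

#' Plot guide representation across screen samples
#'
#' Boxplots of per-guide counts (log10 + 1) by sample, the usual view of
#' representation collapsing under selection.
#'
#' @param tables input accepted by [representation_summary()] (long tibble
#'   with `sample`, `guide_id`, `count`, or list of count tables).
#' @return A ggplot.
#' @export
plot_representation <- function(tables) {
  long <- if (is.data.frame(tables)) {
    as_tibble(tables)
  } else {
    bind_rows(imap(tables, ~ tibble(
      sample = .y, guide_id = .x$guide_id, count = .x$count
    )))
  }
  ggplot(long, aes(x = .data$sample, y = .data$count + 1)) +
    geom_boxplot(outlier.size = 0.4) +
    scale_y_log10() +
    labs(x = NULL, y = "guide read count + 1") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot observed vs fitted detected-guide histogram of an MOI fit
#'
#' @param object a `moi_fit` from [estimate_moi()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot moi_fit
#' @export
autoplot.moi_fit <- function(object, ...) {
  obs <- object$histogram |>
    mutate(frac = .data$n_cells / sum(.data$n_cells))
  jmax <- max(obs$detected)
  fit <- tibble(
    detected = 0:jmax,
    frac = ztp_detection_pmf(0:jmax, object$lambda, object$detection_rate)
  )
  ggplot(obs, aes(x = .data$detected, y = .data$frac)) +
    geom_col(fill = "grey70") +
    geom_point(data = fit, colour = "firebrick", size = 2) +
    geom_line(data = fit, colour = "firebrick", linetype = 2) +
    labs(
      x = "detected guides per cell", y = "fraction of cells",
      title = sprintf(
        "MOI %.2f, detection rate %.2f", object$lambda, object$detection_rate
      )
    ) +
    theme_minimal()
}

#' Volcano-style enrichment plot for screen fold-changes
#'
#' Scatter of log2 fold-change by guide rank, highlighting the top guides.
#'
#' @param l2fc tibble from [log2_fold_change()].
#' @param top number of guides to label.
#' @return A ggplot.
#' @export
plot_enrichment <- function(l2fc, top = 3) {
  d <- l2fc |>
    arrange(dplyr::desc(.data$l2fc)) |>
    mutate(rank = dplyr::row_number(), top_hit = .data$rank <= top)
  ggplot(d, aes(x = .data$rank, y = .data$l2fc, colour = .data$top_hit)) +
    geom_point(size = 1) +
    scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                        guide = "none") +
    labs(x = "guide rank", y = expression(log[2] ~ "fold-change")) +
    theme_minimal()
}
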