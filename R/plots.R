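# ggplot2 views of the package's result types. Watson signal plots upward in
# red, Crick downward in blue, following the field's display convention.

#' Fine-scale two-strand break track plot
#'
#' Nucleotide-resolution histogram of a region: Watson line heights up,
#' Crick down.
#'
#' @param track Break map or HpM track.
#' @param contig,from,to Region to draw (defaults to the whole first contig).
#' @return A ggplot object.
#' @export
plot_fine_scale <- function(track, contig = NULL, from = -Inf, to = Inf) {
  vc <- signal_col(track)
  x <- as_tibble(track)
  contig <- contig %||% x$contig[1]
  x <- x |>
    filter(.data$contig == !!contig, .data$pos >= from, .data$pos <= to) |>
    mutate(y = if_else(.data$strand == "watson", .data[[vc]], -.data[[vc]]))
  ggplot2::ggplot(x, ggplot2::aes(.data$pos, .data$y, colour = .data$strand)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0),
                          linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::scale_colour_manual(
      values = c(watson = "firebrick", crick = "steelblue")
    ) +
    ggplot2::labs(x = paste0(contig, " position (bp)"), y = "signal",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.aggregate_profile <- function(object, ...) {
  stranded <- "strand" %in% names(object)
  p <- ggplot2::ggplot(
    object,
    if (stranded) {
      ggplot2::aes(.data$offset, .data$mean_value, colour = .data$strand)
    } else {
      ggplot2::aes(.data$offset, .data$mean_value)
    }
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "offset from locus (bp)",
      y = sprintf("mean signal per locus (n = %d)",
                  attr(object, "n_loci") %||% NA)
    ) +
    ggplot2::theme_minimal()
  if (stranded) {
    p <- p + ggplot2::scale_colour_manual(
      values = c(watson = "firebrick", crick = "steelblue")
    )
  }
  p
}

#' @export
autoplot.offset_correlation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$offset, .data$r)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(
      data = object[which.max(object$r), ], colour = "firebrick", na.rm = TRUE
    ) +
    ggplot2::labs(x = "Crick - Watson offset (bp)",
                  y = "Pearson r (Watson vs Crick)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.composition_profile <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$position, .data$fraction, colour = .data$base)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = "position relative to dyad (bp)",
                  y = "base fraction") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fractionation <- function(object, ...) {
  s <- object$summary |> filter(.data$class != "excluded")
  ggplot2::ggplot(s, ggplot2::aes(.data$class, .data$pct_of_tested)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "% of tested sites") +
    ggplot2::theme_minimal()
}
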