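#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot syntenic block occurrences
#'
#' One horizontal segment per occurrence, faceted by genome; the reference
#' occurrence of each block set is emphasized.
#'
#' @param object a `synteny_blocks` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.synteny_blocks <- function(object, ...) {
  occ <- object$occurrences
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$start, xend = .data$end,
                                    y = .data$chrom, yend = .data$chrom,
                                    colour = .data$is_reference)) +
    ggplot2::geom_segment(linewidth = 2, alpha = 0.7) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$genome), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "marker position", y = NULL, colour = "reference") +
    ggplot2::theme_minimal()
}

#' Plot CAR sizes
#'
#' Bar chart of markers per contiguous ancestral region, with the ordered /
#' unordered split shown by fill.
#'
#' @param object a `car_set`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.car_set <- function(object, ...) {
  cars <- object$cars |>
    dplyr::count(.data$car_id, .data$ordered)
  ggplot2::ggplot(cars, ggplot2::aes(x = factor(.data$car_id), y = .data$n,
                                     fill = .data$ordered)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "CAR", y = "markers", fill = "order fixed") +
    ggplot2::theme_minimal()
}

#' Plot a segmentation
#'
#' Atoms as coloured intervals per sequence; waste regions are the gaps.
#'
#' @param object a `segmentation`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.segmentation <- function(object, ...) {
  atoms <- object$atoms
  lens <- tibble::tibble(seq = names(object$seq_lengths),
                         len = as.numeric(object$seq_lengths))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = lens,
                          ggplot2::aes(x = 0, xend = .data$len, y = .data$seq,
                                       yend = .data$seq),
                          colour = "grey70", linewidth = 1)
  if (nrow(atoms) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = atoms,
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$seq,
                   yend = .data$seq, colour = .data$family),
      linewidth = 4)
  }
  p + ggplot2::labs(x = "bp", y = NULL) + ggplot2::theme_minimal()
}
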