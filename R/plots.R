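# ggplot2 helpers for the main result types.

#' Plot a sliding-window genome scan
#'
#' Window midpoints against the statistic, one facet per chromosome and one
#' colour per population (or pair).
#'
#' @param scan A [genome_scan()] tibble.
#' @return A ggplot object.
#' @export
plot_scan <- function(scan) {
  d <- scan[!is.na(scan$value), ]
  d$mid <- (d$start + d$end) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid / 1e6, y = .data$value,
                                  colour = .data$pop)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(stat ~ chrom, scales = "free") +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-window female-specific mutation counts
#'
#' @param scan A [female_specific_scan()] tibble.
#' @return A ggplot object.
#' @export
plot_female_specific <- function(scan) {
  scan$mid <- (scan$start + scan$end) / 2
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$mid / 1e6, y = .data$count)) +
    ggplot2::geom_col(width = 0.02, fill = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = "high-frequency female-specific alleles") +
    ggplot2::theme_minimal()
}

#' Tile plot of painted chromosomes
#'
#' Mirrors the classic supergene painting: one row per haplotype, coloured
#' 20-kb tiles by assigned cluster, grey for unassigned, white for missing.
#'
#' @param painting A `painting` tibble (possibly row-bound across samples).
#' @return A ggplot object.
#' @export
plot_painting <- function(painting) {
  painting$track <- paste0(painting$sample, " | hap", painting$hap)
  cols <- c(chrysippus = "#d95f02", dorippus = "#1b9e77",
            orientis = "#7570b3", unassigned = "grey70", missing = "white")
  ggplot2::ggplot(painting,
                  ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                               ymin = 0, ymax = 1, fill = .data$cluster)) +
    ggplot2::geom_rect(colour = NA) +
    ggplot2::facet_grid(track ~ ., switch = "y") +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::labs(x = "position (Mb)", fill = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   strip.text.y.left = ggplot2::element_text(angle = 0),
                   panel.grid = ggplot2::element_blank())
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.painted_chromosome <- function(object, ...) plot_painting(object$painting)

#' Trajectory of the fused haplotype and infection
#'
#' @param object A `neow_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neow_sim <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trajectory,
                            c("fused_freq", "infected_freq"),
                            names_to = "series", values_to = "freq")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$gen, y = .data$freq,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "generation", y = "frequency", colour = NULL) +
    ggplot2::theme_minimal()
}
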