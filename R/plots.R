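#' Plot five-stage allele-frequency trajectories
#'
#' One line per locus across the stages F0, F0_LD80, F2, F2_LD25, F2_LD75,
#' faceted by insecticide line. Low-coverage stages are drawn as empty dots.
#'
#' @param traj Output of [frequency_trajectories()] (optionally filtered),
#'   or of [kdr_report()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(traj) {
  if (all(c("stage", "freq") %in% names(traj))) {
    long <- traj %>%
      dplyr::mutate(locus = if ("name" %in% names(traj)) .data$name else
        paste0(.data$chrom, ":", .data$pos))
  } else {
    long <- traj %>%
      dplyr::mutate(locus = paste0(.data$chrom, ":", .data$pos)) %>%
      tidyr::pivot_longer(dplyr::starts_with("f_"), names_to = "stage",
                          values_to = "freq", names_prefix = "f_") %>%
      dplyr::mutate(flagged = .data$flagged)
  }
  long$stage <- factor(long$stage, levels = stage_levels())
  ggplot2::ggplot(long, ggplot2::aes(.data$stage, .data$freq,
                                     group = .data$locus,
                                     colour = .data$locus)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$flagged), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                name = "coverage < 30") +
    ggplot2::facet_wrap(~line) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "allele frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Heatmap of per-gene copy-number profiles
#'
#' @param profiles Output of [gene_profiles()].
#' @param value `"z"` (centre-reduced) or `"normalized"`.
#' @param genes Optional subset of gene ids.
#' @return A ggplot object.
#' @export
plot_copy_number <- function(profiles, value = c("z", "normalized"),
                             genes = NULL) {
  value <- match.arg(value)
  if (!is.null(genes)) {
    profiles <- profiles %>% dplyr::filter(.data$gene_id %in% genes)
  }
  profiles$condition <- factor(profiles$condition,
                               levels = condition_levels())
  ggplot2::ggplot(profiles,
                  ggplot2::aes(.data$condition, .data$gene_id,
                               fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick",
                                  midpoint = if (value == "z") 0 else 1,
                                  name = value) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Manhattan-style plot of a Bayesian scan
#'
#' Plots `-log10(q)` along the genome, with the significance threshold as a
#' dashed line.
#'
#' @param object An `fst_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fst_scan <- function(object, ...) {
  d <- object$result %>%
    dplyr::filter(!.data$skipped) %>%
    dplyr::mutate(mlq = -log10(pmax(.data$q, 1e-6)))
  ggplot2::ggplot(d, ggplot2::aes(.data$pos / 1e6, .data$mlq,
                                  colour = .data$chrom)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$config$q_threshold),
                        linetype = "dashed") +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(
      x = "position (Mb)", y = expression(-log[10](q)),
      title = sprintf("%s, line %s", object$result$contrast[1],
                      object$result$line[1])
    ) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
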