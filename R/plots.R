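#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot consensus repeat-length profiles
#'
#' Family-count histograms of consensus tract lengths, faceted by sample and
#' locus — the visual a reviewer checks when judging an instability call.
#'
#' @param profiles Long profile tibble from [collapse_to_profile()].
#' @param sample_ids,locus_ids Optional filters.
#' @return A ggplot.
#' @export
plot_length_profiles <- function(profiles, sample_ids = NULL,
                                 locus_ids = NULL) {
  if (!is.null(sample_ids)) {
    profiles <- dplyr::filter(profiles, .data$sample_id %in% sample_ids)
  }
  if (!is.null(locus_ids)) {
    profiles <- dplyr::filter(profiles, .data$locus_id %in% locus_ids)
  }
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$tract_len_units,
                               y = .data$family_count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_grid(sample_id ~ locus_id, scales = "free_y") +
    ggplot2::labs(x = "consensus tract length (repeat units)",
                  y = "UMI families") +
    ggplot2::theme_bw()
}

#' Plot per-locus sensitivity and specificity
#'
#' @param metrics Tibble from [per_locus_metrics()].
#' @return A ggplot.
#' @export
plot_locus_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(metrics, c("sensitivity", "specificity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$locus_id, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn optimize_panel Plot the combination scan: best sensitivity
#'   and specificity per panel size.
#' @param object An `msi_panel`.
#' @method autoplot msi_panel
#' @export
autoplot.msi_panel <- function(object, ...) {
  long <- tidyr::pivot_longer(object$selection_log,
                              c("sensitivity", "specificity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$size, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::scale_x_continuous(breaks = object$selection_log$size) +
    ggplot2::labs(x = "panel size (loci)", y = "best per size",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' @describeIn build_call_matrix Heatmap of the instability call matrix
#'   (tumors by loci; no-calls grey).
#' @param object A `call_matrix`.
#' @param ... Unused.
#' @method autoplot call_matrix
#' @export
autoplot.call_matrix <- function(object, ...) {
  long <- tibble::as_tibble(object$unstable, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "locus_id",
                        values_to = "unstable") |>
    dplyr::left_join(
      tibble::as_tibble(object$no_call, rownames = "sample_id") |>
        tidyr::pivot_longer(-"sample_id", names_to = "locus_id",
                            values_to = "no_call"),
      by = c("sample_id", "locus_id")
    ) |>
    dplyr::mutate(state = dplyr::case_when(
      .data$no_call ~ "no-call",
      .data$unstable ~ "unstable",
      TRUE ~ "stable"
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$locus_id, y = .data$sample_id,
                                     fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(stable = "grey90",
                                          unstable = "firebrick",
                                          `no-call` = "grey60")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
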