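#' Plot Kaplan-Meier survival curves by group
#'
#' @param clinical Tibble with `time`, `event` and (optionally) `group`
#'   columns, e.g. from [sim_clinical()] or [stratify_survival()]'s
#'   `groups` element.
#'
#' @return A ggplot object (step curves, one per group).
#' @export
plot_km <- function(clinical) {
  grp <- if ("group" %in% names(clinical)) clinical$group else "all"
  curves <- tibble::tibble(time = clinical$time, event = clinical$event,
                           group = grp) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1),
      km_curve(.x$time, .x$event)[, c("time", "survival")])) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$survival,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Betweenness vs eigenvector centrality plot
#'
#' Scatter of the two centralities with the least-squares line; point
#' size encodes the regression residual, the node-importance measure
#' used to flag bridge-like signalling proteins.
#'
#' @param report Output of [network_centralities()].
#'
#' @return A ggplot object.
#' @export
plot_centralities <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(.data$eigenvector,
                                       .data$betweenness)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey60", linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$residual)),
                        alpha = 0.7) +
    ggplot2::labs(x = "Eigenvector centrality",
                  y = "Betweenness centrality",
                  size = "|residual|") +
    ggplot2::theme_minimal()
}

#' Histogram of Boolean scores with the shortlist cutoff
#'
#' @param scores Output of [score_genes()] (optionally after
#'   [shortlist()]).
#' @param cutoff Score cutoff drawn as a vertical line.
#'
#' @return A ggplot object.
#' @export
plot_boolean_scores <- function(scores, cutoff = 0.5) {
  ggplot2::ggplot(scores, ggplot2::aes(.data$score)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = "Boolean probability score", y = "Genes") +
    ggplot2::theme_minimal()
}

#' Signature-score strip plot by sample class
#'
#' @param scores Tibble with `sample`, `score`.
#' @param classes Named vector ("tumor"/"normal") over samples.
#'
#' @return A ggplot object.
#' @export
plot_signature <- function(scores, classes) {
  dat <- dplyr::mutate(scores, class = unname(classes[.data$sample]))
  ggplot2::ggplot(dat, ggplot2::aes(.data$class, .data$score)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "Signature score") +
    ggplot2::theme_minimal()
}
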