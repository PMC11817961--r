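#' Bar chart of SSR abundance by motif length
#'
#' @param summary An `ssr_genome_summary` from [summarize_genome()].
#' @return A ggplot object.
#' @export
plot_ssr_summary <- function(summary) {
  tidy(summary) |>
    ggplot2::ggplot(ggplot2::aes(factor(.data$unit_length),
                                 .data$relative_abundance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "motif length (bp)", y = "SSRs per Mb",
                  title = "SSR relative abundance by motif length") +
    ggplot2::theme_minimal()
}

#' SSR density along chromosomes
#'
#' @param density Tibble from [window_density()].
#' @return A ggplot object (one panel per chromosome).
#' @export
plot_window_density <- function(density) {
  density |>
    ggplot2::ggplot(ggplot2::aes(.data$window_start / 1e6, .data$n_ssrs)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "SSRs per window",
                  title = "SSR density along chromosomes") +
    ggplot2::theme_minimal()
}

#' PCoA scatter plot
#'
#' @param x An `ssr_pcoa` object.
#' @param axes Two axis numbers to display (default 1:2).
#' @param groups Optional tibble `sample_id`, `group` for colouring.
#' @return A ggplot object.
#' @export
plot_pcoa <- function(x, axes = c(1, 2), groups = NULL) {
  sc <- x$scores
  ax <- paste0("axis", axes)
  if (!all(ax %in% names(sc))) stop("requested axes not available", call. = FALSE)
  if (!is.null(groups)) sc <- dplyr::left_join(sc, groups, by = "sample_id")
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]])) +
    ggplot2::labs(
      x = sprintf("PCo%d (%.1f%%)", axes[1], x$pct_var[axes[1]]),
      y = sprintf("PCo%d (%.1f%%)", axes[2], x$pct_var[axes[2]]),
      title = "Principal coordinate analysis"
    ) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point(color = "steelblue")
  else p + ggplot2::geom_point(ggplot2::aes(color = .data$group))
}

#' @export
autoplot.ssr_pcoa <- function(object, ...) plot_pcoa(object, ...)

#' Evanno plot: mean LnP(K) and delta-K against K
#'
#' @param ev An `ssr_evanno` object.
#' @return A ggplot object with delta-K; mean LnP is shown as a secondary
#'   panel via faceting.
#' @export
plot_evanno <- function(ev) {
  tb <- tibble::as_tibble(ev) |>
    dplyr::select("K", "mean_lnp", "delta_k") |>
    tidyr::pivot_longer(-"K", names_to = "stat") |>
    dplyr::mutate(stat = dplyr::recode(.data$stat, mean_lnp = "mean LnP(K)",
                                       delta_k = "delta K"))
  ggplot2::ggplot(tb, ggplot2::aes(.data$K, .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$stat), scales = "free_y") +
    ggplot2::labs(y = NULL, title = "Evanno model choice") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ssr_evanno <- function(object, ...) plot_evanno(object)

#' Stacked admixture bar plot
#'
#' @param fit An `ssr_structure_fit` from [em_admixture()].
#' @param order_by Cluster number to sort individuals by (default 1).
#' @return A ggplot object.
#' @export
plot_structure <- function(fit, order_by = 1L) {
  q <- tidy(fit)
  lev <- fit$Q |>
    dplyr::arrange(dplyr::desc(.data[[paste0("k", order_by)]])) |>
    dplyr::pull("sample_id")
  q |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = lev)) |>
    ggplot2::ggplot(ggplot2::aes(.data$sample_id, .data$q,
                                 fill = factor(.data$cluster))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry proportion", fill = "cluster",
                  title = sprintf("Admixture proportions, K = %d", fit$K)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.ssr_structure_fit <- function(object, ...) plot_structure(object, ...)

#' Cumulative probability-of-identity curve
#'
#' @param ident Tibble from [ssr_identity()].
#' @return A ggplot object (log10 y scale).
#' @export
plot_cumulative_pi <- function(ident) {
  ident |>
    dplyr::select("rank", PI = "cum_pi", PIsibs = "cum_pi_sibs") |>
    tidyr::pivot_longer(-"rank", names_to = "stat") |>
    ggplot2::ggplot(ggplot2::aes(.data$rank, .data$value,
                                 color = .data$stat)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "number of combined markers",
                  y = "cumulative probability of identity",
                  title = "Discriminating power of marker combinations") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
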