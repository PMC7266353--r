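#' Plot surviving-lineage counts through time
#'
#' The classic diagnostic of coalescent bias: for large samples of long
#' genomes the Hudson model's lineage count shoots far above the haploid
#' population size `2N` while the DTWF count can never exceed it.
#'
#' @param ... one or more `genealogy` objects (named arguments become the
#'   legend labels) or a single tibble with columns `generation`,
#'   `lineages` and optionally `model`.
#' @param N diploid population size: drawn as a dotted `2N` reference line.
#' @return A ggplot.
#' @export
plot_lineage_counts <- function(..., N = NULL) {
  args <- list(...)
  if (length(args) == 1 && is.data.frame(args[[1]])) {
    df <- args[[1]]
    if (!"model" %in% names(df)) df$model <- "simulation"
  } else {
    labs <- names(args)
    if (is.null(labs)) labs <- rep("", length(args))
    df <- dplyr::bind_rows(lapply(seq_along(args), function(i) {
      sim <- args[[i]]
      lab <- if (nzchar(labs[i])) labs[i] else sim$config$model
      dplyr::mutate(lineage_counts(sim), model = lab)
    }))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$generation + 1,
                                        y = .data$lineages,
                                        colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations in the past (+1)",
                  y = "surviving lineages", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(N)) {
    p <- p + ggplot2::geom_hline(yintercept = 2 * N, linetype = "dotted")
  }
  p
}

#' Plot the IBD segment-count / total-length plane
#'
#' One point per sample pair, coloured by the pair's most recent common
#' ancestor time. Discrete genealogical relationships (half siblings,
#' cousins, ...) appear as clusters; an expectation table from
#' [expected_ibd()] can be overlaid as open circles.
#'
#' @param pairs output of [ibd_pair_summary()].
#' @param expectation optional tibble with columns `expected_total_cm` and
#'   `expected_n` (or their detection-conditioned variants).
#' @return A ggplot.
#' @export
plot_ibd_pairs <- function(pairs, expectation = NULL) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$total_cm,
                                           y = .data$n_segments)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$min_tmrca)),
                        alpha = 0.5, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "total IBD length (cM)", y = "number of IBD segments",
                  colour = "min TMRCA") +
    ggplot2::theme_minimal()
  if (!is.null(expectation)) {
    xcol <- intersect(c("expected_total_cm_detected", "expected_total_cm"),
                      names(expectation))[1]
    ycol <- intersect(c("expected_n_detected", "expected_n"),
                      names(expectation))[1]
    p <- p + ggplot2::geom_point(
      data = expectation,
      ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]]),
      shape = 21, fill = "white", colour = "black", size = 2,
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot ancestry variance against time since admixture
#'
#' @param df tibble with columns `g`, `variance` and `model` (simulated
#'   and/or expected curves).
#' @return A ggplot.
#' @export
plot_ancestry_variance <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g, y = .data$variance,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations since admixture pulse",
                  y = "variance of ancestry fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a site frequency spectrum
#'
#' @param df tibble with columns `carriers`, `sites` (or `expected_sites`)
#'   and optionally `model`.
#' @param max_carriers truncate the spectrum for readability.
#' @return A ggplot.
#' @export
plot_sfs <- function(df, max_carriers = 20) {
  ycol <- intersect(c("sites", "expected_sites"), names(df))[1]
  df <- dplyr::filter(df, .data$carriers <= max_carriers)
  if (!"model" %in% names(df)) df$model <- "simulation"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$carriers, y = .data[[ycol]],
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "derived-allele carriers", y = "sites", fill = NULL) +
    ggplot2::theme_minimal()
}
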