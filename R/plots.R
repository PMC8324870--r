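# ggplot2 views of analysis results.

#' Control-separation densities per screen
#'
#' Density of replicate-mean robust z-scores for targeting, positive-control
#' and negative-control hairpins, faceted by screen. Well-behaved screens
#' show positive controls shifted clearly below the negative controls.
#'
#' @param object A `screen_analysis` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_analysis <- function(object, ...) {
  ggplot2::ggplot(object$hairpin_summary,
                  ggplot2::aes(x = .data$mean_z, colour = .data$class)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(ggplot2::vars(.data$screen_id)) +
    ggplot2::labs(x = "replicate-mean robust z", y = "density",
                  colour = "hairpin class",
                  title = "Control separation by screen") +
    ggplot2::theme_minimal()
}

#' Gene-level depletion overview for one or more screens
#'
#' RSA log10 p against the top-3 mean z summary; hits at the configured
#' thresholds are highlighted.
#'
#' @param x A `screen_analysis`.
#' @return A ggplot object.
#' @export
plot_gene_results <- function(x) {
  stopifnot(inherits(x, "screen_analysis"))
  tidy(x) |>
    dplyr::filter(.data$class == "targeting") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$top3_mean_z, y = -.data$rsa_logp,
                                 colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$screen_id)) +
    ggplot2::labs(x = "top-3 hairpin mean z", y = "-RSA log10 p",
                  colour = "hit") +
    ggplot2::theme_minimal()
}

#' Hit-overlap region counts across screens
#'
#' Bar chart of the gene counts in each screen-intersection region, the
#' numbers a Venn diagram would display; the all-screens region holds the
#' common dependencies.
#'
#' @param x A `screen_analysis` covering >= 2 screens.
#' @return A ggplot object.
#' @export
plot_hit_overlap <- function(x) {
  stopifnot(inherits(x, "screen_analysis"))
  if (is.null(x$overlap)) abort("hit overlap needs at least 2 screens")
  x$overlap$regions |>
    dplyr::mutate(pattern = factor(.data$pattern,
                                   levels = rev(unique(.data$pattern)))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$n_genes, y = .data$pattern)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "genes", y = "screens sharing the hit") +
    ggplot2::theme_minimal()
}
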