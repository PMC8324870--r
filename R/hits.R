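# Hit calling at fixed RSA logP / FDR thresholds and cross-screen
# intersection of the resulting hit sets.

#' Mean of a gene's k most-depleted hairpin z-scores
#'
#' Alternative gene summary statistic: the mean of the k smallest replicate-
#' averaged z-scores. Genes with fewer than k hairpins use all of them.
#'
#' @param z Numeric vector of a gene's per-hairpin mean z-scores.
#' @param k Number of hairpins to average (default 3).
#' @return Scalar mean.
#' @export
top_k_mean <- function(z, k = 3L) {
  if (length(z) < 1L) abort("gene must have at least one hairpin")
  if (k < 1L) abort("k must be >= 1")
  mean(sort(z)[seq_len(min(k, length(z)))])
}

#' Call per-screen hits at RSA logP and FDR thresholds
#'
#' A targeting gene is a hit in a screen iff `rsa_logp <= logp_threshold`
#' AND `fdr_q <= fdr_threshold` (both comparisons inclusive). Control genes
#' are never called: positive controls are intentionally essential and would
#' otherwise contaminate every cross-screen intersection.
#'
#' @param gene_results Output of [rsa_gene_stats()].
#' @param logp_threshold RSA log10 p threshold (default -1.5).
#' @param fdr_threshold FDR q threshold (default 0.3).
#' @return Tibble of hits: `screen_id`, `gene`, `rsa_logp`, `fdr_q`,
#'   `top3_mean_z`.
#' @export
call_hits <- function(gene_results, logp_threshold = -1.5, fdr_threshold = 0.3) {
  if (!is.finite(logp_threshold) || !is.finite(fdr_threshold)) {
    abort("hit thresholds must be finite")
  }
  gene_results |>
    dplyr::filter(.data$class == "targeting",
                  .data$rsa_logp <= logp_threshold,
                  !is.na(.data$fdr_q), .data$fdr_q <= fdr_threshold) |>
    dplyr::select("screen_id", "gene", "rsa_logp", "fdr_q", "top3_mean_z") |>
    dplyr::arrange(.data$screen_id, .data$rsa_logp)
}

#' Intersect hit sets across screens
#'
#' Returns the genes hit in every screen together with the full gene-by-
#' screen membership matrix and per-intersection-region counts (the numbers
#' a Venn diagram would display).
#'
#' @param hits Tibble from [call_hits()] covering >= 2 screens, or a named
#'   list of per-screen hit gene vectors.
#' @return List with `common` (character vector of genes hit in all
#'   screens), `membership` (tibble, one row per gene with one logical
#'   column per screen), and `regions` (tibble of intersection patterns and
#'   gene counts).
#' @export
common_hits <- function(hits) {
  if (is.data.frame(hits)) {
    sets <- split(hits$gene, hits$screen_id)
  } else {
    sets <- hits
  }
  if (length(sets) < 2L) abort("need hit sets from at least 2 screens")
  screens <- names(sets)
  genes <- sort(unique(unlist(sets)))
  membership <- tibble(gene = genes)
  for (scr in screens) membership[[scr]] <- genes %in% sets[[scr]]
  common <- genes[rowSums(as.matrix(membership[screens])) == length(screens)]
  pattern <- apply(as.matrix(membership[screens]), 1, function(m) {
    paste(screens[m], collapse = "&")
  })
  regions <- membership |>
    dplyr::mutate(pattern = pattern) |>
    dplyr::count(.data$pattern, name = "n_genes") |>
    dplyr::arrange(dplyr::desc(.data$n_genes))
  list(common = common, membership = membership, regions = regions)
}
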