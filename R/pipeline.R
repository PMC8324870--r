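# End-to-end orchestration: counts -> hairpin scores -> gene RSA stats ->
# hits -> cross-screen intersection -> QC, with a run manifest for
# reproducibility.

#' Run the full screen analysis pipeline
#'
#' Takes a count object (or a simulated [make_screen_suite()]) and produces
#' every downstream artifact: per-replicate hairpin scores, replicate-mean
#' summaries with depletion percentiles, gene-level RSA statistics with FDR,
#' per-screen hit calls at the configured thresholds, the cross-screen
#' common-hit set, and QC metrics. A run manifest records the configuration
#' so reruns are reproducible.
#'
#' @param x A [screen_counts()] object or a `screen_suite`.
#' @param library An [shrna_library()]; taken from the suite when `x` is one.
#' @param pseudocount Fold-change pseudocount in RPM (default 0.5).
#' @param mad_constant Robust-z MAD constant (default 1.4826).
#' @param logp_threshold RSA log10 p hit threshold (default -1.5).
#' @param fdr_threshold FDR q hit threshold (default 0.3).
#' @param fdr_method `"bh"` or `"permutation"` (see [rsa_gene_stats()]).
#' @param n_permutations,seed Permutation-FDR settings.
#' @return List of class `screen_analysis`: `scores`, `hairpin_summary`,
#'   `gene_results`, `hits`, `overlap` (from [common_hits()], `NULL` for a
#'   single screen), `qc`, `manifest`.
#' @examples
#' suite <- make_screen_suite(sim_config(n_genes = 20, depth = 2e5), seed = 1)
#' fit <- run_pipeline(suite)
#' glance(fit)
#' @export
run_pipeline <- function(x, library = NULL, pseudocount = 0.5,
                         mad_constant = 1.4826, logp_threshold = -1.5,
                         fdr_threshold = 0.3, fdr_method = "bh",
                         n_permutations = 100, seed = 1L) {
  if (inherits(x, "screen_suite")) {
    library <- x$library
    x <- x$counts
  }
  stopifnot(inherits(x, "screen_counts"))
  if (is.null(library)) abort("a library manifest is required")
  scores <- score_hairpins(x, library, pseudocount = pseudocount,
                           mad_constant = mad_constant)
  hairpin_summary <- summarize_hairpins(scores)
  gene_results <- rsa_gene_stats(hairpin_summary, fdr_method = fdr_method,
                                 n_permutations = n_permutations, seed = seed)
  hits <- call_hits(gene_results, logp_threshold = logp_threshold,
                    fdr_threshold = fdr_threshold)
  n_screens <- length(unique(x$samples$screen_id))
  overlap <- if (n_screens >= 2L) {
    sets <- split(hits$gene, factor(hits$screen_id,
                                    levels = unique(x$samples$screen_id)))
    common_hits(sets)
  }
  qc <- qc_report(x, hairpin_summary)
  manifest <- list(
    n_hairpins = nrow(library),
    n_screens = n_screens,
    params = list(pseudocount = pseudocount, mad_constant = mad_constant,
                  logp_threshold = logp_threshold,
                  fdr_threshold = fdr_threshold, fdr_method = fdr_method,
                  seed = seed),
    timestamp = format(Sys.time(), tz = "UTC"))
  structure(list(scores = scores, hairpin_summary = hairpin_summary,
                 gene_results = gene_results, hits = hits, overlap = overlap,
                 qc = qc, manifest = manifest),
            class = "screen_analysis")
}

#' @export
print.screen_analysis <- function(x, ...) {
  cat("<screen_analysis> ", x$manifest$n_screens, " screen(s), ",
      x$manifest$n_hairpins, " hairpins\n", sep = "")
  hit_counts <- table(x$hits$screen_id)
  cat("  hits/screen: ",
      paste(names(hit_counts), hit_counts, sep = "=", collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$overlap)) {
    cat("  common hits: ", paste(x$overlap$common, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Tidy gene-level results of a screen analysis
#'
#' @param x A `screen_analysis` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble with one row per screen x gene, including a logical `hit`
#'   column.
#' @export
tidy.screen_analysis <- function(x, ...) {
  hit_key <- paste(x$hits$screen_id, x$hits$gene)
  x$gene_results |>
    dplyr::mutate(hit = paste(.data$screen_id, .data$gene) %in% hit_key) |>
    dplyr::arrange(.data$screen_id, .data$rsa_logp)
}

#' One-row-per-screen summary of a screen analysis
#'
#' @param x A `screen_analysis` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble with per-screen gene/hit counts and QC metrics.
#' @export
glance.screen_analysis <- function(x, ...) {
  hits_per_screen <- x$hits |> dplyr::count(.data$screen_id, name = "n_hits")
  x$gene_results |>
    dplyr::group_by(.data$screen_id) |>
    dplyr::summarise(n_genes = sum(.data$class == "targeting"), .groups = "drop") |>
    dplyr::left_join(hits_per_screen, by = "screen_id") |>
    dplyr::mutate(n_hits = dplyr::coalesce(.data$n_hits, 0L),
                  n_common_hits = if (is.null(x$overlap)) NA_integer_
                                  else length(x$overlap$common)) |>
    dplyr::left_join(x$qc$screens, by = "screen_id")
}

#' Write analysis artifacts to a directory
#'
#' Emits the score table, hairpin summary, gene results and hits as TSV,
#' plus a JSON summary (per-screen hit counts, common hits, intersection
#' regions, QC metrics, run manifest).
#'
#' @param x A `screen_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "screen_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(x$scores, file.path(dir, "hairpin_scores.tsv"))
  readr::write_tsv(x$hairpin_summary, file.path(dir, "hairpin_summary.tsv"))
  readr::write_tsv(x$gene_results, file.path(dir, "gene_results.tsv"))
  readr::write_tsv(x$hits, file.path(dir, "hits.tsv"))
  if (!is.null(x$overlap)) {
    readr::write_tsv(x$overlap$membership, file.path(dir, "hit_membership.tsv"))
  }
  summary <- list(
    hits_per_screen = as.list(table(x$hits$screen_id)),
    common_hits = if (is.null(x$overlap)) NULL else x$overlap$common,
    regions = if (is.null(x$overlap)) NULL else as.data.frame(x$overlap$regions),
    qc_screens = as.data.frame(x$qc$screens),
    qc_samples = as.data.frame(x$qc$samples),
    manifest = x$manifest)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, na = "null", null = "null")
  invisible(dir)
}
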