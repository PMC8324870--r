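# Per-hairpin depletion scoring: library-size normalization, log2 fold
# change against the reference pool, robust z-scores, replicate averaging,
# percentile ranks.

#' Library-size normalization to reads per million
#'
#' @param counts Non-negative count vector.
#' @param total Normalization denominator; defaults to `sum(counts)`, i.e.
#'   assigned reads for the sample.
#' @return Numeric vector summing to 1e6 when `total = sum(counts)`.
#' @export
normalize_counts <- function(counts, total = sum(counts)) {
  if (!is_count_vector(counts)) abort("counts must be non-negative integers")
  if (total <= 0) abort("empty sample: normalization total must be > 0")
  counts / total * 1e6
}

#' Log2 fold change of a tumor sample against the reference pool
#'
#' A symmetric pseudocount (in reads-per-million units) is added to both
#' numerator and denominator so that zero counts - expected under an in vivo
#' bottleneck - stay finite and LFC(reference, reference) is exactly zero.
#'
#' @param sample_norm,reference_norm Size-normalized (RPM) vectors aligned to
#'   the library.
#' @param pseudocount Pseudocount in RPM; default 0.5.
#' @return Numeric vector of log2 fold changes.
#' @export
log_fold_change <- function(sample_norm, reference_norm, pseudocount = 0.5) {
  if (length(sample_norm) != length(reference_norm)) {
    abort("sample and reference vectors have different lengths")
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) abort("pseudocount must be > 0")
  log2((sample_norm + pseudocount) / (reference_norm + pseudocount))
}

#' Robust z-score (median / MAD)
#'
#' `z = (x - median(x)) / (c * mad)`, where `mad` is the median absolute
#' deviation from the median and `c = 1.4826` rescales the MAD to estimate a
#' normal standard deviation. Set `mad_constant = 1` for the raw MAD.
#'
#' @param x Numeric vector, length >= 2.
#' @param mad_constant Consistency constant applied to the MAD; default 1.4826.
#' @return Numeric vector with median 0.
#' @export
robust_z <- function(x, mad_constant = 1.4826) {
  if (length(x) < 2L) abort("robust_z needs at least 2 values")
  med <- median(x)
  s <- mad(x, center = med, constant = mad_constant)
  if (s == 0) abort("degenerate score distribution: MAD is zero")
  (x - med) / s
}

#' Average hairpin z-scores across tumor replicates
#'
#' @param z_list List of per-replicate z-score vectors (or a matrix with one
#'   column per replicate).
#' @return Element-wise arithmetic mean.
#' @export
aggregate_replicates <- function(z_list) {
  if (is.matrix(z_list)) z_list <- asplit(z_list, 2)
  if (length(z_list) < 1L) abort("need at least one replicate")
  len <- lengths(z_list)
  if (length(unique(len)) != 1L) abort("replicate vectors have inconsistent lengths")
  Reduce(`+`, z_list) / length(z_list)
}

#' Rank hairpins by depletion and convert to percentiles
#'
#' Most depleted (lowest mean z) gets rank 1; `percentile = rank / N` lies in
#' (0, 1]. Ties are broken stably by input order so results are deterministic.
#'
#' @param mean_z Numeric vector.
#' @return Tibble with columns `rank` and `percentile`.
#' @export
to_ranks <- function(mean_z) {
  if (length(mean_z) < 1L) abort("empty score vector")
  r <- rank(mean_z, ties.method = "first")
  tibble(rank = as.integer(r), percentile = r / length(mean_z))
}

#' Score hairpin depletion for every screen in a count object
#'
#' For each screen: normalizes every sample to reads per million (denominator
#' = assigned reads), computes per-tumor-replicate log2 fold change against
#' the screen's reference sample, transforms each replicate's fold changes
#' into robust z-scores across all hairpins.
#'
#' @param x A [screen_counts()] object.
#' @param library An [shrna_library()].
#' @param pseudocount Pseudocount in RPM for the fold change (default 0.5).
#' @param mad_constant MAD consistency constant (default 1.4826).
#' @return Tibble with one row per screen x tumor replicate x hairpin:
#'   `screen_id`, `sample_id`, `replicate`, `hairpin_id`, `gene`, `class`,
#'   `count`, `norm_count`, `ref_norm`, `lfc`, `z`.
#' @export
score_hairpins <- function(x, library, pseudocount = 0.5, mad_constant = 1.4826) {
  stopifnot(inherits(x, "screen_counts"), inherits(library, "shrna_library"))
  if (!setequal(x$counts$hairpin_id, library$hairpin_id)) {
    abort("count matrix rows do not match the library")
  }
  counts <- x$counts[match(library$hairpin_id, x$counts$hairpin_id), ]
  screens <- unique(x$samples$screen_id)
  out <- purrr::map_dfr(screens, function(scr) {
    sm <- dplyr::filter(x$samples, .data$screen_id == scr)
    ref_id <- sm$sample_id[sm$role == "reference"]
    if (length(ref_id) != 1L) {
      abort(paste0("screen ", scr, ": exactly one reference sample required"))
    }
    ref_norm <- normalize_counts(counts[[ref_id]])
    tum <- dplyr::filter(sm, .data$role == "tumor_replicate")
    purrr::map_dfr(seq_len(nrow(tum)), function(i) {
      sid <- tum$sample_id[i]
      nc <- normalize_counts(counts[[sid]])
      lfc <- log_fold_change(nc, ref_norm, pseudocount = pseudocount)
      tibble(screen_id = scr, sample_id = sid,
             replicate = tum$replicate[i],
             hairpin_id = library$hairpin_id,
             gene = library$gene, class = library$class,
             count = counts[[sid]],
             norm_count = nc, ref_norm = ref_norm,
             lfc = lfc, z = robust_z(lfc, mad_constant = mad_constant))
    })
  })
  out
}

#' Summarize hairpin scores across replicates
#'
#' Averages per-replicate robust z-scores and converts the replicate means
#' into depletion ranks and percentiles within each screen (rank 1 = most
#' depleted of all N hairpins). Percentiles feed the gene-level RSA
#' statistic.
#'
#' @param scores Output of [score_hairpins()].
#' @return Tibble with one row per screen x hairpin: `screen_id`,
#'   `hairpin_id`, `gene`, `class`, `n_replicates`, `mean_lfc`, `mean_z`,
#'   `rank`, `percentile`.
#' @export
summarize_hairpins <- function(scores) {
  scores |>
    dplyr::group_by(.data$screen_id, .data$hairpin_id, .data$gene, .data$class) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     mean_lfc = mean(.data$lfc),
                     mean_z = mean(.data$z), .groups = "drop") |>
    dplyr::group_by(.data$screen_id) |>
    dplyr::mutate(rank = as.integer(rank(.data$mean_z, ties.method = "first")),
                  percentile = .data$rank / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$screen_id, .data$rank)
}
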