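# Screen quality control (control separation, barcode representation) and
# the standard in vivo tumor metrics (caliper volume, %TGI).

#' Separation between positive- and negative-control hairpins
#'
#' SSMD = (mean(neg) - mean(pos)) / sqrt(var(neg) + var(pos)), positive when
#' positive-control hairpins (targeting essential genes) deplete below the
#' negative controls. AUC is the rank-sum probability that a random
#' negative-control score exceeds a random positive-control score (1 =
#' perfect separation, 0.5 = none); it is invariant under any strictly
#' increasing transform of the scores.
#'
#' @param pos,neg Numeric score vectors (e.g. mean z) for the positive- and
#'   negative-control hairpins; each needs >= 2 values.
#' @return Tibble with columns `ssmd` and `auc`.
#' @export
control_separation <- function(pos, neg) {
  if (length(pos) < 2L || length(neg) < 2L) {
    abort("need at least 2 hairpins in each control class")
  }
  v <- var(neg) + var(pos)
  if (v == 0) abort("degenerate control scores: zero variance in both classes")
  ssmd <- (mean(neg) - mean(pos)) / sqrt(v)
  cmp <- outer(neg, pos, `>`) + 0.5 * outer(neg, pos, `==`)
  tibble(ssmd = ssmd, auc = mean(cmp))
}

#' Barcode representation diagnostics for one sample
#'
#' @param counts Non-negative count vector over all library hairpins.
#' @return Tibble with `detected_fraction` (share of hairpins with >= 1
#'   read) and `gini` (Gini coefficient of the count distribution; 0 =
#'   perfectly even representation). An all-zero sample returns 0 for both.
#' @export
representation_stats <- function(counts) {
  if (length(counts) < 1L) abort("empty count vector")
  if (any(counts < 0)) abort("counts must be non-negative")
  detected <- mean(counts > 0)
  tot <- sum(as.numeric(counts))
  if (tot == 0) return(tibble(detected_fraction = 0, gini = 0))
  x <- sort(as.numeric(counts))
  n <- length(x)
  g <- sum((2 * seq_len(n) - n - 1) * x) / (as.numeric(n) * tot)
  tibble(detected_fraction = detected, gini = g)
}

#' Caliper tumor volume
#'
#' `TV = (length x width^2) / 2` in mm^3. If width exceeds length the two
#' are swapped with a warning (the longer caliper axis is the length by
#' convention).
#'
#' @param length,width Caliper measurements in mm (vectorized).
#' @return Tumor volumes in mm^3.
#' @export
tumor_volume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0)) abort("measurements must be positive")
  swap <- width > length
  if (any(swap)) {
    warn("width > length for some measurements; axes swapped")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  length * width^2 / 2
}

#' Percent tumor growth inhibition
#'
#' `%TGI = 100 x (1 - MTV_treated / MTV_control)` where MTV is the final
#' median tumor volume of the group. Positive values mean inhibition; growth
#' stimulation comes out negative.
#'
#' @param treated_volumes,control_volumes Final tumor volumes (mm^3) per
#'   animal in the treated and control groups.
#' @return Scalar percent TGI.
#' @export
percent_tgi <- function(treated_volumes, control_volumes) {
  if (length(treated_volumes) < 1L || length(control_volumes) < 1L) {
    abort("both groups must be non-empty")
  }
  mtv_control <- median(control_volumes)
  if (mtv_control <= 0) abort("control median tumor volume must be > 0")
  100 * (1 - median(treated_volumes) / mtv_control)
}

#' Screen-level QC report
#'
#' Per screen: SSMD and AUC separation of positive- vs negative-control
#' hairpin mean z-scores, and the median log2 fold change of each control
#' class. Per sample: detected-barcode fraction and Gini coefficient of the
#' raw counts.
#'
#' @param x A [screen_counts()] object.
#' @param hairpin_summary Output of [summarize_hairpins()].
#' @return List with tibbles `screens` and `samples`.
#' @export
qc_report <- function(x, hairpin_summary) {
  stopifnot(inherits(x, "screen_counts"))
  screens <- purrr::map_dfr(split(hairpin_summary, hairpin_summary$screen_id),
                            function(hs) {
    pos <- hs$mean_z[hs$class == "positive_control"]
    neg <- hs$mean_z[hs$class == "negative_control"]
    sep <- if (length(pos) >= 2 && length(neg) >= 2) {
      control_separation(pos, neg)
    } else {
      tibble(ssmd = NA_real_, auc = NA_real_)
    }
    tibble(screen_id = hs$screen_id[1],
           ssmd_controls = sep$ssmd, auc_controls = sep$auc,
           median_lfc_pos = median(hs$mean_lfc[hs$class == "positive_control"]),
           median_lfc_neg = median(hs$mean_lfc[hs$class == "negative_control"]))
  })
  samples <- purrr::map_dfr(x$samples$sample_id, function(sid) {
    dplyr::bind_cols(tibble(sample_id = sid),
                     representation_stats(x$counts[[sid]]))
  })
  samples <- dplyr::left_join(samples,
                              dplyr::select(x$tallies, "sample_id", "total_reads",
                                            "unassigned"),
                              by = "sample_id")
  list(screens = screens, samples = samples)
}
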