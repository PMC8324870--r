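# Gene-level redundant shRNA activity (RSA) statistic and FDR control.
#
# RSA asks: given that a gene's n hairpins sit at depletion ranks
# r_1 < ... < r_n among all N hairpins in the screen, how surprising is it
# that at least i of them fall within the top r_i, for the best i? Each
# order statistic gets a hypergeometric tail probability
# p_i = P(X >= i), X ~ Hypergeom(N, n, r_i), and the gene's p-value is the
# minimum over i. Consistent depletion across several hairpins is rewarded;
# a single outlier hairpin is not enough to drive the minimum.

#' RSA log10 p-value for one gene's hairpin ranks
#'
#' Computed in log space throughout (no underflow for screens up to ~1e5
#' hairpins). Returns `log10(min_i P(X >= i))` with
#' `X ~ Hypergeometric(N, n, r_i)`; more negative = more consistently
#' depleted.
#'
#' @param ranks Integer vector of the gene's hairpin depletion ranks
#'   (1 = most depleted), distinct values in `1..n_total`.
#' @param n_total Total number of hairpins N in the screen.
#' @return Scalar log10 p-value in (-Inf, 0].
#' @examples
#' rsa_logp(5, 100)              # log10(0.05)
#' rsa_logp(1:10, 2370)          # -log10 choose(2370, 10)
#' @export
rsa_logp <- function(ranks, n_total) {
  ranks <- as.integer(ranks)
  n_total <- as.integer(n_total)
  n <- length(ranks)
  if (n < 1L) abort("gene must have at least one hairpin rank")
  ranks <- sort(ranks)
  if (anyDuplicated(ranks) > 0 || ranks[1] < 1L || ranks[n] > n_total) {
    abort("ranks must be distinct integers in 1..n_total")
  }
  i <- seq_len(n)
  # P(X >= i) = phyper(i - 1, n, N - n, r_i, lower.tail = FALSE)
  log_p <- phyper(i - 1L, n, n_total - n, ranks,
                  lower.tail = FALSE, log.p = TRUE) / log(10)
  min(pmin(log_p, 0))
}

#' Exact-summation oracle for the RSA statistic
#'
#' Recomputes [rsa_logp()] by direct summation of hypergeometric probability
#' masses from log binomial coefficients — an independent route used for
#' verification. Restricted to small screens where the summation is exact to
#' double precision.
#'
#' @inheritParams rsa_logp
#' @return Scalar log10 p-value.
#' @export
rsa_logp_oracle <- function(ranks, n_total) {
  n_total <- as.integer(n_total)
  if (n_total > 500L) abort("oracle restricted to n_total <= 500")
  ranks <- sort(as.integer(ranks))
  n <- length(ranks)
  if (n < 1L || anyDuplicated(ranks) > 0 || ranks[1] < 1L || ranks[n] > n_total) {
    abort("ranks must be distinct integers in 1..n_total")
  }
  tail_log10 <- function(i, r) {
    j <- seq.int(i, min(n, r))
    terms <- lchoose(n, j) + lchoose(n_total - n, r - j) - lchoose(n_total, r)
    m <- max(terms)
    (m + log(sum(exp(terms - m)))) / log(10)
  }
  p <- vapply(seq_len(n), function(i) tail_log10(i, ranks[i]), double(1))
  min(pmin(p, 0))
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment (wraps `stats::p.adjust`), with input
#' validation to the open-closed interval (0, 1].
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

# Permutation-based FDR: shuffle gene labels across hairpins, recompute the
# RSA p for every gene in each permutation, and estimate
# FDR(p) = mean #{null p <= p} / #{observed p <= p}, made monotone in p.
permutation_fdr <- function(p_obs, hairpin_summary, n_total = nrow(hairpin_summary),
                            n_permutations = 100, seed = 1L) {
  null_counts <- numeric(length(p_obs))
  with_local_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perm_gene <- sample(hairpin_summary$gene)
      p_null <- vapply(split(hairpin_summary$rank, perm_gene),
                       function(r) 10^rsa_logp(r, n_total), double(1))
      null_counts <- null_counts +
        vapply(p_obs, function(p) sum(p_null <= p), double(1))
    }
  })
  obs_counts <- vapply(p_obs, function(p) sum(p_obs <= p), double(1))
  q <- pmin(null_counts / n_permutations / obs_counts, 1)
  # enforce monotonicity: q non-decreasing in p (step-up style)
  ord <- order(p_obs, decreasing = TRUE)
  q[ord] <- cummin(q[ord])
  q
}

#' Gene-level RSA statistics for every screen
#'
#' Collapses the per-hairpin summary to one row per gene and screen: the RSA
#' log10 p-value over the gene's hairpin depletion ranks, the corresponding
#' p, an FDR q-value, the mean of the gene's 3 most-depleted hairpin
#' z-scores (alternative summary statistic), hairpin count and best rank.
#' The FDR family is the targeting genes of each screen; control genes get
#' `NA` q-values (they are QC spike-ins, not tested hypotheses).
#'
#' @param hairpin_summary Output of [summarize_hairpins()].
#' @param fdr_method `"bh"` (Benjamini-Hochberg, default) or `"permutation"`
#'   (gene-label shuffle).
#' @param n_permutations Permutation count when `fdr_method = "permutation"`.
#' @param seed Seed for the permutation stream.
#' @param top_k Hairpins averaged for the alternative summary (default 3).
#' @return Tibble with one row per screen x gene: `screen_id`, `gene`,
#'   `class`, `n_hairpins`, `best_rank`, `rsa_logp`, `rsa_p`, `fdr_q`,
#'   `top3_mean_z`.
#' @export
rsa_gene_stats <- function(hairpin_summary, fdr_method = c("bh", "permutation"),
                           n_permutations = 100, seed = 1L, top_k = 3L) {
  fdr_method <- match.arg(fdr_method)
  purrr::map_dfr(split(hairpin_summary, hairpin_summary$screen_id), function(hs) {
    n_total <- nrow(hs)
    res <- hs |>
      dplyr::group_by(.data$screen_id, .data$gene, .data$class) |>
      dplyr::summarise(
        n_hairpins = dplyr::n(),
        best_rank = min(.data$rank),
        rsa_logp = rsa_logp(.data$rank, n_total),
        top3_mean_z = top_k_mean(.data$mean_z, k = top_k),
        .groups = "drop") |>
      dplyr::mutate(rsa_p = 10^.data$rsa_logp, fdr_q = NA_real_)
    targeting <- res$class == "targeting"
    if (any(targeting)) {
      res$fdr_q[targeting] <- if (fdr_method == "bh") {
        bh_fdr(res$rsa_p[targeting])
      } else {
        permutation_fdr(res$rsa_p[targeting],
                        hs[hs$class == "targeting", ], n_total = n_total,
                        n_permutations = n_permutations, seed = seed)
      }
    }
    dplyr::arrange(res, .data$rsa_logp)
  })
}
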