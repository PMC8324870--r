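test_that("RSA logP matches closed forms on analytic cases", {
  # single hairpin at rank r: p = r / N
  expect_equal(rsa_logp(5, 100), log10(0.05), tolerance = 1e-12)
  # two hairpins at ranks {1, 2} of 4: min(2/4, 1/choose(4, 2))
  expect_equal(rsa_logp(c(1, 2), 4), log10(1 / 6), tolerance = 1e-12)
  # all 10 hairpins in the top 10 of 2370: p = 1 / choose(2370, 10)
  expect_equal(rsa_logp(1:10, 2370), -lchoose(2370, 10) / log(10),
               tolerance = 1e-9)
  expect_error(rsa_logp(c(1, 1), 4), "distinct")
  expect_error(rsa_logp(5, 4), "1..n_total")
})

test_that("degenerate rank configurations hit the logP boundaries", {
  # every hairpin in the screen belongs to the gene -> p_i = 1 for all i
  expect_equal(rsa_logp(1:6, 6), 0)
  expect_equal(rsa_logp_oracle(1:6, 6), 0)
  # worst possible ranks r_i = N - n + i -> p_i = 1
  N <- 40; n <- 4
  worst <- N - n + seq_len(n)
  expect_equal(rsa_logp_oracle(worst, N), 0)
  expect_equal(rsa_logp(worst, N), 0)
})

test_that("log-space implementation agrees with the exact-summation oracle", {
  withr::with_seed(77, {
    for (case in seq_len(1000)) {
      N <- sample(10:300, 1)
      n <- sample(1:min(8, N), 1)
      ranks <- sort(sample.int(N, n))
      expect_equal(rsa_logp(ranks, N), rsa_logp_oracle(ranks, N),
                   tolerance = 1e-9)
    }
  })
  expect_error(rsa_logp_oracle(1:3, 1000), "500")
})

test_that("logP is bounded by the first order statistic and monotone in ranks", {
  withr::with_seed(31, {
    for (case in seq_len(200)) {
      N <- sample(20:200, 1)
      n <- sample(2:6, 1)
      ranks <- sort(sample.int(N, n))
      lp <- rsa_logp(ranks, N)
      expect_lte(lp, 0)
      expect_lte(lp, log10(phyper(0, n, N - n, ranks[1], lower.tail = FALSE)) + 1e-12)
      # improving (decreasing) one rank never worsens logP
      i <- sample.int(n, 1)
      improved <- ranks
      improved[i] <- improved[i] - 1L
      if (improved[i] >= 1 && !improved[i] %in% ranks) {
        expect_lte(rsa_logp(improved, N), lp + 1e-12)
      }
    }
  })
})

test_that("null RSA p-values are anti-conservative by the documented offset", {
  # Monte-Carlo null: ranks drawn uniformly without replacement. The min
  # over order statistics is not a calibrated p-value; at alpha = 0.05
  # about 14% of null genes pass (frozen from a seeded 1e4-draw run).
  set.seed(424242)
  N <- 100; n <- 4
  p <- replicate(10000, 10^rsa_logp(sort(sample.int(N, n)), N))
  frac <- mean(p <= 0.05)
  expect_gt(frac, 0.05)              # anti-conservative, as documented
  expect_equal(frac, 0.1365, tolerance = 0.02)
  expect_equal(unname(quantile(p, 0.05)), 0.0233, tolerance = 0.01)
})

test_that("BH q-values match the hand step-up and a brute-force implementation", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  brute_bh <- function(p) {
    m <- length(p)
    vapply(seq_len(m), function(i) {
      min(vapply(which(rank(p, ties.method = "max") >= rank(p, ties.method = "max")[i]),
                 function(j) p[j] * m / rank(p, ties.method = "max")[j],
                 double(1)), 1)
    }, double(1))
  }
  withr::with_seed(5, {
    for (case in 1:20) {
      p <- runif(sample(1:30, 1))
      expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
    }
  })
})

test_that("gene-level RSA table has coherent p/q columns and top-3 summary", {
  suite <- make_screen_suite(
    sim_config(n_genes = 30, hairpins_per_gene = 5, control_hairpins = 3,
               depth = 3e5, n_models = 1), seed = 8)
  fit_scores <- summarize_hairpins(score_hairpins(suite$counts, suite$library))
  res <- rsa_gene_stats(fit_scores)
  expect_equal(nrow(res), 33)  # 30 targeting + RPL30 + PSMA1 + LUC
  expect_true(all(res$rsa_p > 0 & res$rsa_p <= 1))
  expect_equal(res$rsa_p, 10^res$rsa_logp)
  targeting <- res[res$class == "targeting", ]
  expect_true(all(targeting$fdr_q >= targeting$rsa_p - 1e-12))
  expect_true(all(is.na(res$fdr_q[res$class != "targeting"])))
  # top-3 summary equals the hand computation from the hairpin table
  g <- targeting$gene[1]
  z <- fit_scores$mean_z[fit_scores$gene == g]
  expect_equal(targeting$top3_mean_z[1], mean(sort(z)[1:3]))
})

test_that("permutation FDR is a monotone, bounded alternative to BH", {
  suite <- make_screen_suite(
    sim_config(n_genes = 20, hairpins_per_gene = 4, control_hairpins = 2,
               depth = 2e5, n_models = 1), seed = 12)
  smry <- summarize_hairpins(score_hairpins(suite$counts, suite$library))
  res <- rsa_gene_stats(smry, fdr_method = "permutation",
                        n_permutations = 30, seed = 2)
  q <- res$fdr_q[res$class == "targeting"]
  p <- res$rsa_p[res$class == "targeting"]
  expect_true(all(q >= 0 & q <= 1))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  # planted essentials still separate clearly from neutral genes
  planted <- c(suite$truth$pan_essential, suite$truth$model_essential$M1)
  tg <- res[res$class == "targeting", ]
  expect_lt(mean(tg$rsa_logp[tg$gene %in% planted]),
            mean(tg$rsa_logp[!tg$gene %in% planted]))
  expect_lt(max(tg$fdr_q[tg$gene %in% suite$truth$pan_essential]), 0.3)
})
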