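test_that("synthetic library honours the configured structure", {
  cfg <- sim_config(n_genes = 2, hairpins_per_gene = 1, control_hairpins = 2)
  lib <- build_library(cfg, seed = 1)
  expect_equal(sum(lib$class == "targeting"), 2)
  expect_equal(sum(lib$class == "positive_control"), 4)  # RPL30 + PSMA1
  expect_equal(sum(lib$class == "negative_control"), 2)  # LUC
  # barcodes keep pairwise Hamming distance >= 3
  m <- do.call(rbind, strsplit(lib$barcode, ""))
  d <- outer(seq_len(nrow(m)), seq_len(nrow(m)),
             Vectorize(function(i, j) sum(m[i, ] != m[j, ])))
  expect_true(all(d[upper.tri(d)] >= 3))
})

test_that("default library is a 237-gene x 10-hairpin epigenome-style design", {
  lib <- default_library()
  targeting <- table(lib$gene[lib$class == "targeting"])
  expect_equal(length(targeting), 237L)
  expect_true(all(targeting == 10L))
  expect_equal(nrow(lib), 2400L)
  for (g in c("RPL30", "PSMA1", "LUC")) {
    expect_equal(sum(lib$gene == g), 10L)
  }
})

test_that("reference pool: determinism, evenness limit, zero depth", {
  cfg <- sim_config(n_genes = 10, hairpins_per_gene = 3, control_hairpins = 2)
  lib <- build_library(cfg, seed = 2)
  r1 <- simulate_reference(lib, cfg, seed = 5)
  r2 <- simulate_reference(lib, cfg, seed = 5)
  expect_identical(r1$counts, r2$counts)
  expect_false(identical(r1$counts, simulate_reference(lib, cfg, seed = 6)$counts))
  # near-uniform pool in the large-concentration limit
  even_cfg <- sim_config(n_genes = 10, hairpins_per_gene = 3,
                         control_hairpins = 2, library_skew_alpha = 1e6,
                         depth = 1e6)
  even <- simulate_reference(lib, even_cfg, seed = 7)
  expect_lt(representation_stats(even$counts)$gini, 0.02)
  zero <- simulate_reference(lib, sim_config(n_genes = 10, hairpins_per_gene = 3,
                                             control_hairpins = 2, depth = 0),
                             seed = 8)
  expect_true(all(zero$counts == 0))
})

test_that("default transplantation sits inside the 1000-2000 cells/barcode band", {
  expect_equal(cells_per_barcode(sim_config()), 1250)
  expect_equal(cells_per_barcode(sim_config(), default_library()), 1250)
  expect_gte(cells_per_barcode(sim_config()), 1000)
  expect_lte(cells_per_barcode(sim_config()), 2000)
})

test_that("tumor growth model yields the closed-form expected fold changes", {
  # one fully effective hairpin against s = 0.5 grows 2^5 vs 2^10 -> LFC ~ -5
  cfg <- sim_config(n_genes = 40, hairpins_per_gene = 5, control_hairpins = 2,
                    depth = 2e6, n_models = 1)
  lib <- build_library(cfg, seed = 9)
  truth <- list(
    gene_effects = tibble::tibble(model = "M1", gene = unique(lib$gene),
                                  effect = 0),
    hairpin_efficacy = tibble::tibble(hairpin_id = lib$hairpin_id, efficacy = 1))
  truth$gene_effects$effect[truth$gene_effects$gene == lib$gene[1]] <- 0.5
  ref <- simulate_reference(lib, cfg, seed = 10)
  tum <- simulate_tumor(ref$proportions, lib, truth, "M1", cfg, seed = 11)
  lfc <- log_fold_change(normalize_counts(tum), normalize_counts(ref$counts))
  target <- lib$gene == lib$gene[1]
  # depleted barcodes absorb ~2.5% of the pool, lifting the rest by ~log2(1.024)
  expect_equal(mean(lfc[target]), -5, tolerance = 0.2)
  expect_equal(mean(lfc[!target]), 0.035, tolerance = 0.05)

  # all-neutral truth: mean LFC stays at zero
  null_truth <- truth
  null_truth$gene_effects$effect <- 0
  tum0 <- simulate_tumor(ref$proportions, lib, null_truth, "M1", cfg, seed = 12)
  lfc0 <- log_fold_change(normalize_counts(tum0), normalize_counts(ref$counts))
  expect_lt(abs(mean(lfc0)), 0.05)
})

test_that("written FASTQ is deterministic and collapses at error rate 1", {
  cfg <- sim_config(n_genes = 4, hairpins_per_gene = 2, control_hairpins = 2,
                    depth = 500, seq_error_rate = 0.01)
  lib <- build_library(cfg, seed = 13)
  ref <- simulate_reference(lib, cfg, seed = 14)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(ref$counts, lib, f1, config = cfg, seed = 15)
  write_fastq(ref$counts, lib, f2, config = cfg, seed = 15)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(length(readLines(f1)), 4 * 500)

  all_err <- sim_config(n_genes = 4, hairpins_per_gene = 2, control_hairpins = 2,
                        depth = 500, seq_error_rate = 1)
  f3 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(ref$counts, lib, f3, config = all_err, seed = 16)
  res <- count_sample(f3, lib)
  expect_lt(res$tallies$assigned / res$tallies$total_reads, 0.01)
})

test_that("screen suites carry the planted truth and full sample structure", {
  suite <- default_suite()
  expect_equal(ncol(suite$counts$counts) - 1L, 16L)  # 4 models x (1 ref + 3 tumors)
  expect_equal(length(suite$truth$pan_essential), 5L)
  expect_equal(lengths(suite$truth$model_essential), setNames(rep(3L, 4), paste0("M", 1:4)))
  # pan-model essentials carry the configured effect in every model
  for (m in paste0("M", 1:4)) {
    ge <- suite$truth$gene_effects
    eff <- ge$effect[ge$model == m][match(suite$truth$pan_essential,
                                          ge$gene[ge$model == m])]
    expect_true(all(eff == 0.5))
  }
  expect_equal(suite$infected_fraction, 1 - exp(-0.3))
  # different seeds: same structure, different counts
  cfg <- sim_config(n_genes = 6, hairpins_per_gene = 2, control_hairpins = 2,
                    depth = 1e4, n_models = 2)
  s1 <- make_screen_suite(cfg, seed = 1)
  s2 <- make_screen_suite(cfg, seed = 2)
  expect_equal(dim(s1$counts$counts), dim(s2$counts$counts))
  expect_false(identical(s1$counts$counts, s2$counts$counts))
})

test_that("planted RSA signal strengthens monotonically with effect size", {
  lib <- default_library()
  mean_logp <- vapply(c(0, 0.2, 0.5), function(s) {
    per_seed <- vapply(1:3, function(seed) {
      suite <- make_screen_suite(sim_config(essential_effect = s, n_models = 1),
                                 seed = 300 + seed, library = lib)
      smry <- summarize_hairpins(score_hairpins(suite$counts, suite$library))
      res <- rsa_gene_stats(smry)
      mean(res$rsa_logp[res$gene %in% suite$truth$pan_essential])
    }, double(1))
    mean(per_seed)
  }, double(1))
  expect_true(mean_logp[1] > mean_logp[2])
  expect_true(mean_logp[2] > mean_logp[3])
})
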