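test_that("spacer filter accepts <=1 mismatch at positions 18-21", {
  expect_true(match_spacer(make_read("ACGTACGTACGTACGTAC", spacer = "CGAA")))
  expect_true(match_spacer(make_read("ACGTACGTACGTACGTAC", spacer = "CGAT")))
  expect_false(match_spacer(make_read("ACGTACGTACGTACGTAC", spacer = "CGTT")))
  # N counts as a mismatch
  expect_true(match_spacer(make_read("ACGTACGTACGTACGTAC", spacer = "CGAN")))
  expect_false(match_spacer(make_read("ACGTACGTACGTACGTAC", spacer = "CGNN")))
  # short reads fail quietly, never error
  expect_false(match_spacer("ACGT"))
  expect_false(match_spacer(strrep("A", 20)))
})

test_that("barcode extraction slices the documented windows", {
  bc <- "ACGTACGTACGTACGTAC"
  expect_identical(extract_barcode(make_read(bc)), bc)
  nt_read <- paste0("TTTTGGGGCCCCAAAATT", strrep("G", 22))
  expect_identical(extract_barcode(nt_read, "nontargeting_layout"),
                   "TTTTGGGGCCCCAAAATT")
  # 39-nt targeting read is too short for the 23-40 window
  expect_true(is.na(extract_barcode(strrep("A", 39))))
  expect_true(is.na(extract_barcode(strrep("A", 17), "nontargeting_layout")))
})

test_that("barcode assignment: exact, unique 1-mismatch, ambiguous", {
  lib <- tiny_library()
  expect_identical(assign_barcode("AAAAAAAAAAAAAAAAAA", lib), "G1_sh1")
  # one mismatch from exactly one barcode
  expect_identical(assign_barcode("AAAAAAAAAAAAAAAAAT", lib), "G1_sh1")
  # two mismatches from everything -> unassigned
  expect_true(is.na(assign_barcode("AAAAAAAAAAAAAAAATT", lib)))
  # a sequence at distance 1 from two distinct barcodes -> unassigned
  close_lib <- shrna_library(data.frame(
    hairpin_id = c("a", "b"),
    barcode = c("AAAAAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAAAAT"),
    gene = c("G1", "G2"), class = "targeting"))
  expect_true(is.na(assign_barcode("AAAAAAAAAAAAAAAAAC", close_lib)))
  # the library's own barcodes always map to themselves (exact wins)
  expect_identical(assign_barcode(close_lib$barcode, close_lib), c("a", "b"))
})

test_that("count_sample tallies every read into exactly one bin", {
  lib <- tiny_library()
  reads <- c(make_read(lib$barcode[1]),
             make_read(lib$barcode[1]),
             make_read(lib$barcode[2]),
             make_read(lib$barcode[3], spacer = "CGTT"))  # spacer fail
  path <- write_fastq_lines(reads, withr::local_tempfile(fileext = ".fastq"))
  res <- count_sample(path, lib)
  expect_equal(unname(res$counts), c(2L, 1L, 0L))
  expect_equal(res$tallies$spacer_fail, 1L)
  expect_equal(res$tallies$total_reads, 4L)
  expect_equal(res$tallies$assigned + res$tallies$unassigned +
                 res$tallies$spacer_fail + res$tallies$extraction_fail,
               res$tallies$total_reads)
})

test_that("empty FASTQ gives all-zero counts", {
  lib <- tiny_library()
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), path)
  res <- count_sample(path, lib)
  expect_equal(sum(res$counts), 0L)
  expect_equal(res$tallies$total_reads, 0L)
})

test_that("error-free simulated FASTQ round-trips to the simulated counts", {
  cfg <- sim_config(n_genes = 8, hairpins_per_gene = 4, control_hairpins = 2,
                    depth = 3000, seq_error_rate = 0)
  lib <- build_library(cfg, seed = 3)
  ref <- simulate_reference(lib, cfg, seed = 4)
  path <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(ref$counts, lib, path, config = cfg, seed = 5)
  res <- count_sample(path, lib)
  expect_equal(res$counts, ref$counts)
  expect_equal(res$tallies$unassigned, 0L)
  expect_equal(res$tallies$spacer_fail, 0L)
})

test_that("assigned fraction decreases monotonically in the error rate", {
  base <- sim_config(n_genes = 6, hairpins_per_gene = 3, control_hairpins = 2,
                     depth = 2000)
  lib <- build_library(base, seed = 11)
  ref <- simulate_reference(lib, base, seed = 12)
  frac <- vapply(c(0, 0.05, 0.2), function(e) {
    cfg <- sim_config(n_genes = 6, hairpins_per_gene = 3, control_hairpins = 2,
                      depth = 2000, seq_error_rate = e)
    path <- withr::local_tempfile(fileext = ".fastq")
    write_fastq(ref$counts, lib, path, config = cfg, seed = 13)
    res <- count_sample(path, lib)
    res$tallies$assigned / res$tallies$total_reads
  }, double(1))
  expect_equal(frac[1], 1)
  expect_true(frac[1] > frac[2])
  expect_true(frac[2] > frac[3])
})

test_that("deconvolve_samples assembles a conserving screen_counts", {
  cfg <- sim_config(n_genes = 5, hairpins_per_gene = 3, control_hairpins = 2,
                    tumor_replicates = 2, n_models = 1, depth = 1500,
                    seq_error_rate = 0.01)
  dir <- withr::local_tempdir()
  suite <- make_screen_suite(cfg, seed = 21, fastq_dir = dir)
  x <- deconvolve_samples(suite$counts$samples, suite$library)
  expect_s3_class(x$counts, "tbl_df")
  conserved <- x$tallies$total_reads ==
    vapply(x$samples$sample_id, function(s) sum(x$counts[[s]]), double(1)) +
    x$tallies$unassigned + x$tallies$spacer_fail + x$tallies$extraction_fail
  expect_true(all(conserved))
  expect_equal(x$tallies$total_reads, rep(1500, 3))
})
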