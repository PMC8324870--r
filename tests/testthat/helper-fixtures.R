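# Shared fixtures, built in code and cached for the test session. The
# default-scale objects (2,400-hairpin library, 4-model suite) are expensive
# enough that several files share one instance.

.fixtures <- new.env(parent = emptyenv())

# Fixture seed family for default-scale simulations.
FIXTURE_SEED <- 101L

default_library <- function() {
  if (is.null(.fixtures$lib)) {
    .fixtures$lib <- build_library(sim_config(), seed = FIXTURE_SEED)
  }
  .fixtures$lib
}

default_suite <- function() {
  if (is.null(.fixtures$suite)) {
    .fixtures$suite <- make_screen_suite(sim_config(), seed = FIXTURE_SEED,
                                         library = default_library())
  }
  .fixtures$suite
}

default_fit <- function() {
  if (is.null(.fixtures$fit)) {
    .fixtures$fit <- run_pipeline(default_suite())
  }
  .fixtures$fit
}

# Hand-held 3-hairpin library with barcodes at pairwise distance >= 3.
tiny_library <- function() {
  shrna_library(data.frame(
    hairpin_id = c("G1_sh1", "G1_sh2", "G2_sh1"),
    barcode = c("AAAAAAAAAAAAAAAAAA",
                "CCCCCCAAAAAAAAAAAA",
                "GGGGGGGGGAAAAAAAAA"),
    gene = c("G1", "G1", "G2"),
    class = "targeting"
  ))
}

# A targeting-layout read whose positions 18-21 hold `spacer` and whose
# positions 23-40 hold `barcode` (length 50).
make_read <- function(barcode, spacer = "CGAA", linker = "A") {
  paste0(strrep("A", 17), spacer, linker, barcode, strrep("T", 10))
}

write_fastq_lines <- function(reads, path) {
  qual <- vapply(reads, function(r) strrep("I", nchar(r)), character(1))
  writeLines(paste0("@r", seq_along(reads), "\n", reads, "\n+\n", qual), path)
  path
}

# Small random screen_counts object (1 reference + n_tumors per screen).
random_counts <- function(library, n_screens = 1, n_tumors = 2, max_count = 50,
                          seed = 1) {
  withr::with_seed(seed, {
    counts <- tibble::tibble(hairpin_id = library$hairpin_id)
    rows <- list()
    for (s in seq_len(n_screens)) {
      scr <- paste0("S", s)
      ids <- c(paste0(scr, "_ref"), paste0(scr, "_T", seq_len(n_tumors)))
      roles <- c("reference", rep("tumor_replicate", n_tumors))
      for (i in seq_along(ids)) {
        counts[[ids[i]]] <- sample.int(max_count, nrow(library), replace = TRUE)
      }
      rows[[s]] <- tibble::tibble(sample_id = ids, screen_id = scr, role = roles)
    }
    screen_counts(counts, sample_sheet(dplyr::bind_rows(rows)), library = library)
  })
}
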