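# Synthetic pooled-screen generator. Emulates the study conditions the
# analysis assumes: an epigenome-scale library (237 targeting genes x 10
# hairpins plus RPL30/PSMA1/LUC control sets), a Dirichlet-skewed plasmid
# pool, a single multinomial engraftment bottleneck at 1000-2000 cells per
# barcode, deterministic exponential outgrowth with per-gene essentiality
# effects and per-hairpin efficacy, and multinomial sequencing with optional
# per-base substitution errors in the written FASTQ.

#' Simulation configuration
#'
#' Defaults describe the screen design the analysis pipeline targets: a
#' 237-gene x 10-hairpin library with 10 hairpins for each of two positive
#' controls (RPL30, PSMA1) and one negative control (LUC); infection at MOI
#' 0.3; 3e6 transplanted cells per mouse (about 1250 cells per barcode,
#' inside the 1000-2000 representation band); 3 tumor replicates in each of
#' 4 models; ~10 population doublings in vivo; 5e6 reads per sample.
#'
#' @param n_genes Targeting genes (default 237).
#' @param hairpins_per_gene Hairpins per targeting gene (default 10).
#' @param control_hairpins Hairpins per control gene (default 10).
#' @param library_skew_alpha Symmetric Dirichlet concentration for the
#'   reference pool proportions; larger = more even (default 50).
#' @param moi Multiplicity of infection; metadata only under the
#'   single-integration assumption (default 0.3).
#' @param cells_per_mouse Cells transplanted per mouse (default 3e6).
#' @param tumor_replicates Tumor replicates per model (default 3).
#' @param n_models PDX models, i.e. screens (default 4).
#' @param doublings In vivo population doublings of neutral cells
#'   (default 10).
#' @param depth Sequencing reads per sample (default 5e6).
#' @param seq_error_rate Per-base substitution rate in written FASTQ
#'   (default 0.001).
#' @param read_length Read length for written FASTQ (default 50).
#' @param n_common_essential Pan-model essential genes planted in every
#'   model (default 5).
#' @param n_model_essential Additional model-specific essential genes per
#'   model (default 3).
#' @param essential_effect Essentiality effect s in `[0, 1]` for planted
#'   genes (default 0.5).
#' @param positive_control_effect Effect for positive-control genes
#'   (default 0.8).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 237L, hairpins_per_gene = 10L,
                       control_hairpins = 10L, library_skew_alpha = 50,
                       moi = 0.3, cells_per_mouse = 3e6,
                       tumor_replicates = 3L, n_models = 4L,
                       doublings = 10, depth = 5e6,
                       seq_error_rate = 0.001, read_length = 50L,
                       n_common_essential = 5L, n_model_essential = 3L,
                       essential_effect = 0.5, positive_control_effect = 0.8) {
  cfg <- list(n_genes = as.integer(n_genes),
              hairpins_per_gene = as.integer(hairpins_per_gene),
              control_hairpins = as.integer(control_hairpins),
              library_skew_alpha = library_skew_alpha, moi = moi,
              cells_per_mouse = cells_per_mouse,
              tumor_replicates = as.integer(tumor_replicates),
              n_models = as.integer(n_models), doublings = doublings,
              depth = depth, seq_error_rate = seq_error_rate,
              read_length = as.integer(read_length),
              n_common_essential = as.integer(n_common_essential),
              n_model_essential = as.integer(n_model_essential),
              essential_effect = essential_effect,
              positive_control_effect = positive_control_effect)
  pos_nums <- c("n_genes", "hairpins_per_gene", "library_skew_alpha",
                "cells_per_mouse", "tumor_replicates", "n_models",
                "doublings", "read_length")
  for (f in pos_nums) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) abort(paste0(f, " must be positive"))
  }
  if (cfg$moi <= 0 || cfg$moi > 1.5) abort("moi must lie in (0, 1.5]")
  if (cfg$seq_error_rate < 0 || cfg$seq_error_rate > 1) {
    abort("seq_error_rate must lie in [0, 1]")
  }
  if (cfg$essential_effect < 0 || cfg$essential_effect > 1 ||
      cfg$positive_control_effect < 0 || cfg$positive_control_effect > 1) {
    abort("effect sizes must lie in [0, 1]")
  }
  if (cfg$read_length < 40L) abort("read_length must be >= 40 for the targeting layout")
  structure(cfg, class = "sim_config")
}

# Random barcodes with pairwise Hamming distance >= 3: oversample random
# 18-mers, score all pairs via a one-hot inner product (matches = 18 - d),
# drop one member of any close pair.
random_barcodes <- function(n, length = 18L, min_dist = 3L, seed = 1L,
                            max_rounds = 20L) {
  bases <- c("A", "C", "G", "T")
  with_local_seed(seed, {
    for (round in seq_len(max_rounds)) {
      m <- ceiling(n * 1.3) + 16L
      mat <- matrix(sample(bases, m * length, replace = TRUE), nrow = m)
      seqs <- apply(mat, 1, paste0, collapse = "")
      onehot <- matrix(0, nrow = m, ncol = length * 4L)
      for (b in seq_along(bases)) {
        onehot[, (seq_len(length) - 1L) * 4L + b] <- (mat == bases[b])
      }
      sim <- tcrossprod(onehot)
      diag(sim) <- 0
      drop <- logical(m)
      close <- which(sim >= length - min_dist + 1L, arr.ind = TRUE)
      close <- close[close[, 1] < close[, 2], , drop = FALSE]
      for (k in seq_len(nrow(close))) {
        i <- close[k, 1]; j <- close[k, 2]
        if (!drop[i] && !drop[j]) drop[j] <- TRUE
      }
      keep <- seqs[!drop]
      if (length(keep) >= n) return(keep[seq_len(n)])
    }
    abort("could not satisfy the barcode distance constraint")
  })
}

#' Build a synthetic shRNA library
#'
#' Targeting genes are named `CRG001..CRGnnn`; the control genes RPL30 and
#' PSMA1 (positive) and LUC (negative) each carry `control_hairpins`
#' hairpins. Barcodes are random 18-mers kept at pairwise Hamming distance
#' >= 3 so single-mismatch assignment is unambiguous.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return An [shrna_library()].
#' @export
build_library <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sprintf("CRG%03d", seq_len(config$n_genes))
  tab <- dplyr::bind_rows(
    tidyr::expand_grid(gene = genes, sh = seq_len(config$hairpins_per_gene)) |>
      dplyr::mutate(class = "targeting"),
    tidyr::expand_grid(gene = c("RPL30", "PSMA1"),
                       sh = seq_len(config$control_hairpins)) |>
      dplyr::mutate(class = "positive_control"),
    tidyr::expand_grid(gene = "LUC", sh = seq_len(config$control_hairpins)) |>
      dplyr::mutate(class = "negative_control")
  )
  tab$hairpin_id <- sprintf("%s_sh%02d", tab$gene, tab$sh)
  tab$barcode <- random_barcodes(nrow(tab), seed = derive_seed(seed, 1L))
  shrna_library(tab[c("hairpin_id", "barcode", "gene", "class")])
}

# Ground truth: which genes are essential where, how strongly, and how
# effective each individual hairpin is. Efficacy is fixed per hairpin across
# models (it is a property of the hairpin sequence): 8 of 10 hairpins are
# potent (Beta(5,1)), 2 of 10 weak (Beta(1,3)).
make_sim_truth <- function(library, config, seed) {
  targeting <- unique(library$gene[library$class == "targeting"])
  with_local_seed(seed, {
    # planted sets are capped by the gene pool for small test libraries
    pan <- sample(targeting, min(config$n_common_essential, length(targeting)))
    remaining <- setdiff(targeting, pan)
    model_specific <- list()
    for (m in seq_len(config$n_models)) {
      picked <- sample(remaining,
                       min(config$n_model_essential, length(remaining)))
      remaining <- setdiff(remaining, picked)
      model_specific[[paste0("M", m)]] <- picked
    }
    n_hp <- nrow(library)
    weak <- rep(FALSE, n_hp)
    for (g in unique(library$gene)) {
      idx <- which(library$gene == g)
      n_weak <- floor(length(idx) * 0.2)
      if (n_weak > 0) weak[sample(idx, n_weak)] <- TRUE
    }
    efficacy <- ifelse(weak, rbeta(n_hp, 1, 3), rbeta(n_hp, 5, 1))
  })
  gene_effects <- purrr::map_dfr(seq_len(config$n_models), function(m) {
    model <- paste0("M", m)
    genes <- unique(library$gene)
    effect <- numeric(length(genes))
    effect[genes %in% c(pan, model_specific[[model]])] <- config$essential_effect
    effect[genes %in% c("RPL30", "PSMA1")] <- config$positive_control_effect
    tibble(model = model, gene = genes, effect = effect)
  })
  structure(list(pan_essential = sort(pan),
                 model_essential = model_specific,
                 gene_effects = gene_effects,
                 hairpin_efficacy = tibble(hairpin_id = library$hairpin_id,
                                           efficacy = efficacy)),
            class = "sim_truth")
}

#' Simulate the pre-transplantation reference pool
#'
#' Pool proportions are drawn from a symmetric Dirichlet (concentration
#' `library_skew_alpha`) to mimic uneven plasmid representation; reads are a
#' multinomial draw of `depth` reads over those proportions.
#'
#' @param library An [shrna_library()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `counts` (named integer vector) and `proportions`.
#' @export
simulate_reference <- function(library, config = sim_config(), seed = 1L) {
  n <- nrow(library)
  with_local_seed(seed, {
    g <- rgamma(n, shape = config$library_skew_alpha, rate = 1)
    props <- g / sum(g)
    counts <- if (config$depth > 0) {
      as.integer(rmultinom(1, size = config$depth, prob = props))
    } else {
      integer(n)
    }
  })
  list(counts = setNames(counts, library$hairpin_id),
       proportions = setNames(props, library$hairpin_id))
}

#' Simulate one tumor replicate
#'
#' Engraftment is a single multinomial bottleneck of `cells_per_mouse`
#' cells over the reference pool proportions. Each engrafted cell population
#' then grows deterministically for `doublings` doublings at relative
#' fitness `f = 1 - s_gene x e_hairpin`, so a fully effective hairpin
#' against a gene with effect s = 0.5 ends ~5 log2 units below neutral
#' barcodes. Sequencing is a multinomial draw of `depth` reads over the
#' post-growth cell mass.
#'
#' @param reference_proportions Named pool proportions from
#'   [simulate_reference()].
#' @param library An [shrna_library()].
#' @param truth A `sim_truth` (from [make_screen_suite()]).
#' @param model Model id, e.g. `"M1"`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Named integer count vector.
#' @export
simulate_tumor <- function(reference_proportions, library, truth, model,
                           config = sim_config(), seed = 1L) {
  ge <- truth$gene_effects[truth$gene_effects$model == model, ]
  s <- ge$effect[match(library$gene, ge$gene)]
  e <- truth$hairpin_efficacy$efficacy[
    match(library$hairpin_id, truth$hairpin_efficacy$hairpin_id)]
  fitness <- 1 - s * e
  with_local_seed(seed, {
    engrafted <- rmultinom(1, size = config$cells_per_mouse,
                           prob = reference_proportions)[, 1]
    w <- engrafted * 2^(config$doublings * fitness)
    counts <- if (sum(w) > 0 && config$depth > 0) {
      as.integer(rmultinom(1, size = config$depth, prob = w / sum(w)))
    } else {
      integer(nrow(library))
    }
  })
  setNames(counts, library$hairpin_id)
}

#' Write simulated counts as a raw FASTQ file
#'
#' Emits one read per count unit in the targeting amplicon layout: a fixed
#' 17-nt stub, the CGAA spacer at positions 18--21, one linker base at 22,
#' the 18-nt barcode at 23--40, then filler to `read_length`. Per-base
#' substitution errors are applied at `seq_error_rate`. With an error rate
#' of zero, deconvolution reproduces `counts` exactly.
#'
#' @param counts Named count vector aligned to the library.
#' @param library An [shrna_library()].
#' @param path Output path; a `.gz` suffix writes gzip-compressed FASTQ.
#' @param config A [sim_config()] (read length, error rate).
#' @param seed Integer seed for error placement.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(counts, library, path, config = sim_config(), seed = 1L) {
  stopifnot(length(counts) == nrow(library))
  stub <- "GTACCTGAAACTGGCTT"           # positions 1-17
  linker <- "A"                          # position 22
  filler <- strrep("TCGA", 64L)
  tail_len <- config$read_length - 40L
  reads <- rep(paste0(stub, SPACER_SEQ, linker, library$barcode,
                      substr(filler, 1L, tail_len)),
               times = counts)
  n <- length(reads)
  if (n > 0 && config$seq_error_rate > 0) {
    with_local_seed(seed, {
      n_err <- rbinom(n, config$read_length, config$seq_error_rate)
      hit <- which(n_err > 0)
      bases <- c("A", "C", "G", "T")
      for (i in hit) {
        pos <- sample.int(config$read_length, n_err[i])
        for (p in pos) {
          cur <- substr(reads[i], p, p)
          substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1)
        }
      }
    })
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (n > 0) {
    qual <- strrep("I", config$read_length)
    block <- paste0("@read_", seq_len(n), "\n", reads, "\n+\n", qual)
    writeLines(block, con)
  }
  invisible(path)
}

#' Average cells per barcode at transplantation
#'
#' The in vivo representation implied by the configuration:
#' `cells_per_mouse / library size`. The default (3e6 cells over 2,400
#' barcodes) gives 1,250 cells/barcode, inside the 1000--2000 band the
#' screen design targets.
#'
#' @param config A [sim_config()].
#' @param library Optional [shrna_library()]; defaults to the size implied
#'   by the config.
#' @return Scalar cells per barcode.
#' @export
cells_per_barcode <- function(config = sim_config(), library = NULL) {
  n <- if (is.null(library)) {
    config$n_genes * config$hairpins_per_gene + 3L * config$control_hairpins
  } else {
    nrow(library)
  }
  config$cells_per_mouse / n
}

#' Generate a complete multi-model screen suite
#'
#' One shared library; per model: one reference pool plus `tumor_replicates`
#' tumors, with the configured pan-model essential set planted in every
#' model and `n_model_essential` extra essentials unique to each model.
#' All randomness derives deterministically from `seed` per
#' (model, replicate, stage).
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed.
#' @param library Optional prebuilt [shrna_library()] (e.g. to share one
#'   library across many simulated suites); default builds one from the
#'   seed.
#' @param fastq_dir If non-`NULL`, writes one FASTQ.gz per sample into this
#'   directory and records paths in the sample sheet.
#' @param null_effects If `TRUE`, zeroes every essentiality effect
#'   (including controls): a pure-noise suite for null calibration.
#' @return List of class `screen_suite`: `library`, `counts`
#'   ([screen_counts()]), `truth` (`sim_truth`), `config`, `seed`,
#'   `infected_fraction` (1 - exp(-MOI)).
#' @export
make_screen_suite <- function(config = sim_config(), seed = 1L, library = NULL,
                              fastq_dir = NULL, null_effects = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(library)) library <- build_library(config, seed = derive_seed(seed, 0L))
  truth <- make_sim_truth(library, config, seed = derive_seed(seed, 1L))
  if (null_effects) {
    truth$gene_effects$effect <- 0
    truth$pan_essential <- character(0)
    truth$model_essential <- purrr::map(truth$model_essential, ~character(0))
  }
  models <- paste0("M", seq_len(config$n_models))
  counts <- tibble(hairpin_id = library$hairpin_id)
  rows <- list()
  for (mi in seq_along(models)) {
    model <- models[mi]
    ref <- simulate_reference(library, config, seed = derive_seed(seed, 2L, mi))
    ref_id <- paste0(model, "_ref")
    counts[[ref_id]] <- unname(ref$counts)
    rows[[length(rows) + 1]] <- tibble(sample_id = ref_id, screen_id = model,
                                       role = "reference", replicate = NA_integer_)
    for (r in seq_len(config$tumor_replicates)) {
      tum_id <- paste0(model, "_T", r)
      counts[[tum_id]] <- unname(
        simulate_tumor(ref$proportions, library, truth, model, config,
                       seed = derive_seed(seed, 3L, mi, r)))
      rows[[length(rows) + 1]] <- tibble(sample_id = tum_id, screen_id = model,
                                         role = "tumor_replicate", replicate = r)
    }
  }
  samples <- dplyr::bind_rows(rows)
  if (!is.null(fastq_dir)) {
    dir.create(fastq_dir, showWarnings = FALSE, recursive = TRUE)
    samples$fastq <- file.path(fastq_dir, paste0(samples$sample_id, ".fastq.gz"))
    for (i in seq_len(nrow(samples))) {
      write_fastq(counts[[samples$sample_id[i]]], library, samples$fastq[i],
                  config = config, seed = derive_seed(seed, 4L, i))
    }
  }
  structure(list(library = library,
                 counts = screen_counts(counts, sample_sheet(samples),
                                        library = library),
                 truth = truth, config = config, seed = seed,
                 infected_fraction = 1 - exp(-config$moi)),
            class = "screen_suite")
}

#' @export
print.screen_suite <- function(x, ...) {
  cat("<screen_suite> ", nrow(x$library), " hairpins, ",
      x$config$n_models, " models x (1 reference + ",
      x$config$tumor_replicates, " tumors), seed ", x$seed, "\n", sep = "")
  cat("  pan-model essentials: ",
      paste(x$truth$pan_essential, collapse = ", "), "\n", sep = "")
  invisible(x)
}
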