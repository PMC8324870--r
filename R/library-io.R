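#' Construct and validate an shRNA library manifest
#'
#' An shRNA library is a tibble with one row per hairpin and columns
#' `hairpin_id`, `barcode`, `gene` and `class`. Each hairpin carries a unique
#' DNA barcode that is read out by amplicon sequencing; `class` distinguishes
#' targeting hairpins from positive controls (essential housekeeping genes
#' such as RPL30 or PSMA1, expected to deplete) and negative controls
#' (e.g. luciferase, LUC, expected to stay flat).
#'
#' @param entries Data frame with columns `hairpin_id`, `barcode`, `gene`,
#'   `class`. Gene symbols are taken verbatim (case-sensitive).
#' @param library_type `"targeting_layout"` (barcodes read from positions
#'   23--40 of each read, all barcodes 18 nt) or `"nontargeting_layout"`
#'   (barcodes read from positions 1--18).
#' @return A tibble of class `shrna_library`.
#' @examples
#' shrna_library(data.frame(
#'   hairpin_id = c("G1_sh1", "G1_sh2"),
#'   barcode = c("ACGTACGTACGTACGTAC", "TTGCATGCATGCATGCAT"),
#'   gene = "G1", class = "targeting"
#' ))
#' @export
shrna_library <- function(entries,
                          library_type = c("targeting_layout", "nontargeting_layout")) {
  library_type <- match.arg(library_type)
  required <- c("hairpin_id", "barcode", "gene", "class")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0) {
    abort(paste0("library manifest is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  lib <- as_tibble(entries)[required]
  lib$hairpin_id <- as.character(lib$hairpin_id)
  lib$barcode <- toupper(as.character(lib$barcode))
  lib$gene <- as.character(lib$gene)
  lib$class <- as.character(lib$class)

  if (nrow(lib) == 0) abort("library manifest has no entries")
  if (anyDuplicated(lib$hairpin_id) > 0) {
    dup <- unique(lib$hairpin_id[duplicated(lib$hairpin_id)])
    abort(paste0("duplicate hairpin_id in library: ", paste(head(dup, 3), collapse = ", ")))
  }
  if (anyDuplicated(lib$barcode) > 0) {
    dup <- unique(lib$barcode[duplicated(lib$barcode)])
    abort(paste0("duplicate barcode in library: ", paste(head(dup, 3), collapse = ", ")))
  }
  if (any(!nzchar(lib$gene) | is.na(lib$gene))) {
    abort("every library entry must carry a non-empty gene symbol")
  }
  bad_class <- setdiff(unique(lib$class),
                       c("targeting", "positive_control", "negative_control"))
  if (length(bad_class) > 0) {
    abort(paste0("unknown hairpin class: ", paste(bad_class, collapse = ", ")))
  }
  if (library_type == "targeting_layout" && any(nchar(lib$barcode) != 18L)) {
    abort("targeting-layout barcodes must all be 18 nt")
  }
  if (any(grepl("[^ACGTN]", lib$barcode))) {
    abort("barcodes must use the A/C/G/T/N alphabet")
  }
  structure(lib,
            class = c("shrna_library", class(tibble())),
            library_type = library_type)
}

#' @export
print.shrna_library <- function(x, ...) {
  cat("<shrna_library> ", nrow(x), " hairpins, ",
      length(unique(x$gene[x$class == "targeting"])), " targeting genes (",
      attr(x, "library_type"), ")\n", sep = "")
  NextMethod()
}

#' Read / write an shRNA library manifest
#'
#' The manifest is a tab-separated file with a mandatory header and columns
#' `hairpin_id`, `barcode`, `gene`, `class`.
#'
#' @param path Path to a manifest TSV.
#' @param library_type See [shrna_library()].
#' @return [read_shrna_library()] returns a validated `shrna_library`;
#'   [write_shrna_library()] returns `path` invisibly.
#' @export
read_shrna_library <- function(path, library_type = "targeting_layout") {
  if (!file.exists(path)) abort(paste0("library manifest not found: ", path))
  raw <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character())),
    error = function(e) abort(paste0("failed to parse library manifest ", path, ": ",
                                     conditionMessage(e)))
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed manifest row at line ", probs$row[1] + 1L, " of ", path))
  }
  shrna_library(raw, library_type = library_type)
}

#' @rdname read_shrna_library
#' @param library An `shrna_library`.
#' @export
write_shrna_library <- function(library, path) {
  stopifnot(inherits(library, "shrna_library"))
  readr::write_tsv(as_tibble(library), path)
  invisible(path)
}

#' Construct a sample sheet
#'
#' Maps sequenced samples to screens and roles. Each screen (one
#' patient-derived xenograft model) must have exactly one pre-transplantation
#' reference sample and at least one tumor replicate.
#'
#' @param samples Data frame with columns `sample_id`, `screen_id`, `role`
#'   (`"reference"` or `"tumor_replicate"`) and optionally `replicate`
#'   (integer index among tumor replicates) and `fastq` (path).
#' @return A tibble of class `sample_sheet`.
#' @export
sample_sheet <- function(samples) {
  required <- c("sample_id", "screen_id", "role")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    abort(paste0("sample sheet is missing column(s): ", paste(missing, collapse = ", ")))
  }
  ss <- as_tibble(samples)
  ss$sample_id <- as.character(ss$sample_id)
  ss$screen_id <- as.character(ss$screen_id)
  ss$role <- as.character(ss$role)
  if (!"replicate" %in% names(ss)) {
    ss <- ss |>
      dplyr::group_by(.data$screen_id) |>
      dplyr::mutate(replicate = ifelse(.data$role == "tumor_replicate",
                                       cumsum(.data$role == "tumor_replicate"),
                                       NA_integer_)) |>
      dplyr::ungroup()
  }
  if (anyDuplicated(ss$sample_id) > 0) abort("duplicate sample_id in sample sheet")
  bad_role <- setdiff(unique(ss$role), c("reference", "tumor_replicate"))
  if (length(bad_role) > 0) {
    abort(paste0("unknown sample role: ", paste(bad_role, collapse = ", ")))
  }
  counts <- table(ss$screen_id, ss$role)
  for (scr in rownames(counts)) {
    n_ref <- if ("reference" %in% colnames(counts)) counts[scr, "reference"] else 0L
    n_tum <- if ("tumor_replicate" %in% colnames(counts)) counts[scr, "tumor_replicate"] else 0L
    if (n_ref != 1L) {
      abort(paste0("screen ", scr, " must have exactly one reference sample (found ",
                   n_ref, ")"))
    }
    if (n_tum < 1L) {
      abort(paste0("screen ", scr, " must have at least one tumor replicate"))
    }
  }
  structure(ss, class = c("sample_sheet", class(tibble())))
}

#' Construct a screen count object
#'
#' Bundles the per-hairpin read-count matrix with the sample sheet and
#' per-sample deconvolution tallies. Rows of `counts` must exactly match the
#' library's hairpins; unassigned reads are carried per sample in `tallies`,
#' never as a matrix row, so the matrix row count equals the library size N
#' used by downstream rank statistics.
#'
#' @param counts Tibble with `hairpin_id` plus one non-negative integer
#'   column per sample.
#' @param samples A [sample_sheet()] (or data frame coercible to one).
#' @param library Optional `shrna_library`; when given, rows are checked and
#'   reordered to match it.
#' @param tallies Optional tibble with columns `sample_id`, `total_reads`,
#'   `spacer_fail`, `extraction_fail`, `unassigned`. Defaults to tallies with
#'   only assigned reads.
#' @return A list of class `screen_counts` with elements `counts`, `samples`,
#'   `tallies`.
#' @export
screen_counts <- function(counts, samples, library = NULL, tallies = NULL) {
  counts <- as_tibble(counts)
  if (!"hairpin_id" %in% names(counts)) abort("counts must have a hairpin_id column")
  sample_ids <- setdiff(names(counts), "hairpin_id")
  if (length(sample_ids) == 0) abort("count matrix has no sample columns")
  if (!inherits(samples, "sample_sheet")) samples <- sample_sheet(samples)
  if (!setequal(sample_ids, samples$sample_id)) {
    abort("count matrix columns do not match the sample sheet")
  }
  counts <- counts[c("hairpin_id", samples$sample_id)]
  for (s in samples$sample_id) {
    if (!is_count_vector(counts[[s]])) {
      abort(paste0("counts for sample ", s, " must be non-negative integers"))
    }
    counts[[s]] <- as.integer(counts[[s]])
  }
  if (anyDuplicated(counts$hairpin_id) > 0) abort("duplicate hairpin_id in count matrix")
  if (!is.null(library)) {
    if (!setequal(counts$hairpin_id, library$hairpin_id)) {
      abort("count matrix rows do not match the library entries")
    }
    counts <- counts[match(library$hairpin_id, counts$hairpin_id), ]
  }
  assigned <- vapply(samples$sample_id, function(s) sum(counts[[s]]), double(1))
  if (is.null(tallies)) {
    tallies <- tibble(sample_id = samples$sample_id,
                      total_reads = unname(assigned),
                      spacer_fail = 0, extraction_fail = 0, unassigned = 0)
  }
  tallies <- as_tibble(tallies)
  req <- c("sample_id", "total_reads", "spacer_fail", "extraction_fail", "unassigned")
  if (!all(req %in% names(tallies))) {
    abort(paste0("tallies must have columns: ", paste(req, collapse = ", ")))
  }
  tallies <- tallies[match(samples$sample_id, tallies$sample_id), req]
  conserved <- tallies$total_reads ==
    assigned + tallies$unassigned + tallies$spacer_fail + tallies$extraction_fail
  if (any(!conserved)) {
    abort(paste0("read conservation violated for sample(s): ",
                 paste(samples$sample_id[!conserved], collapse = ", ")))
  }
  structure(list(counts = counts, samples = samples, tallies = tallies),
            class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat("<screen_counts> ", nrow(x$counts), " hairpins x ", nrow(x$samples),
      " samples across ", length(unique(x$samples$screen_id)), " screen(s)\n", sep = "")
  invisible(x)
}

#' Write / read a screen count matrix
#'
#' Counts go to a tab-separated file (first column `hairpin_id`, one integer
#' column per sample); sample roles and per-sample tallies go to a JSON
#' sidecar at `<path>.json`. The round trip is lossless.
#'
#' @param x A `screen_counts` object.
#' @param path Path for the counts TSV.
#' @return [write_counts()] returns `path` invisibly; [read_counts()] returns
#'   a `screen_counts`.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "screen_counts"))
  readr::write_tsv(x$counts, path)
  sidecar <- list(samples = as.data.frame(x$samples),
                  tallies = as.data.frame(x$tallies))
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_counts
#' @param library Optional `shrna_library` used to validate rows.
#' @export
read_counts <- function(path, library = NULL) {
  if (!file.exists(path)) abort(paste0("counts file not found: ", path))
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    abort(paste0("counts sidecar not found: ", sidecar_path))
  }
  counts <- readr::read_tsv(path, col_types = readr::cols(
    hairpin_id = readr::col_character(), .default = readr::col_double()))
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  samples <- as_tibble(sidecar$samples)
  if ("replicate" %in% names(samples)) {
    samples$replicate <- as.integer(samples$replicate)
  }
  screen_counts(counts, sample_sheet(samples), library = library,
                tallies = as_tibble(sidecar$tallies))
}
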