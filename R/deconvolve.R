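# Read deconvolution: spacer filter, positional barcode extraction,
# mismatch-tolerant matching against the library.
#
# Coordinates in the user-facing API are 1-based inclusive, matching how
# amplicon layouts are described at the bench; they are converted to
# substring bounds in exactly one place (the constants below).

SPACER_SEQ <- "CGAA"
SPACER_START <- 18L   # spacer occupies bases 18-21
SPACER_END <- 21L
BARCODE_START_TARGETING <- 23L  # barcode occupies bases 23-40; base 22 ignored
BARCODE_END_TARGETING <- 40L
BARCODE_LEN <- 18L

#' Spacer filter for targeting-layout reads
#'
#' A read passes if the 4 bases at positions 18--21 (1-based) differ from the
#' `CGAA` spacer at no more than one position. `N` bases count as mismatches.
#' Reads shorter than 21 nt fail (they are tallied as spacer failures, never
#' raised as errors).
#'
#' @param sequences Character vector of read sequences.
#' @param max_mismatch Allowed spacer mismatches (default 1).
#' @return Logical vector.
#' @examples
#' match_spacer(paste0(strrep("A", 17), "CGAT", "ACGT")) # one mismatch: TRUE
#' @export
match_spacer <- function(sequences, max_mismatch = 1L) {
  long_enough <- !is.na(sequences) & nchar(sequences) >= SPACER_END
  out <- rep(FALSE, length(sequences))
  if (!any(long_enough)) return(out)
  spacer <- substr(sequences[long_enough], SPACER_START, SPACER_END)
  mm <- rep(0L, length(spacer))
  for (k in seq_len(4L)) {
    mm <- mm + (substr(spacer, k, k) != substr(SPACER_SEQ, k, k))
  }
  out[long_enough] <- mm <= max_mismatch
  out
}

#' Extract the 18-nt barcode from reads
#'
#' Targeting layout: positions 23--40 (1-based inclusive). Nontargeting
#' layout: positions 1--18. Reads too short for the window return `NA`
#' (tallied as extraction failures by [count_sample()]).
#'
#' @param sequences Character vector of read sequences.
#' @param layout `"targeting_layout"` or `"nontargeting_layout"`.
#' @return Character vector of 18-nt barcodes (or `NA`).
#' @export
extract_barcode <- function(sequences,
                            layout = c("targeting_layout", "nontargeting_layout")) {
  layout <- match.arg(layout)
  if (layout == "targeting_layout") {
    from <- BARCODE_START_TARGETING; to <- BARCODE_END_TARGETING
  } else {
    from <- 1L; to <- BARCODE_LEN
  }
  out <- rep(NA_character_, length(sequences))
  ok <- !is.na(sequences) & nchar(sequences) >= to
  out[ok] <- substr(sequences[ok], from, to)
  out
}

#' Precompute a mismatch-tolerant barcode matcher
#'
#' Builds the exact-match table plus the map from every Hamming-distance-1
#' neighbour of a library barcode back to its hairpin. Neighbours reachable
#' from two or more distinct barcodes are marked ambiguous and resolve to
#' unassigned. Building the matcher once and reusing it across samples avoids
#' recomputing ~54 neighbours per barcode for every FASTQ.
#'
#' @param library An [shrna_library()].
#' @return An opaque matcher object for [assign_barcode()] / [count_sample()].
#' @export
barcode_matcher <- function(library) {
  stopifnot(inherits(library, "shrna_library"))
  bc <- library$barcode
  len <- unique(nchar(bc))
  if (length(len) != 1L) abort("barcode matcher requires equal-length barcodes")
  bases <- c("A", "C", "G", "T")
  neighbours <- vector("list", len * 3L)
  origin <- vector("list", len * 3L)
  slot <- 0L
  for (pos in seq_len(len)) {
    prefix <- substr(bc, 1L, pos - 1L)
    suffix <- substr(bc, pos + 1L, len)
    cur <- substr(bc, pos, pos)
    for (b in bases) {
      keep <- cur != b
      if (!any(keep)) next
      slot <- slot + 1L
      neighbours[[slot]] <- paste0(prefix[keep], b, suffix[keep])
      origin[[slot]] <- library$hairpin_id[keep]
    }
  }
  nb <- unlist(neighbours[seq_len(slot)], use.names = FALSE)
  hp <- unlist(origin[seq_len(slot)], use.names = FALSE)
  # ambiguous neighbours (reachable from >1 barcode) resolve to unassigned;
  # a neighbour that is itself a library barcode is shadowed by exact lookup
  dup <- duplicated(nb) | duplicated(nb, fromLast = TRUE)
  if (any(dup)) {
    hp[dup] <- NA_character_
    keep <- !duplicated(nb)
    nb <- nb[keep]
    hp <- hp[keep]
  }
  structure(list(barcodes = bc, hairpins = library$hairpin_id,
                 neighbour_seq = nb, neighbour_hairpin = hp,
                 barcode_length = len),
            class = "barcode_matcher")
}

#' Assign extracted barcodes to library hairpins
#'
#' Exact matches win; otherwise a sequence is assigned to a hairpin if it is
#' within Hamming distance 1 of exactly one library barcode; anything else
#' (including distance-1 ties between two barcodes) is unassigned (`NA`).
#'
#' @param sequences Character vector of 18-nt sequences.
#' @param library An [shrna_library()] or a prebuilt [barcode_matcher()].
#' @return Character vector of hairpin ids, `NA` where unassigned.
#' @export
assign_barcode <- function(sequences, library) {
  matcher <- if (inherits(library, "barcode_matcher")) library else barcode_matcher(library)
  out <- rep(NA_character_, length(sequences))
  ok <- !is.na(sequences) & nchar(sequences) == matcher$barcode_length
  idx <- match(sequences[ok], matcher$barcodes)
  res <- matcher$hairpins[idx]
  miss <- is.na(idx)
  if (any(miss)) {
    j <- match(sequences[ok][miss], matcher$neighbour_seq)
    res[miss] <- matcher$neighbour_hairpin[j]
  }
  out[ok] <- res
  out
}

#' Deconvolute one FASTQ sample into per-hairpin counts
#'
#' Applies the spacer filter (targeting layout), extracts the barcode window,
#' matches against the library, and tallies every read into exactly one of:
#' assigned, unassigned, spacer failure, extraction failure. Plain and
#' gzip-compressed FASTQ are accepted; base qualities are ignored.
#'
#' @param path FASTQ(.gz) path.
#' @param library An [shrna_library()].
#' @param matcher Optional prebuilt [barcode_matcher()] (saves time when
#'   counting many samples against one library).
#' @return List with `counts` (named integer vector aligned to the library)
#'   and `tallies` (`total_reads`, `spacer_fail`, `extraction_fail`,
#'   `assigned`, `unassigned`).
#' @export
count_sample <- function(path, library, matcher = NULL) {
  stopifnot(inherits(library, "shrna_library"))
  if (!file.exists(path)) abort(paste0("FASTQ not found: ", path))
  layout <- attr(library, "library_type")
  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(path, format = "fastq")),
    error = function(e) abort(paste0("failed to read FASTQ ", path, ": ",
                                     conditionMessage(e)))
  )
  n_total <- length(reads)
  counts <- setNames(integer(nrow(library)), library$hairpin_id)
  tallies <- list(total_reads = n_total, spacer_fail = 0L,
                  extraction_fail = 0L, assigned = 0L, unassigned = 0L)
  if (n_total == 0L) return(list(counts = counts, tallies = tallies))

  if (layout == "targeting_layout") {
    pass <- match_spacer(reads)
    tallies$spacer_fail <- sum(!pass)
    reads <- reads[pass]
  }
  bc <- extract_barcode(reads, layout)
  tallies$extraction_fail <- sum(is.na(bc))
  bc <- bc[!is.na(bc)]
  if (is.null(matcher)) matcher <- barcode_matcher(library)
  hp <- assign_barcode(bc, matcher)
  tallies$unassigned <- sum(is.na(hp))
  hp <- hp[!is.na(hp)]
  tallies$assigned <- length(hp)
  if (length(hp) > 0) {
    tab <- table(factor(hp, levels = library$hairpin_id))
    counts[] <- as.integer(tab)
  }
  stopifnot(tallies$assigned + tallies$unassigned + tallies$spacer_fail +
              tallies$extraction_fail == tallies$total_reads)
  list(counts = counts, tallies = tallies)
}

#' Deconvolute all samples of a screen suite from FASTQ
#'
#' @param samples A [sample_sheet()] whose `fastq` column points at one
#'   FASTQ(.gz) per sample.
#' @param library An [shrna_library()].
#' @return A [screen_counts()] object.
#' @export
deconvolve_samples <- function(samples, library) {
  if (!inherits(samples, "sample_sheet")) samples <- sample_sheet(samples)
  if (!"fastq" %in% names(samples)) abort("sample sheet needs a fastq column")
  matcher <- barcode_matcher(library)
  per_sample <- purrr::map(samples$fastq, count_sample,
                           library = library, matcher = matcher)
  counts <- tibble(hairpin_id = library$hairpin_id)
  for (i in seq_len(nrow(samples))) {
    counts[[samples$sample_id[i]]] <- unname(per_sample[[i]]$counts)
  }
  tallies <- purrr::map2_dfr(per_sample, samples$sample_id, function(x, sid) {
    tibble(sample_id = sid,
           total_reads = x$tallies$total_reads,
           spacer_fail = x$tallies$spacer_fail,
           extraction_fail = x$tallies$extraction_fail,
           unassigned = x$tallies$unassigned)
  })
  screen_counts(counts, samples, library = library, tallies = tallies)
}
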