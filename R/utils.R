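# Internal helpers shared across modules.

# Evaluate `code` with a locally fixed RNG state; the caller's RNG state is
# untouched. All randomised operations in the package route through this so a
# master seed yields byte-identical outputs.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

# Deterministic child-seed derivation: one master seed fans out to
# per-(model, replicate, stage) streams. Kept in [1, 2^31 - 2].
derive_seed <- function(master, ...) {
  idx <- c(...)
  x <- as.double(master) %% 2147483647
  for (k in idx) {
    x <- (x * 48271 + as.double(k) * 16807 + 11) %% 2147483647
  }
  as.integer(x + 1)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count_vector <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x == floor(x))
}
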