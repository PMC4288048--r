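# Internal helpers shared across modules.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# amino-acid alphabet accepted everywhere: the 20 residues plus X
aa_alphabet_ok <- function(seq) {
  grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seq)
}

assert_protein_alphabet <- function(seq, what = "sequence") {
  bad <- !aa_alphabet_ok(seq)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside the amino-acid alphabet (20 residues + X): %s",
                 what, paste(utils::head(seq[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# gap in bases strictly between two genes (0 when overlapping/adjacent)
intergenic_gap <- function(end_left, start_right) {
  max(0L, as.integer(start_right) - as.integer(end_left) - 1L)
}
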