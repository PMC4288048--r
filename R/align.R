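#' Global pairwise protein alignment
#'
#' Needleman–Wunsch global alignment with BLOSUM62 scoring and affine gaps:
#' a gap of length L costs 10 + L (gap-opening 10, gap-extension 1).  This
#' one engine, with fixed parameters, backs both reference-numbered residue
#' mapping and percent-identity computation, so the two always agree on
#' coordinates.
#'
#' @param a,b Amino-acid strings (20-letter alphabet plus X).
#' @return List with `score`, `aligned_a`, `aligned_b` (equal-length gapped
#'   strings).
#' @export
align_global <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1,
            nzchar(a), nzchar(b))
  assert_protein_alphabet(c(a, b), "alignment input")
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
  list(score = Biostrings::score(pa),
       aligned_a = as.character(Biostrings::alignedPattern(pa)),
       aligned_b = as.character(Biostrings::alignedSubject(pa)))
}
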