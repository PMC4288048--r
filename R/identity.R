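#' Pairwise percent identity between two proteins
#'
#' Globally aligns the pair (same engine and parameters as the residue
#' analysis) and computes 100 x identical residue pairs / denominator.  In
#' the default `"aligned_positions"` mode the denominator is the number of
#' columns where both sequences have a residue; in `"full_length"` mode it
#' is the full alignment length including gap columns, so it can never
#' exceed the default mode's value.
#'
#' @param a,b Amino-acid strings.
#' @param mode Denominator mode.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, mode = c("aligned_positions", "full_length")) {
  mode <- match.arg(mode)
  al <- align_global(a, b)
  x <- strsplit(al$aligned_a, "")[[1]]
  y <- strsplit(al$aligned_b, "")[[1]]
  both <- x != "-" & y != "-"
  ident <- sum(x == y & both)
  denom <- if (mode == "aligned_positions") sum(both) else length(x)
  100 * ident / denom
}

#' Pairwise percent-identity matrix
#'
#' @param proteins Tibble (`gene_id`, `sequence`) or named character vector.
#' @param mode See [pairwise_identity()].
#' @return Symmetric numeric matrix with a diagonal of exactly 100 and
#'   `gene_id` dimnames.
#' @export
identity_matrix <- function(proteins, mode = c("aligned_positions", "full_length")) {
  mode <- match.arg(mode)
  if (is.data.frame(proteins)) {
    seqs <- stats::setNames(proteins$sequence, proteins$gene_id)
  } else {
    seqs <- proteins
  }
  n <- length(seqs)
  stopifnot(n >= 1, !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- pairwise_identity(seqs[[i]], seqs[[j]], mode)
      m[i, j] <- v; m[j, i] <- v
    }
  }
  m
}

#' Within-locus vs cross-locus identity of double-LuxR partners
#'
#' For convergent double \emph{luxR-luxR-luxI} loci, each locus contributes
#' two partner regulators (slots A and B).  "Within-locus" compares the two
#' partners of one locus; "cross-locus" compares same-slot regulators across
#' loci (A vs A, B vs B).  The census's headline contrast is a low
#' within-locus identity against a potentially high cross-locus identity —
#' the signature of an ancient duplication followed by divergence.
#'
#' @param matrix Percent-identity matrix from [identity_matrix()].
#' @param groups Data frame with columns `gene_id`, `locus_id`, `slot`
#'   (`"A"`/`"B"`); must reference matrix labels only, with both slots
#'   present per locus.
#' @return List: `within` (tibble `locus_id`, `identity`), `within_min`,
#'   `within_max`, `within_mean`, `between` (tibble `slot`, `gene_a`,
#'   `gene_b`, `identity`), `between_max` (`NA` with a single locus).
#' @export
group_summary <- function(matrix, groups) {
  groups <- tibble::as_tibble(groups)
  unknown <- setdiff(groups$gene_id, rownames(matrix))
  if (length(unknown)) {
    stop("group references unknown label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  loci <- split(groups, groups$locus_id)
  within <- dplyr::bind_rows(lapply(loci, function(g) {
    stopifnot(nrow(g) == 2L, setequal(g$slot, c("A", "B")))
    tibble::tibble(locus_id = g$locus_id[1],
                   identity = matrix[g$gene_id[1], g$gene_id[2]])
  }))
  between <- tibble::tibble(slot = character(), gene_a = character(),
                            gene_b = character(), identity = numeric())
  for (sl in c("A", "B")) {
    ids <- groups$gene_id[groups$slot == sl]
    if (length(ids) > 1) {
      cmb <- utils::combn(ids, 2)
      between <- rbind(between, tibble::tibble(
        slot = sl, gene_a = cmb[1, ], gene_b = cmb[2, ],
        identity = matrix[cbind(cmb[1, ], cmb[2, ])]))
    }
  }
  list(within = within,
       within_min = min(within$identity), within_max = max(within$identity),
       within_mean = mean(within$identity),
       between = between,
       between_max = if (nrow(between)) max(between$identity) else NA_real_)
}

#' Write an identity matrix as TSV (labels in first row/column) and as a
#' long-format CSV
#'
#' @param matrix Matrix from [identity_matrix()].
#' @param tsv_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_identity_matrix <- function(matrix, tsv_path = NULL, csv_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- data.frame(gene_id = rownames(matrix), matrix, check.names = FALSE)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(csv_path)) {
    idx <- which(upper.tri(matrix, diag = TRUE), arr.ind = TRUE)
    long <- data.frame(gene_a = rownames(matrix)[idx[, 1]],
                       gene_b = colnames(matrix)[idx[, 2]],
                       identity = matrix[idx])
    long <- long[order(long$gene_a, long$gene_b), ]
    utils::write.table(long, csv_path, sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(c(tsv_path, csv_path))
}
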