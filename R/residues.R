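#' Build a reference site map
#'
#' A site map carries a reference protein sequence plus the positions that
#' are invariant across functionally validated homologs, in the reference's
#' own numbering (TraR numbering for regulators, TraI numbering for
#' synthases).
#'
#' @param reference_id Identifier, e.g. `"TraR"`.
#' @param sequence Reference amino-acid string.
#' @param sites Data frame with columns `position` (1-based), `expected`
#'   (single residue) and `role` (`autoinducer_binding`, `DNA_binding` or
#'   `synthase_active`).  May have zero rows (fill-in map).
#' @return List of class `site_map`.
#' @export
site_map <- function(reference_id, sequence, sites) {
  sequence <- toupper(sequence)
  assert_protein_alphabet(sequence, "reference sequence")
  sites <- tibble::as_tibble(sites)
  if (nrow(sites)) {
    stopifnot(all(c("position", "expected", "role") %in% names(sites)),
              all(sites$position >= 1), all(sites$position <= nchar(sequence)))
    at <- substring(sequence, sites$position, sites$position)
    bad <- at != sites$expected
    if (any(bad)) {
      stop("site map residue mismatch at position(s) ",
           paste(sites$position[bad], collapse = ", "),
           ": reference has ", paste(at[bad], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(reference_id = reference_id, sequence = sequence,
                 sites = sites), class = "site_map")
}

#' Load a site map from YAML
#'
#' @param path YAML with fields `reference_id`, `sequence`, `sites`
#'   (list of `{position, expected, role}`).
#' @return A [site_map()].
#' @export
read_site_map <- function(path) {
  y <- yaml::read_yaml(path)
  sites <- if (length(y$sites)) {
    dplyr::bind_rows(lapply(y$sites, function(s)
      tibble::tibble(position = as.integer(s$position),
                     expected = as.character(s$expected),
                     role = as.character(s$role))))
  } else {
    tibble::tibble(position = integer(), expected = character(),
                   role = character())
  }
  site_map(y$reference_id, gsub("\\s", "", y$sequence), sites)
}

#' Packaged reference site maps
#'
#' `site_map_trar()` carries the seven invariant regulator sites in TraR
#' numbering: the autoinducer-binding residues W57, Y61, D70 and W85 and the
#' DNA-binding residues E178, L182 and G188.  `site_map_trai()` is the
#' synthase map; its site list ships empty for the user to fill in (the ten
#' synthase-active residues are defined in the structural literature).  Both
#' reference sequences are deterministic synthetic stand-ins (see the
#' fixture files `inst/extdata/*_synthetic_sites.yaml`) constructed to carry
#' the expected residues at the stated positions; numbering, not provenance,
#' is what the analysis uses.
#'
#' @return A [site_map()].
#' @export
site_map_trar <- function() {
  read_site_map(system.file("extdata", "trar_synthetic_sites.yaml",
                            package = "luxcensus", mustWork = TRUE))
}

#' @rdname site_map_trar
#' @export
site_map_trai <- function() {
  read_site_map(system.file("extdata", "trai_synthetic_sites.yaml",
                            package = "luxcensus", mustWork = TRUE))
}

#' Align a query protein to a reference site map
#'
#' @param query Amino-acid string (or one-row protein tibble).
#' @param reference A [site_map()].
#' @return As [align_global()], query first.
#' @export
align_to_reference <- function(query, reference) {
  if (is.data.frame(query)) query <- query$sequence[1]
  align_global(query, reference$sequence)
}

#' Report conservation at reference-numbered sites
#'
#' Aligns the query to the reference (or reads a caller-supplied alignment,
#' e.g. two rows extracted from an external MSA) and, for every site in the
#' map, reads the query residue in the column aligned to that reference
#' position.  A match is `conserved`, a different residue is `substituted`
#' (labelled expected+position+observed, e.g. `"W57V"`), a gap is `missing`
#' (observed `"-"`).  The PAB-like flag is raised on the Y61W substitution —
#' the hallmark of plant-associated-bacteria LuxR solos.
#'
#' @param query Amino-acid string (or one-row protein tibble with columns
#'   `gene_id`, `sequence`).
#' @param reference A [site_map()].
#' @param alignment Optional list with `aligned_a` (query) and `aligned_b`
#'   (reference) gapped strings; when supplied no alignment is computed.
#' @param gene_id Identifier recorded in the report.
#' @return List of class `substitution_report`: `gene_id`, `reference_id`,
#'   `sites` tibble (`position`, `expected`, `observed`, `role`, `label`,
#'   `status`), `pab_like_flag`.
#' @export
check_conserved_sites <- function(query, reference, alignment = NULL,
                                  gene_id = NULL) {
  if (is.data.frame(query)) {
    if (is.null(gene_id) && "gene_id" %in% names(query)) gene_id <- query$gene_id[1]
    query <- query$sequence[1]
  }
  if (is.null(gene_id)) gene_id <- "query"
  if (is.null(alignment)) alignment <- align_to_reference(query, reference)
  qa <- strsplit(alignment$aligned_a, "")[[1]]
  ra <- strsplit(alignment$aligned_b, "")[[1]]
  stopifnot(length(qa) == length(ra))
  ref_pos <- cumsum(ra != "-")
  col_of <- match(seq_len(max(ref_pos)), ref_pos)

  s <- reference$sites
  observed <- character(nrow(s)); status <- character(nrow(s))
  for (k in seq_len(nrow(s))) {
    col <- col_of[s$position[k]]
    obs <- qa[col]
    observed[k] <- obs
    status[k] <- if (obs == "-") "missing"
    else if (obs == s$expected[k]) "conserved"
    else "substituted"
  }
  sites <- tibble::tibble(position = s$position, expected = s$expected,
                          observed = observed, role = s$role,
                          label = paste0(s$expected, s$position, observed),
                          status = status)
  structure(list(gene_id = gene_id, reference_id = reference$reference_id,
                 sites = sites,
                 pab_like_flag = any(sites$position == 61 &
                                       sites$expected == "Y" &
                                       sites$observed == "W")),
            class = "substitution_report")
}

#' @export
print.substitution_report <- function(x, ...) {
  cat(sprintf("Substitution report for %s vs %s\n", x$gene_id, x$reference_id))
  n_sub <- sum(x$sites$status == "substituted")
  cat(sprintf("  %d site(s): %d conserved, %d substituted, %d missing\n",
              nrow(x$sites), sum(x$sites$status == "conserved"),
              n_sub, sum(x$sites$status == "missing")))
  if (n_sub) cat("  substitutions:",
                 paste(x$sites$label[x$sites$status == "substituted"],
                       collapse = ", "), "\n")
  if (x$pab_like_flag) cat("  PAB-like flag: Y61W observed\n")
  invisible(x)
}
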