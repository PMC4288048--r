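#' Signature rule set for LuxR/LuxI authentication
#'
#' The two-tier rule the census applies: a Pfam-domain prefilter (profile-HMM
#' hit with e-value strictly below `evalue_max`) shortlists candidates, then
#' an InterPro signature completeness test authenticates them.  A LuxR
#' homolog must carry all four regulator signatures: IPR005143 (autoinducer
#' binding), IPR016032 (signal-transduction response regulator, C-terminal
#' effector), IPR011991 (winged helix-turn-helix DNA-binding) and IPR000792
#' (transcription regulator LuxR, C-terminal).  A LuxI homolog must carry
#' both IPR001690 (autoinducer synthesis protein) and IPR018311 (autoinducer
#' synthesis, conserved site).
#'
#' @param evalue_max Prefilter e-value ceiling (exclusive); default `1e-5`.
#' @param luxR_prefilter,luxI_prefilter Pfam accessions of the
#'   autoinducer-binding (PF03472) and autoinducer-synthase (PF00765)
#'   domains.
#' @param luxR_required,luxI_required InterPro accession sets that define
#'   completeness.
#' @return A list of class `signature_rules`.
#' @export
signature_rules <- function(evalue_max = 1e-5,
                            luxR_prefilter = "PF03472",
                            luxI_prefilter = "PF00765",
                            luxR_required = c("IPR005143", "IPR016032",
                                              "IPR011991", "IPR000792"),
                            luxI_required = c("IPR001690", "IPR018311")) {
  stopifnot(evalue_max > 0,
            length(luxR_required) >= 1, length(luxI_required) >= 1)
  structure(list(evalue_max = evalue_max,
                 luxR_prefilter = luxR_prefilter,
                 luxI_prefilter = luxI_prefilter,
                 luxR_required = luxR_required,
                 luxI_required = luxI_required),
            class = "signature_rules")
}

#' Load a signature rule set from YAML
#'
#' Any field omitted in the YAML keeps its default.
#'
#' @param path YAML file with any of the fields of [signature_rules()].
#' @return A `signature_rules` object.
#' @export
read_signature_rules <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- signature_rules()
  for (nm in intersect(names(y), names(defaults))) defaults[[nm]] <- y[[nm]]
  do.call(signature_rules, unclass(defaults))
}

#' Prefilter proteins on Pfam lux domains
#'
#' A gene is retained iff it has at least one hit whose signature belongs to
#' the LuxR or LuxI prefilter set with e-value strictly below
#' `rules$evalue_max`.  Hits without an e-value (InterProScan membership
#' rows) are treated as passing: with InterProScan input the prefilter is
#' advisory and authentication rests on the completeness test.
#'
#' @param hits Tibble of domain hits (`gene_id`, `signature_id`, `evalue`).
#' @param rules A [signature_rules()] object.
#' @return Character vector of retained `gene_id`s (sorted, unique).
#' @export
prefilter <- function(hits, rules = signature_rules()) {
  if (nrow(hits) == 0L) return(character(0))
  pf <- hits$signature_id %in% c(rules$luxR_prefilter, rules$luxI_prefilter)
  pass <- pf & (is.na(hits$evalue) | hits$evalue < rules$evalue_max)
  sort(unique(hits$gene_id[pass]))
}

verdict_one <- function(gene_id, sigs, rules) {
  sigs <- unique(sigs)
  r_present <- intersect(rules$luxR_required, sigs)
  r_missing <- setdiff(rules$luxR_required, sigs)
  i_present <- intersect(rules$luxI_required, sigs)
  i_missing <- setdiff(rules$luxI_required, sigs)
  is_luxr <- length(r_missing) == 0L
  is_luxi <- length(i_missing) == 0L
  row <- function(verdict, present, missing, trunc = FALSE, dual = FALSE) {
    tibble::tibble(gene_id = gene_id, verdict = verdict,
                   present_signatures = paste(sort(present), collapse = ";"),
                   missing_signatures = paste(sort(missing), collapse = ";"),
                   n_terminal_truncation_suspected = trunc,
                   dual_role = dual)
  }
  if (is_luxr && is_luxi) {
    # a protein complete for both rule sets: report both verdicts, flagged
    return(rbind(row("AUTHENTIC_LUXR", r_present, r_missing, dual = TRUE),
                 row("AUTHENTIC_LUXI", i_present, i_missing, dual = TRUE)))
  }
  if (is_luxr) return(row("AUTHENTIC_LUXR", r_present, r_missing))
  if (is_luxi) return(row("AUTHENTIC_LUXI", i_present, i_missing))
  if (length(r_present) > 0L) {
    trunc <- "IPR005143" %in% r_missing && "IPR000792" %in% r_present
    return(row("LUXR_LIKE_INCOMPLETE", r_present, r_missing, trunc = trunc))
  }
  row("NONE", character(0), union(rules$luxR_required, rules$luxI_required))
}

#' Classify one protein from its signature hits
#'
#' Implements the completeness test: all four LuxR signatures present gives
#' `AUTHENTIC_LUXR`; both LuxI signatures gives `AUTHENTIC_LUXI`; a
#' non-empty proper subset of the LuxR set gives `LUXR_LIKE_INCOMPLETE`
#' (with N-terminal truncation suspected when the autoinducer-binding
#' signature IPR005143 is missing while the C-terminal LuxR signature
#' IPR000792 is present — the footprint of a regulator that lost its signal
#' -binding half); anything else is `NONE`.  Membership is a set test: a
#' signature hit repeated on several protein regions counts once.
#'
#' @param gene_id Protein/gene identifier.
#' @param hits Tibble of domain hits for this gene (others are ignored).
#' @param rules A [signature_rules()] object.
#' @return One-row tibble (two rows, flagged `dual_role`, in the degenerate
#'   case where a protein is complete for both rule sets).
#' @export
classify_protein <- function(gene_id, hits, rules = signature_rules()) {
  sigs <- hits$signature_id[hits$gene_id == gene_id]
  verdict_one(gene_id, sigs, rules)
}

#' Classify many proteins, honouring the prefilter
#'
#' @param hits Tibble of domain hits.
#' @param rules A [signature_rules()] object.
#' @param gene_ids Genes to classify; default: all genes appearing in
#'   `hits`.
#' @param classify_all When `FALSE` (default), only genes passing
#'   [prefilter()] can be classified beyond `NONE` — this reproduces the
#'   two-tier flow where the completeness test is only run on shortlisted
#'   candidates.  When `TRUE`, every gene is put through the completeness
#'   test regardless of the prefilter.
#' @return Tibble with one row per (gene, verdict).
#' @export
classify_proteins <- function(hits, rules = signature_rules(),
                              gene_ids = NULL, classify_all = FALSE) {
  if (is.null(gene_ids)) gene_ids <- sort(unique(hits$gene_id))
  if (length(gene_ids) == 0L) {
    return(verdict_one("x", character(0), rules)[0, ])
  }
  shortlist <- prefilter(hits, rules)
  rows <- lapply(gene_ids, function(g) {
    if (!classify_all && !(g %in% shortlist)) {
      return(verdict_one(g, character(0), rules))
    }
    classify_protein(g, hits, rules)
  })
  dplyr::bind_rows(rows)
}
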