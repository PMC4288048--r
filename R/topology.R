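#' Default product-label synonym map
#'
#' Annotation strings vary between gene callers; topology matching therefore
#' normalizes free-text product labels to a small canonical vocabulary
#' before comparing them to catalog patterns.  Matching is case-insensitive
#' after trimming.  Hypothetical proteins normalize to the wildcard token
#' `"X"`.
#'
#' @return Named character vector: lower-cased product label -> canonical
#'   token.
#' @export
default_synonyms <- function() {
  c("hypothetical protein" = "X",
    "conserved hypothetical protein" = "X",
    "uncharacterized protein" = "X",
    "phytanoyl dioxygenase" = "phyH",
    "phytanoly dioxygenase" = "phyH",
    "phytanoyl-coa dioxygenase" = "phyH",
    "phyh" = "phyH",
    "virb1" = "virB1",
    "type iv secretion protein virb1" = "virB1",
    "virb2" = "virB2",
    "type iv secretion protein virb2" = "virB2",
    "virb3" = "virB3",
    "type iv secretion protein virb3" = "virB3",
    "isoprenylcysteine carboxyl methyltransferase" = "lcmT",
    "lcmt" = "lcmT",
    "cystathionine gamma-synthase" = "metB",
    "metb" = "metB")
}

normalize_product <- function(label, synonyms = default_synonyms()) {
  key <- tolower(trimws(label))
  out <- unname(synonyms[key])
  ifelse(is.na(out), key, out)
}

#' Default gene-neighborhood topology catalog
#'
#' Ships with the one fully characterized pattern, topology `"T"`: the
#' convergently oriented \emph{luxR-luxR-luxI} followed downstream by
#' \emph{phyH} (phytanoyl dioxygenase), a hypothetical protein (`X`), and
#' \emph{virB1-virB2-virB3}.  Users extend the catalog (YAML via
#' [read_topology_catalog()]) with their own neighborhood variants.
#'
#' @return Named list: label -> ordered character vector of canonical
#'   product tokens (`"X"` matches exactly one hypothetical-protein gene).
#' @export
default_topology_catalog <- function() {
  list(T = c("phyH", "X", "virB1", "virB2", "virB3"))
}

#' Read a topology catalog from YAML
#'
#' The YAML maps labels to ordered token lists, e.g.
#' `T: [phyH, X, virB1, virB2, virB3]`.
#'
#' @param path YAML file.
#' @return Named list as in [default_topology_catalog()].
#' @export
read_topology_catalog <- function(path) {
  y <- yaml::read_yaml(path)
  if (!length(y) || is.null(names(y)) || any(!nzchar(names(y)))) {
    stop("topology catalog must map labels to token lists", call. = FALSE)
  }
  if (anyDuplicated(names(y))) stop("duplicate topology labels", call. = FALSE)
  lapply(y, as.character)
}

#' Type the downstream gene neighborhood of a double-luxR locus
#'
#' Reads the product labels of up to `n_downstream` genes downstream of the
#' synthase member (downstream meaning away from the regulator pair),
#' normalizes them through the synonym map, and matches the catalog
#' longest-pattern-first.  The wildcard token `"X"` matches exactly one
#' hypothetical-protein gene.  No match gives `"UNTYPED"`; categories other
#' than `double_luxR_luxI` give `"N/A"`.
#'
#' @param call One-row tibble from [call_arrangements()].
#' @param genes Gene tibble for the same genome.
#' @param catalog Topology catalog (label -> token vector).
#' @param synonyms Product synonym map.
#' @param n_downstream Neighborhood window size in genes; default 8.
#' @return A topology label string.
#' @export
type_topology <- function(call, genes, catalog = default_topology_catalog(),
                          synonyms = default_synonyms(), n_downstream = 8L) {
  if (call$category != "double_luxR_luxI") return("N/A")
  members <- strsplit(call$gene_ids, ";", fixed = TRUE)[[1]]
  ct <- genes[genes$contig_id == call$contig_id &
                genes$genome_id == call$genome_id, , drop = FALSE]
  ord <- ct[order(ct$start), , drop = FALSE]
  pos <- match(members, ord$gene_id)
  if (anyNA(pos)) stop("call members absent from gene table", call. = FALSE)
  i_pos <- match(call$luxI_gene, ord$gene_id)
  if (is.na(i_pos)) stop("synthase member absent from gene table", call. = FALSE)
  r_pos <- setdiff(pos, i_pos)
  # read away from the regulator pair
  dir <- if (i_pos > max(r_pos)) +1L else -1L
  idx <- i_pos + dir * seq_len(n_downstream)
  idx <- idx[idx >= 1L & idx <= nrow(ord)]
  tokens <- normalize_product(ord$product[idx], synonyms)
  pat_order <- order(-lengths(catalog), names(catalog))
  for (k in pat_order) {
    pat <- catalog[[k]]
    if (length(tokens) >= length(pat) &&
        all(tolower(tokens[seq_along(pat)]) == tolower(pat))) {
      return(names(catalog)[k])
    }
  }
  "UNTYPED"
}
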