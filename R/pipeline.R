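#' Run the full circuit census on one genome
#'
#' Chains the census stages: domain prefilter, signature completeness
#' verdicts, arrangement calling, topology typing of double loci, and the
#' per-genome summary row.
#'
#' @param genes,proteins,hits The three input tables (see [read_gff()],
#'   [read_fasta()], [read_domain_hits()]); `proteins` may be `NULL` when
#'   only classification is needed.
#' @param rules A [signature_rules()].
#' @param policy A [proximity_policy()].
#' @param catalog Topology catalog.
#' @param genus Genus recorded in the summary row.
#' @param classify_all Passed to [classify_proteins()].
#' @return List of class `census`: `verdicts`, `calls` (topology labels
#'   filled), `summary`.
#' @export
run_census <- function(genes, proteins = NULL, hits,
                       rules = signature_rules(),
                       policy = proximity_policy(),
                       catalog = default_topology_catalog(),
                       genus = NA_character_, classify_all = FALSE) {
  genome_id <- if (nrow(genes)) genes$genome_id[1] else "genome"
  verdicts <- classify_proteins(hits, rules,
                                gene_ids = sort(unique(hits$gene_id)),
                                classify_all = classify_all)
  verdicts <- verdicts[verdicts$gene_id %in% genes$gene_id, , drop = FALSE]
  calls <- call_arrangements(genes, verdicts, policy)
  if (nrow(calls)) {
    for (k in which(calls$category == "double_luxR_luxI")) {
      calls$topology_label[k] <- type_topology(calls[k, ], genes, catalog)
    }
  }
  structure(list(verdicts = verdicts, calls = calls,
                 summary = summarize_genome(calls, genome_id, genus)),
            class = "census")
}

#' @export
print.census <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Census of %s: %d canonical pair(s), %d double(s)%s, %d luxI solo(s), %d luxR solo(s)\n",
              s$genome_id, s$n_canonical, s$n_double,
              if (nzchar(s$double_topologies))
                paste0(" [", s$double_topologies, "]") else "",
              s$n_luxI_solo, s$n_luxR_solo))
  invisible(x)
}

#' Compare arrangement calls against planted truth
#'
#' A call is a true positive when its (category, member gene set) exactly
#' matches a planted truth record.  Truth records of category
#' `truncated_luxR` plant no authentic gene and therefore expect no call;
#' they are excluded from the recall denominator.
#'
#' @param calls Tibble from [call_arrangements()].
#' @param truth Truth tibble from [generate_bundle()].
#' @return List: `tp`, `n_calls`, `n_expected`, `precision`, `recall`.
#' @export
evaluate_calls <- function(calls, truth) {
  expected <- truth[truth$category != "truncated_luxR", , drop = FALSE]
  key <- function(category, gene_ids) {
    paste(category,
          vapply(strsplit(gene_ids, ";", fixed = TRUE),
                 function(g) paste(sort(g), collapse = ";"), character(1)))
  }
  call_keys <- if (nrow(calls)) key(calls$category, calls$gene_ids) else character(0)
  exp_keys <- if (nrow(expected)) key(expected$category, expected$gene_ids) else character(0)
  tp <- 0L
  pool <- exp_keys
  for (k in call_keys) {
    hit <- match(k, pool)
    if (!is.na(hit)) { tp <- tp + 1L; pool <- pool[-hit] }
  }
  list(tp = tp, n_calls = length(call_keys), n_expected = length(exp_keys),
       precision = if (length(call_keys)) tp / length(call_keys) else NA_real_,
       recall = if (length(exp_keys)) tp / length(exp_keys) else NA_real_)
}

#' Random synthetic study configuration
#'
#' Draws a small random census scenario — contig count, background gene
#' count, and one to five planted arrangements over all five categories —
#' for property-style testing of planted-truth recovery.
#'
#' @param seed Integer seed (also the bundle's seed).
#' @param mutation_rate,decoy_rate Passed through to [synthetic_config()].
#' @return A [synthetic_config()].
#' @export
random_config <- function(seed, mutation_rate = 0, decoy_rate = 0) {
  with_local_seed(seed + 77000L, {
    n_arr <- sample(1:5, 1L)
    cats <- sample(c("canonical_pair", "luxR_solo", "luxI_solo",
                     "double_luxR_luxI", "truncated_luxR"),
                   n_arr, replace = TRUE)
    topo <- ifelse(cats == "double_luxR_luxI" & stats::runif(n_arr) < 0.5,
                   "T", NA_character_)
    synthetic_config(
      n_contigs = sample(1:3, 1L),
      n_background_genes = sample(5:25, 1L),
      arrangements = tibble::tibble(category = cats, topology = topo,
                                    contig = NA_integer_),
      mutation_rate = mutation_rate, decoy_rate = decoy_rate,
      seed = seed, genome_id = sprintf("synth%05d", seed))
  })
}
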