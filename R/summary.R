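#' Per-genome census row
#'
#' Collapses arrangement calls into the census table row format: counts per
#' category plus the topology labels of the double loci.
#'
#' @param calls Tibble from [call_arrangements()] (topology labels filled
#'   in for doubles where available), all belonging to `genome_id`.
#' @param genome_id,genus Identifiers for the row.
#' @return One-row tibble: `genome_id`, `genus`, `n_canonical`, `n_double`,
#'   `double_topologies` (`;`-joined, sorted), `n_luxI_solo`, `n_luxR_solo`,
#'   `has_any_luxR`, `has_any_luxI`.
#' @export
summarize_genome <- function(calls, genome_id, genus = NA_character_) {
  if (nrow(calls) && !all(calls$genome_id == genome_id)) {
    stop("calls from a different genome passed to summarize_genome", call. = FALSE)
  }
  n_can <- sum(calls$category == "canonical_pair")
  n_dbl <- sum(calls$category == "double_luxR_luxI")
  n_is  <- sum(calls$category == "luxI_solo")
  n_rs  <- sum(calls$category == "luxR_solo")
  topo <- calls$topology_label[calls$category == "double_luxR_luxI"]
  topo[is.na(topo)] <- "UNTYPED"
  tibble::tibble(
    genome_id = genome_id, genus = genus,
    n_canonical = n_can, n_double = n_dbl,
    double_topologies = paste(sort(topo), collapse = ";"),
    n_luxI_solo = n_is, n_luxR_solo = n_rs,
    has_any_luxR = (2L * n_dbl + n_can + n_rs) >= 1L,
    has_any_luxI = (n_dbl + n_can + n_is) >= 1L)
}

#' Per-genus rollup and global tallies
#'
#' Aggregates genome census rows the way the published family-level table
#' does: per genus, the number of genomes carrying any lux gene over the
#' total genomes screened, and the number of genomes showing each of the
#' four arrangement categories; globally, total genomes and the counts of
#' genomes with at least one luxR and at least one luxI.
#'
#' @param summaries Tibble of [summarize_genome()] rows (column `genus`
#'   required).
#' @param totals_per_genus Named integer vector: genus -> total genomes
#'   screened (including lux-free genomes absent from `summaries`).
#' @return List with `per_genus` (tibble: `genus`, `n_genomes_with_lux`,
#'   `n_genomes_total`, `n_with_canonical`, `n_with_double`,
#'   `n_with_luxI_solo`, `n_with_luxR_solo`) and `global` (named list:
#'   `total_genomes`, `genomes_with_luxR`, `genomes_with_luxI`,
#'   `genomes_with_lux`).
#' @export
rollup <- function(summaries, totals_per_genus) {
  genera <- unique(summaries$genus)
  missing <- setdiff(genera, names(totals_per_genus))
  if (length(missing)) {
    stop("totals_per_genus missing genus: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  per_genus <- dplyr::bind_rows(lapply(names(totals_per_genus), function(g) {
    s <- summaries[summaries$genus == g, , drop = FALSE]
    if (nrow(s) > totals_per_genus[[g]]) {
      stop("more genomes observed than total for genus ", g, call. = FALSE)
    }
    tibble::tibble(
      genus = g,
      n_genomes_with_lux = sum(s$has_any_luxR | s$has_any_luxI),
      n_genomes_total = as.integer(totals_per_genus[[g]]),
      n_with_canonical = sum(s$n_canonical >= 1),
      n_with_double = sum(s$n_double >= 1),
      n_with_luxI_solo = sum(s$n_luxI_solo >= 1),
      n_with_luxR_solo = sum(s$n_luxR_solo >= 1))
  }))
  global <- list(
    total_genomes = sum(per_genus$n_genomes_total),
    genomes_with_luxR = sum(summaries$has_any_luxR),
    genomes_with_luxI = sum(summaries$has_any_luxI),
    genomes_with_lux = sum(summaries$has_any_luxR | summaries$has_any_luxI))
  list(per_genus = per_genus, global = global)
}

#' Packaged family census fixture
#'
#' Loads the transcription of the published 62-genome sphingomonad census
#' table: one row per genome that carries at least one lux homolog (40
#' rows), with per-category counts and double-locus topology labels, plus
#' the per-genus genome totals (Novosphingobium 11, Sphingobium 24,
#' Sphingomonas 22, Sphingopyxis 5).  Known internal inconsistencies of the
#' printed source are recorded in `inst/extdata/table3_notes.md` and are
#' deliberately not reconciled.
#'
#' @return List: `summaries` (tibble in [summarize_genome()] layout) and
#'   `totals` (named integer vector).
#' @export
load_table3 <- function() {
  p_rows <- system.file("extdata", "table3_sphingomonads.tsv",
                        package = "luxcensus", mustWork = TRUE)
  p_tot <- system.file("extdata", "table3_genus_totals.tsv",
                       package = "luxcensus", mustWork = TRUE)
  rows <- utils::read.delim(p_rows, stringsAsFactors = FALSE)
  tot <- utils::read.delim(p_tot, stringsAsFactors = FALSE)
  summaries <- tibble::tibble(
    genome_id = rows$genome_id, genus = rows$genus,
    n_canonical = as.integer(rows$n_canonical),
    n_double = as.integer(rows$n_double),
    double_topologies = ifelse(is.na(rows$double_topologies), "",
                               rows$double_topologies),
    n_luxI_solo = as.integer(rows$n_luxI_solo),
    n_luxR_solo = as.integer(rows$n_luxR_solo))
  summaries$has_any_luxR <-
    (2L * summaries$n_double + summaries$n_canonical + summaries$n_luxR_solo) >= 1L
  summaries$has_any_luxI <-
    (summaries$n_double + summaries$n_canonical + summaries$n_luxI_solo) >= 1L
  list(summaries = summaries,
       totals = stats::setNames(as.integer(tot$n_genomes_total), tot$genus))
}
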