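#' Read gene coordinates from a GFF3 file
#'
#' Parses CDS (or, when no CDS features are present, gene) features into the
#' package's gene table.  Coordinates stay 1-based inclusive, exactly as in
#' GFF3; no half-open conversion happens anywhere in the package.
#'
#' @param path Path to a GFF3 file.
#' @param genome_id Genome identifier attached to every record.
#' @return A tibble with columns `genome_id`, `contig_id`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`), `gene_id`, `product`, sorted by
#'   (contig, start).
#' @details A CDS with strand `"."` is rejected: arrangement calling needs an
#'   orientation for every gene.  Duplicated `ID` attributes are a hard error
#'   because `gene_id` keys every downstream table.
#' @export
read_gff <- function(path, genome_id = "genome") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*(#|$|>)", lines))
  # FASTA tail after ##FASTA is legal GFF3; stop validating there
  fasta_at <- grep("^##FASTA", lines)
  if (length(fasta_at)) body <- body[body < fasta_at[1]]
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    stop(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated fields, found %d",
                 body[which(nf != 9)[1]], path, nf[which(nf != 9)[1]]),
         call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gr$type)
  keep <- types == "CDS"
  if (!any(keep)) keep <- types == "gene"
  gr <- gr[keep]
  if (length(gr) == 0L) {
    return(tibble::tibble(genome_id = character(), contig_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), gene_id = character(),
                          product = character()))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    stop("CDS feature without strand ('.') is not allowed: ",
         paste(utils::head(gr$ID[strand == "*"], 3), collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(ids == "")) {
    stop("CDS/gene feature without an ID attribute in ", path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  product <- if (!is.null(gr$product)) {
    # multi-value attributes come back as a CharacterList; re-join and decode
    vapply(as.list(gr$product), function(x)
      if (length(x)) paste(x, collapse = ",") else "", character(1))
  } else rep("", length(gr))
  product[is.na(product)] <- ""
  product <- gsub("%2C", ",", gsub("%3B", ";", gsub("%3D", "=", product,
                  fixed = TRUE), fixed = TRUE), fixed = TRUE)
  product <- gsub("%25", "%", product, fixed = TRUE)
  out <- tibble::tibble(
    genome_id = genome_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start     = GenomicRanges::start(gr),
    end       = GenomicRanges::end(gr),
    strand    = strand,
    gene_id   = ids,
    product   = product
  )
  out[order(out$contig_id, out$start), , drop = FALSE]
}

#' Read protein sequences from FASTA
#'
#' @param path Path to an amino-acid FASTA file; record ids must equal
#'   `gene_id`s.
#' @return A tibble with columns `gene_id` and `sequence`.  Sequences are
#'   upper-cased and a trailing stop symbol `*` is stripped.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  if (any(nchar(seqs) == 0L)) {
    stop("empty protein sequence for: ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }
  assert_protein_alphabet(seqs, paste0("FASTA ", path))
  tibble::tibble(gene_id = unname(ids), sequence = unname(seqs))
}

#' Read protein-domain hits (HMMER3 domtblout or InterProScan TSV)
#'
#' @param path Path to the hit table.
#' @param dialect `"domtblout"`, `"interproscan_tsv"`, or `"auto"` to sniff
#'   from the column layout (tab-separated 11+ columns means InterProScan;
#'   whitespace-separated 23 columns means domtblout).
#' @return A tibble with columns `gene_id`, `signature_id`, `evalue`
#'   (`NA` for InterPro membership rows), `ali_start`, `ali_end`.
#' @details For domtblout (hmmscan orientation: query = protein, target =
#'   profile) the per-domain independent e-value (`i-Evalue`, column 13) is
#'   used, and the Pfam accession version suffix (`PF03472.14` ->
#'   `PF03472`) is stripped.  One InterProScan row yields up to two hits:
#'   the member-database signature (with its score column as e-value when
#'   numeric) and, when integrated, the IPR accession (e-value absent).
#' @export
read_domain_hits <- function(path, dialect = c("auto", "domtblout", "interproscan_tsv")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(gene_id = character(), signature_id = character(),
                          evalue = numeric(), ali_start = integer(),
                          ali_end = integer()))
  }
  if (dialect == "auto") {
    ntab <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
    dialect <- if (ntab >= 11) "interproscan_tsv" else "domtblout"
    if (dialect == "domtblout" &&
        length(strsplit(trimws(lines[1]), "\\s+")[[1]]) < 23) {
      stop("cannot sniff domain-hit dialect of ", path, call. = FALSE)
    }
  }
  if (dialect == "domtblout") parse_domtblout(lines, path)
  else parse_interproscan_tsv(lines, path)
}

parse_domtblout <- function(lines, path) {
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22) {
      stop(sprintf("malformed domtblout row %d in %s: %d fields", i, path, length(f)),
           call. = FALSE)
    }
    ev <- suppressWarnings(as.numeric(f[13]))
    if (is.na(ev)) {
      stop(sprintf("non-numeric i-Evalue in domtblout row %d of %s: '%s'", i, path, f[13]),
           call. = FALSE)
    }
    sig <- sub("\\.\\d+$", "", f[2])
    if (sig == "-") sig <- f[1]
    tibble::tibble(gene_id = f[4], signature_id = sig, evalue = ev,
                   ali_start = as.integer(f[18]), ali_end = as.integer(f[19]))
  })
  dplyr::bind_rows(rows)
}

parse_interproscan_tsv <- function(lines, path) {
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      stop(sprintf("malformed InterProScan row %d in %s: %d fields", i, path, length(f)),
           call. = FALSE)
    }
    ev <- suppressWarnings(as.numeric(f[9]))
    if (!is.na(ev) && ev < 0) {
      stop(sprintf("negative e-value in InterProScan row %d of %s", i, path),
           call. = FALSE)
    }
    out <- tibble::tibble(gene_id = f[1], signature_id = f[5], evalue = ev,
                          ali_start = suppressWarnings(as.integer(f[7])),
                          ali_end = suppressWarnings(as.integer(f[8])))
    if (length(f) >= 12 && !is.na(f[12]) && f[12] != "-" && nzchar(f[12])) {
      out <- rbind(out, tibble::tibble(
        gene_id = f[1], signature_id = f[12], evalue = NA_real_,
        ali_start = NA_integer_, ali_end = NA_integer_))
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Write the census report files
#'
#' Emits four deterministic files into `dir`: `verdicts.tsv` (per-gene
#' signature verdicts), `arrangements.tsv` (per-arrangement calls with
#' topology labels), `genome_summaries.tsv` (per-genome census rows) and
#' `lux_candidates.faa` (authenticated LuxR/LuxI proteins, for external
#' phylogenetics).  Rerunning on the same input reproduces identical bytes.
#'
#' @param dir Output directory (created if missing).
#' @param verdicts Tibble from [classify_proteins()].
#' @param calls Tibble from [call_arrangements()].
#' @param summaries Tibble of [summarize_genome()] rows.
#' @param proteins Protein tibble (`gene_id`, `sequence`); used for the
#'   candidate FASTA.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(dir, verdicts, calls, summaries, proteins = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", dir, call. = FALSE)
  }
  write_tsv_det <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  v <- as.data.frame(verdicts)
  v <- v[order(v$gene_id, v$verdict), , drop = FALSE]
  p_verd <- file.path(dir, "verdicts.tsv")
  write_tsv_det(v, p_verd)

  a <- as.data.frame(calls)
  a <- a[order(a$genome_id, a$contig_id, a$category, a$gene_ids), , drop = FALSE]
  p_arr <- file.path(dir, "arrangements.tsv")
  write_tsv_det(a, p_arr)

  s <- as.data.frame(summaries)
  s <- s[order(s$genome_id), , drop = FALSE]
  p_sum <- file.path(dir, "genome_summaries.tsv")
  write_tsv_det(s, p_sum)

  p_fa <- file.path(dir, "lux_candidates.faa")
  cand <- character(0)
  if (!is.null(proteins) && nrow(verdicts)) {
    auth <- verdicts$gene_id[verdicts$verdict %in%
                               c("AUTHENTIC_LUXR", "AUTHENTIC_LUXI")]
    keep <- proteins[proteins$gene_id %in% auth, , drop = FALSE]
    keep <- keep[order(keep$gene_id), , drop = FALSE]
    cand <- as.vector(rbind(paste0(">", keep$gene_id), keep$sequence))
  }
  writeLines(cand, p_fa)
  invisible(c(p_verd, p_arr, p_sum, p_fa))
}
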