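#' Configuration for the synthetic-genome generator
#'
#' The generator emulates a multi-contig annotated draft genome carrying
#' planted quorum-sensing arrangements: each arrangement category has the
#' strand/adjacency geometry of its real counterpart (canonical pairs as a
#' convergent \emph{luxI}(+)/\emph{luxR}(-) couple; double loci as two
#' tandem regulators with a convergent synthase; topology-typed doubles with
#' the requested downstream product labels; truncated regulators as a lone
#' gene whose signature set lacks the autoinducer-binding domain).  Planted
#' arrangements are separated by >5 kb spacers so the proximity policy can
#' never merge two of them.
#'
#' @param n_contigs Number of contigs.
#' @param n_background_genes Background (non-lux) genes, spread across
#'   contigs.
#' @param arrangements Data frame with columns `category` (one of
#'   `canonical_pair`, `luxR_solo`, `luxI_solo`, `double_luxR_luxI`,
#'   `truncated_luxR`), `topology` (label from the catalog or `NA`) and
#'   `contig` (1-based index or `NA` for random assignment).
#' @param mutation_rate Per-residue substitution probability applied to the
#'   packaged seed sequences; in `[0, 1)`.
#' @param decoy_rate Fraction of background genes given a partial or
#'   sub-threshold lux-like signature set; in `[0, 1]`.
#' @param seed Integer RNG seed; identical (config, seed) gives a
#'   byte-identical bundle.
#' @param genome_id Genome identifier used in all emitted records.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_contigs = 2L, n_background_genes = 20L,
                             arrangements = tibble::tibble(
                               category = c("canonical_pair", "luxR_solo"),
                               topology = NA_character_, contig = NA_integer_),
                             mutation_rate = 0, decoy_rate = 0,
                             seed = 1L, genome_id = "synthG") {
  arrangements <- tibble::as_tibble(arrangements)
  if (!"topology" %in% names(arrangements)) arrangements$topology <- NA_character_
  if (!"contig" %in% names(arrangements)) arrangements$contig <- NA_integer_
  stopifnot(n_contigs >= 1, n_background_genes >= 0,
            mutation_rate >= 0, mutation_rate < 1,
            decoy_rate >= 0, decoy_rate <= 1,
            all(arrangements$category %in%
                  c("canonical_pair", "luxR_solo", "luxI_solo",
                    "double_luxR_luxI", "truncated_luxR")))
  if (any(!is.na(arrangements$contig) &
          (arrangements$contig < 1 | arrangements$contig > n_contigs))) {
    stop("arrangement assigned to a contig outside 1..n_contigs", call. = FALSE)
  }
  structure(list(n_contigs = as.integer(n_contigs),
                 n_background_genes = as.integer(n_background_genes),
                 arrangements = arrangements,
                 mutation_rate = mutation_rate, decoy_rate = decoy_rate,
                 seed = as.integer(seed), genome_id = genome_id),
            class = "synthetic_config")
}

#' Substitute residues of a protein at a fixed per-position rate
#'
#' Each position is independently replaced, with probability `rate`, by a
#' residue drawn uniformly from the 19 other standard residues.  Length is
#' always preserved; `rate = 0` returns the input unchanged.
#'
#' @param seq Amino-acid string.
#' @param rate Substitution probability in `[0, 1)`.
#' @return Mutated amino-acid string.
#' @export
mutate_sequence <- function(seq, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(AA20, a), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

seed_proteins <- function() {
  p <- system.file("extdata", "seed_proteins_synthetic.fasta",
                   package = "luxcensus", mustWork = TRUE)
  read_fasta(p)
}

# log-uniform e-value draw
r_evalue <- function(n, lo_exp, hi_exp) 10^stats::runif(n, lo_exp, hi_exp)

LUXR_SIGS <- c("IPR005143", "IPR016032", "IPR011991", "IPR000792")
LUXI_SIGS <- c("IPR001690", "IPR018311")

#' Generate a synthetic annotated genome bundle
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_bundle`: `genes`, `proteins`, `hits`
#'   (the tables the IO layer produces from real input) and `truth`
#'   (tibble: `truth_id`, `category`, `topology`, `contig_id`, `gene_ids`).
#' @details Planted regulators carry the full four-signature InterPro set
#'   plus PF03472 with e-values drawn log-uniform in `[1e-50, 1e-6]`;
#'   synthases carry both synthase signatures plus PF00765; truncated
#'   regulators carry PF03472 plus the three C-terminal signatures (the
#'   autoinducer-binding signature IPR005143 is absent).  Decoy background
#'   genes receive either a prefilter domain at a sub-threshold e-value
#'   (log-uniform `[1e-4, 1]`) or one-to-two regulator signatures only —
#'   never a complete set.  Gene lengths are drawn uniformly in 750–900 bp
#'   and intra-block intergenic gaps in 50–400 bp.
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  seeds <- seed_proteins()
  luxr_seeds <- seeds$sequence[grepl("^luxR_seed", seeds$gene_id)]
  luxi_seeds <- seeds$sequence[grepl("^luxI_seed", seeds$gene_id)]

  with_local_seed(config$seed, {
    arr <- config$arrangements
    arr$contig <- ifelse(is.na(arr$contig),
                         sample.int(config$n_contigs, nrow(arr), replace = TRUE),
                         arr$contig)
    # spread background genes over contigs
    bg_contig <- if (config$n_background_genes > 0)
      sort(sample.int(config$n_contigs, config$n_background_genes, replace = TRUE))
    else integer(0)

    genes <- list(); prots <- list(); hits <- list(); truth <- list()
    gid_n <- 0L
    new_gid <- function() {
      gid_n <<- gid_n + 1L
      sprintf("%s_g%04d", config$genome_id, gid_n)
    }

    add_gene <- function(contig, start, end, strand, gid, product, sequence) {
      genes[[length(genes) + 1L]] <<- tibble::tibble(
        genome_id = config$genome_id, contig_id = contig,
        start = as.integer(start), end = as.integer(end),
        strand = strand, gene_id = gid, product = product)
      prots[[length(prots) + 1L]] <<- tibble::tibble(gene_id = gid,
                                                     sequence = sequence)
    }
    add_hits <- function(gid, sigs, evalues, len) {
      hits[[length(hits) + 1L]] <<- tibble::tibble(
        gene_id = gid, signature_id = sigs, evalue = evalues,
        ali_start = rep(1L, length(sigs)),
        ali_end = rep(as.integer(len), length(sigs)))
    }

    plant_gene <- function(contig, cursor, strand, kind, product) {
      seq <- switch(kind,
        luxR = mutate_sequence(sample(luxr_seeds, 1L), config$mutation_rate),
        luxI = mutate_sequence(sample(luxi_seeds, 1L), config$mutation_rate),
        truncR = {
          s <- mutate_sequence(sample(luxr_seeds, 1L), config$mutation_rate)
          substring(s, max(1L, nchar(s) - 139L), nchar(s))  # C-terminal half
        },
        background = random_protein(sample(250:300, 1L)))
      len_nt <- if (kind == "background") sample(750:900, 1L)
                else 3L * (nchar(seq) + 1L)
      start <- cursor
      end <- start + len_nt - 1L
      gid <- new_gid()
      add_gene(contig, start, end, strand, gid, product, seq)
      nl <- nchar(seq)
      if (kind == "luxR") {
        add_hits(gid, c(LUXR_SIGS, "PF03472"), c(rep(NA_real_, 4), r_evalue(1, -50, -6)), nl)
      } else if (kind == "luxI") {
        add_hits(gid, c(LUXI_SIGS, "PF00765"), c(rep(NA_real_, 2), r_evalue(1, -50, -6)), nl)
      } else if (kind == "truncR") {
        add_hits(gid, c(setdiff(LUXR_SIGS, "IPR005143"), "PF03472"),
                 c(rep(NA_real_, 3), r_evalue(1, -50, -6)), nl)
      } else if (kind == "background" && stats::runif(1) < config$decoy_rate) {
        if (stats::runif(1) < 0.5) {
          # sub-threshold prefilter domain
          add_hits(gid, sample(c("PF03472", "PF00765"), 1L), r_evalue(1, -4, 0), nl)
        } else {
          k <- sample(1:2, 1L)
          add_hits(gid, sample(LUXR_SIGS, k), rep(NA_real_, k), nl)
        }
      }
      list(gid = gid, end = end)
    }

    block_gap <- function() sample(50:200, 1L)
    bg_gap <- function() sample(50:400, 1L)
    SPACER <- 6000L  # isolates blocks beyond any sane proximity policy

    truth_n <- 0L
    plant_block <- function(contig, cursor, category, topology) {
      gids <- character(0)
      if (category == "canonical_pair") {
        g1 <- plant_gene(contig, cursor, "+", "luxI", "acyl-homoserine-lactone synthase")
        g2 <- plant_gene(contig, g1$end + block_gap(), "-", "luxR",
                         "LuxR family transcriptional regulator")
        gids <- c(g1$gid, g2$gid); cursor <- g2$end
      } else if (category == "luxR_solo") {
        g <- plant_gene(contig, cursor, sample(c("+", "-"), 1L), "luxR",
                        "LuxR family transcriptional regulator")
        gids <- g$gid; cursor <- g$end
      } else if (category == "luxI_solo") {
        g <- plant_gene(contig, cursor, sample(c("+", "-"), 1L), "luxI",
                        "acyl-homoserine-lactone synthase")
        gids <- g$gid; cursor <- g$end
      } else if (category == "truncated_luxR") {
        g <- plant_gene(contig, cursor, sample(c("+", "-"), 1L), "truncR",
                        "LuxR-like protein, N-terminal truncation")
        gids <- g$gid; cursor <- g$end
      } else if (category == "double_luxR_luxI") {
        g1 <- plant_gene(contig, cursor, "+", "luxR",
                         "LuxR family transcriptional regulator")
        g2 <- plant_gene(contig, g1$end + block_gap(), "+", "luxR",
                         "LuxR family transcriptional regulator")
        g3 <- plant_gene(contig, g2$end + block_gap(), "-", "luxI",
                         "acyl-homoserine-lactone synthase")
        gids <- c(g1$gid, g2$gid, g3$gid); cursor <- g3$end
        if (!is.na(topology)) {
          labels <- topology_products(topology)
          for (lab in labels) {
            g <- plant_gene(contig, cursor + block_gap(),
                            sample(c("+", "-"), 1L), "background", lab)
            cursor <- g$end
          }
        }
      }
      truth_n <<- truth_n + 1L
      truth[[length(truth) + 1L]] <<- tibble::tibble(
        truth_id = sprintf("truth%03d", truth_n),
        category = category,
        topology = if (is.na(topology)) NA_character_ else topology,
        contig_id = contig, gene_ids = paste(gids, collapse = ";"))
      cursor
    }

    for (c_idx in seq_len(config$n_contigs)) {
      contig <- sprintf("%s_ctg%02d", config$genome_id, c_idx)
      cursor <- 1L
      blocks <- which(arr$contig == c_idx)
      n_bg <- sum(bg_contig == c_idx)
      # interleave: background genes split around the blocks
      cuts <- if (length(blocks)) sort(sample.int(length(blocks) + 1L, n_bg,
                                                  replace = TRUE)) else
        rep(1L, n_bg)
      for (b in seq_along(blocks)) {
        for (k in seq_len(sum(cuts == b))) {
          g <- plant_gene(contig, cursor + bg_gap(), sample(c("+", "-"), 1L),
                          "background", "hypothetical protein")
          cursor <- g$end
        }
        cursor <- cursor + SPACER
        cursor <- plant_block(contig, cursor, arr$category[blocks[b]],
                              arr$topology[blocks[b]])
        cursor <- cursor + SPACER
      }
      for (k in seq_len(sum(cuts == length(blocks) + 1L))) {
        g <- plant_gene(contig, cursor + bg_gap(), sample(c("+", "-"), 1L),
                        "background", "hypothetical protein")
        cursor <- g$end
      }
    }

    genes <- dplyr::bind_rows(genes)
    genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
    structure(list(genes = genes,
                   proteins = dplyr::bind_rows(prots),
                   hits = if (length(hits)) dplyr::bind_rows(hits) else
                     tibble::tibble(gene_id = character(),
                                    signature_id = character(),
                                    evalue = numeric(), ali_start = integer(),
                                    ali_end = integer()),
                   truth = dplyr::bind_rows(truth),
                   config = config),
              class = "synthetic_bundle")
  })
}

# downstream product labels for a topology label in the default catalog
topology_products <- function(label, catalog = default_topology_catalog()) {
  if (!label %in% names(catalog)) {
    stop("unknown topology label: ", label, call. = FALSE)
  }
  tokens <- catalog[[label]]
  expand <- c(X = "hypothetical protein", phyH = "phytanoyl dioxygenase",
              virB1 = "virB1", virB2 = "virB2", virB3 = "virB3",
              lcmT = "isoprenylcysteine carboxyl methyltransferase",
              metB = "cystathionine gamma-synthase")
  out <- unname(expand[tokens])
  ifelse(is.na(out), tokens, out)
}

#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' Emits `genes.gff3`, `proteins.faa`, `hits.domtbl` (HMMER3 domtblout
#' dialect; InterPro membership rows carry e-value 0 to mean "no threshold
#' applies") plus `truth.tsv`.  Reading the first three back through the IO
#' layer reproduces the in-memory tables.
#'
#' @param bundle A [generate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- bundle$genes
  # GFF3 attribute encoding for reserved characters
  prod <- gsub("%", "%25", g$product, fixed = TRUE)
  prod <- gsub("=", "%3D", gsub(";", "%3B", gsub(",", "%2C", prod,
               fixed = TRUE), fixed = TRUE), fixed = TRUE)
  gff <- c("##gff-version 3",
           sprintf("%s\tluxcensus\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s",
                   g$contig_id, g$start, g$end, g$strand, g$gene_id, prod))
  p_gff <- file.path(dir, "genes.gff3")
  writeLines(gff, p_gff)

  p_faa <- file.path(dir, "proteins.faa")
  writeLines(as.vector(rbind(paste0(">", bundle$proteins$gene_id),
                             bundle$proteins$sequence)), p_faa)

  h <- bundle$hits
  ev <- ifelse(is.na(h$evalue), 0, h$evalue)
  p_dom <- file.path(dir, "hits.domtbl")
  writeLines(sprintf(
    "%s %s 200 %s - 250 %.2e 100.0 0.1 1 1 %.2e %.2e 90.0 0.1 1 200 %d %d 1 250 0.95 -",
    tolower(h$signature_id), h$signature_id, h$gene_id, ev, ev, ev,
    ifelse(is.na(h$ali_start), 1L, h$ali_start),
    ifelse(is.na(h$ali_end), 250L, h$ali_end)), p_dom)

  p_truth <- file.path(dir, "truth.tsv")
  utils::write.table(as.data.frame(bundle$truth), p_truth, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(c(p_gff, p_faa, p_dom, p_truth))
}
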