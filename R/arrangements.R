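#' Proximity policy for cognate-pair calling
#'
#' The census pairs a regulator and a synthase only when their genes are in
#' "close proximity" on the same contig.  Proximity is quantified as at most
#' `max_intervening_genes` annotated genes between the two and at most
#' `max_gap_bp` bases of intergenic distance.  The defaults (3 genes,
#' 5,000 bp) keep a regulator four genes downstream of a pair unpaired,
#' i.e. a solo.
#'
#' @param max_intervening_genes Maximum number of genes between two cognate
#'   members; default 3.
#' @param max_gap_bp Maximum intergenic distance in bp; default 5000.
#' @return A list of class `proximity_policy` (same-contig is always
#'   required).
#' @export
proximity_policy <- function(max_intervening_genes = 3L, max_gap_bp = 5000L) {
  stopifnot(max_intervening_genes >= 0, max_gap_bp >= 0)
  structure(list(max_intervening_genes = as.integer(max_intervening_genes),
                 max_gap_bp = as.integer(max_gap_bp),
                 same_contig_required = TRUE),
            class = "proximity_policy")
}

# orientation relation of two genes given in genomic order
strand_relation <- function(strand_left, strand_right) {
  if (strand_left == strand_right) "tandem"
  else if (strand_left == "+") "convergent"
  else "divergent"
}

# --- per-contig assignment ---------------------------------------------------
#
# Finds the arrangement assignment that maximizes, lexicographically,
# (#double loci, #canonical pairs), preferring smaller total intergenic
# distance and then smaller start coordinates among optima.  Candidate sets
# are tiny in real genomes (a handful of lux genes per contig), so an exact
# depth-first search is affordable; above `max_exact` lux genes a
# nearest-first greedy is used instead.

contig_assign <- function(ord, r_idx, i_idx, policy, max_exact = 14L) {
  n_lux <- length(r_idx) + length(i_idx)

  ok <- function(a, b) {
    lo <- min(a, b); hi <- max(a, b)
    (hi - lo - 1L) <= policy$max_intervening_genes &&
      intergenic_gap(ord$end[lo], ord$start[hi]) <= policy$max_gap_bp
  }
  gap <- function(a, b) {
    lo <- min(a, b); hi <- max(a, b)
    intergenic_gap(ord$end[lo], ord$start[hi])
  }

  # candidate double loci: two same-strand regulators within policy of each
  # other, plus a synthase within policy of at least one of them
  triples <- list()
  if (length(r_idx) >= 2 && length(i_idx) >= 1) {
    for (a in seq_along(r_idx)) for (b in seq_along(r_idx)) {
      if (a >= b) next
      r1 <- r_idx[a]; r2 <- r_idx[b]
      if (ord$strand[r1] != ord$strand[r2] || !ok(r1, r2)) next
      for (i in i_idx) {
        if (ok(i, r1) || ok(i, r2)) {
          triples[[length(triples) + 1L]] <-
            list(r = c(r1, r2), i = i,
                 cost = gap(r1, r2) + min(gap(i, r1), gap(i, r2)))
        }
      }
    }
  }

  # candidate canonical pairs
  pair_ok <- function(r, i) ok(r, i)

  best <- NULL
  lex_gt <- function(k1, k2) {
    for (j in seq_along(k1)) {
      if (k1[j] > k2[j]) return(TRUE)
      if (k1[j] < k2[j]) return(FALSE)
    }
    FALSE  # equal keys: keep the first assignment found (deterministic order)
  }
  consider <- function(doubles, pairs) {
    nd <- length(doubles); np <- nrow(pairs)
    cost <- sum(vapply(doubles, function(t) t$cost, numeric(1))) +
      (if (np) sum(pairs$cost) else 0)
    key <- c(nd, np, -cost)
    if (is.null(best) || lex_gt(key, best$key)) {
      best <<- list(key = key, doubles = doubles, pairs = pairs)
    }
  }

  empty_pairs <- tibble::tibble(r = integer(), i = integer(), cost = numeric())

  best_pairs_for <- function(rs, is) {
    # maximum R-I matching, min total gap among maxima; exact DFS
    rs <- sort(rs); is <- sort(is)
    best_p <- list(n = -1L, cost = Inf, pairs = empty_pairs)
    rec <- function(k, used_i, acc) {
      if (k > length(rs)) {
        n <- nrow(acc); cost <- if (n) sum(acc$cost) else 0
        if (n > best_p$n || (n == best_p$n && cost < best_p$cost)) {
          best_p <<- list(n = n, cost = cost, pairs = acc)
        }
        return(invisible())
      }
      r <- rs[k]
      cand <- is[!(is %in% used_i)]
      cand <- cand[vapply(cand, function(i) pair_ok(r, i), logical(1))]
      if (length(cand)) {
        cand <- cand[order(vapply(cand, function(i) gap(r, i), numeric(1)), cand)]
        for (i in cand) {
          rec(k + 1L,
              c(used_i, i),
              rbind(acc, tibble::tibble(r = r, i = i, cost = gap(r, i))))
        }
      }
      rec(k + 1L, used_i, acc)  # leave this regulator unpaired
    }
    rec(1L, integer(0), empty_pairs)
    best_p$pairs
  }

  if (n_lux <= max_exact) {
    rec_d <- function(k, used, acc) {
      if (k > length(triples)) {
        rs <- setdiff(r_idx, used); is <- setdiff(i_idx, used)
        consider(acc, best_pairs_for(rs, is))
        return(invisible())
      }
      t <- triples[[k]]
      if (!any(c(t$r, t$i) %in% used)) rec_d(k + 1L, c(used, t$r, t$i), c(acc, list(t)))
      rec_d(k + 1L, used, acc)
    }
    rec_d(1L, integer(0), list())
  } else {
    # greedy fallback for unusually lux-dense contigs: doubles first
    # (leftmost), then nearest-first pairs
    used <- integer(0); doubles <- list()
    t_ord <- order(vapply(triples, function(t) ord$start[t$r[1]], numeric(1)),
                   vapply(triples, function(t) t$cost, numeric(1)))
    for (t in triples[t_ord]) {
      if (!any(c(t$r, t$i) %in% used)) {
        doubles <- c(doubles, list(t)); used <- c(used, t$r, t$i)
      }
    }
    rs <- setdiff(r_idx, used); is <- setdiff(i_idx, used)
    cand <- expand.grid(r = rs, i = is)
    if (nrow(cand)) {
      keep <- mapply(function(r, i) pair_ok(r, i), cand$r, cand$i)
      cand <- cand[keep, , drop = FALSE]
      cand$cost <- mapply(function(r, i) gap(r, i), cand$r, cand$i)
      cand <- cand[order(cand$cost, ord$start[cand$r], ord$start[cand$i]), , drop = FALSE]
    }
    pairs <- empty_pairs
    for (k in seq_len(nrow(cand))) {
      r <- cand$r[k]; i <- cand$i[k]
      if (!(r %in% used) && !(i %in% used)) {
        pairs <- rbind(pairs, tibble::tibble(r = r, i = i, cost = cand$cost[k]))
        used <- c(used, r, i)
      }
    }
    best <- list(doubles = doubles, pairs = pairs)
  }
  if (is.null(best)) best <- list(doubles = list(), pairs = empty_pairs)
  best
}

#' Call genomic arrangements of authenticated lux genes
#'
#' Assigns every `AUTHENTIC_LUXR` / `AUTHENTIC_LUXI` gene to exactly one
#' arrangement: a convergent-double locus (two same-strand regulators within
#' policy of each other plus a synthase within policy), a canonical
#' \emph{luxI/R} pair, or a solo.  Double loci take precedence over
#' canonical pairs — otherwise the middle regulator of a
#' \emph{luxR-luxR-luxI} trio would be stolen as a pair partner — and the
#' assignment maximizes (#doubles, then #pairs) with nearest-distance
#' tie-breaking, so the output is deterministic and order-independent.
#'
#' For every call the strand relations of its members are reported
#' (tandem / convergent / divergent); for luxI solos the intergenic distance
#' to the nearest upstream gene (relative to the solo's own strand) and the
#' presence of an immediately adjacent `LUXR_LIKE_INCOMPLETE` gene — the
#' truncated-regulator footprint — are recorded.
#'
#' @param genes Gene tibble (see [read_gff()]).
#' @param verdicts Verdict tibble (see [classify_proteins()]); must cover
#'   every gene it references.
#' @param policy A [proximity_policy()].
#' @return Tibble with one row per arrangement call: `genome_id`,
#'   `contig_id`, `category`, `gene_ids` (genomic order, `;`-separated),
#'   `strands`, `luxR_pair_relation`, `luxR_luxI_relation`,
#'   `topology_label` (`NA` until [type_topology()] is applied to doubles;
#'   `"N/A"` for other categories), `upstream_intergenic_bp`,
#'   `adjacent_truncated_luxR`.
#' @export
call_arrangements <- function(genes, verdicts, policy = proximity_policy()) {
  missing_genes <- setdiff(verdicts$gene_id, genes$gene_id)
  if (length(missing_genes)) {
    stop("verdicts reference genes absent from the gene table: ",
         paste(utils::head(missing_genes, 5), collapse = ", "), call. = FALSE)
  }
  vmap <- split(verdicts$verdict, verdicts$gene_id)
  dual <- names(vmap)[vapply(vmap, function(v)
    all(c("AUTHENTIC_LUXR", "AUTHENTIC_LUXI") %in% v), logical(1))]
  if (length(dual)) {
    warning("gene(s) authenticated as both LuxR and LuxI treated in the LuxR role: ",
            paste(dual, collapse = ", "), call. = FALSE)
  }
  role_of <- function(g) {
    v <- vmap[[g]]
    if (is.null(v)) "NONE"
    else if ("AUTHENTIC_LUXR" %in% v) "R"
    else if ("AUTHENTIC_LUXI" %in% v) "I"
    else if ("LUXR_LIKE_INCOMPLETE" %in% v) "T"
    else "NONE"
  }

  calls <- list()
  for (ct in split(genes, ~ genome_id + contig_id, drop = TRUE)) {
    ord <- ct[order(ct$start), , drop = FALSE]
    role <- vapply(ord$gene_id, role_of, character(1))
    r_idx <- which(role == "R"); i_idx <- which(role == "I")
    if (!length(r_idx) && !length(i_idx)) next
    asg <- contig_assign(ord, r_idx, i_idx, policy)

    trunc_adjacent <- function(members) {
      nb <- unique(c(members - 1L, members + 1L))
      nb <- setdiff(nb[nb >= 1L & nb <= nrow(ord)], members)
      any(role[nb] == "T")
    }
    mk <- function(category, members) {
      members <- sort(members)
      rel_rr <- NA_character_; rel_ri <- NA_character_
      mem_role <- role[members]
      if (sum(mem_role == "R") == 2L) {
        rr <- members[mem_role == "R"]
        rel_rr <- strand_relation(ord$strand[rr[1]], ord$strand[rr[2]])
      }
      if (any(mem_role == "R") && any(mem_role == "I")) {
        ii <- members[mem_role == "I"]
        rr <- members[mem_role == "R"]
        rnear <- rr[which.min(abs(rr - ii))]
        lo <- min(rnear, ii); hi <- max(rnear, ii)
        rel_ri <- strand_relation(ord$strand[lo], ord$strand[hi])
      }
      up_bp <- NA_integer_
      if (category == "luxI_solo") {
        m <- members[1]
        if (ord$strand[m] == "+") {
          if (m > 1L) up_bp <- intergenic_gap(ord$end[m - 1L], ord$start[m])
        } else {
          if (m < nrow(ord)) up_bp <- intergenic_gap(ord$end[m], ord$start[m + 1L])
        }
      }
      luxI_gene <- if (any(mem_role == "I"))
        ord$gene_id[members[mem_role == "I"][1]] else NA_character_
      tibble::tibble(
        genome_id = ord$genome_id[1], contig_id = ord$contig_id[1],
        category = category,
        gene_ids = paste(ord$gene_id[members], collapse = ";"),
        strands = paste(ord$strand[members], collapse = ";"),
        luxI_gene = luxI_gene,
        luxR_pair_relation = rel_rr, luxR_luxI_relation = rel_ri,
        topology_label = if (category == "double_luxR_luxI") NA_character_ else "N/A",
        upstream_intergenic_bp = up_bp,
        adjacent_truncated_luxR = trunc_adjacent(members))
    }

    used <- integer(0)
    for (t in asg$doubles) {
      calls[[length(calls) + 1L]] <- mk("double_luxR_luxI", c(t$r, t$i))
      used <- c(used, t$r, t$i)
    }
    for (k in seq_len(nrow(asg$pairs))) {
      calls[[length(calls) + 1L]] <- mk("canonical_pair",
                                        c(asg$pairs$r[k], asg$pairs$i[k]))
      used <- c(used, asg$pairs$r[k], asg$pairs$i[k])
    }
    for (r in setdiff(r_idx, used)) calls[[length(calls) + 1L]] <- mk("luxR_solo", r)
    for (i in setdiff(i_idx, used)) calls[[length(calls) + 1L]] <- mk("luxI_solo", i)
  }

  out <- if (length(calls)) dplyr::bind_rows(calls) else
    tibble::tibble(genome_id = character(), contig_id = character(),
                   category = character(), gene_ids = character(),
                   strands = character(), luxI_gene = character(),
                   luxR_pair_relation = character(),
                   luxR_luxI_relation = character(),
                   topology_label = character(),
                   upstream_intergenic_bp = integer(),
                   adjacent_truncated_luxR = logical())
  out <- out[order(out$genome_id, out$contig_id, out$gene_ids), , drop = FALSE]

  # conservation law: every authenticated gene sits in exactly one call
  n_r <- sum(vapply(vmap, function(v) "AUTHENTIC_LUXR" %in% v, logical(1)))
  n_i <- sum(vapply(vmap, function(v) "AUTHENTIC_LUXI" %in% v &&
                      !("AUTHENTIC_LUXR" %in% v), logical(1)))
  nd <- sum(out$category == "double_luxR_luxI")
  np <- sum(out$category == "canonical_pair")
  stopifnot(n_r == 2L * nd + np + sum(out$category == "luxR_solo"),
            n_i == nd + np + sum(out$category == "luxI_solo"))
  out
}
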