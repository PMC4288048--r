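# Independent oracles used by the property and acceptance tests.  These are
# deliberately naive re-derivations, sharing no code with the package paths
# they check.

# Quadratic-space affine-gap Needleman-Wunsch: a gap of length L costs
# 10 + L (open 10, extend 1), BLOSUM62 substitution scores.
nw_score_oracle <- function(a, b) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sm <- e$BLOSUM62
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in residue-residue column
  X <- matrix(NEG, n + 1, m + 1)  # ends with gap in b (a residue unmatched)
  Y <- matrix(NEG, n + 1, m + 1)  # ends with gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(10 + i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(10 + j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sm[x[i], y[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - 11, X[i, j + 1] - 1, Y[i, j + 1] - 11)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - 11, Y[i + 1, j] - 1, X[i + 1, j] - 11)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force verdict from plain set comparisons.
verdict_oracle <- function(sigs) {
  luxr <- c("IPR005143", "IPR016032", "IPR011991", "IPR000792")
  luxi <- c("IPR001690", "IPR018311")
  has_r <- all(luxr %in% sigs); has_i <- all(luxi %in% sigs)
  if (has_r && has_i) return(c("AUTHENTIC_LUXR", "AUTHENTIC_LUXI"))
  if (has_r) return("AUTHENTIC_LUXR")
  if (has_i) return("AUTHENTIC_LUXI")
  if (any(luxr %in% sigs)) return("LUXR_LIKE_INCOMPLETE")
  "NONE"
}

# Exhaustive (doubles-then-pairs lexicographic maximum) arrangement counts
# for a single-contig instance.  genes: tibble sorted by start with column
# role in {R, I, none}; policy as in the package.
arrangement_counts_oracle <- function(genes, policy) {
  ord <- genes[order(genes$start), , drop = FALSE]
  n <- nrow(ord)
  ok <- function(a, b) {
    lo <- min(a, b); hi <- max(a, b)
    (hi - lo - 1L) <= policy$max_intervening_genes &&
      max(0L, ord$start[hi] - ord$end[lo] - 1L) <= policy$max_gap_bp
  }
  Rs <- which(ord$role == "R"); Is <- which(ord$role == "I")
  triples <- list()
  if (length(Rs) >= 2 && length(Is) >= 1) {
    for (a in seq_along(Rs)) for (b in seq_along(Rs)) for (i in Is) {
      if (a < b && ord$strand[Rs[a]] == ord$strand[Rs[b]] &&
          ok(Rs[a], Rs[b]) && (ok(i, Rs[a]) || ok(i, Rs[b]))) {
        triples[[length(triples) + 1L]] <- c(Rs[a], Rs[b], i)
      }
    }
  }
  pairs <- list()
  for (r in Rs) for (i in Is) if (ok(r, i)) pairs[[length(pairs) + 1L]] <- c(r, i)

  max_pairs_given <- function(used) {
    f <- function(k, used) {
      if (k > length(pairs)) return(0L)
      r <- f(k + 1L, used)
      p <- pairs[[k]]
      if (!any(p %in% used)) r <- max(r, 1L + f(k + 1L, c(used, p)))
      r
    }
    f(1L, used)
  }
  best <- c(-1L, -1L)
  rec_tri <- function(k, used, nd) {
    if (k > length(triples)) {
      np <- max_pairs_given(used)
      if (nd > best[1] || (nd == best[1] && np > best[2])) best <<- c(nd, np)
      return(invisible(NULL))
    }
    t <- triples[[k]]
    if (!any(t %in% used)) rec_tri(k + 1L, c(used, t), nd + 1L)
    rec_tri(k + 1L, used, nd)
  }
  rec_tri(1L, integer(0), 0L)
  n_r <- length(Rs); n_i <- length(Is)
  c(doubles = best[1], pairs = best[2],
    luxR_solos = n_r - 2L * best[1] - best[2],
    luxI_solos = n_i - best[1] - best[2])
}

# Random single-contig lux instance for arrangement property tests.
random_lux_contig <- function(seed, n_lux_max = 6L) {
  withr::with_seed(seed, {
    n <- sample(2:8, 1L)
    roles <- sample(c("R", "I", "none"), n, replace = TRUE,
                    prob = c(0.4, 0.3, 0.3))
    while (sum(roles != "none") > n_lux_max) {
      roles[sample(which(roles != "none"), 1L)] <- "none"
    }
    start <- integer(n); end <- integer(n); cur <- 1L
    for (k in seq_len(n)) {
      cur <- cur + sample(0:4000, 1L)
      start[k] <- cur
      cur <- cur + sample(750:900, 1L)
      end[k] <- cur
    }
    tibble::tibble(genome_id = "t", contig_id = "c1",
                   start = start, end = end,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   gene_id = sprintf("g%02d", seq_len(n)),
                   product = "hypothetical protein",
                   role = roles)
  })
}

verdicts_from_roles <- function(genes) {
  v <- ifelse(genes$role == "R", "AUTHENTIC_LUXR",
              ifelse(genes$role == "I", "AUTHENTIC_LUXI",
                     ifelse(genes$role == "T", "LUXR_LIKE_INCOMPLETE", "NONE")))
  tibble::tibble(gene_id = genes$gene_id, verdict = v,
                 present_signatures = "", missing_signatures = "",
                 n_terminal_truncation_suspected = FALSE, dual_role = FALSE)
}

# Mirror a contig: flip coordinates and strands.
reverse_contig <- function(genes) {
  L <- max(genes$end) + 500L
  out <- genes
  out$start <- L - genes$end + 1L
  out$end <- L - genes$start + 1L
  out$strand <- ifelse(genes$strand == "+", "-", "+")
  out[order(out$start), , drop = FALSE]
}

random_aa <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE), collapse = "")
}

sub_at <- function(s, pos, res) {
  ch <- strsplit(s, "")[[1]]; ch[pos] <- res; paste(ch, collapse = "")
}
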