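mk_genes <- function(roles, strands, gaps = 200L, contig = "c1") {
  n <- length(roles)
  gaps <- rep_len(gaps, n)
  start <- integer(n); end <- integer(n); cur <- 1L
  for (k in seq_len(n)) {
    cur <- cur + gaps[k]
    start[k] <- cur; cur <- cur + 899L; end[k] <- cur
  }
  tibble::tibble(genome_id = "t", contig_id = contig, start = start, end = end,
                 strand = strands, gene_id = sprintf("%s_g%d", contig, seq_len(n)),
                 product = "hypothetical protein", role = roles)
}

call_on <- function(genes, policy = proximity_policy()) {
  call_arrangements(genes[, setdiff(names(genes), "role")],
                    verdicts_from_roles(genes), policy)
}

test_that("a convergent synthase/regulator couple is one canonical pair", {
  g <- mk_genes(c("I", "R"), c("+", "-"))
  calls <- call_on(g)
  expect_equal(calls$category, "canonical_pair")
  expect_equal(calls$gene_ids, "c1_g1;c1_g2")
  expect_equal(calls$luxR_luxI_relation, "convergent")
})

test_that("a lone regulator is a luxR solo; contigs never share a pair", {
  g <- mk_genes(c("R"), "+")
  expect_equal(call_on(g)$category, "luxR_solo")

  g2 <- rbind(mk_genes("I", "+", contig = "cA"),
              mk_genes("R", "-", contig = "cB"))
  calls <- call_on(g2)
  expect_setequal(calls$category, c("luxI_solo", "luxR_solo"))
})

test_that("two tandem regulators with a proximal synthase form a double locus", {
  g <- mk_genes(c("R", "R", "I"), c("+", "+", "-"))
  calls <- call_on(g)
  expect_equal(calls$category, "double_luxR_luxI")
  expect_equal(calls$luxR_pair_relation, "tandem")
  expect_equal(calls$luxR_luxI_relation, "convergent")
  expect_equal(calls$luxI_gene, "c1_g3")
})

test_that("a synthase beyond the proximity policy stays a solo", {
  # regulator four genes downstream of a pair: the distant regulator is a solo
  g <- mk_genes(c("I", "R", "none", "none", "none", "none", "R"),
                c("+", "-", "+", "+", "+", "+", "+"))
  calls <- call_on(g)
  expect_setequal(calls$category, c("canonical_pair", "luxR_solo"))
  # and a >5 kb gap unpairs even rank-adjacent genes
  g2 <- mk_genes(c("I", "R"), c("+", "-"), gaps = c(100L, 6000L))
  expect_setequal(call_on(g2)$category, c("luxI_solo", "luxR_solo"))
})

test_that("luxI solos report upstream distance and truncated neighbors", {
  # truncated regulator immediately upstream, convergently oriented
  g <- mk_genes(c("T", "I"), c("+", "-"), gaps = c(100L, 300L))
  calls <- call_on(g)
  expect_equal(calls$category, "luxI_solo")
  expect_true(calls$adjacent_truncated_luxR)
  # solo on "-" strand: upstream is the next gene to the right; none here
  expect_true(is.na(calls$upstream_intergenic_bp))

  g2 <- mk_genes(c("none", "I"), c("+", "+"), gaps = c(100L, 900L))
  calls2 <- call_on(g2)
  expect_equal(calls2$upstream_intergenic_bp, 899L)
  expect_false(calls2$adjacent_truncated_luxR)
})

test_that("lux gene counts decompose exactly over the called categories", {
  for (s in 1:25) {
    g <- random_lux_contig(s)
    calls <- call_on(g)
    nd <- sum(calls$category == "double_luxR_luxI")
    np <- sum(calls$category == "canonical_pair")
    expect_equal(sum(g$role == "R"),
                 2L * nd + np + sum(calls$category == "luxR_solo"))
    expect_equal(sum(g$role == "I"),
                 nd + np + sum(calls$category == "luxI_solo"))
  }
})

test_that("mirroring a contig leaves the category multiset unchanged", {
  for (s in 26:45) {
    g <- random_lux_contig(s)
    calls <- call_on(g)
    grev <- reverse_contig(g)
    calls_rev <- call_on(grev)
    expect_equal(sort(calls$category), sort(calls_rev$category), info = paste("seed", s))
  }
})

test_that("assignment matches the exhaustive doubles-then-pairs optimum", {
  policy <- proximity_policy()
  for (s in 101:160) {
    g <- random_lux_contig(s)
    calls <- call_on(g, policy)
    got <- c(doubles = sum(calls$category == "double_luxR_luxI"),
             pairs = sum(calls$category == "canonical_pair"),
             luxR_solos = sum(calls$category == "luxR_solo"),
             luxI_solos = sum(calls$category == "luxI_solo"))
    want <- arrangement_counts_oracle(g, policy)
    expect_equal(got, want, info = paste("seed", s))
  }
})

test_that("verdicts referencing unknown genes are a hard error", {
  g <- mk_genes("R", "+")
  v <- rbind(verdicts_from_roles(g),
             verdicts_from_roles(mk_genes("I", "+", contig = "ghost")))
  expect_error(call_arrangements(g[, setdiff(names(g), "role")], v),
               "absent")
})

test_that("the downstream neighborhood of a double locus is typed by catalog", {
  g <- mk_genes(c("R", "R", "I", "none", "none", "none", "none", "none"),
                c("+", "+", "-", "+", "-", "+", "+", "-"))
  g$product <- c("regulator", "regulator", "synthase",
                 "phytanoyl dioxygenase", "hypothetical protein",
                 "virB1", "virB2", "virB3")
  calls <- call_on(g)
  dbl <- calls[calls$category == "double_luxR_luxI", ]
  expect_equal(type_topology(dbl, g), "T")

  g$product[4:8] <- "unrelated thing"
  expect_equal(type_topology(dbl, g), "UNTYPED")

  # user catalog and synonym normalization (case-insensitive, trimmed)
  g$product[4] <- "  Cystathionine Gamma-Synthase "
  g$product[5] <- "lcmT"
  expect_equal(type_topology(dbl, g, catalog = list(custom1 = c("metB", "lcmT"))),
               "custom1")

  # non-double categories are not typed
  solo <- call_on(mk_genes("R", "+"))
  expect_equal(type_topology(solo, mk_genes("R", "+")), "N/A")
})

test_that("topology catalogs load from YAML with unique labels", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("T: [phyH, X, virB1, virB2, virB3]",
               "T3: [phyH, X]"), p)
  cat <- read_topology_catalog(p)
  expect_equal(names(cat), c("T", "T3"))
  expect_equal(cat$T3, c("phyH", "X"))
})
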