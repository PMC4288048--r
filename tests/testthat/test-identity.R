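test_that("identity is 100 for identical sequences and 75 for AAAA/AAAT", {
  expect_equal(pairwise_identity("MKTAYIAKQR", "MKTAYIAKQR"), 100)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 75)
})

test_that("identity is symmetric, diagonal is exactly 100", {
  withr::with_seed(21, {
    prot <- tibble::tibble(gene_id = sprintf("p%d", 1:5),
                           sequence = vapply(1:5, function(i) random_aa(60),
                                             character(1)))
    m <- identity_matrix(prot)
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 100))
    expect_true(all(m >= 0 & m <= 100))
    # invariant under relabeling / input order
    perm <- c(3, 1, 5, 2, 4)
    m2 <- identity_matrix(prot[perm, ])
    expect_equal(m2[rownames(m), colnames(m)], m)
  })
})

test_that("gap-inclusive identity never exceeds the aligned-positions mode", {
  withr::with_seed(22, {
    for (k in 1:15) {
      a <- random_aa(sample(20:60, 1)); b <- random_aa(sample(20:60, 1))
      expect_lte(pairwise_identity(a, b, "full_length"),
                 pairwise_identity(a, b, "aligned_positions"))
    }
  })
})

test_that("partner-group summaries separate within- from cross-locus identity", {
  seeds <- luxcensus:::seed_proteins()
  A <- seeds$sequence[seeds$gene_id == "luxR_seed_1"]
  withr::with_seed(5, {
    prot <- tibble::tibble(gene_id = character(), sequence = character())
    grp <- tibble::tibble(gene_id = character(), locus_id = character(),
                          slot = character())
    for (i in 1:3) {
      # slot-A regulators are clones across loci; each B partner diverged
      prot <- rbind(prot, tibble::tibble(
        gene_id = c(sprintf("L%dA", i), sprintf("L%dB", i)),
        sequence = c(A, mutate_sequence(A, 0.5))))
      grp <- rbind(grp, tibble::tibble(
        gene_id = c(sprintf("L%dA", i), sprintf("L%dB", i)),
        locus_id = sprintf("L%d", i), slot = c("A", "B")))
    }
    m <- identity_matrix(prot)
    gs <- group_summary(m, grp)
    expect_equal(gs$between_max, 100)      # cloned same-slot partners
    expect_lt(gs$within_mean, gs$between_max)
    expect_equal(nrow(gs$within), 3L)
  })
})

test_that("a single locus has no cross-locus statistics", {
  prot <- tibble::tibble(gene_id = c("a", "b"),
                         sequence = c("MKTAYIAKQR", "MKTAYWAKQR"))
  gs <- group_summary(identity_matrix(prot),
                      data.frame(gene_id = c("a", "b"), locus_id = "L1",
                                 slot = c("A", "B")))
  expect_true(is.na(gs$between_max))
  expect_equal(nrow(gs$between), 0L)
})

test_that("groups referencing unknown labels are an error", {
  prot <- tibble::tibble(gene_id = c("a", "b"),
                         sequence = c("MKTAYIAKQR", "MKTAYWAKQR"))
  expect_error(group_summary(identity_matrix(prot),
                             data.frame(gene_id = c("a", "zzz"),
                                        locus_id = "L1", slot = c("A", "B"))),
               "unknown label")
})

test_that("matrix export is deterministic in both layouts", {
  prot <- tibble::tibble(gene_id = c("b", "a"),
                         sequence = c("MKTAYIAKQR", "MKTAYWAKQR"))
  m <- identity_matrix(prot)
  t1 <- withr::local_tempfile(); c1 <- withr::local_tempfile()
  write_identity_matrix(m, t1, c1)
  tsv <- utils::read.delim(t1, check.names = FALSE)
  expect_equal(tsv$gene_id, rownames(m))
  long <- utils::read.csv(c1)
  expect_equal(nrow(long), 3L)  # upper triangle incl. diagonal of a 2x2
})
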