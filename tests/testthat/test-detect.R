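hit <- function(gene, sig, ev = NA_real_) {
  tibble::tibble(gene_id = gene, signature_id = sig, evalue = ev,
                 ali_start = NA_integer_, ali_end = NA_integer_)
}

test_that("the Pfam prefilter applies a strict 1e-5 e-value cut", {
  rules <- signature_rules()
  h <- dplyr::bind_rows(
    hit("g1", "PF03472", 1e-20),
    hit("g2", "PF03472", 1e-4),
    hit("g3", "PF03472", 1e-5),      # boundary: not strictly below
    hit("g4", "PF00765", 1e-9),
    hit("g5", "IPR005143", 1e-30),   # not a prefilter signature
    hit("g6", "PF03472", NA_real_))  # no e-value: advisory pass
  expect_equal(prefilter(h, rules), c("g1", "g4", "g6"))
  expect_equal(prefilter(h[0, ], rules), character(0))
})

test_that("completeness verdicts follow the signature rule sets", {
  rules <- signature_rules()
  v <- classify_protein("g", hit("g", c("IPR005143", "IPR016032",
                                        "IPR011991", "IPR000792")), rules)
  expect_equal(v$verdict, "AUTHENTIC_LUXR")
  expect_equal(v$missing_signatures, "")

  v <- classify_protein("g", hit("g", c("IPR001690", "IPR018311")), rules)
  expect_equal(v$verdict, "AUTHENTIC_LUXI")

  v <- classify_protein("g", hit("none", "IPR005143"), rules)  # no hits for g
  expect_equal(v$verdict, "NONE")

  v <- classify_protein("g", hit("g", c("IPR000792", "IPR011991")), rules)
  expect_equal(v$verdict, "LUXR_LIKE_INCOMPLETE")
  expect_true(v$n_terminal_truncation_suspected)

  # incomplete but with the autoinducer-binding signature present:
  # no truncation suspicion
  v <- classify_protein("g", hit("g", c("IPR005143", "IPR011991")), rules)
  expect_equal(v$verdict, "LUXR_LIKE_INCOMPLETE")
  expect_false(v$n_terminal_truncation_suspected)
})

test_that("a repeated signature hit counts once (set membership, not counts)", {
  rules <- signature_rules()
  h <- hit("g", rep(c("IPR005143", "IPR016032", "IPR011991", "IPR000792"), 3))
  expect_equal(classify_protein("g", h, rules)$verdict, "AUTHENTIC_LUXR")
})

test_that("a dual-complete protein is reported with both verdicts, flagged", {
  rules <- signature_rules()
  v <- classify_protein("g", hit("g", c("IPR005143", "IPR016032", "IPR011991",
                                        "IPR000792", "IPR001690", "IPR018311")),
                        rules)
  expect_equal(sort(v$verdict), c("AUTHENTIC_LUXI", "AUTHENTIC_LUXR"))
  expect_true(all(v$dual_role))
})

test_that("adding signatures never demotes a verdict", {
  rank_of <- function(v) {
    if (any(v %in% c("AUTHENTIC_LUXR", "AUTHENTIC_LUXI"))) 3L
    else if (any(v == "LUXR_LIKE_INCOMPLETE")) 2L else 1L
  }
  rules <- signature_rules()
  all_sigs <- c(rules$luxR_required, rules$luxI_required, "IPR999999")
  withr::with_seed(42, {
    for (k in 1:200) {
      sigs <- sample(all_sigs, sample(0:5, 1))
      extra <- sample(all_sigs, 1)
      v1 <- classify_protein("g", hit("g", sigs), rules)$verdict
      v2 <- classify_protein("g", hit("g", c(sigs, extra)), rules)$verdict
      expect_gte(rank_of(v2), rank_of(v1))
    }
  })
})

test_that("raising the e-value ceiling never shrinks the prefiltered set", {
  withr::with_seed(7, {
    for (k in 1:20) {
      h <- hit(sprintf("g%02d", 1:15),
               sample(c("PF03472", "PF00765", "IPR005143"), 15, replace = TRUE),
               10^runif(15, -30, 0))
      s1 <- prefilter(h, signature_rules(evalue_max = 1e-8))
      s2 <- prefilter(h, signature_rules(evalue_max = 1e-3))
      expect_true(all(s1 %in% s2))
    }
  })
})

test_that("verdicts agree with a brute-force set-comparison oracle", {
  rules <- signature_rules()
  pool <- c(rules$luxR_required, rules$luxI_required,
            "IPR123456", "IPR999999", "PF03472", "PF00765")
  withr::with_seed(99, {
    for (k in 1:1000) {
      sigs <- sample(pool, sample(0:8, 1))
      got <- sort(classify_protein("g", hit("g", sigs), rules)$verdict)
      expect_equal(got, sort(verdict_oracle(sigs)), info = paste(sigs, collapse = ","))
    }
  })
})

test_that("rule sets are overridable from YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("evalue_max: 1.0e-3",
               "luxR_required: [IPR005143, IPR000792]"), p)
  rules <- read_signature_rules(p)
  expect_equal(rules$evalue_max, 1e-3)
  expect_equal(rules$luxR_required, c("IPR005143", "IPR000792"))
  expect_equal(rules$luxI_required, c("IPR001690", "IPR018311"))  # default kept
  v <- classify_protein("g", hit("g", c("IPR005143", "IPR000792")), rules)
  expect_equal(v$verdict, "AUTHENTIC_LUXR")
})
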