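test_that("aligning a reference to itself is the identity alignment", {
  m <- site_map_trar()
  al <- align_to_reference(m$sequence, m)
  expect_equal(al$aligned_a, m$sequence)
  expect_equal(al$aligned_b, m$sequence)
})

test_that("one internal deletion produces exactly one gap column", {
  m <- site_map_trar()
  q <- paste0(substr(m$sequence, 1, 119), substr(m$sequence, 121, nchar(m$sequence)))
  al <- align_to_reference(q, m)
  expect_equal(sum(strsplit(al$aligned_a, "")[[1]] == "-"), 1L)
  expect_equal(sum(strsplit(al$aligned_b, "")[[1]] == "-"), 0L)
})

test_that("a single-residue query still spans the reference (global mode)", {
  m <- site_map_trar()
  al <- align_to_reference("W", m)
  expect_equal(nchar(al$aligned_b), nchar(m$sequence))
  expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
})

test_that("alignment scores equal a brute-force affine-gap DP", {
  withr::with_seed(31, {
    for (k in 1:40) {
      a <- random_aa(sample(5:30, 1)); b <- random_aa(sample(5:30, 1))
      expect_equal(align_global(a, b)$score, nw_score_oracle(a, b),
                   info = paste(a, b))
    }
  })
})

test_that("non-amino-acid input is rejected", {
  expect_error(align_global("MKT!", "MKT"), "alphabet")
})

test_that("the reference itself is all-conserved for both packaged maps", {
  for (m in list(site_map_trar(), site_map_trai())) {
    rep <- check_conserved_sites(m$sequence, m)
    expect_true(all(rep$sites$status == "conserved"))
    expect_false(rep$pab_like_flag)
  }
})

test_that("named regulator substitutions are reported in reference numbering", {
  m <- site_map_trar()
  r <- check_conserved_sites(sub_at(m$sequence, 57, "V"), m)
  expect_equal(r$sites$label[r$sites$position == 57], "W57V")
  expect_equal(r$sites$status[r$sites$position == 57], "substituted")
  expect_false(r$pab_like_flag)

  r <- check_conserved_sites(sub_at(m$sequence, 61, "W"), m)
  expect_equal(r$sites$label[r$sites$position == 61], "Y61W")
  expect_true(r$pab_like_flag)

  r <- check_conserved_sites(sub_at(m$sequence, 182, "I"), m)
  expect_equal(r$sites$label[r$sites$position == 182], "L182I")
})

test_that("sites falling in query gaps are reported as missing", {
  m <- site_map_trar()
  # N-terminally truncated query: starts at reference position 100
  q <- substr(m$sequence, 100, nchar(m$sequence))
  r <- check_conserved_sites(q, m)
  expect_true(all(r$sites$status[r$sites$position < 100] == "missing"))
  expect_true(all(r$sites$observed[r$sites$position < 100] == "-"))
  expect_true(all(r$sites$status[r$sites$position > 100] == "conserved"))
})

test_that("insertions far from the sites never change the site report", {
  m <- site_map_trar()
  base <- check_conserved_sites(m$sequence, m)
  withr::with_seed(8, {
    for (k in 1:10) {
      ins <- random_aa(sample(3:10, 1))
      q <- paste0(m$sequence, ins)  # C-terminal insertion, beyond site 188
      r <- check_conserved_sites(q, m)
      expect_equal(r$sites, base$sites)
    }
  })
})

test_that("a caller-supplied alignment (MSA column mode) is honoured", {
  m <- site_map_trar()
  q <- sub_at(m$sequence, 61, "W")
  al <- list(aligned_a = q, aligned_b = m$sequence)  # pre-aligned, gapless
  r <- check_conserved_sites(q, m, alignment = al)
  expect_true(r$pab_like_flag)
})

test_that("a site map that contradicts its own sequence is rejected", {
  expect_error(site_map("X", "MKTAY",
                        data.frame(position = 2, expected = "W",
                                   role = "DNA_binding")),
               "mismatch")
})
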