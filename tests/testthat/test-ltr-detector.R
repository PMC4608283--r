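# Structural LTR detection: candidate discovery, validation, whole-genome
# detection and its invariances.

test_that("random sequence yields no high-identity long candidates", {
  s <- generate_background(100000, seed = 21)
  cands <- find_candidate_pairs(s)
  if (nrow(cands)) {
    expect_true(all(cands$identity < 0.8 |
                      (cands$ltr5_end - cands$ltr5_start + 1) < 100))
  } else succeed()
})

test_that("an exact planted direct repeat is recovered exactly", {
  withr::with_seed(22, {
    rep_ <- ltrscan:::random_dna(500)
    inner <- ltrscan:::random_dna(4000)
    s <- paste0(ltrscan:::random_dna(20000), rep_, inner, rep_,
                ltrscan:::random_dna(20000))
  })
  cands <- find_candidate_pairs(s)
  expect_equal(nrow(cands), 1)
  # boundaries identifiable up to chance single-base flank homology
  expect_lte(abs(cands$ltr5_start - 20001), 1)
  expect_lte(abs(cands$ltr5_end - 20500), 1)
  expect_lte(abs(cands$ltr3_start - 24501), 1)
  expect_equal(cands$identity, 1.0)
})

test_that("identity of a mutated repeat tracks the substitution oracle", {
  withr::with_seed(23, {
    rep_ <- ltrscan:::random_dna(600)
    rep2 <- mutate_uniform(rep_, 0.10)
    s <- paste0(ltrscan:::random_dna(15000), rep_,
                ltrscan:::random_dna(3000), rep2,
                ltrscan:::random_dna(15000))
  })
  cands <- find_candidate_pairs(s)
  expect_equal(nrow(cands), 1)
  # substitution-only planted pair: alignment identity should sit within
  # 0.03 of the direct per-site identity
  oracle <- subst_identity_oracle(
    substr(s, cands$ltr5_start, cands$ltr5_end),
    substr(s, cands$ltr3_start, cands$ltr3_start +
             (cands$ltr5_end - cands$ltr5_start)))
  expect_lt(abs(cands$identity - oracle), 0.03)
})

test_that("validation applies the length, identity and TSD rules", {
  # build an oversized repeat structure (span > 12 kb) with a TSD
  withr::with_seed(24, {
    rep_ <- ltrscan:::random_dna(600)
    tsd <- "ACGTA"
    s <- paste0(ltrscan:::random_dna(14000), tsd, rep_,
                ltrscan:::random_dna(11600), rep_, tsd,
                ltrscan:::random_dna(14000))
  })
  cands <- find_candidate_pairs(s)
  expect_equal(nrow(cands), 1)
  v <- validate_element(cands[1, ], s)
  expect_false(v$accepted)
  expect_identical(v$reason, "too_long")

  # identity below threshold
  cand <- data.frame(ltr5_start = 100L, ltr5_end = 400L,
                     ltr3_start = 3000L, ltr3_end = 3300L,
                     identity = 0.55)
  v2 <- validate_element(cand, generate_background(5000, seed = 25))
  expect_false(v2$accepted)
  expect_identical(v2$reason, "low_identity")

  # coordinates outside the sequence are an error
  bad <- data.frame(ltr5_start = -5L, ltr5_end = 400L,
                    ltr3_start = 3000L, ltr3_end = 3300L, identity = 0.9)
  expect_error(validate_element(bad, "ACGT"), "outside")
})

test_that("a perfect planted element is accepted with its exact TSD", {
  el <- build_element(element_spec("Copia", divergence_age = 0), seed = 26)
  withr::with_seed(27, {
    s <- paste0(ltrscan:::random_dna(20000), "ACGTA", el$seq, "ACGTA",
                ltrscan:::random_dna(20000))
  })
  cands <- find_candidate_pairs(s)
  expect_gte(nrow(cands), 1)
  v <- validate_element(cands[which.max(cands$identity), ], s)
  expect_true(v$accepted)
  # the planted TSD is recovered up to chance one-base extension (the
  # longest exact flank duplication wins)
  expect_true(grepl("ACGTA", v$tsd, fixed = TRUE))
  expect_lte(abs(v$start - 20006), 1)
  expect_lte(abs(v$end - (20005 + nchar(el$seq))), 1)
  # reported TSD flanks are identical strings on both sides
  t <- nchar(v$tsd)
  expect_identical(substr(s, v$start - t, v$start - 1),
                   substr(s, v$end + 1, v$end + t))
  expect_true(v$has_pbs)
  expect_true(v$has_ppt)
})

test_that("detection recovers planted elements with exact bookkeeping", {
  sim <- mini()
  det <- detect_ltr(sim$genome)
  expect_equal(nrow(det$elements), 3)
  m <- match_to_truth(det$elements, sim$elements)
  expect_true(all(!is.na(m)))
  expect_true(all(abs(det$elements$start - sim$elements$start[m]) <= 5))
  expect_true(all(abs(det$elements$end - sim$elements$end[m]) <= 5))
  # accepted elements respect the structural invariants
  expect_true(all(det$elements$ltr_identity >= 0.8))
  expect_true(all(det$elements$length <= 12000))
  # deterministic ordering by (scaffold, start)
  expect_true(!is.unsorted(det$elements$start))
})

test_that("detection is invariant to line wrapping and scaffold order", {
  sim <- mini()
  two <- c(sim$genome, rev_scaf = generate_background(15000, seed = 28))
  det1 <- detect_ltr(two)
  det2 <- detect_ltr(two[rev(seq_along(two))])
  expect_equal(det1$elements$start, det2$elements$start)
  expect_equal(det1$elements$ltr_identity, det2$elements$ltr_identity)

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  x <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(x, f1, width = 60)
  Biostrings::writeXStringSet(x, f2, width = 9999)
  d1 <- detect_ltr(f1); d2 <- detect_ltr(f2)
  expect_equal(d1$elements, d2$elements)
})

test_that("nested overlapping calls resolve to a single element", {
  # an intact element planted inside the internal region of an older one:
  # two candidate pairs overlap, the resolution rule keeps exactly one
  inner_el <- build_element(
    element_spec("NA", domain_list = "GAG", ltr_length = 300,
                 internal_length = 1200, divergence_age = 0), seed = 29)
  outer <- build_element(
    element_spec("Copia", ltr_length = 800, internal_length = 6000,
                 divergence_age = 0.08), seed = 30)
  mid <- nchar(outer$seq) %/% 2
  withr::with_seed(31, {
    s <- paste0(ltrscan:::random_dna(16000), "GCTAG",
                substr(outer$seq, 1, mid), "TTAGC", inner_el$seq, "TTAGC",
                substr(outer$seq, mid + 1, nchar(outer$seq)), "GCTAG",
                ltrscan:::random_dna(16000))
  })
  det <- detect_ltr(c(s1 = s))
  expect_equal(nrow(det$elements), 1)
})

test_that("empty or short genomes give empty results", {
  det <- detect_ltr(c(s1 = "ACGTACGT"))
  expect_equal(nrow(det$elements), 0)
})
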