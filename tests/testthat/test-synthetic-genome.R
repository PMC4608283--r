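# The synthetic-genome generator: backgrounds, planted elements, reads.

test_that("background sequence honors length, GC, N budget and seed", {
  s <- generate_background(1000, n_run_fraction = 0, seed = 1)
  expect_equal(nchar(s), 1000)
  expect_false(grepl("N", s, fixed = TRUE))

  # binomial oracle: observed GC within 3 SD of 0.5 at n = 1e6
  s2 <- generate_background(1e6, gc = 0.5, seed = 2)
  gcf <- mean(strsplit(s2, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcf - 0.5), 3 * sqrt(0.25 / 1e6))

  expect_identical(generate_background(5000, seed = 7),
                   generate_background(5000, seed = 7))
  expect_error(generate_background(0))

  s3 <- generate_background(50000, n_run_fraction = 0.1, seed = 3)
  nfrac <- mean(strsplit(s3, "")[[1]] == "N")
  expect_gt(nfrac, 0.05)
  expect_lt(nfrac, 0.15)
})

test_that("built elements have the specified structure", {
  sp <- element_spec("Copia", "Tork", ltr_length = 600,
                     internal_length = 3500, divergence_age = 0)
  el <- build_element(sp, seed = 4)
  expect_equal(nchar(el$seq), 2 * 600 + 3500)
  # zero divergence: LTR pair identical
  expect_identical(substr(el$seq, 1, 600),
                   substr(el$seq, nchar(el$seq) - 599, nchar(el$seq)))
  # PBS is the reverse complement of a bundled tRNA 3' end, within 20 bp
  # of the LTR5 end
  pbs <- substr(el$seq, el$truth$pbs[1], el$truth$pbs[2])
  expect_identical(pbs, revcomp(trna_3prime_library()[[el$truth$trna]]))
  expect_lte(el$truth$pbs[1] - 600, 20)
  # PPT is purine-rich just before the 3' LTR
  ppt <- strsplit(substr(el$seq, el$truth$ppt[1], el$truth$ppt[2]), "")[[1]]
  expect_equal(mean(ppt %in% c("A", "G")), 1)
  # domain intervals carry the planted reference's reverse translation
  lib <- make_domain_library()
  rt <- el$truth$domains[el$truth$domains$kind == "RT", ]
  planted <- substr(el$seq, rt$start, rt$end)
  expect_identical(planted, ltrscan:::reverse_translate(
    lib$seq[lib$id == rt$ref]))
})

test_that("LTR divergence follows the K2P model expectation", {
  # simulate and compare the mean observed mismatch fraction with the
  # closed-form P+Q at K = 0.10
  pq <- k2p_event_probs(0.10, tstv = 2)
  expect_true(withr::with_seed(5, {
    mism <- replicate(100, {
      l5 <- ltrscan:::random_dna(1000)
      l3 <- mutate_k2p(l5, 0.10, 2)
      mean(strsplit(l5, "")[[1]] != strsplit(l3, "")[[1]])
    })
    exp_p <- pq[["P"]] + pq[["Q"]]
    se <- sqrt(exp_p * (1 - exp_p) / (100 * 1000))
    abs(mean(mism) - exp_p) < 3 * se
  }))
})

test_that("element specs enforce the non-autonomous domain rule", {
  # GAG-only spec: truth superfamily is NA
  sp <- element_spec("Copia", domain_list = "GAG", internal_length = 1500)
  expect_identical(sp$truth_superfamily, "NA")
  expect_error(element_spec("NA", domain_list = c("GAG", "RT")),
               "GAG/PR")
  # domain list that does not fit the internal length
  expect_error(build_element(element_spec("Copia", internal_length = 500),
                             seed = 1),
               "does not fit")
})

test_that("planting records exact coordinates and duplicates the TSD", {
  sim <- mini()
  g <- sim$genome[[1]]
  for (i in seq_len(nrow(sim$elements))) {
    e <- sim$elements[i, ]
    # truth start/end match string search for the element
    expect_identical(substr(g, e$start, e$end),
                     sim$element_seqs[[e$element_id]])
    # TSD flanks immediately outside both LTRs are identical
    t <- nchar(e$tsd)
    expect_identical(substr(g, e$start - t, e$start - 1),
                     substr(g, e$end + 1, e$end + t))
    expect_identical(substr(g, e$start - t, e$start - 1), e$tsd)
  }
  # intervals within scaffold bounds, non-overlapping
  expect_true(all(sim$elements$start > 0))
  expect_true(all(sim$elements$end <= nchar(g)))
  o <- order(sim$elements$start)
  expect_true(all(diff(sim$elements$start[o]) >
                    sim$elements$length[o][-nrow(sim$elements)]))
})

test_that("planting fails loudly when there is no room", {
  bg <- stats::setNames(generate_background(30000, seed = 9), "tiny")
  specs <- replicate(4, element_spec("Copia"), simplify = FALSE)
  expect_error(plant_elements(bg, specs, seed = 10), "insufficient room")
})

test_that("read simulation matches its sampling design", {
  lib <- withr::with_seed(6, c(A = ltrscan:::random_dna(2000),
                               B = ltrscan:::random_dna(2000)))
  # error-free reads are exact substrings of their origin
  rd0 <- generate_reads(lib["A"], c(A = 1), read_length = 80, depth = 50,
                        error_rate = 0, seed = 13)
  ok <- vapply(rd0$tissues[[1]]$seq, function(s)
    grepl(s, lib[["A"]], fixed = TRUE) ||
      grepl(revcomp(s), lib[["A"]], fixed = TRUE), TRUE)
  expect_true(all(ok))

  # binomial oracle on 9:1 origin levels
  rd <- generate_reads(lib, c(A = 9, B = 1), read_length = 100,
                       depth = 5000, error_rate = 0.005, seed = 14)
  expect_lt(abs(rd$truth_counts["A", 1] - 4500),
            3 * sqrt(5000 * 0.9 * 0.1))

  # determinism: same seed gives byte-identical FASTQ
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(rd$tissues[[1]], f1)
  rd2 <- generate_reads(lib, c(A = 9, B = 1), read_length = 100,
                        depth = 5000, error_rate = 0.005, seed = 14)
  write_fastq(rd2$tissues[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(generate_reads(lib, c(A = 0, B = 0), depth = 10), "zero total")
  expect_error(generate_reads(lib, c(A = 1, B = 1), read_length = 3000),
               "read_length")
})

test_that("element reconstruction from truth coordinates is exact", {
  sim <- mini()
  for (id in names(sim$element_seqs)) {
    e <- sim$elements[sim$elements$element_id == id, ]
    expect_identical(
      substr(sim$genome[[e$scaffold]], e$start, e$end),
      sim$element_seqs[[id]])
  }
})
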