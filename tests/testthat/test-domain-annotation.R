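# Six-frame translation, domain scanning and superfamily classification.

test_that("six-frame translation follows the standard code", {
  fr <- translate_six_frames("ATGGCC")
  expect_identical(fr[["+1"]], "MA")
  expect_identical(translate_six_frames("TAA")[["+1"]], "*")
  # reverse-complement symmetry
  s <- withr::with_seed(32, ltrscan:::random_dna(99))
  expect_identical(translate_six_frames(s)[["-1"]],
                   translate_six_frames(revcomp(s))[["+1"]])
  # N codons become X, non-IUPAC characters are an error
  expect_identical(translate_six_frames("ATGNNN")[["+1"]], "MX")
  expect_error(translate_six_frames("AZQT"))
})

test_that("planted domains are found with tiny E-values at +-1 codon", {
  lib <- make_domain_library()
  el <- build_element(element_spec("Gypsy", "Athila"), seed = 33,
                      domain_lib = lib)
  hits <- scan_domains(el$seq, lib)
  expect_setequal(unique(hits$kind), c("GAG", "PR", "INT", "RT", "RH"))
  rt_hit <- hits[hits$kind == "RT", ][1, ]
  expect_lt(rt_hit$e_value, 1e-10)
  rt_true <- el$truth$domains[el$truth$domains$kind == "RT", ]
  expect_lte(abs(rt_hit$start - rt_true$start), 3)
  expect_lte(abs(rt_hit$end - rt_true$end), 3)
  expect_identical(rt_hit$ref, "Gypsy_Athila_RT")
})

test_that("random sequence produces no hits at the E-value cutoff", {
  lib <- make_domain_library()
  for (seed in 34:43) {
    s <- withr::with_seed(seed, ltrscan:::random_dna(5000))
    expect_equal(nrow(scan_domains(s, lib)), 0)
  }
})

test_that("hit sets are monotone in the E-value cutoff", {
  lib <- make_domain_library()
  lib_small <- lib[lib$superfamily == "Copia" & lib$lineage == "Tork", ]
  el <- build_element(element_spec("Copia", "Tork"), seed = 44)
  strict <- scan_domains(el$seq, lib_small, e_cutoff = 1e-4,
                         prefilter = FALSE)
  loose <- scan_domains(el$seq, lib_small, e_cutoff = Inf,
                        prefilter = FALSE)
  key <- function(h) paste(h$kind, h$ref, h$frame)
  expect_true(all(key(strict) %in% key(loose)))
  expect_error(scan_domains(el$seq, lib[0, ]), "empty")
})

test_that("the superfamily rule handles all censuses", {
  no_hits <- scan_domains(
    withr::with_seed(45, ltrscan:::random_dna(2000)), make_domain_library())
  expect_identical(classify_superfamily(no_hits)$superfamily, "RXX-NA")

  # GAG+PR only -> RXX-NA
  el_na <- build_element(element_spec("NA", domain_list = c("GAG", "PR"),
                                      internal_length = 2600), seed = 46)
  h <- scan_domains(el_na$seq, make_domain_library())
  cl <- classify_superfamily(h)
  expect_identical(cl$superfamily, "RXX-NA")
  expect_equal(cl$n_domains, 2)

  # planted Gypsy-order element -> RLG, forward orientation
  el_g <- build_element(element_spec("Gypsy", "Del"), seed = 47)
  cl_g <- classify_superfamily(scan_domains(el_g$seq, make_domain_library()))
  expect_identical(cl_g$superfamily, "RLG")
  expect_identical(cl_g$lineage, "Del")
  expect_identical(cl_g$orientation, "forward")
})

test_that("disrupted ORFs still yield the full domain census", {
  # frameshift + premature stop: per-frame local hits cover the
  # fragments and same-kind hits are merged into one census entry
  el <- build_element(element_spec("Copia", "Sire", disrupt = TRUE),
                      seed = 48)
  cl <- classify_superfamily(scan_domains(el$seq, make_domain_library()))
  expect_identical(cl$superfamily, "RLC")
  expect_gte(cl$n_domains, 4)
})

test_that("domain census shares reproduce the printed arithmetic", {
  sh <- domain_census_shares(108, 215, 392)
  expect_equal(sh$four_or_five_pct, 82.4)
  expect_equal(sh$five_pct_nearest, 55)
  # degenerate case: everything five-domain
  expect_equal(domain_census_shares(0, 10, 10)$four_or_five_pct, 100)
  # empty classified collection
  empty <- summarize_domain_census(data.frame())
  expect_equal(nrow(empty$by_n_domains), 0)
})
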