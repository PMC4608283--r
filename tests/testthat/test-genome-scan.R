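# Copy counting, masking, window densities and the density correlation.

test_that("a verbatim reference copy is found complete at full identity", {
  ref <- withr::with_seed(81, ltrscan:::random_dna(3000))
  g <- withr::with_seed(82, paste0(ltrscan:::random_dna(30000), ref,
                                   ltrscan:::random_dna(30000)))
  hits <- find_copies(c(s1 = g), c(R1 = ref), c(R1 = "Copia"))
  expect_equal(sum(hits$complete), 1)
  h <- hits[hits$complete, ]
  expect_gte(h$identity, 0.999)
  expect_gte(h$coverage, 0.99)
  expect_equal(h$start, 30001, tolerance = 2)
})

test_that("mutated and fragmented copies follow the completeness rule", {
  withr::with_seed(83, {
    ref <- ltrscan:::random_dna(3000)
    bg <- ltrscan:::random_dna(2e5)
    g <- bg
    pos <- seq(20000, 180000, length.out = 6)
    for (p in rev(pos)) {
      cp <- mutate_k2p(ref, 0.15)
      if (stats::runif(1) < 0.5) cp <- revcomp(cp)
      g <- paste0(substr(g, 1, p - 1), cp, substr(g, p, nchar(g)))
    }
    # a half-length fragment: hit but not complete
    g <- paste0(g, substr(ref, 1, 1500), ltrscan:::random_dna(5000))
  })
  hits <- find_copies(c(s1 = g), c(R1 = ref), c(R1 = "Copia"))
  expect_equal(sum(hits$complete), 6)
  frag <- hits[!hits$complete, ]
  expect_equal(nrow(frag), 1)
  expect_lt(frag$coverage, 0.7)
})

test_that("copy counts are strand-symmetric", {
  sim <- mini()
  refs <- sim$element_seqs[1]
  h1 <- find_copies(sim$genome, refs, stats::setNames("Copia", names(refs)))
  grc <- stats::setNames(vapply(sim$genome, revcomp, ""), names(sim$genome))
  h2 <- find_copies(grc, refs, stats::setNames("Copia", names(refs)))
  expect_equal(sum(h1$complete), sum(h2$complete))
})

test_that("masking statistics handle N correctly and are monotone", {
  ref <- withr::with_seed(84, ltrscan:::random_dna(4000))
  # genome: half N run, half TE
  g <- c(s1 = paste0(strrep("N", 4000), ref))
  mk <- mask_genome(g, c(R1 = ref))
  expect_equal(mk$stats$frac_all, 0.5, tolerance = 0.01)
  expect_equal(mk$stats$frac_non_n, 1.0, tolerance = 0.01)

  # library = genome masks everything
  g2 <- c(s1 = withr::with_seed(85, ltrscan:::random_dna(20000)))
  mk2 <- mask_genome(g2, c(L1 = g2[[1]]))
  expect_equal(mk2$stats$frac_all, 1.0, tolerance = 0.01)

  # masked fraction is monotone as min_id decreases
  withr::with_seed(86, {
    g3 <- paste0(ltrscan:::random_dna(20000), mutate_k2p(ref, 0.12),
                 ltrscan:::random_dna(20000))
  })
  lo <- mask_genome(c(s1 = g3), c(R1 = ref), min_id = 0.70)
  hi <- mask_genome(c(s1 = g3), c(R1 = ref), min_id = 0.95)
  expect_gte(lo$stats$masked_bp, hi$stats$masked_bp)
})

test_that("masked fraction matches the planted element budget", {
  sim <- mini()
  mk <- mask_genome(sim$genome, sim$element_seqs)
  planted_bp <- sum(sim$elements$length)
  expect_lt(abs(mk$stats$frac_all - planted_bp / sum(nchar(sim$genome))),
            0.02)
})

test_that("window membership and densities follow the definition", {
  hits <- data.frame(scaffold = "s1", start = 11, track = "Copia")
  wd <- window_density(hits, NULL, c(s1 = 2e6))
  w <- wd[wd$track == "Copia" & wd$count > 0, ]
  # position 10 (0-based) is in [0, 1M) but not [500k, 1.5M)
  expect_equal(w$win_start, 0)
  expect_equal(w$density_per_mb, 1)

  # Poisson oracle: uniform hits over 10 Mb, non-overlapping windows
  withr::with_seed(87, {
    h2 <- data.frame(scaffold = "s1",
                     start = sample.int(1e7, 100), track = "Copia")
  })
  wd2 <- window_density(h2, NULL, c(s1 = 1e7), window = 1e6, step = 1e6)
  cnt <- wd2$count[wd2$track == "Copia"]
  expect_equal(sum(cnt), 100)
  expect_true(all(abs(cnt - 10) <= 3 * sqrt(10)))

  # empty hits: all densities zero
  wd3 <- window_density(hits[0, ], NULL, c(s1 = 2e6))
  expect_true(nrow(wd3) == 0 || all(wd3$count == 0))
})

test_that("density correlation behaves at the extremes", {
  expect_equal(density_correlation(1:10, 1:10)$r, 1.0)
  expect_equal(density_correlation(c(1, 2, 3, 4), c(4, 3, 2, 1))$r, -1.0)
  expect_error(density_correlation(rep(1, 5), 1:5), "variance")
})
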