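# RT extraction, distance matrices, neighbor joining, lineage assignment.

test_that("RT extraction enforces the minimum residue length", {
  lib <- make_domain_library()
  el <- build_element(element_spec("Copia", "Oryco"), seed = 51)
  hits <- scan_domains(el$seq, lib)
  aa <- extract_rt(el$seq, hits)
  ref <- lib$seq[lib$id == "Copia_Oryco_RT"]
  # planted intact RT: extracted sequence equals the reference up to a
  # residue at each boundary
  expect_gte(nchar(aa), nchar(ref) - 2)
  expect_true(grepl(substr(aa, 2, nchar(aa) - 1), ref, fixed = TRUE))

  # a 149-residue RT is not retained
  expect_identical(extract_rt(el$seq, hits, min_residues = 10000),
                   NA_character_)
  # element with no RT
  no_rt <- hits[hits$kind != "RT", ]
  expect_identical(extract_rt(el$seq, no_rt), NA_character_)
})

test_that("pairwise distances follow the Poisson-corrected p-distance", {
  a <- strrep("ARNDCQEGHILKMFPSTWYV", 10)
  seqs <- c(x = a, y = a)
  d <- pairwise_distance_matrix(seqs)
  expect_equal(d["x", "y"], 0)

  # closed form: p = 0.10 -> d = -ln(0.9) = 0.10536
  b <- withr::with_seed(53, {
    ch <- strsplit(a, "")[[1]]
    idx <- sample(length(ch), round(0.10 * nchar(a)))
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in idx) ch[i] <- sample(setdiff(aas, ch[i]), 1)
    paste(ch, collapse = "")
  })
  d2 <- pairwise_distance_matrix(c(x = a, y = b))
  expect_equal(d2["x", "y"], -log(0.9), tolerance = 1e-9)

  # symmetry and zero diagonal on random sets
  seqs3 <- withr::with_seed(54, stats::setNames(
    replicate(4, ltrscan:::mutate_aa(a, 0.2)), paste0("s", 1:4)))
  d3 <- pairwise_distance_matrix(seqs3)
  expect_equal(d3, t(d3))
  expect_true(all(diag(d3) == 0))
  expect_error(pairwise_distance_matrix(c(x = "A")), "two")
  expect_error(pairwise_distance_matrix(c(x = "", y = "A")), "zero-length")
})

test_that("neighbor joining is exact on additive matrices", {
  # the classic 4-taxon additive matrix: topology (A,B|C,D) and all six
  # path distances recovered exactly
  taxa <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- ape::read.tree(text = neighbor_joining(d))
  co <- stats::cophenetic(tr)[taxa, taxa]
  expect_equal(max(abs(co - d)), 0)

  # 3 taxa: closed-form star lengths
  d3 <- d[1:3, 1:3]
  tr3 <- ape::read.tree(text = neighbor_joining(d3))
  co3 <- stats::cophenetic(tr3)[taxa[1:3], taxa[1:3]]
  expect_equal(max(abs(co3 - d3)), 0)

  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")

  # random additive 8-taxon matrices reproduce the input to 1e-9
  for (seed in 55:64) {
    t1 <- withr::with_seed(seed, ape::rtree(8))
    dm <- stats::cophenetic(t1)
    dm <- dm[order(rownames(dm)), order(colnames(dm))]
    t2 <- ape::read.tree(text = neighbor_joining(dm))
    co2 <- stats::cophenetic(t2)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(co2 - dm)), 1e-9)
  }
})

test_that("neighbor joining is invariant to taxon input order", {
  t1 <- withr::with_seed(65, ape::rtree(7))
  dm <- stats::cophenetic(t1)
  perm <- withr::with_seed(66, sample(nrow(dm)))
  tr_a <- ape::read.tree(text = neighbor_joining(dm))
  tr_b <- ape::read.tree(text = neighbor_joining(dm[perm, perm]))
  expect_equal(ape::dist.topo(ape::unroot(tr_a), ape::unroot(tr_b)), 0,
               ignore_attr = TRUE)
  ids <- rownames(dm)
  expect_equal(stats::cophenetic(tr_a)[ids, ids],
               stats::cophenetic(tr_b)[ids, ids], tolerance = 1e-9)
})

test_that("lineage assignment recovers planted lineages", {
  refs <- reference_rts()
  # elements: mutated copies (5 % AA substitutions) of three lineages
  els <- withr::with_seed(67, c(
    e1 = ltrscan:::mutate_aa(refs[["Tork"]], 0.05),
    e2 = ltrscan:::mutate_aa(refs[["Athila"]], 0.05),
    e3 = ltrscan:::mutate_aa(refs[["Reina"]], 0.05)
  ))
  out <- assign_lineages(els, refs)
  expect_identical(out$assignments$lineage, c("Tork", "Athila", "Reina"))
  expect_true(all(out$assignments$support < 0.2))

  # references only: empty assignment list
  empty <- assign_lineages(character(0), refs)
  expect_equal(nrow(empty$assignments), 0)
  expect_error(assign_lineages(els, character(0)), "no reference")
})

test_that("elements without a single-lineage neighborhood are undefined", {
  refs <- reference_rts()
  # two identically-sequenced references with different lineage labels:
  # the smallest clade containing an element near them is mixed
  twin <- c(refs[["Tork"]], refs[["Tork"]])
  names(twin) <- c("Tork", "Sire")
  el <- withr::with_seed(68,
    c(eq = ltrscan:::mutate_aa(refs[["Tork"]], 0.05)))
  out <- assign_lineages(el, c(twin, refs[c("Athila", "Del")]))
  expect_identical(out$assignments$lineage, "undefined")
})
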