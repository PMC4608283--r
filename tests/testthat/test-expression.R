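# Read assignment, TMM normalization and expression shares.

test_that("read assignment is exact on clean reads and conserves counts", {
  lib <- withr::with_seed(101, c(A = ltrscan:::random_dna(2500),
                                 B = ltrscan:::random_dna(2500)))
  rd <- generate_reads(lib["A"], c(A = 1), read_length = 100, depth = 400,
                       error_rate = 0, seed = 102)
  a <- assign_reads(rd$tissues[[1]], lib)
  expect_equal(unname(a$counts["A"]), 400)
  expect_equal(unname(a$counts["B"]), 0)
  expect_equal(a$unassigned, 0)

  # binomial oracle on 9:1 levels with sequencing errors
  rd2 <- generate_reads(lib, c(A = 9, B = 1), read_length = 100,
                        depth = 4000, error_rate = 0.005, seed = 103)
  a2 <- assign_reads(rd2$tissues[[1]], lib)
  expect_lt(abs(a2$counts[["A"]] - rd2$truth_counts["A", 1]), 30)
  # count conservation
  expect_equal(sum(a2$counts) + a2$unassigned, a2$n_reads)

  # reads from sequence absent from the library stay unassigned
  bg <- withr::with_seed(104, c(X = ltrscan:::random_dna(50000)))
  rd3 <- generate_reads(bg, c(X = 1), read_length = 100, depth = 1000,
                        error_rate = 0.005, seed = 105)
  a3 <- assign_reads(rd3$tissues[[1]], lib)
  expect_gte(a3$unassigned / 1000, 0.99)
  expect_error(assign_reads(rd3$tissues[[1]], character(0)), "empty")
})

test_that("multi-mapping reads split fractionally among tied elements", {
  s <- withr::with_seed(106, ltrscan:::random_dna(2000))
  lib <- c(A = s, B = s)   # identical references: every read ties
  rd <- generate_reads(lib["A"], c(A = 1), read_length = 100, depth = 200,
                       error_rate = 0, seed = 107)
  a <- assign_reads(rd$tissues[[1]], lib)
  expect_equal(unname(a$counts["A"]), 100)
  expect_equal(unname(a$counts["B"]), 100)
  expect_equal(sum(a$counts) + a$unassigned, 200)
})

test_that("TMM factors match the published algorithm", {
  m <- withr::with_seed(108,
    matrix(stats::rnbinom(800, mu = 50, size = 2) + 1, 200, 4,
           dimnames = list(NULL, paste0("t", 1:4))))

  # step-by-step reference computation, written independently
  tmm_ref <- function(counts, refcol) {
    ls <- colSums(counts)
    out <- numeric(ncol(counts))
    for (j in seq_len(ncol(counts))) {
      if (j == refcol) { out[j] <- 1; next }
      o <- counts[, j]; r <- counts[, refcol]
      M <- log2((o / ls[j]) / (r / ls[refcol]))
      A <- (log2(o / ls[j]) + log2(r / ls[refcol])) / 2
      w <- (ls[j] - o) / (ls[j] * o) + (ls[refcol] - r) / (ls[refcol] * r)
      use <- is.finite(M) & is.finite(A)
      M <- M[use]; A <- A[use]; w <- w[use]
      n <- length(M)
      loM <- floor(0.3 * n) + 1; hiM <- n + 1 - loM
      loA <- floor(0.05 * n) + 1; hiA <- n + 1 - loA
      keep <- rank(M) >= loM & rank(M) <= hiM &
        rank(A) >= loA & rank(A) <= hiA
      out[j] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
    }
    out / exp(mean(log(out)))
  }
  mine <- tmm_normalize(m, ref_column = 1)
  expect_equal(unname(mine), tmm_ref(m, 1), tolerance = 1e-6)

  # identical columns: factors 1.0
  m2 <- cbind(a = m[, 1], b = m[, 1])
  expect_equal(unname(tmm_normalize(m2)), c(1, 1))

  # pure depth difference: normalized values equal across columns
  m3 <- cbind(a = m[, 1], b = 2 * m[, 1])
  norm <- cpm_normalized(m3, colSums(m3), tmm_normalize(m3))
  expect_equal(norm[, "a"], norm[, "b"], tolerance = 1e-9)
})

test_that("TMM agrees with the installed independent implementation", {
  skip_if_not_installed("edgeR")
  for (seed in 109:111) {
    m <- withr::with_seed(seed,
      matrix(stats::rnbinom(1000, mu = 80, size = 1.5) + 1, 250, 4,
             dimnames = list(NULL, paste0("t", 1:4))))
    mine <- tmm_normalize(m, ref_column = 2)
    theirs <- edgeR::calcNormFactors(m, refColumn = 2, method = "TMM")
    expect_equal(unname(mine), unname(theirs), tolerance = 1e-6)
  }
})

test_that("expression shares partition the grand total", {
  norm <- matrix(c(60, 60, 20, 20, 20, 20), nrow = 3, byrow = TRUE,
                 dimnames = list(c("e1", "e2", "e3"), c("t1", "t2")))
  classes <- c(e1 = "NA", e2 = "Copia", e3 = "Gypsy")
  sh <- expression_shares(norm, classes)
  expect_equal(sum(sh$by_class$pct), 100, tolerance = 0.1)
  expect_equal(sh$by_class$pct[sh$by_class$class == "NA"], 60)
  expect_equal(sum(sh$by_tissue$pct), 100, tolerance = 0.1)

  # a single class holds 100 %
  sh1 <- expression_shares(norm[1, , drop = FALSE], classes["e1"])
  expect_equal(sh1$by_class$pct, 100)

  # equal totals across 8 tissues: 12.5 % each
  m8 <- matrix(10, 2, 8, dimnames = list(c("e1", "e2"), paste0("t", 1:8)))
  sh8 <- expression_shares(m8, c(e1 = "X", e2 = "X"))
  expect_true(all(sh8$by_tissue$pct == 12.5))

  expect_error(expression_shares(m8 * 0, c(e1 = "X", e2 = "X")),
               "zero grand total")
})

test_that("doubling a library changes its factor, not its profile", {
  sim_counts <- withr::with_seed(112,
    matrix(stats::rnbinom(600, mu = 40, size = 2) + 1, 150, 4,
           dimnames = list(NULL, paste0("t", 1:4))))
  doubled <- sim_counts
  doubled[, 3] <- 2 * doubled[, 3]
  n1 <- cpm_normalized(sim_counts, colSums(sim_counts),
                       tmm_normalize(sim_counts, ref_column = 1))
  n2 <- cpm_normalized(doubled, colSums(doubled),
                       tmm_normalize(doubled, ref_column = 1))
  # invariance is approximate: the precision weights shift with depth
  expect_equal(n1[, 3], n2[, 3], tolerance = 0.02)
})

test_that("fold change is a plain normalized-count ratio", {
  norm <- matrix(c(5, 310), 1, 2,
                 dimnames = list("e1", c("young", "mature")))
  expect_equal(fold_change(norm, "e1", "young", "mature"), 62)
})
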