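# Shared fixtures, built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

# The bundled study genome (~3 Mb, 30 planted elements) plus detection
# and classification results.
study <- function() {
  if (is.null(.fixture_env$sim)) {
    sim <- simulate_study_genome(seed = 101)
    det <- detect_ltr(sim$genome)
    seqs <- element_sequences(sim$genome, det$elements)
    cls <- classify_elements(det$elements, seqs)
    .fixture_env$sim <- sim
    .fixture_env$det <- det
    .fixture_env$seqs <- seqs
    .fixture_env$cls <- cls
  }
  .fixture_env
}

# A small genome (one 220 kb scaffold, three elements: Copia, Gypsy,
# non-autonomous) for cheap per-module tests.
mini <- function() {
  if (is.null(.fixture_env$mini_sim)) {
    bg <- generate_background(220000, seed = 11)
    specs <- list(
      element_spec("Copia", "Tork", divergence_age = 0.05),
      element_spec("Gypsy", "Tat", divergence_age = 0.10),
      element_spec("NA", domain_list = c("GAG", "PR"),
                   internal_length = 2600, divergence_age = 0.04)
    )
    sim <- plant_elements(stats::setNames(bg, "s1"), specs, seed = 12)
    .fixture_env$mini_sim <- sim
  }
  .fixture_env$mini_sim
}

# Match detected elements to planted truth rows by nearest start (within
# `slop` bp); returns the truth row index per detection (NA = unmatched).
match_to_truth <- function(detected, truth, slop = 50) {
  vapply(seq_len(nrow(detected)), function(i) {
    j <- which(truth$scaffold == detected$scaffold[i] &
                 abs(truth$start - detected$start[i]) < slop)
    if (length(j) == 1) j else NA_integer_
  }, 1L)
}

# Independent Gotoh (affine-gap Needleman-Wunsch) score oracle, matching
# the convention gap cost = opening + length * extension.  Small inputs
# only (pure R).
nw_score_oracle <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 10, gap_ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + (i - 1) * gap_ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + (j - 1) * gap_ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Global-alignment identity oracle via Biostrings on full matrices is the
# implementation itself, so boundary tests use this mismatch-count
# identity for equal-length, substitution-only pairs.
subst_identity_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  mean(av == bv)
}
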