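# Low-level sequence and RNG utilities shared across the pipeline.

DNA_BASES <- c("A", "C", "G", "T")

# transition partner of each base (A<->G, C<->T)
TRANSITION_OF <- c(A = "G", C = "T", G = "A", T = "C")
TRANSVERSIONS_OF <- list(
  A = c("C", "T"), C = c("A", "G"),
  G = c("C", "T"), T = c("A", "G")
)

#' Run code with a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so that seeded helpers do
#' not perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a stage seed from a master seed
#'
#' Deterministic and collision-poor for small offsets; result always fits a
#' 32-bit signed integer.
#'
#' @param seed master seed (integer).
#' @param offset stage offset (small integer).
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629)
}

#' Random i.i.d. DNA string
#' @param n length in bp.
#' @param gc GC fraction.
#' @return a single character string.
#' @keywords internal
random_dna <- function(n, gc = 0.4) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of DNA strings
#' @param s character vector (IUPAC letters allowed).
#' @return character vector.
#' @export
revcomp <- function(s) {
  if (length(s) == 1)
    return(as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# Map a DNA string to integers A=0 C=1 G=2 T=3, anything else NA.
dna_to_int <- function(s) {
  v <- utf8ToInt(s)
  out <- rep(NA_real_, length(v))
  out[v == 65L | v == 97L] <- 0
  out[v == 67L | v == 99L] <- 1
  out[v == 71L | v == 103L] <- 2
  out[v == 84L | v == 116L] <- 3
  out
}

# Rolling k-mer codes (base-4); NA wherever the window overlaps a non-ACGT
# base, so seeds never span N runs.
kmer_codes <- function(b, k) {
  n <- length(b)
  if (n < k) return(numeric(0))
  code <- b[seq_len(n - k + 1)]
  for (j in 2:k) code <- code * 4 + b[j:(n - k + j)]
  code
}

#' Kimura two-parameter event probabilities at a given distance
#'
#' For a target K2P distance `K` (expected substitutions per site along the
#' whole path) and a transition/transversion ratio `tstv` = alpha/(2 beta),
#' returns the per-site probabilities of observing a transition (P) and a
#' transversion (Q) difference.
#'
#' @param K K2P distance (substitutions/site), >= 0.
#' @param tstv transition/transversion ratio, > 0.
#' @return named numeric vector c(P=, Q=).
#' @export
k2p_event_probs <- function(K, tstv = 2) {
  stopifnot(K >= 0, tstv > 0)
  bt <- K / (2 * tstv + 2)    # beta * t
  at <- K - 2 * bt            # alpha * t
  P <- 0.25 - 0.5 * exp(-2 * (at + bt)) + 0.25 * exp(-4 * bt)
  Q <- 0.5 - 0.5 * exp(-4 * bt)
  c(P = P, Q = Q)
}

#' Mutate a sequence under the Kimura two-parameter model
#'
#' Each site independently becomes a transition with probability P and a
#' transversion (either partner, equiprobable) with probability Q, where
#' (P, Q) correspond to the requested K2P distance `K` at ratio `tstv`.
#' Non-ACGT characters are left untouched.
#'
#' @param s DNA string.
#' @param K target K2P distance.
#' @param tstv transition/transversion ratio.
#' @return mutated DNA string.
#' @export
mutate_k2p <- function(s, K, tstv = 2) {
  if (K == 0) return(s)
  pq <- k2p_event_probs(K, tstv)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ok <- ch %in% DNA_BASES
  u <- stats::runif(length(ch))
  is_ts <- ok & u < pq["P"]
  is_tv <- ok & !is_ts & u < pq["P"] + pq["Q"]
  if (any(is_ts)) ch[is_ts] <- TRANSITION_OF[ch[is_ts]]
  if (any(is_tv)) {
    pick <- stats::runif(sum(is_tv)) < 0.5
    tv <- ch[is_tv]
    ch[is_tv] <- mapply(function(b, first) TRANSVERSIONS_OF[[b]][if (first) 1 else 2],
                        tv, pick, USE.NAMES = FALSE)
  }
  paste(ch, collapse = "")
}

#' Mutate a sequence with uniform random substitutions
#' @param s DNA string.
#' @param rate per-site substitution probability.
#' @return mutated string.
#' @export
mutate_uniform <- function(s, rate) {
  if (rate == 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(ch %in% DNA_BASES & stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
  paste(ch, collapse = "")
}

#' Mutate an amino-acid sequence with uniform random substitutions
#' @param s AA string.
#' @param rate per-site substitution probability.
#' @return mutated string.
#' @keywords internal
mutate_aa <- function(s, rate) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  paste(ch, collapse = "")
}

# Percent with one decimal, standard rounding.
pct1 <- function(x) round(100 * x, 1)

# Substring by 1-based inclusive coordinates (clamped).
subseq_chr <- function(s, start, end) {
  substr(s, max(1L, as.integer(start)), min(nchar(s), as.integer(end)))
}

#' Write a TSV file
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
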