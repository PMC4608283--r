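# Per-element expression across tissues: k-mer seeded read assignment to
# the element library, count matrices, trimmed-mean-of-M-values (TMM)
# scaling normalization, and class/tissue percentage shares.

# Index library k-mers once: data.table(code, elem, pos).
library_kmer_index <- function(library, k) {
  idx <- lapply(names(library), function(id) {
    b <- dna_to_int(library[[id]])
    codes <- kmer_codes(b, k)
    pos <- which(!is.na(codes))
    data.table::data.table(code = codes[pos], elem = id, pos = pos)
  })
  out <- data.table::rbindlist(idx)
  data.table::setkey(out, code)
  out
}

count_mismatches <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Assign reads to an element library
#'
#' k-mer seeded ungapped comparison on both strands: each read is scored
#' against every library position suggested by shared k-mers (three probe
#' offsets per read) and assigned to its best-scoring element if the
#' ungapped identity reaches `min_identity`; ties are split fractionally
#' among the tied elements.  Deterministic.
#'
#' @param reads data.frame with id and seq (all reads same length), or a
#'   FASTQ path.
#' @param library named character vector of reference sequences.
#' @param min_identity assignment identity threshold (default 0.95).
#' @param seed_k seed length (default 13; read length must be >= this).
#' @return list with `counts` (named numeric, fractional allowed),
#'   `unassigned` (count) and `n_reads`.
#' @export
assign_reads <- function(reads, library, min_identity = 0.95, seed_k = 13L) {
  if (!length(library)) stop("empty element library")
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  rl <- nchar(reads$seq[1])
  stopifnot(all(nchar(reads$seq) == rl), rl >= seed_k)
  index <- library_kmer_index(library, seed_k)
  n <- nrow(reads)
  counts <- stats::setNames(numeric(length(library)), names(library))
  offsets <- unique(c(1L, (rl - seed_k) %/% 2L + 1L, rl - seed_k + 1L))

  cand_for <- function(seqs, strand) {
    cc <- list()
    for (off in offsets) {
      frag <- substr(seqs, off, off + seed_k - 1L)
      codes <- vapply(frag, function(f) {
        b <- dna_to_int(f)
        if (anyNA(b)) return(NA_real_)
        kmer_codes(b, seed_k)
      }, 0, USE.NAMES = FALSE)
      keep <- which(!is.na(codes))
      if (!length(keep)) next
      q <- data.table::data.table(code = codes[keep], read = keep, off = off)
      m <- index[q, on = "code", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(m)) {
        m$rstart <- m$pos - m$off + 1L
        m$strand <- strand
        cc[[length(cc) + 1L]] <- m[, c("read", "elem", "rstart", "strand")]
      }
    }
    if (length(cc)) unique(data.table::rbindlist(cc)) else NULL
  }

  fwd <- cand_for(reads$seq, "+")
  rc <- revcomp(reads$seq)
  rev <- cand_for(rc, "-")
  cand <- data.table::rbindlist(list(fwd, rev))
  unassigned <- n
  if (nrow(cand)) {
    cand <- cand[cand$rstart >= 1L, ]
    elen <- nchar(library)[cand$elem]
    cand <- cand[cand$rstart + rl - 1L <= elen, ]
  }
  if (nrow(cand)) {
    mism <- integer(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      rd <- if (cand$strand[i] == "+") reads$seq[cand$read[i]] else rc[cand$read[i]]
      ref <- substr(library[[cand$elem[i]]], cand$rstart[i],
                    cand$rstart[i] + rl - 1L)
      mism[i] <- count_mismatches(rd, ref)
    }
    cand$identity <- 1 - mism / rl
    cand <- cand[cand$identity >= min_identity, ]
    if (nrow(cand)) {
      best <- cand[, list(elem = elem, top = max(identity),
                          identity = identity), by = "read"]
      best <- best[best$identity >= best$top - 1e-12, ]
      share <- best[, list(elem = unique(elem)), by = "read"]
      share <- share[, list(elem = elem, w = 1 / .N), by = "read"]
      agg <- share[, list(w = sum(w)), by = "elem"]
      counts[agg$elem] <- agg$w
      unassigned <- n - length(unique(best$read))
    }
  }
  list(counts = counts, unassigned = unassigned, n_reads = n)
}

#' Build a count matrix over tissues
#'
#' @param tissue_reads named list of read data.frames (one per tissue).
#' @param library named character vector of references.
#' @param ... passed to [assign_reads()].
#' @return list with `counts` (elements x tissues), `unassigned` (per
#'   tissue), `lib_sizes` (total reads per tissue).
#' @export
count_matrix <- function(tissue_reads, library, ...) {
  counts <- matrix(0, length(library), length(tissue_reads),
                   dimnames = list(names(library), names(tissue_reads)))
  unassigned <- stats::setNames(numeric(length(tissue_reads)),
                                names(tissue_reads))
  lib_sizes <- unassigned
  for (t in names(tissue_reads)) {
    a <- assign_reads(tissue_reads[[t]], library, ...)
    counts[, t] <- a$counts
    unassigned[t] <- a$unassigned
    lib_sizes[t] <- a$n_reads
  }
  list(counts = counts, unassigned = unassigned, lib_sizes = lib_sizes)
}

# Single-column TMM factor vs a reference column (two-sided trimming of
# M by `logratio_trim` and of A by `sum_trim`; inverse-variance weights).
tmm_one <- function(obs, ref, logratio_trim = 0.3, sum_trim = 0.05,
                    do_weighting = TRUE) {
  n_o <- sum(obs); n_r <- sum(ref)
  logR <- log2((obs / n_o) / (ref / n_r))
  absE <- (log2(obs / n_o) + log2(ref / n_r)) / 2
  v <- (n_o - obs) / n_o / obs + (n_r - ref) / n_r / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR)) stop("no co-expressed rows shared with the reference")
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
    (rank(absE) >= loS & rank(absE) <= hiS)
  f <- if (do_weighting)
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  else mean(logR[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-library scaling factors: per column versus a reference column,
#' the factor is the weighted mean of trimmed log-ratios (30 % two-sided
#' trim on M, 5 % on A), exponentiated and rescaled so the factors have
#' geometric mean one.  The default reference is the column whose library
#' size is closest to the median.
#'
#' @param counts elements x tissues count matrix (>= 2 columns, positive
#'   column totals).
#' @param ref_column reference column index or name (NULL = median
#'   library).
#' @param logratio_trim,sum_trim trim fractions.
#' @param do_weighting inverse-variance weighting of retained M values.
#' @return named numeric vector of factors (geometric mean 1).
#' @export
tmm_normalize <- function(counts, ref_column = NULL, logratio_trim = 0.3,
                          sum_trim = 0.05, do_weighting = TRUE) {
  stopifnot(ncol(counts) >= 2, all(colSums(counts) > 0))
  if (is.null(ref_column)) {
    ls <- colSums(counts)
    ref_column <- which.min(abs(ls - stats::median(ls)))
  }
  if (is.character(ref_column)) ref_column <- match(ref_column, colnames(counts))
  ref <- counts[, ref_column]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref_column) return(1)
    tmm_one(counts[, j], ref, logratio_trim, sum_trim, do_weighting)
  }, 0)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Normalized expression values (counts per million, TMM-scaled)
#'
#' @param counts count matrix.
#' @param lib_sizes per-column library sizes (defaults to column sums).
#' @param factors TMM factors (defaults to [tmm_normalize()]).
#' @return matrix of normalized values.
#' @export
cpm_normalized <- function(counts, lib_sizes = colSums(counts),
                           factors = tmm_normalize(counts)) {
  t(t(counts) / (lib_sizes * factors)) * 1e6
}

#' Class and tissue shares of overall expression
#'
#' Restricted to elements flagged expressed (normalized value above
#' `min_cpm` in at least one tissue), percentage shares of the summed
#' normalized expression by element class and by tissue.
#'
#' @param norm normalized matrix (elements x tissues).
#' @param classes named character vector mapping element id to class.
#' @param min_cpm expressed-element threshold (default 1).
#' @return list with `by_class`, `by_tissue` (data.frames with pct) and
#'   `expressed` ids.
#' @export
expression_shares <- function(norm, classes, min_cpm = 1) {
  stopifnot(all(rownames(norm) %in% names(classes)))
  expressed <- rownames(norm)[apply(norm, 1, max) > min_cpm]
  m <- norm[expressed, , drop = FALSE]
  total <- sum(m)
  if (total == 0) stop("zero grand total expression")
  cls <- classes[rownames(m)]
  by_class <- vapply(split(seq_len(nrow(m)), cls),
                     function(i) sum(m[i, , drop = FALSE]), 0)
  by_tissue <- colSums(m)
  list(
    by_class = data.frame(class = names(by_class),
                          pct = pct1(by_class / total),
                          row.names = NULL),
    by_tissue = data.frame(tissue = names(by_tissue),
                           pct = pct1(by_tissue / total),
                           row.names = NULL),
    expressed = expressed
  )
}

#' Fold change of one element between two tissues
#' @param norm normalized matrix.
#' @param element element id.
#' @param from,to tissue names.
#' @return ratio of normalized values (to / from).
#' @export
fold_change <- function(norm, element, from, to) {
  unname(norm[element, to] / norm[element, from])
}
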