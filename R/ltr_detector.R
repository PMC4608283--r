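# Structural detection of full-length LTR retrotransposons: a repeat
# element delimited by highly similar direct LTRs, flanked by a target-site
# duplication, with primer-binding-site and polypurine-tract evidence
# recorded just inside the LTRs.  Detection is seed-and-extend: exact
# k-mer matches on the forward/forward diagonal are chained into candidate
# direct-repeat pairs, boundaries are refined by X-drop extension and TSD
# snapping, and candidates are validated against the structural rules.

#' Default detector parameters
#'
#' @param seed_k exact-match seed length (bp).
#' @param min_ltr,max_ltr admissible LTR length range (bp).
#' @param min_inner minimum internal-region length (bp).
#' @param max_span maximum distance between LTR start positions (bp).
#' @param min_identity minimum LTR-pair identity for acceptance.
#' @param tsd_range TSD lengths searched (exact match; longest wins).
#' @param max_element_length elements longer than this are rejected.
#' @param pbs_min_match minimum matching bases against a tRNA 3' end.
#' @param ppt_window,ppt_min_purine polypurine-tract window and purity.
#' @param max_occ k-mer occurrence cap (repetitive seeds are skipped).
#' @param max_seed_gap maximum gap between chained seeds on a diagonal.
#' @param strict require PBS and PPT evidence for acceptance (by default
#'   they are scored but not mandatory).
#' @return named list of parameters.
#' @export
ltr_params <- function(seed_k = 14, min_ltr = 100, max_ltr = 6000,
                       min_inner = 100, max_span = 13000,
                       min_identity = 0.80, tsd_range = 4:6,
                       max_element_length = 12000,
                       pbs_min_match = 12, ppt_window = 15,
                       ppt_min_purine = 0.8, max_occ = 40,
                       max_seed_gap = 400, strict = FALSE) {
  stopifnot(min_ltr <= max_ltr, max_ltr < max_span)
  as.list(environment())
}

NUC_MAT <- NULL
nuc_submat <- function() {
  if (is.null(NUC_MAT)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
    utils::assignInMyNamespace("NUC_MAT", m)
  }
  NUC_MAT
}

# local-alignment scoring used by pair_match / find_copies (cached)
NUC_MAT_LOCAL <- NULL
nuc_submat_local <- function() {
  if (is.null(NUC_MAT_LOCAL)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
    utils::assignInMyNamespace("NUC_MAT_LOCAL", m)
  }
  NUC_MAT_LOCAL
}

# Global-alignment identity of two sequences: matches / alignment columns.
pair_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = nuc_submat(), gapOpening = 6, gapExtension = 1)
  Biostrings::nmatch(pa) / Biostrings::nchar(pa)
}

# X-drop extension along a fixed diagonal.  Compares b[s1 +/- t] with
# b[s3 +/- t] and returns the extension length maximizing the running
# score (match +1, mismatch/N -2) before the score drops `xdrop` below
# its maximum.
xdrop_extend <- function(b, s1, s3, dirn, maxlen, xdrop = 15) {
  n <- length(b)
  t <- seq_len(maxlen)
  i1 <- s1 + dirn * t
  i3 <- s3 + dirn * t
  ok <- i1 >= 1 & i1 <= n & i3 >= 1 & i3 <= n
  if (!any(ok)) return(0L)
  t <- t[ok]; i1 <- i1[ok]; i3 <- i3[ok]
  eq <- !is.na(b[i1]) & !is.na(b[i3]) & b[i1] == b[i3]
  sc <- ifelse(eq, 1, -2)
  cs <- cumsum(sc)
  rm_ <- cummax(cs)
  cut <- which(rm_ - cs > xdrop)
  last <- if (length(cut)) cut[1] - 1L else length(cs)
  if (last == 0L || max(cs[seq_len(last)]) <= 0) return(0L)
  # furthest position attaining the maximum: neutral stretches at the
  # repeat boundary are crossed rather than truncated
  best <- max(cs[seq_len(last)])
  t[max(which(cs[seq_len(last)] == best))]
}

#' Find candidate direct-repeat (LTR) pairs in one sequence
#'
#' @param sequence a single scaffold sequence (character).
#' @param params detector parameters from [ltr_params()].
#' @return data.frame of candidates: ltr5_start/end, ltr3_start/end,
#'   identity, n_seeds, diag.
#' @export
find_candidate_pairs <- function(sequence, params = ltr_params()) {
  p <- params
  empty <- data.frame(ltr5_start = integer(), ltr5_end = integer(),
                      ltr3_start = integer(), ltr3_end = integer(),
                      identity = numeric(), n_seeds = integer(),
                      diag = integer())
  n <- nchar(sequence)
  if (n < p$max_span) return(empty)
  b <- dna_to_int(sequence)
  codes <- kmer_codes(b, p$seed_k)
  pos <- which(!is.na(codes))
  if (!length(pos)) return(empty)
  dt <- data.table::data.table(code = codes[pos], pos = pos)
  cnt <- dt[, .N, by = "code"]
  keep <- cnt[cnt$N >= 2L & cnt$N <= p$max_occ, ][["code"]]
  dt <- dt[dt$code %in% keep, ]
  if (!nrow(dt)) return(empty)

  min_spacing <- p$min_ltr + p$min_inner
  pairs <- dt[, {
    if (.N >= 2L) {
      cmb <- utils::combn(sort(pos), 2L)
      d <- cmb[2L, ] - cmb[1L, ]
      sel <- d >= min_spacing & d <= p$max_span
      list(p1 = cmb[1L, sel], p2 = cmb[2L, sel])
    } else list(p1 = integer(0), p2 = integer(0))
  }, by = "code"]
  if (!nrow(pairs)) return(empty)

  seeds <- data.table::data.table(p1 = pairs$p1, diag = pairs$p2 - pairs$p1)
  data.table::setorder(seeds, diag, p1)
  # cluster: split where the diagonal jumps or seeds are far apart
  dd <- c(Inf, diff(seeds$diag))
  dp <- c(Inf, abs(diff(seeds$p1)))   # p1 order resets across diagonals
  newgrp <- dd > 15 | dp > p$max_seed_gap
  grp <- cumsum(newgrp)
  seeds$grp <- grp

  cand <- list()
  for (g in unique(grp)) {
    s <- seeds[seeds$grp == g, ]
    if (nrow(s) < 3L) next
    span <- max(s$p1) + p$seed_k - min(s$p1)
    if (span < 50L) next
    dg <- as.integer(round(stats::median(s$diag)))
    s1 <- min(s$p1); e1 <- max(s$p1) + p$seed_k - 1L
    left <- xdrop_extend(b, s1, s1 + dg, -1L, p$max_ltr)
    right <- xdrop_extend(b, e1, e1 + dg, +1L, p$max_ltr)
    L <- s1 - left; R <- e1 + right
    if (R >= L + dg) next                      # repeat longer than spacing: tandem
    ltr_len <- R - L + 1L
    if (ltr_len < p$min_ltr || ltr_len > p$max_ltr) next
    inner <- dg - ltr_len
    if (inner < p$min_inner) next
    if (R + dg - L + 1L > p$max_span) next
    cand[[length(cand) + 1L]] <- data.frame(
      ltr5_start = L, ltr5_end = R, ltr3_start = L + dg, ltr3_end = R + dg,
      identity = NA_real_, n_seeds = nrow(s), diag = dg)
  }
  if (!length(cand)) return(empty)
  out <- do.call(rbind, cand)

  # merge near-duplicate candidates (same repeat found via split chains)
  out <- out[order(out$ltr5_start, -out$n_seeds), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j == i || !keep[j]) next
      ov <- min(out$ltr5_end[i], out$ltr5_end[j]) -
        max(out$ltr5_start[i], out$ltr5_start[j])
      w <- min(out$ltr5_end[i] - out$ltr5_start[i],
               out$ltr5_end[j] - out$ltr5_start[j])
      if (ov > 0.5 * w && abs(out$diag[i] - out$diag[j]) <= 15) {
        keep[if (out$n_seeds[i] >= out$n_seeds[j]) j else i] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]

  out$identity <- vapply(seq_len(nrow(out)), function(i) {
    pair_identity(subseq_chr(sequence, out$ltr5_start[i], out$ltr5_end[i]),
                  subseq_chr(sequence, out$ltr3_start[i], out$ltr3_end[i]))
  }, 0)
  rownames(out) <- NULL
  out
}

# Exact-match TSD search with boundary snapping: tries boundary
# adjustments d5, d3 in -wiggle..wiggle and TSD lengths 4-6.  The
# candidate needing the smallest total boundary adjustment wins (the true
# duplication sits at the true boundaries; chance matches are scattered),
# with remaining ties broken by the longest TSD.
find_tsd <- function(sequence, start, end, tsd_range = 4:6, wiggle = 6L) {
  n <- nchar(sequence)
  best <- NULL
  for (len in sort(tsd_range, decreasing = TRUE)) {
    for (d5 in -wiggle:wiggle) {
      for (d3 in -wiggle:wiggle) {
        s <- start + d5; e <- end + d3
        if (s - len < 1 || e + len > n) next
        left <- substr(sequence, s - len, s - 1L)
        right <- substr(sequence, e + 1L, e + len)
        if (left == right && !grepl("N", left, fixed = TRUE)) {
          cost <- abs(d5) + abs(d3)
          if (is.null(best) || cost < best$cost ||
              (cost == best$cost && len > nchar(best$tsd))) {
            best <- list(tsd = left, start = s, end = e, cost = cost)
          }
        }
      }
    }
  }
  best
}

# PBS: compare the 20 bp window after the 5' LTR against the reverse
# complement of each tRNA 3' end; report the best offset/match count.
score_pbs <- function(sequence, ltr5_end, trna_lib = trna_3prime_library(),
                      window = 20L) {
  best <- list(trna = NA_character_, match = 0L, offset = NA_integer_)
  for (id in names(trna_lib)) {
    probe <- revcomp(trna_lib[[id]])
    pl <- nchar(probe)
    pv <- strsplit(probe, "")[[1]]
    for (off in 0:window) {
      s <- ltr5_end + 1L + off
      frag <- substr(sequence, s, s + pl - 1L)
      if (nchar(frag) < pl) next
      m <- sum(strsplit(frag, "")[[1]] == pv)
      if (m > best$match) best <- list(trna = id, match = m, offset = off)
    }
  }
  best
}

# PPT: best purine fraction over sliding windows ending within `margin`
# bp of the 3' LTR start.
score_ppt <- function(sequence, ltr3_start, window = 15L, margin = 20L) {
  best <- list(purine = 0, start = NA_integer_, end = NA_integer_)
  for (e in (ltr3_start - 1L):(ltr3_start - margin)) {
    s <- e - window + 1L
    if (s < 1) break
    frag <- strsplit(substr(sequence, s, e), "")[[1]]
    fr <- mean(frag %in% c("A", "G"))
    if (fr > best$purine) best <- list(purine = fr, start = s, end = e)
  }
  best
}

#' Validate a candidate pair against the structural definition
#'
#' Accepts a candidate iff its LTR-pair identity reaches `min_identity`,
#' the element does not exceed `max_element_length`, and an exact
#' target-site duplication flanks it (lengths in `tsd_range`, longest
#' wins, boundaries snapped within +-3 bp).  PBS and PPT evidence is
#' scored and recorded; under `strict = TRUE` both are also required.
#'
#' @param candidate one row of [find_candidate_pairs()] output.
#' @param sequence the scaffold sequence the candidate came from.
#' @param params detector parameters.
#' @param trna_lib tRNA 3'-end library for PBS scoring.
#' @return for accepted candidates a one-row data.frame (the element);
#'   otherwise a rejection with a machine-readable `reason`
#'   (too_long / low_identity / n_rich / no_tsd / no_pbs_ppt).
#' @export
validate_element <- function(candidate, sequence, params = ltr_params(),
                             trna_lib = trna_3prime_library()) {
  p <- params
  n <- nchar(sequence)
  if (candidate$ltr5_start < 1 || candidate$ltr3_end > n)
    stop("candidate coordinates outside sequence")
  reject <- function(reason)
    data.frame(accepted = FALSE, reason = reason,
               ltr5_start = candidate$ltr5_start, ltr3_end = candidate$ltr3_end)

  elen <- candidate$ltr3_end - candidate$ltr5_start + 1L
  if (elen > p$max_element_length) return(reject("too_long"))
  if (candidate$identity < p$min_identity) return(reject("low_identity"))

  ltr5 <- subseq_chr(sequence, candidate$ltr5_start, candidate$ltr5_end)
  ltr3 <- subseq_chr(sequence, candidate$ltr3_start, candidate$ltr3_end)
  nfrac <- function(s) {
    ch <- strsplit(s, "")[[1]]; mean(!ch %in% DNA_BASES)
  }
  if (nfrac(ltr5) > 0.10 || nfrac(ltr3) > 0.10) return(reject("n_rich"))

  tsd <- find_tsd(sequence, candidate$ltr5_start, candidate$ltr3_end,
                  p$tsd_range)
  if (is.null(tsd)) return(reject("no_tsd"))
  d5 <- tsd$start - candidate$ltr5_start
  d3 <- tsd$end - candidate$ltr3_end
  ltr5_start <- candidate$ltr5_start + d5
  ltr5_end <- candidate$ltr5_end + d5   # keep LTR width, shift with boundary
  ltr3_start <- candidate$ltr3_start + d3
  ltr3_end <- candidate$ltr3_end + d3

  pbs <- score_pbs(sequence, ltr5_end, trna_lib)
  ppt <- score_ppt(sequence, ltr3_start, p$ppt_window)
  has_pbs <- !is.na(pbs$trna) && pbs$match >= p$pbs_min_match
  has_ppt <- ppt$purine >= p$ppt_min_purine
  if (p$strict && !(has_pbs && has_ppt)) return(reject("no_pbs_ppt"))

  data.frame(
    accepted = TRUE, reason = NA_character_,
    start = tsd$start, end = tsd$end,
    ltr5_start = ltr5_start, ltr5_end = ltr5_end,
    ltr3_start = ltr3_start, ltr3_end = ltr3_end,
    ltr_identity = candidate$identity, length = tsd$end - tsd$start + 1L,
    tsd = tsd$tsd,
    pbs_trna = if (has_pbs) pbs$trna else NA_character_,
    pbs_match = pbs$match, pbs_offset = pbs$offset,
    ppt_purine = ppt$purine,
    has_pbs = has_pbs, has_ppt = has_ppt,
    stringsAsFactors = FALSE
  )
}

#' Detect full-length LTR retrotransposons in a genome
#'
#' Runs candidate discovery and structural validation per scaffold,
#' resolves overlapping accepted elements greedily by descending
#' (identity, length), and orders output by (scaffold, start).
#'
#' @param genome named character vector of scaffolds, or a FASTA path.
#' @param params detector parameters from [ltr_params()].
#' @param trna_lib tRNA 3'-end library.
#' @return list with `elements` (accepted, with element ids) and
#'   `rejections` (with reasons).
#' @export
detect_ltr <- function(genome, params = ltr_params(),
                       trna_lib = trna_3prime_library()) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_genome_fasta(genome)
  genome <- genome[order(names(genome))]
  acc <- list(); rej <- list()
  for (sc in names(genome)) {
    cands <- find_candidate_pairs(genome[[sc]], params)
    for (i in seq_len(nrow(cands))) {
      v <- validate_element(cands[i, ], genome[[sc]], params, trna_lib)
      v$scaffold <- sc
      if (isTRUE(v$accepted[1])) acc[[length(acc) + 1L]] <- v
      else rej[[length(rej) + 1L]] <- v
    }
  }
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(accepted = logical(), reason = character(),
               scaffold = character())
  if (!length(acc)) {
    return(list(elements = data.frame(
      element_id = character(), scaffold = character(), start = integer(),
      end = integer(), ltr5_start = integer(), ltr5_end = integer(),
      ltr3_start = integer(), ltr3_end = integer(), ltr_identity = numeric(),
      length = integer(), tsd = character()), rejections = rejections))
  }
  el <- do.call(rbind, acc)
  # greedy overlap resolution: best (identity, length) first
  el <- el[order(-el$ltr_identity, -el$length), ]
  chosen <- el[0, ]
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    same <- chosen[chosen$scaffold == e$scaffold, ]
    if (!nrow(same) || all(e$start > same$end | e$end < same$start)) {
      chosen <- rbind(chosen, e)
    }
  }
  el <- chosen[order(chosen$scaffold, chosen$start), ]
  el$element_id <- sprintf("L%03d", seq_len(nrow(el)))
  rownames(el) <- NULL
  cols <- c("element_id", "scaffold", "start", "end", "ltr5_start",
            "ltr5_end", "ltr3_start", "ltr3_end", "ltr_identity", "length",
            "tsd", "pbs_trna", "pbs_match", "pbs_offset", "ppt_purine",
            "has_pbs", "has_ppt")
  list(elements = el[, cols], rejections = rejections)
}

#' Extract element sequences from a genome
#' @param genome named character vector.
#' @param elements detection (or truth) data.frame with scaffold/start/end.
#' @return named character vector keyed by element_id.
#' @export
element_sequences <- function(genome, elements) {
  out <- vapply(seq_len(nrow(elements)), function(i)
    subseq_chr(genome[[elements$scaffold[i]]], elements$start[i],
               elements$end[i]), "")
  names(out) <- elements$element_id
  out
}
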