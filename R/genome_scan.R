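# Genome-wide copy counting, masking and density tracks: seeded local
# alignment of family references against both strands, the 70/70
# completeness rule per copy, repeat masking at an identity floor,
# sliding-window densities along scaffolds and the density correlation
# test.

# k-mer index of a genome: data.table(scaffold, code, pos).
genome_kmer_index <- function(genome, k = 13L) {
  idx <- lapply(names(genome), function(sc) {
    b <- dna_to_int(genome[[sc]])
    codes <- kmer_codes(b, k)
    pos <- which(!is.na(codes))
    data.table::data.table(scaffold = sc, code = codes[pos], pos = pos)
  })
  out <- data.table::rbindlist(idx)
  data.table::setkey(out, code)
  out
}

# Seed hits of one reference against an indexed genome (one strand).
seed_hits_one <- function(index, ref_seq, k, max_seed_gap = 600L) {
  b <- dna_to_int(ref_seq)
  codes <- kmer_codes(b, k)
  rpos <- which(!is.na(codes))
  if (!length(rpos)) return(NULL)
  q <- data.table::data.table(code = codes[rpos], rpos = rpos)
  m <- index[q, on = "code", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(m)) return(NULL)
  m$diag <- m$pos - m$rpos
  data.table::setorder(m, scaffold, diag, pos)
  dd <- c(Inf, diff(m$diag))
  dp <- c(Inf, diff(m$pos))
  sameseq <- c(FALSE, m$scaffold[-1] == m$scaffold[-nrow(m)])
  newgrp <- !sameseq | dd > 25 | dp > max_seed_gap
  m$grp <- cumsum(newgrp)
  g <- m[, list(scaffold = scaffold[1], n_seeds = .N,
                gstart = min(pos), gend = max(pos) + k - 1L,
                rstart = min(rpos), rend = max(rpos) + k - 1L),
         by = "grp"]
  g[g$n_seeds >= 3L & (g$gend - g$gstart) >= 50L, ]
}

#' Find genomic copies of reference elements
#'
#' Both strands are searched by k-mer seeding and chaining; each chained
#' region is aligned locally against its reference to obtain identity and
#' reference coverage.  A copy is complete iff coverage >= `min_cov` and
#' identity >= `min_id`.  Overlapping hits to different references are
#' collapsed to the best (copies often cannot be assigned to a single
#' reference unequivocally, so counting is per superfamily).
#'
#' @param genome named character vector of scaffolds.
#' @param refs named character vector of reference element sequences.
#' @param ref_superfamily named character vector mapping reference id to
#'   superfamily label.
#' @param min_id,min_cov completeness thresholds (defaults 0.70/0.70).
#' @param k seed length.
#' @param report_min_id hits below this identity are dropped entirely.
#' @return data.frame of copy hits: ref, superfamily, scaffold, start,
#'   end, strand, identity, coverage, complete.
#' @export
find_copies <- function(genome, refs, ref_superfamily = NULL,
                        min_id = 0.70, min_cov = 0.70, k = 13L,
                        report_min_id = 0.5) {
  if (!length(refs)) stop("no reference elements")
  if (is.null(ref_superfamily))
    ref_superfamily <- stats::setNames(rep(NA_character_, length(refs)),
                                       names(refs))
  index <- genome_kmer_index(genome, k)
  hits <- list()
  for (rid in names(refs)) {
    for (strand in c("+", "-")) {
      rs <- if (strand == "+") refs[[rid]] else revcomp(refs[[rid]])
      g <- seed_hits_one(index, rs, k)
      if (is.null(g) || !nrow(g)) next
      reflen <- nchar(refs[[rid]])
      for (i in seq_len(nrow(g))) {
        sc <- g$scaffold[i]
        # align the chained genomic region against the chained reference
        # stretch (each padded); coverage stays relative to the full
        # reference length
        pad <- 100L
        rst <- max(1L, g$rstart[i] - pad)
        ren <- min(reflen, g$rend[i] + pad)
        st <- max(1L, g$gstart[i] - (g$rstart[i] - rst) - 30L)
        en <- min(nchar(genome[[sc]]), g$gend[i] + (ren - g$rend[i]) + 30L)
        region <- subseq_chr(genome[[sc]], st, en)
        ref_sub <- subseq_chr(rs, rst, ren)
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(region), Biostrings::DNAString(ref_sub),
          type = "local",
          substitutionMatrix = nuc_submat_local(),
          gapOpening = 5, gapExtension = 2)
        if (Biostrings::nchar(pa) == 0) next
        identity <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
        if (identity < report_min_id) next
        ap <- as.character(Biostrings::alignedPattern(pa))
        as_ <- as.character(Biostrings::alignedSubject(pa))
        gspan <- nchar(gsub("-", "", ap))
        rspan <- nchar(gsub("-", "", as_))
        gstart <- st + Biostrings::start(Biostrings::pattern(pa)) - 1L
        hits[[length(hits) + 1L]] <- data.frame(
          ref = rid, superfamily = ref_superfamily[[rid]], scaffold = sc,
          start = gstart, end = gstart + gspan - 1L, strand = strand,
          identity = identity, coverage = rspan / reflen,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(ref = character(), superfamily = character(),
                      scaffold = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), coverage = numeric(),
                      complete = logical()))
  }
  out <- do.call(rbind, hits)
  # collapse overlaps (> 50 % of the shorter interval), best first
  out <- out[order(-(out$identity * out$coverage), -(out$end - out$start)), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j <= i || !keep[j] || out$scaffold[j] != out$scaffold[i]) next
      ov <- min(out$end[i], out$end[j]) - max(out$start[i], out$start[j]) + 1L
      w <- min(out$end[i] - out$start[i], out$end[j] - out$start[j]) + 1L
      if (ov > 0.5 * w) keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out$complete <- out$coverage >= min_cov & out$identity >= min_id
  out <- out[order(out$scaffold, out$start), ]
  rownames(out) <- NULL
  out
}

#' Mask a genome against a repeat library
#'
#' Genomic segments matching any library sequence at >= `min_id` identity
#' are lower-cased; statistics report the masked fraction of all bases
#' and of non-N bases.
#'
#' @param genome named character vector.
#' @param library named character vector of repeat sequences.
#' @param min_id identity floor for masking (default 0.80).
#' @param k seed length.
#' @return list with `genome` (masked) and `stats` (data.frame
#'   masked_bp, total_bp, n_bp, frac_all, frac_non_n).
#' @export
mask_genome <- function(genome, library, min_id = 0.80, k = 13L) {
  if (!length(library)) stop("empty library")
  hits <- find_copies(genome, library, min_id = min_id, min_cov = 0,
                      k = k, report_min_id = min_id)
  masked <- genome
  masked_bp <- 0L
  for (sc in names(genome)) {
    h <- hits[hits$scaffold == sc, ]
    if (!nrow(h)) next
    ir <- IRanges::reduce(IRanges::IRanges(h$start, h$end))
    masked_bp <- masked_bp + sum(IRanges::width(ir))
    s <- masked[[sc]]
    for (i in seq_along(ir)) {
      st <- IRanges::start(ir)[i]; en <- IRanges::end(ir)[i]
      substr(s, st, en) <- tolower(substr(s, st, en))
    }
    masked[[sc]] <- s
  }
  total <- sum(nchar(genome))
  n_bp <- sum(vapply(genome, function(s)
    sum(strsplit(s, "")[[1]] %in% c("N", "n")), 0L))
  stats <- data.frame(masked_bp = masked_bp, total_bp = total, n_bp = n_bp,
                      frac_all = masked_bp / total,
                      frac_non_n = masked_bp / (total - n_bp))
  list(genome = masked, stats = stats)
}

#' Sliding-window density tracks
#'
#' A hit is counted in every window containing its start position
#' (0-based half-open windows of `window` bp every `step` bp); densities
#' are per Mb, terminal short windows scaled by their actual width.
#'
#' @param hits data.frame with scaffold, start and a `track` column.
#' @param gene_intervals data.frame with scaffold, start (genes track).
#' @param scaffold_lengths named integer vector.
#' @param window,step window and step size in bp (defaults 1 Mbp / 500 kbp).
#' @return data.frame: scaffold, win_start, win_end (0-based half-open),
#'   track, count, density_per_mb.
#' @export
window_density <- function(hits, gene_intervals, scaffold_lengths,
                           window = 1e6, step = 5e5) {
  rows <- list()
  tracks <- rbind(
    data.frame(scaffold = hits$scaffold, start = hits$start,
               track = hits$track, stringsAsFactors = FALSE),
    if (!is.null(gene_intervals) && nrow(gene_intervals))
      data.frame(scaffold = gene_intervals$scaffold,
                 start = gene_intervals$start, track = "gene",
                 stringsAsFactors = FALSE)
  )
  for (sc in names(scaffold_lengths)) {
    len <- scaffold_lengths[[sc]]
    if (len == 0) { warning("zero-length scaffold ", sc); next }
    starts <- seq(0, max(0, len - 1), by = step)
    t_sc <- tracks[tracks$scaffold == sc, ]
    for (ws in starts) {
      we <- min(ws + window, len)
      for (tr in unique(tracks$track)) {
        s0 <- t_sc$start[t_sc$track == tr] - 1L  # to 0-based
        cnt <- sum(s0 >= ws & s0 < we)
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = sc, win_start = ws, win_end = we, track = tr,
          count = cnt, density_per_mb = cnt / ((we - ws) / 1e6),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two density tracks
#'
#' @param track_a,track_b equal-length numeric vectors (n >= 3).
#' @return list(r, p_value, n).
#' @export
density_correlation <- function(track_a, track_b) {
  stopifnot(length(track_a) == length(track_b), length(track_a) >= 3)
  if (stats::var(track_a) == 0 || stats::var(track_b) == 0)
    stop("zero variance in a density track")
  ct <- stats::cor.test(track_a, track_b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(track_a))
}
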