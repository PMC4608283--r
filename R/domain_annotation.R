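# Protein-domain annotation inside elements: six-frame translation,
# Smith-Waterman search against a labeled GAG/PR/INT/RT/RH reference
# library with Karlin-Altschul E-values, and the superfamily rule:
# RLC/RLG from the RT/INT/RH hits (majority reference label, ties broken
# by internal domain order), RXX-NA when only GAG/PR (or nothing) is
# found.

# Karlin-Altschul parameters for BLOSUM62 with affine gaps (open 10,
# extend 1); documented constants, database size = library residue count.
KA_LAMBDA <- 0.267
KA_K <- 0.041

BLOSUM62_MAT <- NULL
blosum62 <- function() {
  if (is.null(BLOSUM62_MAT)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    utils::assignInMyNamespace("BLOSUM62_MAT", e$BLOSUM62)
  }
  BLOSUM62_MAT
}

#' Translate a nucleotide sequence in all six frames
#'
#' Standard genetic code; stop codons render as `*`; N-containing codons
#' render as `X`; frames -1..-3 operate on the reverse complement.
#' Non-IUPAC characters are an error.
#'
#' @param sequence DNA string.
#' @return named character vector with frames "+1".."+3", "-1".."-3".
#' @export
translate_six_frames <- function(sequence) {
  stopifnot(nchar(sequence) > 0)
  d <- Biostrings::DNAString(sequence)   # errors on non-IUPAC input
  r <- Biostrings::reverseComplement(d)
  one <- function(x, f) {
    L <- length(x)
    w <- 3L * ((L - f + 1L) %/% 3L)
    if (w <= 0) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, f, f + w - 1L), if.fuzzy.codon = "X"))
  }
  out <- c(one(d, 1), one(d, 2), one(d, 3), one(r, 1), one(r, 2), one(r, 3))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

# Exact shared AA k-mer prefilter (BLAST-style word seeding): a frame and
# a reference sharing no k-mer cannot reach the E-value cutoff, so the
# alignment is skipped.
aa_kmers <- function(s, k = 6L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Scan an element for protein-coding domains
#'
#' Local amino-acid alignment (BLOSUM62, affine gaps) of every reading
#' frame against every labeled reference; E-values follow the extreme
#' value formula with database size equal to the library residue count;
#' hits above `e_cutoff` are dropped and overlapping same-kind hits are
#' reduced to the best (score, then reference id).
#'
#' @param element_seq element nucleotide sequence.
#' @param lib labeled domain library (data.frame as from
#'   [make_domain_library()]).
#' @param e_cutoff E-value cutoff (default 1e-4).
#' @param prefilter skip frame/reference pairs sharing no exact AA 6-mer.
#' @return data.frame of hits: kind, frame, start, end (nucleotide,
#'   element coordinates), score, e_value, ref, superfamily, lineage.
#' @export
scan_domains <- function(element_seq, lib, e_cutoff = 1e-4,
                         prefilter = TRUE) {
  if (is.null(lib) || nrow(lib) == 0) stop("empty domain library")
  frames <- translate_six_frames(element_seq)
  dbsize <- sum(nchar(lib$seq))
  L <- nchar(element_seq)
  mat <- blosum62()
  hits <- list()
  lib_kmers <- lapply(lib$seq, aa_kmers)
  for (fr in names(frames)) {
    faa <- frames[[fr]]
    if (nchar(faa) < 10) next
    fk <- if (prefilter) aa_kmers(faa) else NULL
    for (j in seq_len(nrow(lib))) {
      if (prefilter && !any(lib_kmers[[j]] %in% fk)) next
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(faa), Biostrings::AAString(lib$seq[j]),
        type = "local", substitutionMatrix = mat,
        gapOpening = 10, gapExtension = 1)
      S <- Biostrings::score(pa)
      e_value <- KA_K * nchar(faa) * dbsize * exp(-KA_LAMBDA * S)
      if (e_value > e_cutoff) next
      ap <- as.character(Biostrings::alignedPattern(pa))
      consumed <- nchar(gsub("-", "", ap))
      aa_start <- Biostrings::start(Biostrings::pattern(pa))
      aa_end <- aa_start + consumed - 1L
      f <- as.integer(substr(fr, 2, 2))
      if (startsWith(fr, "+")) {
        nt_start <- f + 3L * (aa_start - 1L)
        nt_end <- f + 3L * aa_end - 1L
      } else {
        nt_end <- L - (f + 3L * (aa_start - 1L)) + 1L
        nt_start <- L - (f + 3L * aa_end - 1L) + 1L
      }
      hits[[length(hits) + 1L]] <- data.frame(
        kind = lib$kind[j], frame = fr, start = nt_start, end = nt_end,
        aa_start = aa_start, aa_end = aa_end,
        score = S, e_value = e_value, ref = lib$id[j],
        superfamily = lib$superfamily[j], lineage = lib$lineage[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(kind = character(), frame = character(),
                      start = integer(), end = integer(),
                      aa_start = integer(), aa_end = integer(),
                      score = numeric(), e_value = numeric(),
                      ref = character(), superfamily = character(),
                      lineage = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$kind, -out$score, out$ref), ]
  # reduce overlapping same-kind hits to the best
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j <= i || !keep[j] || out$kind[j] != out$kind[i]) next
      ov <- min(out$end[i], out$end[j]) - max(out$start[i], out$start[j])
      if (ov > 0) keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Merge same-kind hits in different frames within `gap` bp into one
# census entry (frameshift tolerance without frameshift-aware alignment).
domain_census <- function(hits, gap = 300L) {
  if (!nrow(hits)) return(hits)
  out <- list()
  for (kind in unique(hits$kind)) {
    h <- hits[hits$kind == kind, ]
    h <- h[order(h$start), ]
    grp <- if (nrow(h) == 1) 1L else
      cumsum(c(1L, (h$start[-1] - h$end[-nrow(h)]) > gap))
    for (g in unique(grp)) {
      hg <- h[grp == g, ]
      best <- hg[which.max(hg$score), ]
      best$start <- min(hg$start); best$end <- max(hg$end)
      best$n_fragments <- nrow(hg)
      out[[length(out) + 1L]] <- best
    }
  }
  out <- do.call(rbind, out)
  # one census entry per kind: the best merged entry
  out <- out[order(out$kind, -out$score), ]
  out[!duplicated(out$kind), ]
}

#' Classify one element into RLC / RLG / RXX-NA
#'
#' No RT/INT/RH hit at all -> RXX-NA (GAG and/or PR alone allowed).
#' Otherwise the superfamily is the majority reference label among the
#' retained RT/INT/RH hits, ties broken by internal domain order
#' (integrase upstream of RT means Copia; downstream of RNaseH means
#' Gypsy).  Orientation is the majority hit strand; a provisional lineage
#' comes from the best RT hit (refined later by RT phylogeny).
#'
#' @param hits [scan_domains()] output for the element.
#' @param element_length element length in bp (used only for bookkeeping).
#' @return one-row data.frame: superfamily, lineage, orientation,
#'   n_domains, plus the census in attribute "census".
#' @export
classify_superfamily <- function(hits, element_length = NA_integer_) {
  census <- domain_census(hits)
  pol <- census[census$kind %in% c("RT", "INT", "RH"), ]
  n_domains <- nrow(census)
  if (!nrow(pol)) {
    out <- data.frame(superfamily = "RXX-NA", lineage = NA_character_,
                      orientation = "unknown", n_domains = n_domains,
                      stringsAsFactors = FALSE)
    attr(out, "census") <- census
    return(out)
  }
  strands <- ifelse(startsWith(pol$frame, "+"), 1L, -1L)
  orientation <- if (sum(strands) > 0) "forward"
  else if (sum(strands) < 0) "reverse" else "unknown"
  tab <- sort(table(pol$superfamily), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) {
    # tie: use internal domain order in element orientation
    ctr <- function(kind) {
      r <- census[census$kind == kind, ]
      if (!nrow(r)) return(NA_real_)
      (r$start + r$end) / 2
    }
    int_c <- ctr("INT"); rt_c <- ctr("RT"); rh_c <- ctr("RH")
    flip <- orientation == "reverse"
    upstream <- function(a, b) if (flip) a > b else a < b
    sf <- if (!is.na(int_c) && !is.na(rt_c) && upstream(int_c, rt_c)) "Copia"
    else if (!is.na(int_c) && !is.na(rh_c) && upstream(rh_c, int_c)) "Gypsy"
    else names(tab)[1]
  } else sf <- names(tab)[1]
  sf_code <- c(Copia = "RLC", Gypsy = "RLG")[[sf]]
  rt <- census[census$kind == "RT", ]
  lineage <- if (nrow(rt)) rt$lineage[1] else pol$lineage[1]
  out <- data.frame(superfamily = sf_code, lineage = lineage,
                    orientation = orientation, n_domains = n_domains,
                    stringsAsFactors = FALSE)
  attr(out, "census") <- census
  out
}

#' Classify a set of elements
#'
#' @param elements detection data.frame (element_id at minimum).
#' @param seqs named character vector of element sequences.
#' @param lib labeled domain library.
#' @param e_cutoff E-value cutoff.
#' @return list with `classified` (elements + superfamily/lineage/
#'   orientation/n_domains) and `hits` (all retained domain hits).
#' @export
classify_elements <- function(elements, seqs, lib = make_domain_library(),
                              e_cutoff = 1e-4) {
  rows <- list(); allhits <- list()
  for (i in seq_len(nrow(elements))) {
    id <- elements$element_id[i]
    hits <- scan_domains(seqs[[id]], lib, e_cutoff)
    cl <- classify_superfamily(hits, nchar(seqs[[id]]))
    if (nrow(hits)) {
      hits$element_id <- id
      allhits[[length(allhits) + 1L]] <- hits
    }
    base <- elements[i, setdiff(names(elements), names(cl)), drop = FALSE]
    rows[[i]] <- cbind(base, cl)
  }
  classified <- do.call(rbind, rows)
  rownames(classified) <- NULL
  hits <- if (length(allhits)) do.call(rbind, allhits) else
    data.frame(element_id = character())
  list(classified = classified, hits = hits)
}

#' Summarize the domain census of a classified collection
#'
#' Counts by number of encoded domains (0-5) and per-kind frequencies,
#' split by superfamily; percentages to one decimal.
#'
#' @param classified [classify_elements()] classified table.
#' @param hits retained hits table (for per-kind frequencies).
#' @return list with `by_n_domains`, `by_kind`, and `shares` (the
#'   four-or-five-domain and five-domain percentage among RLC+RLG).
#' @export
summarize_domain_census <- function(classified, hits = NULL) {
  if (!nrow(classified)) {
    return(list(by_n_domains = data.frame(), by_kind = data.frame(),
                shares = data.frame()))
  }
  auto <- classified[classified$superfamily %in% c("RLC", "RLG"), ]
  by_n <- as.data.frame(table(
    superfamily = auto$superfamily,
    n_domains = factor(auto$n_domains, levels = 0:5)))
  by_kind <- NULL
  if (!is.null(hits) && nrow(hits)) {
    h <- hits[hits$element_id %in% auto$element_id, ]
    cls <- stats::setNames(auto$superfamily, auto$element_id)
    by_kind <- as.data.frame(table(kind = h$kind,
                                   superfamily = cls[h$element_id]))
  }
  shares <- domain_census_shares(sum(auto$n_domains == 4),
                                 sum(auto$n_domains == 5), nrow(auto))
  list(by_n_domains = by_n, by_kind = by_kind, shares = shares)
}

#' Domain-census share arithmetic
#'
#' @param n_four,n_five element counts encoding four / five domains.
#' @param n_auto total RLC+RLG element count.
#' @return data.frame with `four_or_five_pct` (one decimal) and
#'   `five_pct_nearest` (nearest integer).
#' @export
domain_census_shares <- function(n_four, n_five, n_auto) {
  data.frame(
    four_or_five_pct = pct1((n_four + n_five) / n_auto),
    five_pct_nearest = round(100 * n_five / n_auto)
  )
}
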