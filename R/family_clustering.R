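# Family clustering of full-length elements under the identity/coverage
# rule (default 70 %/70 %, the relaxation of the canonical 80/80 family
# criterion) with greedy longest-first incremental clustering and
# per-family reference selection.

# Word-seeded prescreen: a pair that cannot reach the identity/coverage
# thresholds shares essentially no diagonal-consistent k-mers, so the
# (quadratic-cost) alignment is skipped.  At 70 % identity the expected
# number of intact shared 11-mers on the homologous diagonal is ~0.02 per
# aligned position, i.e. >> 3 for any sequence long enough to cluster.
pair_prescreen <- function(a, b, min_cov = 0.70, k = 11L, band = 100L,
                           min_seeds = 3L) {
  ca <- kmer_codes(dna_to_int(a), k)
  cb <- kmer_codes(dna_to_int(b), k)
  posa <- which(!is.na(ca)); posb <- which(!is.na(cb))
  if (!length(posa) || !length(posb)) return(FALSE)
  dt_a <- data.table::data.table(code = ca[posa], pa = posa)
  dt_b <- data.table::data.table(code = cb[posb], pb = posb)
  m <- dt_a[dt_b, on = "code", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(m) < min_seeds) return(FALSE)
  m$diag <- m$pb - m$pa
  data.table::setorder(m, diag, pa)
  grp <- cumsum(c(1L, diff(m$diag) > band))
  shorter <- min(nchar(a), nchar(b))
  for (g in unique(grp)) {
    sel <- grp == g
    if (sum(sel) < min_seeds) next
    span <- max(m$pa[sel]) - min(m$pa[sel]) + k
    # a pair meeting the coverage threshold seeds most of the shorter
    # sequence; 0.6 x min_cov leaves generous slack for seed sparsity
    if (span >= 0.6 * min_cov * shorter) return(TRUE)
  }
  FALSE
}

#' Pairwise match under the identity/coverage rule
#'
#' Word-seeded local alignment; identity is matches over aligned columns;
#' coverage is the aligned span on the shorter sequence divided by its
#' length (the CD-HIT-style convention for the coverage denominator).
#' Pairs sharing no diagonal-consistent seed words are scored as
#' non-matching without alignment.
#'
#' @param a,b nucleotide sequences (non-empty).
#' @param min_id minimum identity.
#' @param min_cov minimum coverage.
#' @param prescreen skip alignment for pairs with no shared seed words.
#' @return list(matches, identity, coverage).
#' @export
pair_match <- function(a, b, min_id = 0.70, min_cov = 0.70,
                       prescreen = TRUE) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (prescreen && !pair_prescreen(a, b, min_cov))
    return(list(matches = FALSE, identity = NA_real_, coverage = NA_real_))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = nuc_submat_local(),
    gapOpening = 5, gapExtension = 2)
  ncol_aln <- Biostrings::nchar(pa)
  if (ncol_aln == 0) {
    return(list(matches = FALSE, identity = 0, coverage = 0))
  }
  identity <- Biostrings::nmatch(pa) / ncol_aln
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  span_a <- nchar(gsub("-", "", ap))
  span_b <- nchar(gsub("-", "", as_))
  shorter <- if (nchar(a) <= nchar(b)) "a" else "b"
  coverage <- if (shorter == "a") span_a / nchar(a) else span_b / nchar(b)
  list(matches = identity >= min_id && coverage >= min_cov,
       identity = identity, coverage = coverage)
}

#' Greedy incremental family clustering
#'
#' Elements are sorted by descending length (ties by id); each element
#' joins the first existing family whose representative (founder) it
#' matches under the identity/coverage rule, otherwise founds a new
#' family.  Deterministic.
#'
#' @param seqs named character vector of element sequences.
#' @param min_id,min_cov clustering thresholds (defaults 0.70/0.70).
#' @return data.frame with family (integer), member (id), founder (id).
#' @export
cluster_families <- function(seqs, min_id = 0.70, min_cov = 0.70) {
  ord <- order(-nchar(seqs), names(seqs))
  ids <- names(seqs)[ord]
  founders <- character(0)
  fam_of <- integer(0)
  assign <- stats::setNames(integer(length(ids)), ids)
  for (id in ids) {
    placed <- FALSE
    for (k in seq_along(founders)) {
      pm <- pair_match(seqs[[id]], seqs[[founders[k]]], min_id, min_cov)
      if (pm$matches) {
        assign[[id]] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      founders <- c(founders, id)
      assign[[id]] <- length(founders)
    }
  }
  data.frame(family = unname(assign), member = names(assign),
             founder = founders[unname(assign)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the per-family reference element
#'
#' Among members whose LTR-pair identity is within two percentage points
#' of the family maximum, the longest wins; remaining ties break by id.
#'
#' @param members character vector of member ids.
#' @param ltr_identity named numeric vector (fractions) keyed by id.
#' @param lengths named integer vector keyed by id.
#' @return the reference element id.
#' @export
select_reference <- function(members, ltr_identity, lengths) {
  stopifnot(length(members) > 0)
  idy <- ltr_identity[members]
  ok <- members[idy >= max(idy) - 0.02]
  ok <- ok[order(-lengths[ok], ok)]
  ok[1]
}

#' Cluster a collection and pick references
#'
#' @param seqs named element sequences.
#' @param elements element table with element_id, ltr_identity, length.
#' @param min_id,min_cov thresholds.
#' @return data.frame family, member, founder, is_reference.
#' @export
build_families <- function(seqs, elements, min_id = 0.70, min_cov = 0.70) {
  fams <- cluster_families(seqs, min_id, min_cov)
  idy <- stats::setNames(elements$ltr_identity, elements$element_id)
  len <- stats::setNames(elements$length, elements$element_id)
  refs <- vapply(split(fams$member, fams$family),
                 select_reference, "", ltr_identity = idy, lengths = len)
  fams$is_reference <- fams$member == refs[as.character(fams$family)]
  fams
}
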