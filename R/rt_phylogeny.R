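# Lineage assignment from reverse-transcriptase domains: extract the RT
# amino-acid sequence of each element (minimum 150 residues), build a
# pairwise-distance matrix (global alignment, Poisson-corrected
# p-distance), join elements with labeled references in a neighbor-joining
# tree, and read each element's lineage off its smallest single-lineage
# reference clade.

#' Extract the RT amino-acid sequence of a classified element
#'
#' Translates the best RT hit interval in its own frame; returns NA
#' unless the translation reaches `min_residues`.
#'
#' @param element_seq element nucleotide sequence.
#' @param hits domain hits for the element ([scan_domains()] output).
#' @param min_residues minimum RT length to keep (default 150).
#' @return AA string, or NA if no qualifying RT.
#' @export
extract_rt <- function(element_seq, hits, min_residues = 150) {
  rt <- hits[hits$kind == "RT", ]
  if (!nrow(rt)) return(NA_character_)
  rt <- rt[which.max(rt$score), ]
  frames <- translate_six_frames(element_seq)
  faa <- frames[[rt$frame]]
  aa <- substr(faa, rt$aa_start, rt$aa_end)
  aa <- gsub("*", "", aa, fixed = TRUE)
  if (nchar(aa) < min_residues) return(NA_character_)
  aa
}

#' Pairwise distance matrix over amino-acid sequences
#'
#' Per pair: global alignment with affine gaps (BLOSUM62); p = 1 -
#' identity over aligned columns where both sequences are non-gap;
#' distance is the Poisson correction -ln(1 - p) (capped), or the raw
#' p-distance if `correction = "none"`.
#'
#' @param sequences named character vector (>= 2, all non-empty).
#' @param correction "poisson" or "none".
#' @param max_distance cap for the corrected distance.
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_distance_matrix <- function(sequences,
                                     correction = c("poisson", "none"),
                                     max_distance = 5) {
  correction <- match.arg(correction)
  if (length(sequences) < 2) stop("need at least two sequences")
  if (any(nchar(sequences) == 0)) stop("zero-length sequence")
  n <- length(sequences)
  ids <- names(sequences)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  mat <- blosum62()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(sequences[[i]]),
        Biostrings::AAString(sequences[[j]]),
        type = "global", substitutionMatrix = mat,
        gapOpening = 10, gapExtension = 1)
      a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
      b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
      both <- a != "-" & b != "-"
      p <- mean(a[both] != b[both])
      dist <- if (correction == "poisson") {
        if (p >= 1) max_distance else min(-log(1 - p), max_distance)
      } else p
      d[i, j] <- d[j, i] <- dist
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical agglomeration: iteratively join the pair minimizing the
#' Q-criterion; branch lengths from the standard formulas; negative branch
#' lengths clamped to zero with the deficit shifted to the sister branch;
#' ties broken lexicographically by the smallest taxon id in each subtree.
#'
#' @param d symmetric distance matrix with taxon rownames, n >= 3.
#' @return Newick string (unrooted; trifurcating root).
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(!is.finite(d))) stop("distances must be finite")
  labs <- rownames(d)
  nwk <- labs          # growing newick fragment per active node
  rep_ <- labs         # smallest taxon id per subtree (tie-break key)
  D <- d
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    m <- min(Q)
    idx <- which(Q <= m + 1e-12, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    key <- apply(idx, 1, function(ij) {
      a <- rep_[ij[1]]; b <- rep_[ij[2]]
      paste(min(a, b), max(a, b))
    })
    pick <- idx[order(key)[1], ]
    f <- pick[1]; g <- pick[2]
    lf <- D[f, g] / 2 + (r[f] - r[g]) / (2 * (n - 2))
    lg <- D[f, g] - lf
    if (lf < 0) { lg <- D[f, g]; lf <- 0 }
    if (lg < 0) { lf <- D[f, g]; lg <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[f], fmt(lf), nwk[g], fmt(lg))
    new_rep <- min(rep_[f], rep_[g])
    dk <- (D[f, -c(f, g)] + D[g, -c(f, g)] - D[f, g]) / 2
    keep <- setdiff(seq_len(n), c(f, g))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk), c(dk, 0))
    nwk <- c(nwk[keep], new_nwk)
    rep_ <- c(rep_[keep], new_rep)
    rownames(D2) <- colnames(D2) <- rep_
    D <- D2
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  ord <- order(rep_)
  parts <- sprintf("%s:%s", nwk, fmt(c(la, lb, lc)))[ord]
  paste0("(", paste(parts, collapse = ","), ");")
}

#' Assign lineages to elements from a joint NJ tree with references
#'
#' Builds a neighbor-joining tree of element RTs together with labeled
#' reference RTs (taxa prefixed `REF_`); each element takes the lineage of
#' the smallest clade (tree split side) containing it and at least one
#' reference -- provided that clade's references carry exactly one lineage;
#' otherwise the element is `undefined`.  Support is the distance to the
#' nearest reference.
#'
#' @param element_rts named character vector of element RT AA sequences.
#' @param reference_rts named character vector of reference RTs; names
#'   must be the lineage labels (duplicated labels allowed).
#' @return list with `assignments` (data.frame element_id, lineage,
#'   support) and `tree` (Newick string).
#' @export
assign_lineages <- function(element_rts, reference_rts) {
  if (!length(reference_rts)) stop("no reference RTs")
  if (!length(element_rts)) {
    return(list(assignments = data.frame(element_id = character(),
                                         lineage = character(),
                                         support = numeric()),
                tree = NA_character_))
  }
  ref_ids <- sprintf("REF_%s_%d", names(reference_rts),
                     seq_along(reference_rts))
  ref_lineage <- stats::setNames(names(reference_rts), ref_ids)
  all_seqs <- c(element_rts, stats::setNames(reference_rts, ref_ids))
  d <- pairwise_distance_matrix(all_seqs)
  nwk <- neighbor_joining(d)
  tree <- ape::read.tree(text = nwk)
  tips <- tree$tip.label
  # all split sides: rooted clades plus their complements
  pp <- ape::prop.part(tree)
  sides <- c(lapply(pp, function(i) tips[i]),
             lapply(pp, function(i) tips[-i]))
  sides <- unique(lapply(sides, sort))
  rows <- list()
  for (el in names(element_rts)) {
    cand <- Filter(function(s) el %in% s && any(s %in% ref_ids), sides)
    support <- min(d[el, ref_ids])
    if (!length(cand)) {
      rows[[el]] <- data.frame(element_id = el, lineage = "undefined",
                               support = support)
      next
    }
    sizes <- vapply(cand, length, 1L)
    best <- cand[[order(sizes)[1]]]
    lins <- unique(ref_lineage[best[best %in% ref_ids]])
    rows[[el]] <- data.frame(
      element_id = el,
      lineage = if (length(lins) == 1) lins else "undefined",
      support = support, stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, rows)
  rownames(assignments) <- NULL
  list(assignments = assignments, tree = nwk)
}

#' Reference RT sequences from a domain library
#' @param lib domain library data.frame.
#' @return named character vector (names = lineage labels).
#' @export
reference_rts <- function(lib = make_domain_library()) {
  rt <- lib[lib$kind == "RT", ]
  stats::setNames(rt$seq, rt$lineage)
}
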