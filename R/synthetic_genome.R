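# Synthetic genomes with planted full-length LTR retrotransposons and full
# ground truth.  The simulator emulates the statistical structure the
# downstream analysis assumes: multi-scaffold assemblies with N runs,
# elements delimited by diverged LTR pairs with TSD/PBS/PPT, labeled
# protein-domain ORFs, gene intervals with a density gradient, and
# per-tissue read sets with known element expression.

#' Generate an i.i.d. background sequence
#'
#' @param length sequence length in bp (> 0).
#' @param gc GC fraction in [0, 1].
#' @param n_run_fraction fraction of the sequence covered by runs of N
#'   (uncharacterized bases), in [0, 1).
#' @param seed optional integer seed (uses the current RNG stream if NULL).
#' @return a single character string.
#' @export
generate_background <- function(length, gc = 0.4, n_run_fraction = 0, seed = NULL) {
  stopifnot(length > 0, gc >= 0, gc <= 1,
            n_run_fraction >= 0, n_run_fraction < 1)
  gen <- function() {
    s <- random_dna(length, gc)
    n_total <- floor(length * n_run_fraction)
    if (n_total > 0) {
      # a few geometric-length runs summing to the requested N budget
      runs <- c()
      while (sum(runs) < n_total) {
        runs <- c(runs, min(stats::rgeom(1, 1 / 500) + 50, n_total - sum(runs)))
      }
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      occupied <- integer(0)
      for (r in runs) {
        for (try in 1:50) {
          st <- sample.int(length - r + 1, 1)
          idx <- st:(st + r - 1)
          if (!any(idx %in% occupied)) {
            ch[idx] <- "N"
            occupied <- c(occupied, idx)
            break
          }
        }
      }
      s <- paste(ch, collapse = "")
    }
    s
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Specification of one planted element
#'
#' @param superfamily "Copia", "Gypsy" or "NA" (non-autonomous).
#' @param lineage lineage label; defaults to the first lineage of the
#'   superfamily (ignored for "NA" beyond picking the domain donor).
#' @param ltr_length LTR length in bp.
#' @param internal_length internal-region length in bp.
#' @param domain_list ordered subset of GAG/PR/INT/RT/RH; for "NA"
#'   superfamily it must be a subset of GAG/PR.
#' @param divergence_age expected K2P distance between the LTR pair.
#' @param ts_tv_ratio transitions per transversion for LTR divergence.
#' @param tsd_length target-site-duplication length (4-6 bp).
#' @param has_pbs,has_ppt plant primer-binding site / polypurine tract.
#' @param disrupt inject a frameshift and a premature stop into the ORF.
#' @param tg_ca force TG...CA LTR termini (the canonical dinucleotides).
#' @param family optional family label; specs sharing a label become
#'   mutated copies of one family master (see [plant_elements()]).
#' @return an object of class "element_spec".
#' @export
element_spec <- function(superfamily = c("Copia", "Gypsy", "NA"),
                         lineage = NULL,
                         ltr_length = 800, internal_length = 4000,
                         domain_list = NULL,
                         divergence_age = 0.05, ts_tv_ratio = 2,
                         tsd_length = 5, has_pbs = TRUE, has_ppt = TRUE,
                         disrupt = FALSE, tg_ca = TRUE, family = NA_character_) {
  superfamily <- match.arg(superfamily)
  stopifnot(ltr_length > 0, internal_length > 0, divergence_age >= 0,
            ts_tv_ratio > 0, tsd_length >= 4, tsd_length <= 6)
  if (is.null(domain_list)) {
    domain_list <- if (superfamily == "NA") c("GAG", "PR") else DOMAIN_KINDS
  }
  stopifnot(all(domain_list %in% DOMAIN_KINDS))
  if (superfamily == "NA" && !all(domain_list %in% c("GAG", "PR"))) {
    stop("a non-autonomous (NA) element may carry only GAG/PR domains")
  }
  if (is.null(lineage)) {
    lineage <- switch(superfamily, Copia = COPIA_LINEAGES[1],
                      Gypsy = GYPSY_LINEAGES[1], "NA" = NA_character_)
  }
  # truth superfamily is NA whenever no RT/INT/RH domain is present
  truth_sf <- if (any(domain_list %in% c("RT", "INT", "RH"))) superfamily else "NA"
  structure(list(
    superfamily = superfamily, lineage = lineage,
    truth_superfamily = truth_sf,
    ltr_length = ltr_length, internal_length = internal_length,
    domain_list = domain_list, divergence_age = divergence_age,
    ts_tv_ratio = ts_tv_ratio, tsd_length = tsd_length,
    has_pbs = has_pbs, has_ppt = has_ppt, disrupt = disrupt,
    tg_ca = tg_ca, family = family
  ), class = "element_spec")
}

#' Build one full-length element from its specification
#'
#' Layout: LTR5 + \[PBS + domain ORF + PPT, with random filler\] + LTR3,
#' where LTR3 is LTR5 mutated under the K2P model at the spec's divergence
#' age, the PBS is the reverse complement of a bundled tRNA 3' end placed
#' within 20 bp of the LTR5 end, and the PPT is a purine tract within
#' 20 bp of the LTR3 start.
#'
#' @param spec an [element_spec()].
#' @param seed optional integer seed.
#' @param domain_lib domain library (defaults to the bundled one).
#' @return list with `seq` (character) and `truth` (list of coordinates
#'   and labels, 1-based inclusive, element-relative).
#' @export
build_element <- function(spec, seed = NULL, domain_lib = make_domain_library()) {
  gen <- function() {
    L <- spec$ltr_length
    ltr5 <- random_dna(L)
    if (spec$tg_ca) {
      substr(ltr5, 1, 2) <- "TG"
      substr(ltr5, L - 1, L) <- "CA"
    }

    pbs_gap <- 3L
    trna_id <- NA_character_
    pbs <- ""
    if (spec$has_pbs) {
      lib <- trna_3prime_library()
      trna_id <- sample(names(lib), 1)
      pbs <- revcomp(lib[[trna_id]])
    }

    # domain donor: NA elements borrow GAG/PR from a Copia lineage
    donor_sf <- if (spec$superfamily == "NA") "Copia" else spec$superfamily
    donor_lin <- if (spec$superfamily == "NA") COPIA_LINEAGES[1] else spec$lineage
    order_sf <- DOMAIN_ORDER[[donor_sf]]
    kinds <- order_sf[order_sf %in% spec$domain_list]

    linker_nt <- reverse_translate("GSGS")
    orf <- "ATG"
    dom_rows <- list()
    for (kind in kinds) {
      ref <- domain_lib[domain_lib$superfamily == donor_sf &
                        domain_lib$lineage == donor_lin &
                        domain_lib$kind == kind, ]
      stopifnot(nrow(ref) == 1)
      orf <- paste0(orf, linker_nt)
      dstart <- nchar(orf) + 1L
      dnt <- reverse_translate(ref$seq)
      orf <- paste0(orf, dnt)
      dom_rows[[kind]] <- data.frame(kind = kind, start = dstart,
                                     end = nchar(orf), ref = ref$id,
                                     stringsAsFactors = FALSE)
    }
    orf <- paste0(orf, linker_nt, "TAA")
    domains <- if (length(dom_rows)) do.call(rbind, dom_rows) else
      data.frame(kind = character(), start = integer(), end = integer(),
                 ref = character())

    if (spec$disrupt && nrow(domains) > 0) {
      # premature stop: overwrite one in-frame codon inside a random domain
      di <- sample(nrow(domains), 1)
      ncod <- (domains$end[di] - domains$start[di] + 1L) %/% 3L
      cpos <- domains$start[di] + 3L * (sample(ncod - 2L, 1)) # skip first codon
      # align to ORF reading frame (ORF starts at position 1 of `orf`)
      cpos <- cpos - ((cpos - 1L) %% 3L)
      substr(orf, cpos, cpos + 2L) <- "TAA"
      # 1-bp insertion at a random later in-frame position (frameshift)
      ipos <- min(nchar(orf) - 4L, cpos + 3L * sample(20L, 1))
      orf <- paste0(substr(orf, 1, ipos), "A", substr(orf, ipos + 1L, nchar(orf)))
      shift <- domains$start > ipos
      domains$start[shift] <- domains$start[shift] + 1L
      domains$end[domains$end >= ipos] <- domains$end[domains$end >= ipos] + 1L
    }

    ppt <- if (spec$has_ppt)
      paste(sample(c("A", "G"), 15, replace = TRUE, prob = c(0.45, 0.55)),
            collapse = "") else ""
    ppt_gap <- 3L

    required <- pbs_gap + nchar(pbs) + nchar(orf) + nchar(ppt) + ppt_gap
    filler_total <- spec$internal_length - required
    if (filler_total < 0) {
      stop("domain_list does not fit: internal_length ", spec$internal_length,
           " < required ", required)
    }
    fa <- floor(filler_total * 0.4)
    fb <- filler_total - fa
    internal <- paste0(strrep("", 0), random_dna(pbs_gap), pbs, random_dna(fa),
                       orf, random_dna(fb), ppt, random_dna(ppt_gap))

    ltr3 <- mutate_k2p(ltr5, spec$divergence_age, spec$ts_tv_ratio)
    if (spec$tg_ca) {
      substr(ltr3, 1, 2) <- "TG"
      substr(ltr3, L - 1, L) <- "CA"
    }

    seq <- paste0(ltr5, internal, ltr3)
    I <- nchar(internal)
    orf_off <- L + pbs_gap + nchar(pbs) + fa
    if (nrow(domains)) {
      domains$start <- domains$start + orf_off
      domains$end <- domains$end + orf_off
    }
    list(seq = seq, truth = list(
      ltr_length = L, internal_length = I, length = nchar(seq),
      ltr5 = c(1L, L), ltr3 = c(L + I + 1L, L + I + L),
      superfamily = spec$truth_superfamily, lineage = spec$lineage,
      k_true = spec$divergence_age, tsd_length = spec$tsd_length,
      domains = domains, trna = trna_id,
      pbs = c(L + pbs_gap + 1L, L + pbs_gap + nchar(pbs)),
      ppt = c(L + I - ppt_gap - nchar(ppt) + 1L, L + I - ppt_gap),
      disrupt = spec$disrupt
    ))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Derive a family member from a family master: symmetric K2P mutation of
# the whole element at age K/2, so the member's own LTR pair diverges by K
# in expectation while members stay mutually alignable.
derive_family_member <- function(master, K, tstv = 2) {
  member <- master
  member$seq <- mutate_k2p(master$seq, K / 2, tstv)
  member$truth$k_true <- K
  member
}

#' Plant elements and genes into a background
#'
#' Each insertion duplicates `tsd_length` host bases on both sides of the
#' element (the target-site duplication).  Gene intervals are planted
#' non-overlapping with a density gradient decreasing along each scaffold;
#' under `placement_bias = "copia_avoid"` Copia elements avoid gene-rich
#' regions so the density correlation carries a negative signal.
#'
#' @param background named character vector of scaffold sequences.
#' @param specs list of [element_spec()] objects.
#' @param placement_bias "none" or "copia_avoid".
#' @param bias_strength exponential weight of Copia avoidance.
#' @param genes_per_mb planted gene density.
#' @param gene_length gene interval length (bp).
#' @param min_gap minimum spacing between insertion points (bp).
#' @param seed optional integer seed.
#' @param domain_lib domain library.
#' @return list with `genome` (named character), `elements` (truth
#'   data.frame, 1-based inclusive final coordinates), `genes`
#'   (data.frame), `element_seqs` (named character) and `element_truths`.
#' @export
plant_elements <- function(background, specs,
                           placement_bias = c("none", "copia_avoid"),
                           bias_strength = 6, genes_per_mb = 25,
                           gene_length = 2000, min_gap = 25000,
                           seed = NULL, domain_lib = make_domain_library()) {
  placement_bias <- match.arg(placement_bias)
  if (is.null(names(background)))
    names(background) <- sprintf("scaffold_%02d", seq_along(background))
  gen <- function() {
    ## 1. build elements, honoring shared family labels
    built <- vector("list", length(specs))
    fams <- vapply(specs, function(s) s$family, "")
    masters <- list()
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      if (!is.na(sp$family) && sum(fams == sp$family, na.rm = TRUE) > 1) {
        if (is.null(masters[[sp$family]])) {
          msp <- sp
          msp$divergence_age <- 0
          masters[[sp$family]] <- build_element(msp, domain_lib = domain_lib)
        }
        built[[i]] <- derive_family_member(masters[[sp$family]],
                                           sp$divergence_age, sp$ts_tv_ratio)
      } else {
        built[[i]] <- build_element(sp, domain_lib = domain_lib)
      }
    }
    ids <- sprintf("E%03d", seq_along(specs))

    slen <- nchar(background)
    ## 2. gene intervals (original background coordinates)
    genes <- list()
    for (sc in names(background)) {
      n_genes <- round(genes_per_mb * slen[[sc]] / 1e6)
      if (n_genes == 0) next
      starts <- integer(0)
      grid <- seq(1000, slen[[sc]] - gene_length - 1000, by = 250)
      # steep exponential gradient: gene-rich scaffold heads, gene-poor
      # tails, so density tracks carry contrast across windows
      w <- exp(-3 * grid / slen[[sc]]) + 0.02
      tries <- 0
      while (length(starts) < n_genes && tries < 50 * n_genes) {
        tries <- tries + 1
        cand <- sample(grid, 1, prob = w)
        if (!any(abs(cand - starts) < gene_length + 500)) starts <- c(starts, cand)
      }
      genes[[sc]] <- data.frame(scaffold = sc, start = sort(starts),
                                end = sort(starts) + gene_length - 1L,
                                stringsAsFactors = FALSE)
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(scaffold = character(), start = integer(), end = integer())
    rownames(genes) <- NULL

    ## 3. choose insertion points (original coordinates)
    scafs <- sample(names(background), length(specs), replace = TRUE,
                    prob = slen / sum(slen))
    ins <- data.frame(id = ids, scaffold = scafs, p = NA_integer_,
                      stringsAsFactors = FALSE)
    unplaced <- character(0)
    chosen <- split(integer(0), NULL)
    for (i in seq_along(specs)) {
      sc <- scafs[i]
      len <- slen[[sc]]
      elen <- built[[i]]$truth$length
      if (len < 2 * min_gap + elen) { unplaced <- c(unplaced, ids[i]); next }
      grid <- seq(min_gap, len - min_gap - elen, by = 503)
      gsc <- genes[genes$scaffold == sc, ]
      # smoothed local gene density (gene bp within +-50 kb), normalized;
      # Copia avoidance weights positions by exp(-strength * density)
      gdens <- vapply(grid, function(x) {
        ov <- pmin(gsc$end, x + 50000) - pmax(gsc$start, x - 50000)
        sum(ov[ov > 0])
      }, 0)
      w <- rep(1, length(grid))
      if (placement_bias == "copia_avoid" &&
          specs[[i]]$superfamily == "Copia" && max(gdens) > 0) {
        w <- exp(-bias_strength * gdens / max(gdens))
      }
      # exclude gene bodies (plus margin), previously chosen points, and
      # insertion sites whose TSD window touches an N run
      inside_gene <- vapply(grid, function(x)
        any(gsc$start - 200 < x & gsc$end + 200 > x), TRUE)
      prev <- ins$p[ins$scaffold == sc & !is.na(ins$p)]
      clash <- vapply(grid, function(x) any(abs(x - prev) < min_gap), TRUE)
      t <- specs[[i]]$tsd_length
      n_in_tsd <- vapply(grid, function(x)
        grepl("N", substr(background[[sc]], x - 2L, x + t + 2L),
              fixed = TRUE), TRUE)
      ok <- !inside_gene & !clash & !n_in_tsd
      if (!any(ok)) { unplaced <- c(unplaced, ids[i]); next }
      ins$p[i] <- sample(grid[ok], 1, prob = w[ok])
    }
    if (length(unplaced)) {
      stop("insufficient room to place elements: ",
           paste(unplaced, collapse = ", "))
    }

    ## 4. assemble scaffolds with TSD duplication and track final coords
    truth <- list()
    genome <- background
    for (sc in names(background)) {
      idx <- which(ins$scaffold == sc)
      idx <- idx[order(ins$p[idx])]
      if (!length(idx)) next
      bg <- background[[sc]]
      pieces <- character(0)
      prev_end <- 0L
      offset <- 0L
      for (i in idx) {
        p <- ins$p[i]
        t <- specs[[i]]$tsd_length
        elen <- built[[i]]$truth$length
        tsd <- substr(bg, p, p + t - 1L)
        pieces <- c(pieces, substr(bg, prev_end + 1L, p + t - 1L),
                    built[[i]]$seq)
        start <- p + t + offset
        tr <- built[[i]]$truth
        truth[[i]] <- data.frame(
          element_id = ids[i], scaffold = sc,
          start = start, end = start + elen - 1L,
          ltr5_start = start + tr$ltr5[1] - 1L, ltr5_end = start + tr$ltr5[2] - 1L,
          ltr3_start = start + tr$ltr3[1] - 1L, ltr3_end = start + tr$ltr3[2] - 1L,
          ltr_length = tr$ltr_length, length = elen,
          tsd = tsd, superfamily = tr$superfamily,
          lineage = tr$lineage, k_true = tr$k_true,
          family_id = specs[[i]]$family, stringsAsFactors = FALSE
        )
        prev_end <- p - 1L     # next piece restarts at p (duplicating the TSD)
        offset <- offset + elen + t
      }
      pieces <- c(pieces, substr(bg, prev_end + 1L, nchar(bg)))
      genome[[sc]] <- paste(pieces, collapse = "")
      # shift downstream genes on this scaffold
      gidx <- which(genes$scaffold == sc)
      if (length(gidx)) {
        ps <- ins$p[idx]
        shifts <- vapply(genes$start[gidx], function(gs) {
          before <- ps <= gs
          sum(vapply(idx[before], function(i)
            built[[i]]$truth$length + specs[[i]]$tsd_length, 0))
        }, 0)
        genes$start[gidx] <- genes$start[gidx] + shifts
        genes$end[gidx] <- genes$end[gidx] + shifts
      }
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$scaffold, truth$start), ]
    rownames(truth) <- NULL

    seqs <- vapply(built, `[[`, "", "seq")
    names(seqs) <- ids
    tr_list <- lapply(built, `[[`, "truth")
    names(tr_list) <- ids
    list(genome = genome, elements = truth, genes = genes,
         element_seqs = seqs, element_truths = tr_list)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate read sets over an element library
#'
#' Reads are drawn per tissue with origin probabilities proportional to the
#' planted expression levels, uniform start positions, random strand, and
#' i.i.d. substitution errors.  Qualities are constant Sanger 'I'.
#'
#' @param library named character vector of reference sequences.
#' @param levels numeric matrix (elements x tissues) of expression levels,
#'   or a vector for a single tissue.
#' @param read_length read length (must not exceed the shortest reference).
#' @param depth number of reads per tissue (scalar or per-tissue vector).
#' @param error_rate per-base substitution error probability.
#' @param seed optional integer seed.
#' @return list with `tissues` (list of data.frames id/seq/qual), and
#'   `truth_counts` (elements x tissues origin-count matrix).
#' @export
generate_reads <- function(library, levels, read_length = 100, depth = 2000,
                           error_rate = 0.01, seed = NULL) {
  if (is.vector(levels)) levels <- matrix(levels, ncol = 1,
                                          dimnames = list(names(levels), "t1"))
  stopifnot(all(levels >= 0), nrow(levels) == length(library))
  if (min(nchar(library)) < read_length)
    stop("read_length exceeds the shortest reference")
  if (is.null(rownames(levels))) rownames(levels) <- names(library)
  depth <- rep(depth, length.out = ncol(levels))
  gen <- function() {
    out <- list()
    truth <- matrix(0L, nrow(levels), ncol(levels),
                    dimnames = dimnames(levels))
    for (t in seq_len(ncol(levels))) {
      lv <- levels[, t]
      if (sum(lv) == 0) stop("zero total expression level in tissue ",
                             colnames(levels)[t])
      n <- depth[t]
      origin <- sample(rownames(levels), n, replace = TRUE,
                       prob = lv / sum(lv))
      tb <- table(factor(origin, levels = rownames(levels)))
      truth[, t] <- as.integer(tb)
      ref <- unname(library[origin])
      st <- floor(stats::runif(n) * (nchar(ref) - read_length + 1L)) + 1L
      seqs <- substring(ref, st, st + read_length - 1L)
      if (error_rate > 0) {
        nerr <- stats::rbinom(n, read_length, error_rate)
        for (r in which(nerr > 0)) {
          ch <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
          for (i in sample.int(read_length, nerr[r]))
            if (ch[i] %in% DNA_BASES) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
          seqs[r] <- paste(ch, collapse = "")
        }
      }
      flip <- stats::runif(n) < 0.5
      if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
      out[[colnames(levels)[t]]] <- data.frame(
        id = sprintf("%s_r%05d", colnames(levels)[t], seq_len(n)),
        seq = seqs, qual = strrep("I", read_length),
        origin = origin, stringsAsFactors = FALSE
      )
    }
    list(tissues = out, truth_counts = truth)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' The bundled synthetic study genome
#'
#' Approximately 3 Mb over three scaffolds with 30 planted full-length
#' elements (12 Copia, 8 Gypsy, 10 non-autonomous) spanning four Copia and
#' five Gypsy lineages, LTR divergence strata K in {0.04, 0.07, 0.10}
#' (ten elements each), four multi-member families, planted genes with a
#' density gradient and strong Copia avoidance of gene-rich regions.
#'
#' @param seed integer seed driving all randomness.
#' @param scaffold_length length of each of the three scaffolds.
#' @param genes_per_mb planted gene density.
#' @return the [plant_elements()] result, plus `specs` and `domain_lib`.
#' @export
simulate_study_genome <- function(seed = 101, scaffold_length = 1e6,
                                  genes_per_mb = 25) {
  ages <- c(0.04, 0.07, 0.10)
  lt <- function(i) c(800, 1000, 1200)[(i - 1) %% 3 + 1]
  specs <- list()
  add <- function(...) specs[[length(specs) + 1L]] <<- element_spec(...)

  # Copia: two 3-member families + six singletons
  for (j in 1:3) add("Copia", "Tork", ltr_length = 1000,
                     divergence_age = ages[j], family = "F1")
  for (j in 1:3) add("Copia", "Retrofit", ltr_length = 1000,
                     divergence_age = ages[j], family = "F2")
  sing_c <- list(c("Sire", 0.04), c("Sire", 0.07), c("Oryco", 0.10),
                 c("Oryco", 0.04), c("Tork", 0.07), c("Retrofit", 0.10))
  for (j in seq_along(sing_c))
    add("Copia", sing_c[[j]][1], ltr_length = lt(j),
        divergence_age = as.numeric(sing_c[[j]][2]))

  # Gypsy: one 2-member family + six singletons
  for (j in 1:2) add("Gypsy", "Tat", ltr_length = 1000,
                     divergence_age = ages[j], family = "F3")
  sing_g <- list(c("Athila", 0.10), c("CRM", 0.04), c("Del", 0.07),
                 c("Galadriel", 0.10), c("Reina", 0.04), c("Tat", 0.07))
  for (j in seq_along(sing_g))
    add("Gypsy", sing_g[[j]][1], ltr_length = lt(j),
        divergence_age = as.numeric(sing_g[[j]][2]))

  # Non-autonomous: one 2-member family + eight singletons
  add("NA", domain_list = c("GAG", "PR"), internal_length = 2600,
      ltr_length = 800, divergence_age = 0.10, family = "F4")
  add("NA", domain_list = c("GAG", "PR"), internal_length = 2600,
      ltr_length = 800, divergence_age = 0.04, family = "F4")
  na_ages <- c(0.04, 0.04, 0.07, 0.07, 0.07, 0.10, 0.10, 0.10)
  for (j in seq_along(na_ages))
    add("NA", domain_list = if (j %% 2) c("GAG", "PR") else "GAG",
        internal_length = 2600, ltr_length = lt(j),
        divergence_age = na_ages[j])

  lib <- make_domain_library()
  bg <- vapply(1:3, function(i)
    generate_background(scaffold_length, gc = 0.4, n_run_fraction = 0.02,
                        seed = derive_seed(seed, i)), "")
  names(bg) <- sprintf("scaffold_%02d", 1:3)
  sim <- plant_elements(bg, specs, placement_bias = "copia_avoid",
                        genes_per_mb = genes_per_mb,
                        seed = derive_seed(seed, 50), domain_lib = lib)
  sim$specs <- specs
  sim$domain_lib <- lib
  sim$seed <- seed
  sim
}

#' Simulate the eight-tissue read sets for a study genome
#'
#' Twelve elements are expressed (four per class) with planted class shares
#' 60/20/20 (non-autonomous / Copia / Gypsy) of total element expression;
#' per-tissue element read totals follow a fixed tissue-activity profile
#' with the shoot apex highest and young female flowers lowest.  Background
#' reads drawn from non-element genome positions fill every library to a
#' constant depth.
#'
#' @param sim result of [simulate_study_genome()].
#' @param seed integer seed.
#' @param total_te_reads element-derived reads across all tissues.
#' @param depth_per_tissue total reads per tissue library.
#' @param read_length read length.
#' @param error_rate per-base error rate.
#' @return list with `tissues` (read data.frames), `truth_counts`,
#'   `tissue_share`, `class_share`, `expressed` element ids.
#' @export
simulate_tissue_reads <- function(sim, seed = sim$seed,
                                  total_te_reads = 16000,
                                  depth_per_tissue = 6000,
                                  read_length = 100, error_rate = 0.005) {
  tissue_share <- c(root = 0.11, leaf = 0.11, shoot_apex = 0.18,
                    young_flower = 0.06, mature_flower = 0.13,
                    pollen = 0.14, kernel = 0.13, mesocarp = 0.14)
  class_share <- c("NA" = 0.60, Copia = 0.20, Gypsy = 0.20)
  el <- sim$elements
  expressed <- unlist(lapply(names(class_share), function(cl)
    utils::head(el$element_id[el$superfamily == cl], 4)))
  lv <- matrix(0, nrow(el), length(tissue_share),
               dimnames = list(el$element_id, names(tissue_share)))
  for (cl in names(class_share)) {
    ids <- utils::head(el$element_id[el$superfamily == cl], 4)
    # uneven within-class weights so elements differ in rank
    w <- c(0.4, 0.3, 0.2, 0.1)[seq_along(ids)]
    for (t in names(tissue_share))
      lv[ids, t] <- class_share[[cl]] * w * tissue_share[[t]]
  }
  te_depth <- round(total_te_reads * tissue_share)
  # element reads are generated over the expressed rows only
  rd <- generate_reads(sim$element_seqs[expressed],
                       lv[expressed, , drop = FALSE],
                       read_length = read_length, depth = te_depth,
                       error_rate = error_rate, seed = derive_seed(seed, 77))
  # top up with background reads from non-element genome positions
  with_seed(derive_seed(seed, 78), {
    for (t in names(rd$tissues)) {
      nbg <- depth_per_tissue - nrow(rd$tissues[[t]])
      if (nbg <= 0) next
      sc <- sample(names(sim$genome), nbg, replace = TRUE)
      seqs <- vapply(sc, function(s) {
        repeat {
          st <- sample.int(nchar(sim$genome[[s]]) - read_length, 1)
          elh <- sim$elements[sim$elements$scaffold == s, ]
          inside <- any(st < elh$end & st + read_length - 1 > elh$start)
          if (!inside) return(substr(sim$genome[[s]], st, st + read_length - 1))
        }
      }, "", USE.NAMES = FALSE)
      seqs[grepl("N", seqs, fixed = TRUE)] <-
        gsub("N", "A", seqs[grepl("N", seqs, fixed = TRUE)], fixed = TRUE)
      bgdf <- data.frame(
        id = sprintf("%s_bg%05d", t, seq_len(nbg)), seq = seqs,
        qual = strrep("I", read_length), origin = "background",
        stringsAsFactors = FALSE
      )
      rd$tissues[[t]] <- rbind(rd$tissues[[t]], bgdf)
    }
  })
  truth <- matrix(0L, nrow(el), length(tissue_share),
                  dimnames = list(el$element_id, names(tissue_share)))
  truth[rownames(rd$truth_counts), ] <- rd$truth_counts
  list(tissues = rd$tissues, truth_counts = truth,
       tissue_share = tissue_share, class_share = class_share,
       expressed = expressed)
}
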