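# End-to-end orchestration: detect -> classify -> lineages -> cluster ->
# scan -> date (-> expression), with the collection summary bookkeeping
# (per-superfamily/lineage counts, LTR statistics, copy totals and
# percentage shares).

#' Superfamily percentage shares
#'
#' @param counts named integer vector of element counts per superfamily.
#' @return data.frame superfamily, count, pct (one decimal, standard
#'   rounding).
#' @export
superfamily_shares <- function(counts) {
  data.frame(superfamily = names(counts), count = unname(counts),
             pct = pct1(unname(counts) / sum(counts)),
             stringsAsFactors = FALSE)
}

#' Mapped-copy percentage share
#' @param n_mapped copies mapped to the chromosome subset.
#' @param n_total total copies.
#' @return percentage to one decimal.
#' @export
mapped_share <- function(n_mapped, n_total) pct1(n_mapped / n_total)

#' Summarize a full-length element collection
#'
#' Table-style bookkeeping: per superfamily (and lineage) the group and
#' element counts, mean LTR length with min-max, mean LTR identity, copy
#' counts and genome coverage, plus overall totals and percentage shares.
#'
#' @param classified classified element table (superfamily, lineage,
#'   ltr_identity, ltr5_start/ltr5_end or ltr_length).
#' @param families family table from [build_families()].
#' @param copies copy-hit table from [find_copies()] (may be NULL).
#' @param genome_bp total genome size in bp (for coverage; may be NA).
#' @return list with `by_superfamily`, `by_lineage`, `shares`, `totals`.
#' @export
summarize_collection <- function(classified, families = NULL, copies = NULL,
                                 genome_bp = NA_real_) {
  cl <- classified
  if (!("ltr_length" %in% names(cl)))
    cl$ltr_length <- cl$ltr5_end - cl$ltr5_start + 1L
  fam_of <- if (!is.null(families))
    stats::setNames(families$family, families$member) else NULL

  summ <- function(sub) {
    data.frame(
      n_groups = if (is.null(fam_of)) NA_integer_ else
        length(unique(fam_of[sub$element_id])),
      n_elements = nrow(sub),
      ltr_mean = round(mean(sub$ltr_length), 1),
      ltr_min = min(sub$ltr_length), ltr_max = max(sub$ltr_length),
      ltr_identity_mean_pct = round(100 * mean(sub$ltr_identity), 2)
    )
  }
  by_sf <- do.call(rbind, lapply(split(cl, cl$superfamily), summ))
  by_sf <- cbind(superfamily = rownames(by_sf), by_sf)
  rownames(by_sf) <- NULL
  lin <- cl[!is.na(cl$lineage), ]
  by_lin <- if (nrow(lin)) {
    x <- do.call(rbind, lapply(split(lin, paste(lin$superfamily, lin$lineage)),
                               summ))
    cbind(group = rownames(x), x)
  } else NULL

  if (!is.null(copies) && nrow(copies)) {
    cc <- copies[copies$complete, ]
    cp <- table(factor(cc$superfamily))
    cov_bp <- tapply(cc$end - cc$start + 1L, factor(cc$superfamily), sum)
    by_sf$copies <- as.integer(cp[match(by_sf$superfamily, names(cp))])
    by_sf$coverage_pct <- round(
      100 * as.numeric(cov_bp[match(by_sf$superfamily, names(cov_bp))]) /
        genome_bp, 2)
  }

  counts <- table(cl$superfamily)
  list(
    by_superfamily = by_sf,
    by_lineage = by_lin,
    shares = superfamily_shares(stats::setNames(as.integer(counts),
                                                names(counts))),
    totals = data.frame(
      n_elements = nrow(cl),
      n_groups = if (is.null(fam_of)) NA_integer_ else
        length(unique(fam_of)),
      n_copies = if (!is.null(copies)) sum(copies$complete) else NA_integer_,
      ltr_identity_mean_pct = round(100 * mean(cl$ltr_identity), 2)
    )
  )
}

#' Run the full annotation pipeline
#'
#' detect -> classify -> lineage phylogeny -> family clustering -> copy
#' scan and density tracks -> insertion dating -> (optional) expression.
#' Every stage's table is written as TSV under `out_dir`; all randomness
#' flows from stage seeds derived from `config$seed`.
#'
#' @param genome named character vector of scaffolds or FASTA path.
#' @param config list: detector params (`params`), domain library
#'   (`domain_lib`), thresholds (`min_id`, `min_cov`), window/step,
#'   substitution rate `r`, `seed`, gene intervals (`genes`), optional
#'   tissue reads (`tissue_reads`).
#' @param out_dir output directory (NULL = no files written).
#' @return list with every stage's outputs.
#' @export
run_ltr_pipeline <- function(genome, config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(
    params = ltr_params(), domain_lib = make_domain_library(),
    min_id = 0.70, min_cov = 0.70, window = 1e6, step = 5e5,
    r = 1.3e-8, seed = 1, genes = NULL, tissue_reads = NULL,
    e_cutoff = 1e-4, min_rt_residues = 150
  ), config)
  looks_like_path <- is.character(genome) && length(genome) == 1 &&
    is.null(names(genome)) && !grepl("^[ACGTUNRYSWKMBDHVacgtn]+$", genome)
  if (looks_like_path) {
    if (!file.exists(genome)) stop("genome path does not exist: ", genome)
    genome <- read_genome_fasta(genome)
  }

  det <- detect_ltr(genome, cfg$params)
  elements <- det$elements
  seqs <- element_sequences(genome, elements)

  cls <- classify_elements(elements, seqs, cfg$domain_lib, cfg$e_cutoff)
  classified <- cls$classified

  # lineage refinement by RT phylogeny
  rts <- list()
  for (id in classified$element_id) {
    h <- cls$hits[cls$hits$element_id == id, , drop = FALSE]
    aa <- extract_rt(seqs[[id]], h, cfg$min_rt_residues)
    if (!is.na(aa)) rts[[id]] <- aa
  }
  lineages <- NULL
  if (length(rts)) {
    lin <- assign_lineages(unlist(rts), reference_rts(cfg$domain_lib))
    lineages <- lin$assignments
    idx <- match(lineages$element_id, classified$element_id)
    refined <- lineages$lineage
    keep <- refined != "undefined"
    classified$lineage[idx[keep]] <- refined[keep]
  }

  families <- if (nrow(classified))
    build_families(seqs, classified, cfg$min_id, cfg$min_cov) else NULL

  copies <- NULL; density <- NULL
  if (!is.null(families) && nrow(families)) {
    refs <- seqs[families$member[families$is_reference]]
    ref_sf <- stats::setNames(
      classified$superfamily[match(names(refs), classified$element_id)],
      names(refs))
    copies <- find_copies(genome, refs, ref_sf, cfg$min_id, cfg$min_cov)
    hits <- data.frame(scaffold = copies$scaffold, start = copies$start,
                       track = copies$superfamily)
    density <- window_density(hits[copies$complete, ], cfg$genes,
                              stats::setNames(nchar(genome), names(genome)),
                              cfg$window, cfg$step)
  }

  dating <- if (nrow(classified)) {
    d <- date_elements(classified, genome, cfg$r)
    d$superfamily <- classified$superfamily[match(d$element_id,
                                                  classified$element_id)]
    d
  } else NULL

  expr <- NULL
  if (!is.null(cfg$tissue_reads) && length(seqs)) {
    cm <- count_matrix(cfg$tissue_reads, seqs)
    factors <- tmm_normalize(cm$counts + 0L, ref_column = NULL)
    norm <- cpm_normalized(cm$counts, cm$lib_sizes, factors)
    classes <- stats::setNames(classified$superfamily,
                               classified$element_id)
    shares <- expression_shares(norm, classes)
    expr <- list(counts = cm$counts, lib_sizes = cm$lib_sizes,
                 unassigned = cm$unassigned, factors = factors,
                 norm = norm, shares = shares)
  }

  summary <- if (nrow(classified))
    summarize_collection(classified, families, copies,
                         sum(nchar(genome))) else NULL

  out <- list(elements = elements, rejections = det$rejections,
              classified = classified, hits = cls$hits,
              lineages = lineages, families = families, copies = copies,
              density = density, dating = dating, expression = expr,
              summary = summary, element_seqs = seqs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_file(elements, file.path(out_dir, "elements.tsv"))
    write_tsv_file(classified, file.path(out_dir, "classified.tsv"))
    if (!is.null(families))
      write_tsv_file(families, file.path(out_dir, "families.tsv"))
    if (!is.null(copies))
      write_tsv_file(copies, file.path(out_dir, "copies.tsv"))
    if (!is.null(density))
      write_tsv_file(density, file.path(out_dir, "density.tsv"))
    if (!is.null(dating))
      write_tsv_file(dating, file.path(out_dir, "dating.tsv"))
    if (!is.null(expr)) {
      write_tsv_file(as.data.frame(expr$counts),
                     file.path(out_dir, "counts.tsv"))
      write_tsv_file(as.data.frame(expr$norm),
                     file.path(out_dir, "normalized.tsv"))
    }
    write_elements_gff3(classified, file.path(out_dir, "elements.gff3"))
  }
  out
}
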