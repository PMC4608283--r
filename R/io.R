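# Writers for the standard interchange formats the pipeline emits:
# FASTA (via Biostrings), GFF3 (1-based inclusive, element + LTR child
# features), BED (0-based half-open) and FASTQ (Sanger qualities).

#' Write a genome to FASTA (60-column wrap)
#' @param genome named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector (names truncated at first whitespace).
#' @export
read_genome_fasta <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("unreadable FASTA '", path, "': ",
                                         conditionMessage(e)))
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

gff3_escape <- function(x) gsub("[;=,\t]", "_", x)

#' Write detected or planted elements to GFF3
#'
#' One `LTR_retrotransposon` feature per element with two `long_terminal_repeat`
#' children; attributes carry ltr_identity, tsd, pbs and ppt evidence where
#' present.
#'
#' @param elements data.frame with scaffold, start, end, ltr coordinates
#'   and optional annotation columns.
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_elements_gff3 <- function(elements, path, source = "ltrscan") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    attrs <- sprintf("ID=%s", e$element_id)
    for (f in c("ltr_identity", "tsd", "superfamily", "lineage", "k_true",
                "pbs_trna", "ppt_purine", "family_id")) {
      if (!is.null(e[[f]]) && !is.na(e[[f]]))
        attrs <- paste0(attrs, ";", f, "=", gff3_escape(as.character(e[[f]])))
    }
    writeLines(sprintf("%s\t%s\tLTR_retrotransposon\t%d\t%d\t.\t+\t.\t%s",
                       e$scaffold, source, e$start, e$end, attrs), con)
    writeLines(sprintf("%s\t%s\tlong_terminal_repeat\t%d\t%d\t.\t+\t.\tParent=%s",
                       e$scaffold, source, e$ltr5_start, e$ltr5_end,
                       e$element_id), con)
    writeLines(sprintf("%s\t%s\tlong_terminal_repeat\t%d\t%d\t.\t+\t.\tParent=%s",
                       e$scaffold, source, e$ltr3_start, e$ltr3_end,
                       e$element_id), con)
  }
  invisible(path)
}

#' Write gene intervals to BED (0-based half-open)
#' @param genes data.frame with scaffold, start, end (1-based inclusive).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  lines <- sprintf("%s\t%d\t%d\tgene_%04d", genes$scaffold,
                   genes$start - 1L, genes$end, seq_len(nrow(genes)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED file.
#' @return data.frame with scaffold, start, end (1-based inclusive).
#' @export
read_genes_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(scaffold = df[[1]], start = df[[2]] + 1L, end = df[[3]],
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#' @param reads data.frame with id, seq, qual.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)
  writeLines(as.vector(lines), path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file.
#' @return data.frame with id, seq, qual.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) %% 4 == 0)
  data.frame(id = sub("^@", "", lines[c(TRUE, FALSE, FALSE, FALSE)]),
             seq = lines[c(FALSE, TRUE, FALSE, FALSE)],
             qual = lines[c(FALSE, FALSE, FALSE, TRUE)],
             stringsAsFactors = FALSE)
}
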