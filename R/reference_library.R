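# Bundled synthetic reference libraries: labeled retroelement protein
# domains (GAG/PR/INT/RT/RH per superfamily and lineage) and tRNA 3' ends
# for primer-binding-site search.  Both are generated deterministically in
# code; a FASTA copy of the domain library lives under inst/extdata/.  The
# real GyDB domain library is a drop-in replacement (same header format).

COPIA_LINEAGES <- c("Tork", "Retrofit", "Oryco", "Sire")
GYPSY_LINEAGES <- c("Athila", "Tat", "CRM", "Del", "Galadriel", "Reina")
DOMAIN_KINDS <- c("GAG", "PR", "INT", "RT", "RH")

# Internal domain order within each superfamily: Copia integrase sits
# upstream of RT; Gypsy integrase downstream of RNaseH.
DOMAIN_ORDER <- list(
  Copia = c("GAG", "PR", "INT", "RT", "RH"),
  Gypsy = c("GAG", "PR", "RT", "RH", "INT")
)

DOMAIN_AA_LENGTH <- c(GAG = 160, PR = 110, INT = 180, RT = 230, RH = 130)

random_aa <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

#' Synthetic labeled protein-domain reference library
#'
#' One entry per (superfamily, lineage, domain kind).  Within a superfamily,
#' lineage variants of a kind derive from a shared superfamily base sequence
#' (25 % amino-acid divergence per lineage), so that reverse-transcriptase
#' phylogeny recovers superfamily-level and lineage-level clades; kinds and
#' superfamilies are mutually unrelated.  Deterministic (fixed internal
#' seed); this is a synthetic stand-in with the same shape and header
#' convention as a curated retroelement domain database.
#'
#' @return data.frame with columns id, kind, superfamily, lineage, seq.
#' @export
make_domain_library <- function() {
  with_seed(760301, {
    rows <- list()
    for (sf in c("Copia", "Gypsy")) {
      lineages <- if (sf == "Copia") COPIA_LINEAGES else GYPSY_LINEAGES
      base <- lapply(DOMAIN_AA_LENGTH, random_aa)
      for (lin in lineages) {
        for (kind in DOMAIN_KINDS) {
          seq <- mutate_aa(base[[kind]], 0.25)
          rows[[length(rows) + 1L]] <- data.frame(
            id = paste(sf, lin, kind, sep = "_"),
            kind = kind, superfamily = sf, lineage = lin,
            seq = seq, stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Synthetic tRNA 3'-end library for PBS search
#'
#' 18-nt 3'-terminal fragments; the primer-binding site of a planted element
#' is the reverse complement of one of these.
#'
#' @return named character vector.
#' @export
trna_3prime_library <- function() {
  c(
    "tRNA-Met" = "TGGTTCGAGTCCGAGTCG",
    "tRNA-Lys" = "TGGCGCCCAACGTGGGGC",
    "tRNA-Trp" = "TGGTAGCTCAGTTGGTAG",
    "tRNA-Ile" = "TGGCCCGTTAGCTCAGTT"
  )
}

#' Write a domain library to FASTA
#'
#' Headers follow `>id|kind|superfamily|lineage`.
#'
#' @param lib data.frame as returned by [make_domain_library()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_domain_library <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(lib))) {
    writeLines(sprintf(">%s|%s|%s|%s", lib$id[i], lib$kind[i],
                       lib$superfamily[i], lib$lineage[i]), con)
    writeLines(lib$seq[i], con)
  }
  invisible(path)
}

#' Read a labeled domain library from FASTA
#'
#' @param path FASTA with `>id|kind|superfamily|lineage` headers.
#' @return data.frame with columns id, kind, superfamily, lineage, seq.
#' @export
read_domain_library <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 4L
  if (any(bad)) stop("malformed domain library header: ", names(aa)[bad][1])
  data.frame(
    id = vapply(parts, `[`, "", 1L),
    kind = vapply(parts, `[`, "", 2L),
    superfamily = vapply(parts, `[`, "", 3L),
    lineage = vapply(parts, `[`, "", 4L),
    seq = as.character(aa), stringsAsFactors = FALSE
  )
}

# First codon (alphabetical) per amino acid, for deterministic
# codon-aware reverse translation of planted domains.
codon_table_first <- function() {
  gc <- Biostrings::GENETIC_CODE
  split_codons <- split(names(gc), unname(gc))
  vapply(split_codons, function(x) sort(x)[1], "")
}

# Reverse-translate an AA string deterministically.
reverse_translate <- function(aa) {
  tab <- codon_table_first()
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(tab[ch], collapse = "")
}
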