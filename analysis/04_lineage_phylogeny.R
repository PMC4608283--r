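#!/usr/bin/env Rscript
# Stage 4: reverse-transcriptase phylogeny.  Extract RT amino-acid
# domains (minimum 150 residues), build a neighbor-joining tree jointly
# with the labeled reference RTs, and assign each element to a lineage
# from its smallest single-lineage reference clade.

library(ltrscan)

out <- "results/synthetic"
genome <- read_genome_fasta(file.path(out, "genome.fa"))
cls <- utils::read.table(file.path(out, "classified.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
hits <- utils::read.table(file.path(out, "domain_hits.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
lib <- read_domain_library(file.path(out, "domain_library.faa"))
seqs <- element_sequences(genome, cls)

rts <- list()
for (id in cls$element_id) {
  h <- hits[hits$element_id == id, , drop = FALSE]
  aa <- extract_rt(seqs[[id]], h)
  if (!is.na(aa)) rts[[id]] <- aa
}
message(length(rts), " elements carry an RT of >= 150 residues")

lin <- assign_lineages(unlist(rts), reference_rts(lib))
writeLines(lin$tree, file.path(out, "rt_nj_tree.nwk"))
write_tsv_file(lin$assignments, file.path(out, "lineage_assignments.tsv"))
message("lineage counts: ",
        paste(names(table(lin$assignments$lineage)),
              table(lin$assignments$lineage), sep = ":", collapse = " "))
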