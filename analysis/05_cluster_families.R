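#!/usr/bin/env Rscript
# Stage 5: cluster the detected collection into families under the
# 70 %-identity / 70 %-coverage rule and select per-family reference
# elements (longest member among those within two points of the best
# LTR-pair identity).

library(ltrscan)

out <- "results/synthetic"
genome <- read_genome_fasta(file.path(out, "genome.fa"))
cls <- utils::read.table(file.path(out, "classified.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
seqs <- element_sequences(genome, cls)

message("clustering ", length(seqs), " elements (70/70 rule) ...")
fams <- build_families(seqs, cls)
write_tsv_file(fams, file.path(out, "families.tsv"))

refs <- seqs[fams$member[fams$is_reference]]
Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs),
                            file.path(out, "family_references.fa"),
                            width = 60)

sizes <- table(table(fams$family))
message(length(unique(fams$family)), " families; size distribution: ",
        paste(names(sizes), sizes, sep = "x", collapse = ", "))

f80 <- cluster_families(seqs, 0.80, 0.80)
message("at the stricter 80/80 rule: ", length(unique(f80$family)),
        " families (never fewer than at 70/70)")
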