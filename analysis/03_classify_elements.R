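#!/usr/bin/env Rscript
# Stage 3: protein-domain annotation and superfamily classification
# (RLC / RLG / RXX-NA) of the detected elements, plus the domain census.

library(ltrscan)

out <- "results/synthetic"
genome <- read_genome_fasta(file.path(out, "genome.fa"))
det <- utils::read.table(file.path(out, "detected_elements.tsv"),
                         header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
seqs <- element_sequences(genome, det)
lib <- read_domain_library(file.path(out, "domain_library.faa"))

message("scanning domains and classifying ", nrow(det), " elements ...")
cls <- classify_elements(det, seqs, lib)
write_tsv_file(cls$classified, file.path(out, "classified.tsv"))
write_tsv_file(cls$hits, file.path(out, "domain_hits.tsv"))

census <- summarize_domain_census(cls$classified, cls$hits)
write_tsv_file(census$by_n_domains, file.path(out, "domain_census.tsv"))

tab <- table(cls$classified$superfamily)
sh <- superfamily_shares(stats::setNames(as.integer(tab), names(tab)))
write_tsv_file(sh, file.path(out, "superfamily_shares.tsv"))
message(paste(sprintf("%s: %d (%.1f %%)", sh$superfamily, sh$count, sh$pct),
              collapse = "; "))
message(sprintf("four-or-five-domain share among RLC+RLG: %.1f %%",
                census$shares$four_or_five_pct))
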