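#!/usr/bin/env Rscript
# Stage 2: structural detection of full-length LTR retrotransposons from
# the genome FASTA alone (no ground truth consulted), then a recovery
# report against the planted truth.

library(ltrscan)

out <- "results/synthetic"
genome <- read_genome_fasta(file.path(out, "genome.fa"))

message("detecting LTR retrotransposons ...")
det <- detect_ltr(genome)
write_tsv_file(det$elements, file.path(out, "detected_elements.tsv"))
write_tsv_file(det$rejections, file.path(out, "rejections.tsv"))
write_elements_gff3(det$elements, file.path(out, "detected_elements.gff3"))
fa <- Biostrings::DNAStringSet(element_sequences(genome, det$elements))
Biostrings::writeXStringSet(fa, file.path(out, "detected_element_seqs.fa"),
                            width = 60)

truth <- utils::read.table(file.path(out, "truth_elements.tsv"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
hit5 <- 0L
for (i in seq_len(nrow(det$elements))) {
  d <- det$elements[i, ]
  j <- which(truth$scaffold == d$scaffold & abs(truth$start - d$start) <= 5 &
               abs(truth$end - d$end) <= 5)
  if (length(j) == 1) hit5 <- hit5 + 1L
}
message(sprintf(
  "detected %d elements; %d/%d planted elements recovered with both
boundaries within 5 bp; mean LTR identity %.1f %%",
  nrow(det$elements), hit5, nrow(truth),
  100 * mean(det$elements$ltr_identity)))
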