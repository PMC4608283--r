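#!/usr/bin/env Rscript
# Stage 1: build the synthetic study genome -- ~3 Mb over three scaffolds
# with 30 planted full-length LTR retrotransposons (12 Copia, 8 Gypsy,
# 10 non-autonomous), gene intervals on a steep density gradient, strong
# Copia avoidance of gene-rich regions, and eight tissue read sets with
# planted expression levels.  Everything downstream is validated against
# the ground truth written here.

library(ltrscan)

seed <- 101
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("simulating study genome (seed ", seed, ") ...")
sim <- simulate_study_genome(seed = seed)

write_genome_fasta(sim$genome, file.path(out, "genome.fa"))
write_elements_gff3(sim$elements, file.path(out, "truth.gff3"),
                    source = "ltrscan_truth")
write_genes_bed(sim$genes, file.path(out, "genes.bed"))
write_tsv_file(sim$elements, file.path(out, "truth_elements.tsv"))
write_tsv_file(sim$genes, file.path(out, "truth_genes.tsv"))
fa <- Biostrings::DNAStringSet(sim$element_seqs)
Biostrings::writeXStringSet(fa, file.path(out, "truth_element_seqs.fa"),
                            width = 60)
write_domain_library(sim$domain_lib, file.path(out, "domain_library.faa"))

message("simulating eight tissue read sets ...")
rd <- simulate_tissue_reads(sim, seed = seed)
dir.create(file.path(out, "reads"), showWarnings = FALSE)
for (t in names(rd$tissues))
  write_fastq(rd$tissues[[t]], file.path(out, "reads", paste0(t, ".fastq")))
write_tsv_file(as.data.frame(rd$truth_counts),
               file.path(out, "truth_read_counts.tsv"))

message(sprintf(
  "genome: %d bp over %d scaffolds; %d elements (%s); %d genes; %d tissues",
  sum(nchar(sim$genome)), length(sim$genome), nrow(sim$elements),
  paste(names(table(sim$elements$superfamily)),
        table(sim$elements$superfamily), collapse = " ", sep = ":"),
  nrow(sim$genes), length(rd$tissues)))
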