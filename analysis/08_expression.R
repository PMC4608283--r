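#!/usr/bin/env Rscript
# Stage 8: expression profiling.  Assign the eight tissue read sets to
# the element library, normalize counts by trimmed mean of M-values, and
# compute class and tissue shares of overall element expression.

library(ltrscan)

out <- "results/synthetic"
cls <- utils::read.table(file.path(out, "classified.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
genome <- read_genome_fasta(file.path(out, "genome.fa"))
seqs <- element_sequences(genome, cls)

fq <- list.files(file.path(out, "reads"), full.names = TRUE)
tissues <- lapply(fq, read_fastq)
names(tissues) <- sub("\\.fastq$", "", basename(fq))

message("assigning reads from ", length(tissues), " tissues ...")
cm <- count_matrix(tissues, seqs)
write_tsv_file(as.data.frame(cm$counts), file.path(out, "read_counts.tsv"))
factors <- tmm_normalize(cm$counts)
norm <- cpm_normalized(cm$counts, cm$lib_sizes, factors)
write_tsv_file(as.data.frame(round(norm, 3)),
               file.path(out, "normalized_cpm.tsv"))

classes <- stats::setNames(cls$superfamily, cls$element_id)
classes[classes == "RXX-NA"] <- "NA"
classes[classes == "RLC"] <- "Copia"
classes[classes == "RLG"] <- "Gypsy"
sh <- expression_shares(norm, classes)
write_tsv_file(sh$by_class, file.path(out, "expression_class_shares.tsv"))
write_tsv_file(sh$by_tissue, file.path(out, "expression_tissue_shares.tsv"))

message(length(sh$expressed), " elements expressed (> 1 CPM in >= 1 tissue)")
message("class shares: ",
        paste(sh$by_class$class, sprintf("%.1f%%", sh$by_class$pct),
              collapse = "; "))
top <- sh$by_tissue[order(-sh$by_tissue$pct), ][1, ]
message(sprintf("highest tissue share: %s (%.1f %%)", top$tissue, top$pct))
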