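#!/usr/bin/env Rscript
# Stage 6: genomic copy counting against the family references, repeat
# masking, sliding-window density tracks and the Copia-vs-gene density
# correlation.

library(ltrscan)

out <- "results/synthetic"
genome <- read_genome_fasta(file.path(out, "genome.fa"))
cls <- utils::read.table(file.path(out, "classified.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
fams <- utils::read.table(file.path(out, "families.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
genes <- read_genes_bed(file.path(out, "genes.bed"))
seqs <- element_sequences(genome, cls)

refs <- seqs[fams$member[fams$is_reference]]
ref_sf <- stats::setNames(
  cls$superfamily[match(names(refs), cls$element_id)], names(refs))

message("scanning for copies of ", length(refs), " references ...")
copies <- find_copies(genome, refs, ref_sf)
write_tsv_file(copies, file.path(out, "copies.tsv"))
cc <- copies[copies$complete, ]
cov <- tapply(cc$end - cc$start + 1, cc$superfamily, sum) /
  sum(nchar(genome)) * 100
message(sum(copies$complete), " complete copies (",
        paste(names(table(cc$superfamily)), table(cc$superfamily),
              sep = ":", collapse = " "), "); coverage ",
        paste(names(cov), sprintf("%.2f%%", cov), collapse = " "))

message("masking the genome against the reference library ...")
mk <- mask_genome(genome, refs)
write_tsv_file(mk$stats, file.path(out, "masking_stats.tsv"))
message(sprintf("masked %.2f %% of all bases (%.2f %% of non-N bases)",
                100 * mk$stats$frac_all, 100 * mk$stats$frac_non_n))

# density tracks: windows scaled to the 3 Mb genome (150 kb / 75 kb)
hits <- data.frame(scaffold = cc$scaffold, start = cc$start,
                   track = cc$superfamily)
wd <- window_density(hits, genes,
                     stats::setNames(nchar(genome), names(genome)),
                     window = 1.5e5, step = 7.5e4)
write_tsv_file(wd, file.path(out, "window_density.tsv"))

key <- paste(wd$scaffold, wd$win_start)
tr_of <- function(t) wd$density_per_mb[wd$track == t][
  order(key[wd$track == t])]
ct <- density_correlation(tr_of("RLC"), tr_of("gene"))
message(sprintf("Copia vs gene density: r = %.2f, p = %.2g (n = %d windows)",
                ct$r, ct$p_value, ct$n))
ct_g <- density_correlation(tr_of("RLG"), tr_of("gene"))
message(sprintf("Gypsy vs gene density: r = %.2f, p = %.2g",
                ct_g$r, ct_g$p_value))
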