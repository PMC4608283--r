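#!/usr/bin/env Rscript
# Stage 9: the collection summary table (per superfamily/lineage group
# and element counts, LTR statistics, copies, coverage) and the
# published-count arithmetic cross-checks.

library(ltrscan)

out <- "results/synthetic"
cls <- utils::read.table(file.path(out, "classified.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
fams <- utils::read.table(file.path(out, "families.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
copies <- utils::read.table(file.path(out, "copies.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
genome <- read_genome_fasta(file.path(out, "genome.fa"))

s <- summarize_collection(cls, fams, copies, sum(nchar(genome)))
write_tsv_file(s$by_superfamily, file.path(out, "summary_superfamily.tsv"))
write_tsv_file(s$by_lineage, file.path(out, "summary_lineage.tsv"))
write_tsv_file(s$shares, file.path(out, "summary_shares.tsv"))
write_tsv_file(s$totals, file.path(out, "summary_totals.tsv"))
print(s$by_superfamily)
print(s$totals)

# published-count arithmetic (the in-collection worked examples)
sh <- superfamily_shares(c(RLC = 241, RLG = 151, `RXX-NA` = 191))
message("published counts 241/151/191 give shares: ",
        paste(sh$superfamily, sprintf("%.1f%%", sh$pct), collapse = "; "))
dc <- domain_census_shares(108, 215, 392)
message(sprintf(
  "domain census: four-or-five-domain %.1f %%; five-domain %d %% (nearest)",
  dc$four_or_five_pct, dc$five_pct_nearest))
message(sprintf("mapped-copy share 5703/10554 = %.1f %%",
                mapped_share(5703, 10554)))
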