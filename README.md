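# ltrscan

Genome-wide annotation of **full-length LTR retrotransposons**: structural
detection, Copia/Gypsy classification, lineage phylogeny, family
clustering, copy counting and chromosomal density, insertion dating, and
expression profiling — built as a tested R package with a synthetic-genome
validation harness.

LTR retrotransposons dominate plant genomes, and a full-length element is
recognizable from structure alone: two highly similar long terminal
repeats (LTRs), a 4–6 bp target-site duplication (TSD) flanking the
insertion, and primer-binding-site (PBS) / polypurine-tract (PPT) signals
just inside the LTRs. Because both LTRs are identical at insertion, their
divergence dates the element: with transition and transversion fractions
P and Q over the aligned pair,

```
K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)        (Kimura two-parameter)
T = K / (2r),   r = 1.3e-8 substitutions/site/year
```

Elements are classified RLC (Copia) / RLG (Gypsy) from their internal
GAG–PR–INT–RT–RH domains (integrase upstream of RT ⇒ Copia, downstream of
RNaseH ⇒ Gypsy), RXX-NA when no RT/INT/RH is found; lineages come from a
neighbor-joining tree of reverse-transcriptase domains against labeled
references. Families follow the 70/70 rule (≥ 70 % identity over ≥ 70 %
of the shorter sequence), and a copy of a family reference is *complete*
at ≥ 70 % coverage and ≥ 70 % identity. Expression uses k-mer read
assignment with fractional multi-mapping and trimmed-mean-of-M-values
(TMM) normalization.

All heavy lifting validated against planted ground truth: the package
ships a simulator (`simulate_study_genome()`) that builds a ~3 Mb genome
with 30 elements of known coordinates, superfamily, lineage, family and
LTR divergence, plus gene tracks and eight tissue read sets.

## Worked example

```r
library(ltrscan)
sim <- simulate_study_genome(seed = 101)   # 3 scaffolds, 30 planted elements
det <- detect_ltr(sim$genome)
nrow(det$elements)                         # 30 -- all planted elements found
seqs <- element_sequences(sim$genome, det$elements)
cls <- classify_elements(det$elements, seqs)
table(cls$classified$superfamily)          # RLC 12, RLG 8, RXX-NA 10
dat <- date_elements(cls$classified, sim$genome)
summary(dat$K)                             # K 0.029-0.131 => 1.1-5.0 Myr
```

The numbered drivers under `analysis/` run the same study end to end and
write every stage's tables under `results/synthetic/`. Output from a full
run (seed 101):

```
detected 30 elements; 30/30 planted elements recovered with both
boundaries within 5 bp; mean LTR identity 93.4 %
RLC: 12 (40.0 %); RLG: 8 (26.7 %); RXX-NA: 10 (33.3 %)
24 families; size distribution: 1x20, 2x2, 3x2
30 complete copies (RLC:12 RLG:8 RXX-NA:10); coverage RLC 2.27% RLG 1.52%
Copia vs gene density: r = -0.44, p = 0.0025 (n = 45 windows)
Gypsy vs gene density: r = -0.05, p = 0.76
planted-K strata recovery: K* = 0.04/0.07/0.10 recovered with
  3.2 % / 3.8 % / 1.8 % relative error
22 elements expressed; class shares: NA 59.0%, Copia 21.3%, Gypsy 19.7%
highest tissue share: shoot_apex (18.8 %)
```

The planted conditions behind those numbers: superfamily mix 12/8/10,
Copia placed to avoid gene-rich regions (hence the negative correlation,
while Gypsy is uniform), expression planted at 60/20/20 class shares with
the shoot apex the most active tissue. Detection, classification,
clustering, dating and quantification recover all of it from sequence
alone.

Methodological details — parameter defaults and their rationale, the
mutation models, what the simulator does and does not emulate, numerical
tolerances — are in `vignettes/ltr-annotation-methods.Rmd`.

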