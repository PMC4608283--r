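---
title: "Methods: structural annotation, classification and dating of full-length LTR retrotransposons"
author: "ltrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural annotation, classification and dating of full-length LTR retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ltrscan` re-implements, as a tested pipeline, a genome-wide analysis of
full-length LTR retrotransposons: structural detection, superfamily and
lineage classification, family clustering, copy counting and chromosomal
density, insertion-time dating from LTR divergence, and per-element
expression profiling across tissues.  Because the full analysis was
originally run on a ~1.5 Gb palm genome assembly that is out of reach at
desk scale, every stage here is validated instead on synthetic genomes
with planted elements and complete ground truth; the generator is a
first-class, tested module, not a fixture.

# Structural detection

A full-length LTR retrotransposon is detected from structure alone,
regardless of transcriptional or transpositional competence: a repeat
element (i) delimited by highly similar 5' and 3' LTRs, (ii) flanked by a
target-site duplication (TSD), and (iii) carrying primer-binding-site
(PBS) and polypurine-tract (PPT) signals just inside the LTRs.  Predicted
elements longer than 12 kb are discarded.

The mechanism is seed-and-extend.  Exact k-mer matches (default k = 14)
on the forward/forward diagonal are paired within an admissible spacing
window, chained by diagonal (band 15 bp, maximum seed gap 400 bp), and
extended outward by X-drop scoring (match +1, mismatch −2, drop 15).  The
extension takes the *furthest* position attaining the maximal running
score, so neutral stretches at a repeat boundary are crossed rather than
truncated.  LTRs are direct repeats, so only the forward strand is
scanned; element orientation is inferred later from domain frames.

Validation applies, in order: the 12 kb length cap; the LTR-pair
identity threshold (default 0.80 — the collection's mean LTR identity is
expected near 90 %, but detection must reach older pairs); an N filter
(seeds never span N; candidates with > 10 % N in either LTR are
rejected); and the TSD requirement.  The TSD is an exact 4–6 bp flank
duplication; boundaries are snapped within ±6 bp, the candidate needing
the smallest total boundary adjustment winning, remaining ties going to
the longest TSD.  Two points deserve emphasis:

* **PBS and PPT are scored, not required.**  The published structural
  definition lists them, but the diversity of the reported collection
  (including TR-GAG-like non-autonomous elements) implies a permissive
  detector; a `strict` flag makes all three criteria mandatory.  PBS
  evidence is the best match, within 20 bp of the 5' LTR, against the
  reverse complement of a bundled tRNA 3'-end library (≥ 12 of 18 bases);
  PPT evidence is a ≥ 80 % purine 15-mer window ending within 20 bp of
  the 3' LTR.
* **Boundary precision is limited by chance flank homology.**  When the
  base just outside a perfect repeat happens to match, the true boundary
  is not identifiable; detected boundaries are therefore exact only up to
  ±1 bp even on noise-free repeats, and the recovery criterion (±5 bp) is
  set accordingly.

Overlapping accepted elements are resolved greedily by descending
(identity, length).  Identity is computed by full global alignment of the
two LTRs (matches over alignment columns).  On 1 Mb of i.i.d. random
sequence the detector accepts nothing, across seeds.

# Domain annotation and superfamily classification

Each element is translated in all six frames (stops as `*`, fuzzy codons
as `X`) and scanned by local amino-acid alignment (BLOSUM62, gap open 10,
extend 1) against a labeled GAG/PR/INT/RT/RH library.  E-values follow
the Karlin–Altschul extreme-value form `E = K·m·n·exp(−λS)` with
λ = 0.267, K = 0.041 (gapped BLOSUM62 constants) and database size n
equal to the library residue count; the cutoff is 1e-4.  An exact
shared-6-mer prefilter skips frame/reference pairs that cannot reach the
cutoff — the same word-seeding idea the original BLASTX search relies
on — leaving the hit set unchanged.

Frameshift-aware (Genewise-style) alignment is deliberately **not**
re-implemented: same-kind hits in different frames within 300 bp are
merged into one census entry, which is sufficient because classification
consumes only domain presence and order.  The rule: an element with none
of RT/INT/RH is RXX-NA (GAG alone or GAG+PR allowed — the candidate
TR-GAG class); otherwise the superfamily is the majority label of the
retained RT/INT/RH references, ties broken by domain order (integrase
upstream of RT ⇒ Copia/RLC; downstream of RNaseH ⇒ Gypsy/RLG).

The bundled domain library is synthetic, generated deterministically in
code (`make_domain_library()`): per superfamily, lineage variants of each
domain derive from a shared base at 25 % amino-acid divergence, so
lineage-level clades exist for the phylogeny stage.  A curated library
(e.g. GyDB) is a drop-in replacement via the same
`>id|kind|superfamily|lineage` header convention.

# RT phylogeny and lineage assignment

RT amino-acid sequences of at least 150 residues are extracted from the
best RT hit in its own frame.  Distances are pairwise global alignments
(BLOSUM62), p-distance over shared non-gap columns, Poisson-corrected
d = −ln(1 − p) (toggleable to raw p).  Pairwise distances replace a
progressive multiple alignment: only tree topology near labeled
references is consumed, and this removes a heavy dependency.

Neighbor joining is the canonical agglomeration: join the pair minimizing
the Q-criterion, branch lengths from the standard formulas, negative
branch lengths clamped to zero with the deficit shifted to the sister
branch, ties broken lexicographically by the smallest taxon id per
subtree — making output invariant to input order.  On additive matrices
the implementation reproduces all path distances to 1e-9.

An element takes the lineage of the smallest tree split side containing
it and at least one reference, provided those references carry exactly
one lineage; otherwise it is `undefined`.  Support is the distance to the
nearest reference.

# Family clustering

Elements are deemed related at ≥ 70 % nucleotide identity over ≥ 70 %
coverage — the published relaxation of the canonical 80/80 rule, which
found no related elements in the original collection.  Coverage is
measured against the **shorter** sequence (the CD-HIT convention; the
source text does not specify the denominator, so this is a documented,
configurable choice).  Clustering is greedy and longest-first: each
element joins the first existing family whose founder it matches, else
founds a family.  A word-seeded prescreen (shared 11-mers on a consistent
diagonal covering ≥ 0.6 × the coverage threshold of the shorter
sequence) skips alignments that cannot match; at the 70 % identity floor
the expected seed density is far above the prescreen's requirement, and a
dedicated test confirms the prescreen never changes a verdict.

Per family, the reference is the longest member among those within two
percentage points of the family's best LTR-pair identity — "two points"
quantifies the qualitative "high identity" wording of the source
procedure and is flagged as interpretation.

# Copy counting, masking, densities

Family references are searched on both strands by k-mer seeding (k = 13)
and chaining; each chained region is aligned locally against the
corresponding reference stretch, and a copy is *complete* iff it covers
≥ 70 % of the reference at ≥ 70 % identity.  Overlapping hits to
different references (sharing > 50 % of the shorter interval) collapse to
the best, because individual copies often cannot be attributed to a
single reference — counting is per superfamily.  Masking lower-cases
genomic segments matching the library at ≥ 80 % identity (the printed
description — "less than 80 % … were masked" — contradicts standard
masking practice and is implemented as ≥ 80 %); statistics are reported
both including and excluding N.

Densities use sliding windows; a hit is counted in every window
containing its start position (the simplest reading of "sequences per
Mb"), terminal windows scaled by actual width.  The defaults are the
published 1 Mbp windows with 500 kbp steps; on the 3 Mb synthetic genome
the analysis uses 150 kb / 75 kb — the proportional scale-down — so the
track has enough windows for a correlation test.  The correlation is
Pearson's product-moment with its two-sided t-test, matching the
parametric R and P reported in the source.

# Insertion dating

Both LTRs of an element are identical at insertion, so their divergence
dates it.  LTR pairs are globally aligned (affine gaps, end gaps
penalized); gapped columns are excluded (the Distmat convention); over
the remaining columns P and Q are the transition and transversion
fractions and

K = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q),    T = K / (2r),

with r = 1.3e-8 substitutions/site/year.  Saturated pairs (either log
argument ≤ 0) are reported as such, not silently dropped.  No molecular
clock beyond T = K/2r is attempted.  Spot values: P = 0.10, Q = 0.05 give
K = 0.17018 and T ≈ 6.545 Myr.

# Expression

Reads are assigned by k-mer seeded (k = 13, three probe offsets per
read) ungapped comparison on both strands; a read goes to its
best-scoring element at ≥ 95 % identity, ties split fractionally among
the tied elements — element families are similar by construction, and
winner-takes-all would bias family references.  Counts are normalized by
trimmed mean of M-values (two-sided trims: 30 % on M, 5 % on A;
inverse-variance weights; factors rescaled to geometric mean one; the
reference column is the median-sized library).  The implementation
follows the published TMM algorithm step by step and is cross-checked in
the tests against an independent step-by-step computation and against the
installed edgeR implementation, to 1e-6.  An element is "expressed" above
1 CPM in at least one tissue — the source states no threshold, so this is
an explicit, configurable default.  Class and tissue shares are
percentages of summed normalized expression over the expressed subset.

# The synthetic study genome

`simulate_study_genome()` fixes the study conditions: three 1 Mb
scaffolds (GC 0.40, 2 % N in runs), 30 planted elements — 12 Copia,
8 Gypsy, 10 non-autonomous, mirroring the reported 41/26/33 % split —
across four Copia and five Gypsy lineages, with LTR lengths 800–1200 bp,
internal regions 2.6–4 kb, and LTR divergence strata K ∈ {0.04, 0.07,
0.10}, ten elements each.  Four families (3+3+2+2 members) exist by
construction; the other twenty elements are singletons, echoing the
mostly-singleton family structure of the reported collection.

Design choices worth recording:

* **TSD default 5 bp** (range 4–6), LTR termini default to the canonical
  TG…CA dinucleotides (toggleable to probe detector robustness).
* **Mutation models.**  Singleton elements mutate the 3' LTR only at the
  spec'd K (equivalent in expectation to symmetric divergence at half the
  rate on each copy); family members are instead derived from a common
  master by symmetric whole-element K2P mutation at K/2 per copy, so each
  member's own LTR pair diverges by K while members stay within the
  70/70 envelope of one another.
* **ts/tv ratio 2.0** — a stated assumption; the source reports no
  empirical transition/transversion ratio for this genome.
* **Insertion sites** are spaced ≥ 25 kb apart (so repeats from distinct
  planted copies never chain within the detector's 13 kb span), outside
  gene bodies, and never where the TSD window would touch an N run — an
  insertion "into" missing sequence has no recoverable TSD even in
  principle.
* **Genes and avoidance.**  Gene intervals (2 kb, 25 per Mb) follow a
  steep exponential density gradient along each scaffold; under
  `copia_avoid`, Copia insertion weights decay exponentially with the
  smoothed local gene density (gene bp within ±50 kb).  This plants the
  negative Copia-vs-gene correlation that the density stage must then
  recover; Gypsy and non-autonomous elements place uniformly.
* **Tissues.**  Eight read sets at 6 000 reads each (100 bp, 0.5 %
  error); element-derived reads are split across tissues by a fixed
  activity profile (shoot apex highest at 18 %, young female flowers
  lowest at 6 %), with planted class shares 60/20/20
  (non-autonomous/Copia/Gypsy) over twelve expressed elements; the
  remainder of each library is background reads drawn from non-element
  genome positions, which the assigner must leave unassigned.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: nested, truncated or fragmented elements; solo
LTRs; indel-rich divergence (all planted divergence is substitutional);
segmental duplications and tandem repeats that stress specificity;
sequencing errors beyond uniform substitutions; paired-end structure;
and real transcriptional noise.  Recovery rates measured here are
ceilings, not forecasts, for real assemblies.

# Problem sizes and numerical choices

Test and validation workloads are sized for a single CPU: detector
recovery and false-positive control run on the 3 Mb genome and on five
1 Mb random sequences; K-strata recovery uses 300 independent 1 kb LTR
pairs per stratum at K ∈ {0.02, 0.05, 0.10, 0.20} (relative errors
observed well under 1 %); the clustering oracle uses fifty 1.2 kb
elements in twenty planted families, with every pair aligned
unconditionally for the exhaustive cross-check; NJ correctness uses fifty
random additive matrices up to eight taxa.  Tolerances: NJ path
distances to 1e-9; TMM factors to 1e-6; K2P spot values to 1e-4; TMM
scaling invariance only to 2 % because the inverse-variance weights
legitimately shift with depth.

# Known limitations

Detection assumes intact direct repeats; heavily diverged (> 20 %) or
truncated elements fall outside the detector's envelope by design.  The
E-value calibration uses fixed gapped-BLOSUM62 constants rather than
per-search estimation, adequate at the 1e-4 cutoff but not for marginal
hits.  The superfamily tie-break needs both integrase and RT/RNaseH
present; elements carrying RT alone classify by reference label majority
only.  Lineage assignment depends on reference coverage of the true
clade — an element from an unrepresented lineage lands in `undefined`
rather than a nearest wrong clade only when the tree keeps it outside
all single-lineage splits.
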