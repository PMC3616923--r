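---
title: "Methods: genetic variation and expression divergence between two varieties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic variation and expression divergence between two varieties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divaria)
```

# Scope and data model

`divaria` compares two closely related plant varieties that share one
reference annotation: variety 1 is the assembled, annotated reference;
variety 2 is described by re-sequencing variant calls (SNPs, small
indels, structural variants) against it. Everything downstream —
premature-stop detection, Ka/Ks, duplication and mobile-element
analysis, expression-divergence classes, promoter and methylation
comparison, and duplication-mode enrichment — runs off four inputs:
a FASTA + GFF3 annotated genome, a variant table, a probe × sample
expression matrix (2 varieties × 3 sucrose time points × 2 replicates),
and small auxiliary tables (IUPAC motifs, bisulfite clones).

All internal coordinates are 0-based half-open; GFF3 and variant
positions (1-based) are converted once at the I/O boundary, and
promoter methylation positions are reported back in the field's 1-based
negative-offset-from-ATG style. Variants are expressed on the forward
strand of the reference, as in VCF practice. Codons containing N
translate to X and are excluded from Ka/Ks site counting.

# Variant application and premature stops

`apply_variants()` rebuilds each chromosome with the variant set
applied and lifts gene models across the resulting coordinate shifts.
Genes wholly contained in a deletion are flagged deleted; a CDS
partially cut by a deletion is clamped to the deletion edge. Structural
*copy-number gains* are flagged (`deleted_or_cnv`, excluding the gene
from substitution analysis) but are not applied to the sequence: the
analysis only ever uses the exclusion flag, and leaving the sequence
untouched preserves the exact closure property the synthetic data rely
on (applying the emitted variants to genome 1 reproduces genome 2).

A *premature stop* is any in-frame stop strictly upstream of the
variety-1 stop position in the translated variety-2 CDS — including
stops induced by frameshifts. A destroyed ATG is reported separately
(`start_lost`), not as a premature stop. Gene-level variant burden uses
gene-span overlap (not CDS overlap), with half-open conventions: a
variant at the gene's end coordinate does not count, and insertions are
points.

# Ka/Ks by Nei–Gojobori counting

Protein sequences are aligned globally (BLOSUM62, affine gaps, opening
10 / extension 0.5) and the alignment is threaded back onto codons, so
gaps occur in whole-codon units. Pairs are accepted when at least 70 %
of the query's codons are aligned (inclusive) and protein identity over
the aligned region reaches an identity floor (default 0.30). The floor
replaces a database-search E-value screen: no search engine is
embedded, and its role — discarding chance pairings of unrelated
proteins — is served by an explicit identity threshold that is exact,
configurable and testable.

Site counting follows the classic NG86 scheme: at each codon position
the synonymous fraction is computed over the single-base changes that
do not create a stop codon, so S + N equals 3 per compared codon.
Observed differences in multi-hit codons are averaged over all minimal
substitution pathways, excluding pathways through stop codons (if every
pathway is blocked, all are counted). Distances are Jukes–Cantor
corrected, `d = -(3/4) ln(1 - (4/3) p)`, with saturation flagged at
p ≥ 3/4. Codon columns containing a gap, an N, or a stop in either
sequence are skipped.

The Ka > Ks test is a one-sided normal test on
(Ka − Ks)/sqrt(var Ka + var Ks) with the large-sample Jukes–Cantor
variances `p(1−p)/(L (1−4p/3)²)`. Two measured properties worth
knowing: under simulated neutral evolution (uniform accepted point
mutations, 60 substitutions over 300 codons) the mean Ka/Ks across 500
pairs sits within [0.9, 1.1] — the ratio's mean exceeds its median
because Ks enters as a noisy denominator — and the test is mildly
anti-conservative (≈6 % rejections at α = 0.05 over 600 neutral pairs),
as expected for a large-sample z approximation. The estimator is
deliberately the self-contained counting method, not a
transition/transversion- or codon-frequency-aware maximum-likelihood
estimator; genome-scale averages from such estimators are approximated,
not reproduced.

# Duplication

All-vs-all protein similarity uses Smith–Waterman local alignment
(BLOSUM62, affine gaps); a hit is retained at ≥70 % identity over the
aligned region covering ≥30 % of the query. A shared-k-mer prefilter
(distinct 4-mers, sparse indicator-matrix crossproduct, default
`min_shared = 8`) keeps the quadratic scan tractable: pairs at the 70 %
retention floor share ≳25 distinct 4-mers while unrelated ~120-aa
proteins share ≲5, and `prefilter = FALSE` forces the exact scan (the
test suite verifies equivalence on mixed families).

Families are the connected components of the qualifying-hit graph —
transitive closure, so A = B and B = C imply one family. Tandem pairs
are same-family, same-chromosome gene pairs separated by at most 10
intervening genes *not in the family* ("unrelated" is read literally;
same-family intervening genes do not count against the budget, which
also means a gene can appear in several pairs of one tandem array).
Segmental duplication is loader-first (`load_segmental_pairs()`), since
curated collinearity resources are the canonical source; the built-in
`find_segmental_blocks()` is a labelled stand-in that chains homologous
gene pairs by dynamic programming — strictly advancing gene ranks on
both chromosomes, same or inverted orientation, per-step rank gap ≤ 25,
≥ 5 anchors, with tandem-array members collapsed to one representative
before chaining.

# Mobile elements

CACTA detection pairs fuzzy occurrences of terminal-inverted-repeat
seeds (mismatch fraction ≤ 0.1, no indels): a forward-sense 5' terminal
with a downstream reverse-complement 3' terminal on the same
chromosome, element length within [200 bp, 30 kb], and an identical
3-bp target-site duplication on both flanks — 3 bp being canonical for
the CACTA superfamily. Pair selection is greedy by total mismatches
(ties: leftmost, then shortest), each terminal used once. The TSD+score
filter deterministically replaces manual artifact inspection.

The LTR scan is a naive direct-repeat finder: exact 20-mer seed matches
in direct orientation 1–15 kb apart, grouped by diagonal, maximally
extended, kept at ≥100 bp and ≥85 % identity with an identical 4–6 bp
TSD. It deliberately omits PBS/PPT detection, nesting resolution and
insertion dating; `load_elements()` ingests a precomputed element GFF3
when a full annotator's output is available. Genes are element-related
when their span overlaps the element span by any amount ("fully or
partially located within").

# Expression divergence

Detection uses a fixed signal threshold (default 25 — half the low-
abundance bin edge) required in *all* replicates of a (variety, time),
a reproducible, monotone stand-in for proprietary array detection
flags; a probe is expressed in a variety when expressed at ≥1 time
point, and per variety the expressed set partitions into normal-only
(0 h), treated-only (2/6 h) and both. Arrays are median-scaled to the
grand median before any call.

The six divergence classes: variety-specific (expressed in exactly one
variety); ≥2-fold (expressed in both, mean 0-h signal ratio ≥ 2,
inclusive); sucrose-regulated in one variety only. Sucrose direction is
up when mean treated / mean 0 h ≥ 2 at ≥1 time point with no time point
showing the opposite call (down symmetric at ≤ 0.5); the 2-fold cut
mirrors the between-variety convention, and the "any time point, no
contradiction" rule is a declared decision since time-point combination
is otherwise unspecified. Whether "expressed in both conditions" should
pool times is equally unspecified; the per-time rule is declared, not
inferred. Abundance bins partition the signal axis at 50/500/5000.
EST-only probes (no gene id) take part in probe-level classes but drop
out of gene-level lists and enrichment.

2^-ΔΔCT confirmation follows the textbook identities
(ΔCT = CT_target − CT_reference per replicate;
ΔΔCT = mean ΔCT_test − mean ΔCT_calibrator), with a two-sample t test
on replicate ΔCT values; zero-variance replicate sets fall back to an
exact 0/1 p by mean difference.

# Promoters and methylation

Two promoter lengths coexist on purpose: 1,500 bp upstream of the start
codon for variation analysis and 1,000 bp for motif work — both in
transcript orientation, truncated and flagged at contig edges, with
promoters overlapping upstream genes kept (no trimming rule exists; a
flag records truncation only). Variation is called by direct comparison
at equal lengths and global alignment otherwise.

Motif scanning matches IUPAC patterns on both strands (a declared
decision) counting overlapping occurrences; a set's motif *frequency*
is its presence fraction, and per-motif set differences use the pooled
two-proportion u statistic with Benjamini–Hochberg FDR across motifs.

Methylation calling aligns bisulfite Sanger clones to the
transcript-strand reference (equal length, ungapped), QC-gating clones
at ≤2 % mismatches over non-cytosine positions. At each reference C, a
clone C is methylated, T unmethylated, anything else ignored; context
(CG/CHG/CHH) comes from the reference. Per-site variety differences use
Fisher's exact test rather than the u statistic because clone counts
are small (≈10 per variety) — exactly the regime where the pooled-z
normal approximation fails (see below).

# The u statistic

`u_test()` implements the pooled two-proportion statistic exactly as
printed in the Methods formula, with one- and two-sided p values (both
are always reported, since the sidedness of the original Z tests is
unstated), a degenerate-pool guard (u = 0, p = 1 when p̄ ∈ {0, 1}), and
BH-FDR across categories in `overrepresentation()` (raw p values are
preserved; the FDR is an addition). The statistic agrees with an
independent pooled-z implementation to machine precision and with a
10^5-draw hypergeometric permutation oracle to within 0.05 for counts
of roughly n ≥ 25; at very small counts (e.g. 3/10 vs 1/10) the normal
approximation is off by >0.3, which is why small-count comparisons in
this package (per-site methylation) use Fisher's test instead. The
default enrichment background is the full annotated gene set,
configurable to the expressed universe.

# The synthetic-data generator

`simulate_dataset()` is first-class, tested code: it builds variety 1
de novo, derives the variant set, and produces variety 2 by
`apply_variants()`, so the closure property holds by construction.
Default conditions (chosen once): 2 chromosomes × 2 Mb, 1,000 genes,
single-exon CDSs of 80–160 codons built as ATG + random sense codons +
stop (internal stops impossible by construction, making premature-stop
truth unambiguous); tandem families (6 % of genes) as 97 %-identical
adjacent copies; 2 segmental blocks of 8 genes copied across
chromosomes; 6 CACTA and 4 LTR elements with exact planted TIRs,
subterminal repeats and TSDs, half of them capturing a gene; 2 %
premature-stop genes (70 % nonsense SNPs, 30 % frameshift deletions
verified to truncate); coding SNPs at 5×10⁻⁴ per bp filtered never to
create stops; 70 % of promoters given 1–3 planted SNPs, a tenth of
which flip a motif occurrence (GTTTTTA ↔ GTTTATA); expression signals
drawn lognormally (meanlog log 400, sdlog 1.2, floored at 60 for
expressed probes) so the 50/500/5,000 bin edges are populated, with
replicate CV 0.1, planted class fractions (6 % variety-specific, 10 %
two-fold, 6 % sucrose-only, 12 % silent) and ≥2.3-fold planted effects
so calls are recoverable under the all-replicates rule; duplicate-pair
expression divergence planted at 50 %; sucrose responses planted at
both 2 h and 6 h with a shared direction, so truth is recoverable under
the any-time-point rule; bisulfite clones (10 per variety) over the
proximal 300 bp promoter with context-specific methylation
probabilities (CG 0.8/0.2, CHG 0.5/0.1, CHH 0.1/0.05 for varieties
1/2), a designated 0.9-vs-0.0 differential CG site per gene, and 1 %
conversion error.

Geometry keeps truth tables exact: intergenic gaps of 3.1–3.3 kb ensure
1.5-kb promoter windows of neighbouring genes never overlap (so planted
promoter variation is attributable to exactly one gene); background
indels stay in gap centres; element-internal edge bases are forced to
differ from the TSD edges so maximal repeat extension stops exactly at
the planted LTR boundary; captured genes sit ≥500 bp inside LTR
elements so the repeat separation stays inside the scan's search range.

What the generator does *not* emulate — and what green tests therefore
do not certify about real data: realistic base composition and repeat
landscapes, introns and alternative transcripts, heterozygosity, array
normalization artefacts and probe cross-hybridization, degenerate or
nested mobile elements, and linkage structure. Recovery rates of 1.0
mean the algorithms are correct under their stated assumptions, not
that real-genome recall is perfect.

# Numerical and design notes

* One global seed drives the generator; stages consume one RNG stream
  sequentially, so identical seeds give byte-identical outputs.
* Default problem sizes (1,000 genes on 2 × 2 Mb; 500 neutral pairs of
  300 codons; 2,000 null simulations for test size) were chosen so a
  complete run finishes in minutes on a single core while leaving
  planted-effect recovery statistically unambiguous.
* Greedy one-use-per-terminal CACTA pairing is used instead of global
  optimal matching; deterministic tie-breaks (fewest mismatches, then
  leftmost, then shortest) make reruns identical.
* Family ids are named by their lexicographically smallest member;
  block and element ids by position — all outputs are order-stable.
* The pipeline is an R API (`pipeline_config()` → `run_pipeline()` →
  `write_report()`): for an R analysis package the functions, scripts
  and this vignette are the interface, and every reported count is
  backed by an exported gene list so reports can be recomputed from
  their exports.

# Known limitations

Splice-site-disrupting variants are flagged only through their burden
counts (no splice model); SV semantics cover deletions and flagged
copy-number gains only; the Ka>Ks z test should not be read as a
substitute for likelihood-ratio selection tests; the built-in segmental
chain finder and LTR scanner are stand-ins whose outputs should yield
to curated resources when those exist; and the u statistic's normal
approximation requires moderate counts, as quantified above.
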