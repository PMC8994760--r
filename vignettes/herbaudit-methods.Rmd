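---
title: "Auditing herbal mixtures with multi-barcode metabarcoding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing herbal mixtures with multi-barcode metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbaudit)
```

## The problem and the model

Multi-ingredient herbal preparations (e.g. traditional Chinese medicine
pills) are manufactured from tens of plant materials. Whether the product
actually contains the prescribed materials — and what else it contains —
can be audited by amplicon sequencing of two plant barcodes: the nuclear
ribosomal **ITS2** spacer (high taxonomic resolution, amplicons roughly
150–510 bp) and the chloroplast **trnL** (UAA) intron (short, therefore
amplifiable from heat-degraded DNA, amplicons ≥ 75 bp).

The audit's reference frame is the *prescription*: the mapping from each
prescribed herbal material (PHM) to its accepted source species (PHS).
The mapping is many-to-many — licorice has three accepted *Glycyrrhiza*
species, and one *Paeonia* species can serve two different materials.
Against a prescription, every species observed in a sample falls into
exactly one of three classes:

* **PHS** — the species is itself prescribed;
* **SHS** (substituted) — same genus as a PHS, but not prescribed;
* **CHS** (contaminated) — outside all prescribed genera.

The headline statistic is the detection **sensitivity** of a
preparation under a barcode,

$$\mathrm{Sensitivity} = 100 \times
  \frac{\#\{\text{detected PHMs}\}}{\#\{\text{PHMs detectable in theory}\}},$$

where a PHM counts as detected when at least one of its PHS survives
filtering in at least one sample of the preparation, and the denominator
is all herbal PHMs of the prescription (processed materials included; no
exclusions). Values are rounded half-up to one decimal, which reproduces
printed values such as 69.4 (25/36), 77.8 (28/36) and 62.5 (5/8). Because
detection is a union over samples and barcodes, the multi-barcode union
sensitivity can never be below either single-barcode sensitivity.

## Pipeline stages and their tunables

**Demultiplexing.** Reads carry 7 bp MID tags at both ends; a read is
assigned to a sample only if both tags match exactly (`max_barcode_errors
= 0`), and the tags (14 bp total) are removed. Orientation is as-given;
`both_orientations = TRUE` additionally tries the reverse complement.

**Primer trimming.** The amplification primers (defaults: S2F/ITS4 for
ITS2, the c/h pair for trnL) are anchored at the read ends after MID
removal and matched IUPAC-aware with a configurable mismatch budget
(default 0). Reads missing either primer are rejected.

**Quality control.** A read is kept iff (i) its length is within the
per-barcode bounds — 150–510 bp for ITS2, ≥ 75 bp for trnL (a 75 bp trnL
read is kept: the rule removes reads *below* 75 bp); (ii) no rolling
5 bp window (step 1) has mean Phred below 20; (iii) it contains no N;
and (iv) no homopolymer run longer than 8 bp. Two readings of the
window-rule prose are possible; we reject a read as soon as *any* window
falls below Q20, the reading that matches the intent of a `-q 20`
truncation-style filter, and we evaluate reads shorter than the window
as a single window. The upstream bad-run-length/length-fraction
pre-filter of the original toolchain is subsumed by this window rule and
deliberately not reimplemented separately.

**Taxonomic assignment.** Alignment candidates per read (12-column
tabular format, e-value ≤ 1e-10 at load) are resolved by the
*prescribed-species-preferred* rule: if any candidate is a PHS, the
top-scoring PHS wins, regardless of higher-scoring non-PHS candidates;
otherwise the top-scoring candidate wins. "Score" is the bitscore
(configurable to identity). Ties break deterministically: species class
(PHS > SHS > CHS), then lower e-value, then lexicographic species name —
the tie order is our choice, as the source procedure does not state one.
No lowest-common-ancestor fallback: a read is always a single species or
unassigned.

**Abundance filtering.** Within each sample, species with relative
abundance strictly below 0.002 (ITS2) or 0.001 (trnL) are discarded and
relative abundances are recomputed over the retained reads; a species at
exactly the threshold is kept ("below"). The filter is applied per
sample (per-preparation pooling is available behind `pooled = TRUE`).
Recomputation can push further species under the threshold; the default
is the single pass, with `iterate = TRUE` available for a fixpoint.

**Rarefaction.** Exact multivariate hypergeometric subsampling (without
replacement), replicated; within a replicate the draws are nested in one
random read permutation, so every replicate curve is monotone. The mean
curve therefore matches the closed form
$E[\text{richness}] = \sum_i \left(1 - \binom{N-n_i}{d}/\binom{N}{d}\right)$,
which the tests assert.

**Sample similarity.** Distances between samples are Euclidean on the
binary PHS presence matrix, so $d^2$ is the Hamming distance.
Hierarchical clustering defaults to complete linkage (the default of the
heatmap tooling this emulates; average and Ward available), networks
keep all pairs with $d \le$ cutoff (5.0 for ITS2, 4.2 for trnL by
convention), and PCA is column-centred and unscaled with the sign of
each component fixed so its largest-magnitude loading is positive
(byte-identical reruns). Whether presence or relative abundance feeds
the PCA is not fixed by the source; both inputs are accepted and the
choice is recorded by the caller, not guessed by the package.

## Marker selection and the MEI score

To discriminate two manufacturers, candidate markers are screened by a
deliberately simplified, single-factor LEfSe-like rule: Kruskal–Wallis
at `alpha = 0.05` **and** a one-dimensional effect size of at least
`lda_cutoff`, where the effect size is `log10` of the absolute
difference of group means on the counts-per-million scale (4 ⇔ a 1%
absolute difference). Full LEfSe (subclass Wilcoxon consistency,
bootstrapped multivariate LDA) is out of scope; a precomputed marker
list can be supplied instead. Candidates are then ranked by greedy mRMR
in the MID (relevance − mean redundancy) flavour on mutual information
after equal-frequency 3-bin discretization; neither the mRMR variant nor
the binning is specified by the source, so both are package choices.

The **MEI score** of a sample under a panel $(S_i)_A, (S_j)_B$ is

$$\mathrm{MEI} = \frac{\sum_i \mathrm{AUr}(S_i)}{\sum_j \mathrm{BUr}(S_j)},$$

the ratio of summed relative abundances of the two marker sets. A zero
denominator is replaced by `epsilon = 1e-6` (source silent); if both
sums are zero the score is 1.0 and flagged degenerate. The score is
invariant to uniform rescaling of abundances. Classification quality is
read off a rank-based (Mann–Whitney, midranks for ties) AUC, with
accuracy and F1 at the Youden-optimal threshold of the rule
`score ≥ t ⇒ group A`. Markers whose *single-marker* AUC — the marker
alone against the complete opposing panel side, our reading of an
unstated protocol — is strictly below 0.5 are pruned; 0.5 exactly is
retained.

### Why the planted-marker test screens at cutoff 3.5

The synthetic two-manufacturer design plants markers with effect size 4
(a 1% absolute abundance shift) on a flat 30-species composition
sampled multinomially at depth 10,000. Under that sampling noise a null
species at mean abundance $p \approx 1/30$ has per-sample standard
deviation $\sqrt{p(1-p)/10^4} \approx 1.8\times10^{-3}$, hence a
group-mean difference scale of $1.8\times10^{-3}\sqrt{2/9} \approx
8.5\times10^{-4}$ — about $10^3$ CPM, i.e. effect size ≈ 3. The
customary screening cutoff of 2.0 therefore cannot recover *exactly*
the planted markers (null species routinely exceed it); 3.5 sits
between the noise ceiling (~3) and the planted effect (4). The package
default remains the customary 2.0 — suitable when, as in the full
pipeline test, downstream mRMR ranking and AUC pruning absorb
screening false positives.

## The synthetic data generator

The generator replaces the study's deposited raw reads with a stated,
fully seeded world:

* **Reference databases** per barcode: genera of congeners derived from
  a shared ancestor at 2–5% substitution divergence (within-genus
  identity 95–98% versus ~25% across genera), ITS2 references 160–450 bp
  and trnL 75–250 bp. Reference sequences are generated without
  homopolymer runs over 6 bp so the read-level homopolymer filter is
  never tripped by construction.
* **Reads**: `MID + primer + reference + revcomp(primer) +
  revcomp(MID)`, per-base substitution errors at 0.1% by default,
  per-base Phred qualities from a truncated normal (mean 34, sd 3,
  clipped to [2, 40]) with an optional degraded-tail mode; sample
  grids mirror the study design (2 manufacturers × 3 batches × 3
  replicates = 18 samples per preparation and barcode; 10,000 reads per
  sample, the depth at which rarefaction saturates).
* **Degradation**: a processed PHM contributes `1 − dropout` of its
  nominal reads (dropout 1.0 models fully destroyed DNA).
* **Hit tables**: each read receives its true species as top hit,
  congeners at ~90% of the top bitscore, optional random false hits,
  and e-values that decrease monotonically in bitscore — so the
  assignment rule, not the (out-of-scope) aligner, is what is tested.

**Exact-allocation mode.** The end-to-end acceptance check plants a
contaminant at relative abundance 0.0015, which must be removed by the
ITS2 threshold (0.002) and retained by the trnL threshold (0.001).
Under multinomial sampling at depth $10^4$ the realized abundance
crosses 0.002 with probability ≈ 0.12 per sample, so that statement is
only decidable when reads are allocated deterministically
(`exact_counts = TRUE`, counts = round(rel × depth)). This was decided
from the binomial analysis before the test existed, not tuned
afterwards; all other recovery statements use the same runs.

What a green synthetic test does **not** establish: performance against
real reference databases (incomplete, unevenly curated), chimeras and
PCR bias, length-dependent error profiles of a real instrument, or
biological overdispersion between replicates (the marker design carries
sequencing noise only). The generator's congeners are uniformly
divergent, which is kinder than real congeneric barcode gaps.

## Numerical conventions

* Rounding of sensitivities: half-up to one decimal
  (`floor(x·10 + 0.5)/10`), matching all printed values.
* Name matching: case-folded first two tokens; authority strings
  (capitalized or dotted tokens after the genus) and infraspecific
  qualifiers are stripped; **no synonym resolution** — one-letter
  spelling variants remain distinct, as in the source tables.
* Zero-read samples keep their row with `NaN` relative abundances and
  are flagged rather than dropped.
* All stochastic stages take explicit seeds; the pipeline report
  records seeds, thresholds and md5 checksums, and identical configs
  give bit-identical outputs.

## Known limitations

* The full PHM→PHS maps of three of the four studied preparations are
  published only in supplementary material not shipped here; the
  package carries the complete YGW prescription and synthetic
  scaffolds elsewhere, so per-material coverage of those preparations
  cannot be recomputed from species sets in-repo (their printed
  detected-PHM counts are used directly, as the acceptance criteria
  prescribe).
* The shipped detection-table fixtures are authoritative in their row
  totals; which specific sample carries a mark is approximate where the
  flattened source layout is ambiguous.
* LEfSe and mRMR are simplified reimplementations, documented above;
  no claim is made of reproducing the study's specific marker list,
  which would require the real reads.
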