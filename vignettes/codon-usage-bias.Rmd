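---
title: "Measuring codon usage bias and separating mutation from selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring codon usage bias and separating mutation from selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

## The problem

Synonymous codons are not used at random. In chloroplast genomes the
usage pattern of the 59 degenerate sense codons carries two
superimposed signals: *mutation pressure* (the genome-wide bias of the
mutational process, which affects all codon positions alike and is
most visible at the nearly-neutral third position) and *natural
selection* (typically translational selection, which prefers specific
codons and decouples the third position from the first two).
`codonbias` computes the standard descriptive statistics of codon
usage for a set of protein-coding sequences (CDSs), the four classical
diagnostics that apportion the bias between mutation and selection,
and the "optimal codon" set obtained by contrasting strongly and
weakly biased genes. A seeded synthetic CDS generator with known
ground truth validates every stage without any external data.

## The analysis gene set

Chloroplast CDS annotations include very short open reading frames,
inverted-repeat duplicates and trans-spliced genes. `filter_cds()`
retains a sequence only if it is longer than 300 nt, a multiple of 3,
starts with ATG, ends with a single terminal stop (TAA/TAG/TGA),
contains no internal stop and no ambiguity characters, and is the
first copy of its gene name (inverted-repeat duplicates such as *ndhB*
would otherwise be double-counted). Every exclusion is recorded with
its reason and retrievable with `cds_exclusions()`, making the
reduction from annotated to analyzed genes auditable. Filtering is
idempotent, so a filtered set can safely be filtered again.

The genetic code used throughout is the standard table, whose sense
codons and stops are identical to the bacterial/plastid table 11: 61
sense codons in families of size 1 (Met, Trp), 2 (nine families), 3
(Ile), 4 (five families) and 6 (Leu, Ser, Arg).

All statistics are defined over sense codons. The initial ATG is
counted (it is a Met codon); the terminal stop is carried in the
64-codon count vector but excluded from every statistic, so a clean
CDS of length $L$ contributes $L/3 - 1$ sense codons.

## Statistics

**RSCU.** For codon $i$ of a family with $k$ synonyms and family total
$x$, $\mathrm{RSCU}_i = x_i\,k/x$: 1 means no bias, values above 1
mark preferred codons. Family sums equal $k$ by construction, which
the test suite checks to machine precision.

**Positional GC.** GC1/GC2/GC3 are the G+C fractions at the three
codon positions over sense codons; GC12 is the mean of the first two,
GCall the mean of all three (equivalently the base-level GC fraction
of the concatenated sense codons). GC3s restricts the third position
to the 59 degenerate codons. A3/T3/G3/C3 are third-position base
counts over all sense codons.

**ENC.** Wright's effective number of codons,
$\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
where $\bar F_k$ averages the family homozygosity
$F = (n\sum p^2 - 1)/(n-1)$ over the degeneracy-$k$ families with at
least $n \ge 2$ observed codons. Families with $F \le 0$ are dropped
from the class mean ($F = 0$ would place an infinity in $k/\bar F_k$;
it arises only at tiny $n$). When Ile, the lone 3-fold family, is not
computable, $\bar F_3$ is imputed as $(\bar F_2 + \bar F_4)/2$ — the
convention of the classical CodonW implementation. ENC is capped at 61
(uniform usage) and cannot fall below 20 (one codon per amino acid).
Note that because $F$ is the finite-sample (bias-corrected) form, a
gene drawn from uniform usage sits *at* the 61 cap on average even at
moderate length, rather than approaching it from below.

At the species level `species_summary()` reports both a pooled-counts
ENC and the mean of per-gene ENC values: published tables are
ambiguous about which variant they print, and the two differ
(pooling averages usage before the nonlinearity, so the pooled value
is usually slightly different from the gene mean). Both are emitted so
either convention can be compared.

## Diagnostics

**Neutrality plot.** `neutrality_fit()` regresses GC12 on GC3 across
genes by ordinary least squares. Slope near 1: one mutational pressure
moves all positions together. Slope near 0: selection (or any
position-specific constraint) holds GC12 fixed while GC3 varies. The
slope is conventionally reported as the mutational share of the bias
and $1-$slope as the selective share; the package reports the fitted
slope, intercept, $R^2$ and gene count, and flags a zero-variance GC3
as a degenerate fit rather than producing an arbitrary slope.

**ENC plot.** The mutation-only expectation at a given GC3s is
$\mathrm{ENC}_{exp} = 2 + s + 29/(s^2 + (1-s)^2)$. The per-gene ratio
$(\mathrm{ENC}_{exp} - \mathrm{ENC}_{obs})/\mathrm{ENC}_{exp}$ is
binned at width 0.05 (edges at multiples of 0.05, left-closed);
genes with $|\mathrm{ratio}| \le 0.05$ are classified as consistent
with pure mutation pressure. The ratio formula is the standard
convention; the band half-width equals the bin width.

**PR2 plot.** Per gene, $x = G3/(G3+C3)$ and $y = A3/(A3+T3)$ over
third positions of *all* sense codons (matching the composition
statistics above, rather than only 4-fold families). (0.5, 0.5) is
mutational equilibrium; quadrant occupancy summarizes the direction of
departure. Genes with an empty denominator are flagged rather than
dropped silently. Swapping A with T and G with C maps $(x,y)$ to
$(1-x, 1-y)$, a symmetry the tests exercise.

**Correlations.** `correlation_matrix()` gives all pairwise Pearson
correlations among GC1, GC2, GC3, GCall, ENC and the codon number,
with two-sided p-values from the $t$ distribution on $n-2$ degrees of
freedom and the conventional star annotation (`**` for p < 0.01, `*`
for p < 0.05). No multiple-testing correction is applied, matching how
such tables are conventionally reported.

## Optimal codons

Genes are ranked by observed ENC; the `round(0.10 n)` genes
(half-up, minimum 1, ties broken by gene id) with the *lowest* ENC
form the high-expression pool and the highest-ENC genes the
low-expression pool. Low ENC means strong codon bias, and in the
expression-pool tradition strong bias is the proxy for high
expression — the direction of the ranking is stated here because the
phrase "top 10%" alone is ambiguous. Pool RSCU profiles are computed
on the *pooled counts* of each pool (not the mean of per-gene RSCU,
which would weight short genes up). A codon is *optimal* when its
high-pool RSCU exceeds 1 and
$\Delta\mathrm{RSCU} = \mathrm{RSCU}_{high} - \mathrm{RSCU}_{low} \ge 0.08$.
Met, Trp and stops are never optimal. The 0.08 threshold is the
conventional one for this procedure (a threshold of 0.8 — which
appears as a variant in parts of the literature — would admit almost
nothing and looks like a transcription slip; `delta_min` makes either
choice selectable). Per-species sets are intersected by
`shared_optimal()`, which also counts A/U-ending members. Reports
spell codons with U, as is conventional.

## The synthetic generator

`generate_cds()` builds genes codon-by-codon: ATG, then amino acids
drawn from a frequency vector with codons drawn from per-family
probability vectors, then one stop (TAA/TAG/TGA at 0.5/0.25/0.25, the
TAA preference typical of plastid genes). Because sampling is
restricted to sense codons, internal stops never occur and the
generating sense-codon probabilities are exact — which is what makes
parameter-recovery tests meaningful. The same spec and seed produce
byte-identical output, and the generator restores the caller's RNG
state.

Three regimes emulate the competing forces:

* **mutation** — each gene has one GC pressure $\theta$, spread evenly
  across genes over `gc_range` (default 0.25–0.55, bracketing the GC
  range of plastid genes); codons are drawn from the 61 sense codons
  with probability proportional to the product of per-base weights
  ($G,C \mapsto \theta/2$; $A,T \mapsto (1-\theta)/2$). All positions
  track $\theta$, so the neutrality slope is near 1 (slightly below,
  because code structure constrains positions 1–2 and finite genes add
  errors-in-variables attenuation).
* **selection** — amino-acid composition fixed; within each family,
  codons are grouped by their first two bases, block mass held fixed,
  and only the third base follows the gene's GC3 target (default range
  0.15–0.55). GC12 is independent of the target *by construction*, so
  the slope is near 0. Keeping the six-fold families' block choice
  fixed matters: letting the Leu/Ser/Arg block vary with GC3 would
  leak signal into positions 1–2.
* **planted-optimal** — a designated 10% of genes is biased (within-
  family probability 0.85) toward a chosen codon in each of four
  families; every other family uses a near-deterministic reference
  codon (probability 0.999) identically in all genes. The planted
  genes therefore have the lowest ENC, land exactly in the
  high-expression pool, and the delta-RSCU procedure should return
  exactly the planted set.

The planted preset's sizes come from a power calculation, fixed before
any test was run. For a family of size $k$ observed $n$ times in a
pool, the sampling standard deviation of a codon's RSCU is about
$\sqrt{(k-1)/n}$ under uniform usage — at the preset's depth
(50 genes of 2400–3600 nt, 10% pools, uniform amino acids, so
$n \approx 250$ per family per pool) that is 0.14 for a six-fold
family, far too noisy to keep spurious codons below a
$\Delta\mathrm{RSCU}$ of 0.08. Concentrating the background families
on one codon at $p = 0.999$ shrinks the dominant codon's
$\Delta\mathrm{RSCU}$ noise to
$k\sqrt{2p(1-p)/n} \approx 0.017$, putting the 0.08 threshold at
roughly 4.7 standard deviations, while the rare codons fail the
RSCU > 1 criterion outright. The mutation/selection presets use 200
genes of 900–1800 nt, enough for the slope's confidence interval to
sit well inside the documented bands ([0.8, 1.2] and [−0.1, 0.2]).

What the generator does *not* emulate: real amino-acid composition,
gene-to-gene functional heterogeneity, GC skew between strands,
within-gene spatial structure, or phylogenetic correlation between
species. Passing the recovery tests therefore shows the estimators are
correct on data satisfying their assumptions, not that real plastomes
satisfy them.

## Numerical and degenerate-input choices

* ENC is `NA` (flagged undefined) when a 2-, 4- or 6-fold class has no
  computable family — only the 3-fold class is imputed.
* `composition()` errors on zero sense codons; GC3s is `NA` when no
  degenerate codon is observed.
* Zero-variance variables yield `NA` correlations and a flagged
  degenerate neutrality fit, never silent zeros.
* Pool construction requires at least 10 genes and errors if the two
  pools would overlap; all-equal ENC falls back to the documented
  gene-id tie-break with a warning.
* Pipeline tables are written at fixed precision (3 decimals for
  fractions, 2 for ENC, 4 for slopes, $R^2$ and correlations) and in
  fixed (species, gene) order, so a re-run is byte-identical.
* Fisher-style exactness is not attempted anywhere: p-values are the
  classical $t$-based two-sided ones.

## Scale of the validation runs

The test-bed sizes are chosen so the whole suite runs in well under a
minute on one CPU while leaving comfortable statistical margins: 200
genes for the slope recoveries, 240 genes of ~4.5 kb for the
uniform-usage RSCU calibration (binomial noise ≈ 0.017 per six-fold
codon, against the ±0.05 assertion), and the planted preset as above.
`scripts/acceptance.R` re-runs exactly these computations from scratch
under a caller-provided seed.

## Limitations

* The GenBank reader implements the feature-table subset needed for
  organellar records (CDS keys, `join`/`order`/`complement` location
  algebra, `/gene` and `/locus_tag` qualifiers); it is not a general
  GenBank parser (no fuzzy locations, no remote accession references).
* Optimal-codon identification uses ENC rank as the expression proxy;
  no expression data is consulted, so "high-expression pool" inherits
  all caveats of that proxy.
* The neutrality slope is reported as the conventional
  mutation-share reading without endorsing the equation of slope with
  variance explained; $R^2$ is reported alongside for that reason.
* Species-level analyses treat genes as independent; chloroplast genes
  share linkage and evolutionary history, so p-values are descriptive,
  not inferential.
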