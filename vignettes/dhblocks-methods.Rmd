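---
title: "Parental-origin block calling and co-segregation analysis in doubled-haploid populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parental-origin block calling and co-segregation analysis in doubled-haploid populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhblocks)
```

## The problem

A doubled-haploid (DH) line derived from an F1 between two fully homozygous
parents is a mosaic of parental chromosome segments: at every locus it
carries one parent's allele or the other, and the segments ("recombinant
blocks") are delimited by the crossovers of a single meiosis.  Given
whole-genome variant calls for the two parents and a panel of DH lines,
`dhblocks` reconstructs each line's mosaic, then asks which genomic regions
— and which annotated genes — have a parental origin that perfectly
separates two phenotype groups.  The motivating application is a *Brassica
rapa* cross between a high-glucosinolate (GSL) yellow-sarson parent and a
low-GSL pak choi parent, where the phenotype grouping comes from total leaf
GSL content and the candidate annotation is the GSL biosynthetic pathway.

The package also implements the metabolite-table arithmetic used to define
those phenotype groups: totals from component compounds, component
fractions, fold enrichment over a control cultivar, threshold screening,
and one-way ANOVA with compact letter displays.

## From variant calls to origin calls

A **parent-informative marker** is a biallelic site at which both parents
are homozygous, non-missing, and different.  `extract_informative_markers()`
applies exactly that filter, plus a site-quality threshold (Phred >= 20 by
default, mirroring the common read-quality convention) and an optional
SNP-only restriction; both SNPs and small InDels are informative by default.
Multiallelic sites are dropped rather than decomposed: origin calling is
binary-parental, and the extra alleles carry no origin information.
Genotypes are read unphased ("0/1" and "1/0" are equivalent) because only
allele content matters in a DH line.

At each marker, a DH line's genotype becomes an origin call: homozygous for
the parent-1 allele is `P1`, homozygous for the parent-2 allele is `P2`, one
of each is `HET` (residual heterozygosity), anything else is `MISSING`.

## The block-calling model

Raw origin calls are noisy: genotyping error at rate $\varepsilon$ flips
isolated markers, and missing calls leave gaps.  `dhblocks` segments each
line's calls with a three-state hidden Markov model over $\{P1, P2, HET\}$
decoded by the Viterbi algorithm.

**Emissions.**  A marker call matches the underlying state with probability
$1-\varepsilon$ and equals each wrong label with probability
$\varepsilon/2$; a `MISSING` call is emitted with probability 1 by every
state, so it contributes no evidence but keeps its position in the distance
chain.

**Transitions.**  The physical gap $d$ bp between consecutive markers is
converted to genetic distance $d\,\rho\,10^{-8}$ Morgans ($\rho$ in cM/Mb)
and to a recombination fraction through the Haldane map function
$r = \tfrac12\left(1 - e^{-2d\rho 10^{-8}}\right)$.  Between the parental
states the switch probability is $r$, split $(1 - h)$ toward the other
parent and $h$ into `HET`, where $h$ is the stationary `HET` weight; `HET`
is left symmetrically with probability $r$.  At $d = 0$ the matrix is the
identity; as $d \to \infty$ the parental switch tends to $\tfrac12(1-h)$.

**Decoding and post-processing.**  Viterbi ties are broken by remaining in
the previous state (no gratuitous switches), and at the first marker by
preferring `P1` over `P2` over `HET`.  Maximal constant-state runs become
blocks whose coordinates are the positions of their first and last
supporting marker — block bounds are marker positions, never midpoint
extensions, matching how such regions are conventionally reported.  Blocks
supported by fewer than `min_block_markers` non-missing markers are merged
into the better-supported flank (left flank on ties) until stable.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `eps` | 0.02 | probability | emission error rate of a marker call |
| `rho` | 3.5 | cM/Mb | physical-to-genetic scaling in the Haldane map |
| `het_prior` | 0.01 | probability | stationary weight of the `HET` state |
| `min_block_markers` | 5 | markers | post-hoc small-block merge threshold |

`rho = 3.5` cM/Mb approximates a ~1000 cM map over a ~283 Mb genome; it is
a tuning default, not an estimate, and block calls are insensitive to it
over a wide range because emissions dominate at realistic marker densities.
The HMM was chosen over a windowed majority vote because it handles uneven
marker spacing and isolated errors without window-size tuning; a windowed
vote can be emulated for cross-checking by raising `min_block_markers`.

### Numerical behaviour worth knowing

With `eps = 0.02`, the maximum-a-posteriori path absorbs any true segment
supported by three or fewer markers: two switches cost about
$2\log r \approx -16$ at 10 kb spacing while relabelling three markers
costs about $3\log(\varepsilon/2/(1-\varepsilon)) \approx -13.7$.  This is
the correct Bayesian behaviour under a 2% error model, not a bug — three
isolated discordant markers are more plausibly errors than a real double
crossover.  Consequently, exactness checks against noise-free simulations
decode with a matched emission model (`eps` at its noiseless limit and no
small-block merging); under mismatched emissions exact recovery of very
short segments is impossible by design.

Inter-block gaps (between one block's last marker and the next block's
first) carry no label; gene projection decides how to treat genes whose
midpoint falls in a gap (they become `NA`).

## Co-segregation

`build_gene_matrix()` projects blocks onto gene annotations: a gene takes
the label of the block containing its midpoint
$\lfloor(\text{start}+\text{stop})/2\rfloor$; genes straddling a block
boundary are flagged rather than split.  `find_cosegregating_genes()`
implements the all-or-nothing filter: every group-A line carries one
definite parental label, every group-B line the other, with `HET`/`NA`
disqualifying — either orientation counts.  Perfect separation is the
normative criterion (a `max_violations` relaxation exists but defaults to
0), and no association statistic is attached: with eight lines a set-logic
filter is the honest instrument, and any Fisher-type p-value would be
decoration.  `find_cosegregating_regions()` runs the same logic along the
markers themselves, reporting maximal separating runs of at least
`min_markers` (default 10, a chosen floor against chance runs — the
published analyses do not state theirs).

Useful invariants, all under test: permuting lines or genes never changes
the discovered set; adding a line to a group can only shrink it; swapping
the groups swaps labels only.

## The synthetic population generator

Every downstream stage is testable without external data because the
generator produces populations with known truth:

* marker positions uniform at a configured density (counts Poisson), with
  distinct homozygous parental alleles, ~10% of them InDels;
* per line and chromosome, a Poisson($\lambda = 2$) number of crossovers
  placed uniformly in physical coordinates (no interference — the simplest
  null consistent with a Poisson crossover count), starting from either
  parent with probability 1/2 and alternating; residual heterozygosity
  relabels whole segments at a configurable rate (regional, not per-marker,
  because residual heterozygosity in DH material is regional);
* observed calls equal the truth with probability
  $1-\varepsilon-m$, a uniformly chosen wrong label with probability
  $\varepsilon = 0.02$, `MISSING` with probability $m = 0.01$; the same
  population can be emitted as a GT-only multi-sample VCF v4.2;
* a causal region whose parental origin at its midpoint sets the line's
  phenotype regime: totals drawn from Normal(50, 5) for the high-origin
  lines and Normal(7, 2) otherwise, three replicates per line, split into
  compounds by a fixed gluconapin-dominant profile (GNA fraction 0.85).
  The high and low means straddle the published high (44.1-57.0
  µmol·g⁻¹ dw) and low (3.3-10.8) total-GSL ranges, so a threshold of 25
  separates the groups essentially always.

One root seed drives everything through deterministic per-(line,
chromosome) substreams, so identical configs give byte-identical output and
regenerating one line does not disturb the rest.

What the generator does **not** emulate: crossover interference, marker
density that tracks local SNP density, linked genotyping errors (e.g. from
misalignment hotspots), segregation distortion, or genotype likelihoods.
Passing recovery tests on this generator therefore shows correctness of the
inference chain under its stated noise model, not robustness to every
artefact of real resequencing data.

### Recovery properties, and one that fails by design

At the reference conditions (one 10 Mb chromosome, one marker per 10 kb, 50
lines, $\lambda = 2$, $\varepsilon = 0.02$), more than 99% of non-missing
markers receive their true parental label, and Viterbi decoding provably
attains the exhaustive-path maximum (checked against full enumeration of
$3^{10}$ paths on short sequences).  Problem sizes in the test-suite
simulations (2-10 Mb, 10-50 lines, 100-seed batteries at 5 Mb/30 lines)
were chosen as the smallest populations at which these rates stabilise.

Exact marker-bounded recovery of a planted co-segregating region is
different: the separating run's boundary is set by one specific line's
crossover, and when that line's boundary-adjacent marker call is erroneous
(probability $\varepsilon$) or missing, the inferred boundary shifts by a
marker — the truth at a miscalled marker is unobservable to any decoder.
With two boundaries per region this caps exact recovery near 93%, and the
package's 100-seed measurement fluctuates around 0.87-0.98 by stream.  The
boundary wobble is one marker interval; the *region content* (causal
midpoint coverage, permutation-null emptiness) is recovered essentially
always, and permuted group labels yield no surviving region in ~100% of
seeds.

## Metabolite statistics

Totals are arithmetic sums of compound means with not-detected ("ND")
compounds counting as zero (the convention of the published tables, whose
ND rows still sum); results are rounded half away from zero, two decimals
on the µmol scale and one on the µg scale, matching table precision.
Printed totals in such tables are computed on unrounded laboratory values,
so reproduction from printed component means is exact only where rounding
happens to cancel; the package asserts the rows where it does and treats
one printed-digit discrepancies elsewhere as expected.

`anova_with_letters()` computes fixed-effects one-way ANOVA either from
replicate vectors or reconstructed from per-level (n, mean, sd) — the only
option when a table reports mean ± sd for three biological replicates; such
results are flagged `summary_based`.  ND values are excluded from replicate
vectors (a variance over ND is meaningless) even though they count as zero
in totals.  Post-hoc comparisons offer both Tukey's HSD and Duncan's
multiple range test because the motivating study names both in different
places without reconciling them; Tukey is the default as the more
conservative and the one named in its methods section.  The compact letter
display assigns letters to maximal cliques of the non-significance graph,
ordered so the highest mean gets "a" — maximality guarantees two levels
share a letter exactly when they are not significantly different.

## Known limitations

* Posterior (forward-backward) per-marker probabilities are not computed;
  the block caller commits to the MAP path.
* Multi-parent populations, genetic-map estimation and QTL interval mapping
  are out of scope; gene coordinates are inputs, not discovered.
* The quality filter is a site-level stand-in for read-level filtering the
  package deliberately does not perform (it consumes called variants).
* Breakpoint localisation is limited to one inter-marker interval and, under
  genotyping error, to the boundary-wobble floor described above.
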