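---
title: "Methods: from lysate microcosms to host-virus pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from lysate microcosms to host-virus pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomtrack)
```

## The problem

When a phytoplankton bloom collapses, grazing and viral lysis release the
cells' intracellular organic matter into seawater. Heterotrophic
prokaryotes that can use that substrate grow within days, and the viruses
that infect them follow. `bloomtrack` implements the inference chain that
turns microcosm observations of this process — amplicon counts of 16S
rRNA amplicon sequence variants (ASVs), viral metagenomic quantification
of viral OTUs (vOTUs), and flow-cytometry totals — into a list of
treatment-specific prokaryotes, treatment-specific viruses, and candidate
host-virus pairs confirmed by co-occurrence in an environmental time
series.

The reference design the defaults encode is a seawater microcosm amended
with the dissolved intracellular fraction of either a diatom
(*Chaetoceros* sp., "CIF") or a raphidophyte (*Heterosigma akashiwo*,
"HIF"), plus an unamended control: 3 treatments x 3 replicate flasks x
days 0-7, with virome sequencing on days 0, 1, 3, 5 and 7. Days 0-1 are
the *early* phase (cell densities flat or falling), days 2-4 the *middle*
phase (growth), days 5-7 the *late* phase (saturation).

## Absolute-abundance calibration

Compositional read counts cannot distinguish growth from the decline of
everything else, so both feature types are rescaled to absolute units.

For ASVs, the approximate cell number is the relative read abundance times
the flow-cytometry cell total:
$$C(i) = \frac{n_i}{\sum_f n_f}\; \times\; P(\mathrm{cells}) \quad
  [\mathrm{cells/mL}].$$
Column sums reproduce the cytometry totals exactly (a property the test
suite checks to $10^{-9}$ relative error).

For vOTUs, the FPKM share among all >1 kb viral scaffolds is additionally
calibrated by the fraction of virus-derived reads among all potential
virus-derived reads, then scaled by the particle total:
$$P(i) = \frac{\mathrm{FPKM}(i)}{\mathrm{FPKM}(\mathrm{viral})} \times
  \frac{R(\mathrm{viral})}{R(\mathrm{viral}) + R(\mathrm{potential}\ v)}
  \times P(\mathrm{viral}) \quad [\mathrm{particles/mL}].$$
The middle factor accounts for viral reads that map to no assembled
scaffold: without it, the FPKM share would be a share of the *assembled*
virome only and $P(i)$ would be overestimated. Because catalogued >10 kb
vOTUs are a subset of all >1 kb viral scaffolds,
$\sum_i \mathrm{FPKM}(i) \le \mathrm{FPKM}(\mathrm{viral})$ must hold per
sample; `votu_quant()` rejects inputs that violate it, and
$\sum_i P(i) \le P(\mathrm{viral})$ follows.

## Community structure

`community_structure()` rarefies the ASV table to even depth (default
9,450 reads, subsampling without replacement), computes Bray-Curtis
dissimilarities
$BC(x,y) = \sum_f |x_f - y_f| \,/\, \sum_f (x_f + y_f)$, ordinates by
principal coordinates (eigendecomposition of the Gower double-centred
matrix, coordinates scaled by $\sqrt{\lambda}$), and runs two ANOSIM
contrasts: early versus middle-late samples, and all pairwise treatment
contrasts among middle-late samples, Bonferroni-corrected over the
pairwise family. ANOSIM uses
$R = (\bar r_B - \bar r_W)/(M/2)$ on the ranked dissimilarities with
$M = n(n-1)/2$ and a label-permutation p-value.

Numerical choices: negative PCoA eigenvalues (Bray-Curtis is not
Euclidean-embeddable) are dropped with a logged warning and excluded from
the proportion-explained denominator; permutation p-values use the
+1/+1 convention (the observed labelling counts as one permutation), so
p is never exactly zero; ANOSIM defaults to 999 permutations.

Phase-wise shifts in the cytometry totals are tested by
`phase_compare()`: within each phase, all (replicate, day) observations of
one treatment are pooled against another treatment's and compared by a
Mann-Whitney U test at P < 0.01. Pooling day-level replicate values
(rather than day means) follows from the comparison being between
*samples* of the same phase; with 6 observations per treatment in the
early phase the exact enumeration path of the test is used automatically.

## Rank tests

All rank tests are implemented directly, with exact small-sample paths:

* `mann_whitney_u()`: $U = \min(U_a, U_b)$; exact two-sided p by
  enumeration of all $\binom{n}{n_a}$ assignments for pooled $n \le 12$,
  else a normal approximation with tie correction and continuity
  correction.
* `kruskal_wallis()`: tie-corrected $H$; exact enumeration for total
  $n \le 10$, else the $\chi^2_{k-1}$ reference.
* `spearman_perm()`: Pearson correlation of midranks; exact enumeration
  over all $n!$ permutations for $n \le 7$, else Monte-Carlo permutations
  with the +1/+1 convention. Constant series make r undefined and are
  returned flagged, with p = 1, so they can never be significant.

## Differential enrichment (class/subclass)

`lefse()` reimplements the three-stage class/subclass procedure commonly
used for differential abundance in microbial ecology: a Kruskal-Wallis
screen on the class labels, a subclass consistency check, and a
bootstrapped linear-discriminant effect size. A feature is significant
only if all three agree:

1. Kruskal-Wallis p < alpha (default 0.05);
2. every between-class subclass pairwise rank-sum comparison agrees in
   sign with the class-level difference (with treatment as class, the
   subclasses are the replicate flasks: all 3 x 3 flask contrasts must
   point the same way — one reversed flask vetoes the feature);
3. the effect size reaches the log10 threshold (default 2.0). Per
   bootstrap round (30 rounds, 2/3 subsampling per class) a 1-D linear
   discriminant is fitted and the absolute separation of the class means
   on the unit discriminant axis recorded; the score is log10 of the mean
   separation, floored at 0 below a separation of 1. A relative
   within-class variance floor ($10^{-10}$ of the global variance) keeps
   the discriminant direction defined for near-constant features without
   ever raising an error.

Alpha, the threshold, the round count and the subsampling fraction are
the published defaults of the original tool, which the study named
without overrides. Three-class designs are handled one-vs-one: a feature
is enriched in a class only if it wins against *every* other class — this
reproduces "significantly more abundant in one treatment than in the
others". Observations enter per (replicate, day) sample; whether the
original study summarised per flask first is not stated, and per-sample
observations are the less lossy default.

On absolute abundances of the magnitudes simulated here (thousands to
millions per mL) the effect-size gate is rarely the binding constraint;
the conjunction with the subclass veto is what controls false positives,
and the type-I rate on exchangeable features stays at or below alpha
(checked by simulation in the test suite).

## Calling responders and increased viruses

`abundant_asvs()` applies the two screening rules: (i) on at least one
day after day 0 the feature ranks in the top 20 by approximate cell
number in *every* replicate flask sampled that day, and (ii) its
abundance exceeds twice its day-0 value at least once. Ties at rank 20
are included (competition ranking), so the result cannot depend on
feature order. The fold rule is evaluated on replicate means by default
(`fold_on_means = FALSE` switches to per-flask), and a day-0 abundance of
exactly zero passes once any later value is positive. Missing flask-days
(lost samples are a fact of microcosm work) reduce the rank quorum for
that day and are logged, never imputed; day-level curves report the
number of replicates actually averaged.

`treatment_specific_asvs()` intersects exclusivity (abundant in exactly
one amended treatment, not the control, not the other) with enrichment
(significant for that same treatment).

For viruses, `find_specific_votus()` tests each vOTU within each
treatment for a significant increase after day 0, with day 0 versus later
as the class and flasks as subclasses. The "after" class defaults to the
virome days beyond day 1 (`after_day_min = 2`), reading "compared with
that after day 1" literally; day-1 samples then enter neither class. Set
`after_day_min = 1` to pool day 1 into the after class instead. A
significant increase alone is not enough: the replicate-mean particle
number must exceed 100 particles/mL on at least one day. The threshold is
the approximate mean burst size of marine bacterial viruses (reported
range 50-185 particles per lysed cell): a "significant" increase that
never reaches one burst worth of particles per mL cannot reflect host
lysis in a meaningful way. vOTUs increased in exactly one amended
treatment are treatment-specific; increases shared by both amended
treatments, or by all three, are reported separately.

## Host-virus pairing

`candidate_pairs()` matches each treatment-specific vOTU's predicted host
taxon against the lineages of the same treatment's specific ASVs, at the
predicted rank or any coarser rank (a phylum-level prediction matches
every ASV of that phylum). Host-unknown vOTUs are screened against all
specific ASVs of the treatment, labelled as such — correlation-only
evidence is weaker than genome-based prediction, and the label keeps the
two separable downstream.

`significant_pairs()` evaluates each candidate on the environmental
monthly series (ASV relative abundance from read mapping, vOTU FPKM; both
are mapping-derived and not closed to a constant sum): Spearman
correlation with no time lag, two-sided permutation p, and
Benjamini-Hochberg q over all tested pairs jointly. A pair is significant
exactly when r > 0.6, P < 0.01 and q < 0.05. Two procedural choices are
deliberate: with zero time delay, local-similarity alignment degenerates
to the contemporaneous correlation, so plain Spearman is the identical
inference; and the q-value procedure behind the reported thresholds is
not documented in the source analysis, so the step-up false-discovery-rate
control of Benjamini and Hochberg is used as the standard choice. The
two-sided permutation p is combined with the one-sided r > 0.6 filter,
which reproduces "significant *positive* correlation".

## What the synthetic generator emulates

`simulate_microcosm()` draws the full design with known ground truth:

* a background community of 80 ASVs with lognormally distributed,
  near-constant densities summing to ~$10^6$ cells/mL;
* planted responders (5 CIF, 8 HIF, 2 shared, 3 treatment-independent,
  mirroring the scale of the reference study) at a baseline of
  5,000 cells/mL, growing logistically within the first day in their
  treatments to a carrying capacity of 10x baseline and saturating by the
  end of the middle phase;
* multinomial read sampling at 20,000 reads per sample on top of
  lognormal flask noise (sdlog 0.2) — overdispersed compositional counts
  from the simplest adequate mechanism;
* 40 background vOTUs (~$1.4 \times 10^6$ particles/mL total) plus 2
  planted vOTUs per responder whose bursts lag host growth by 0-2 days
  with amplitude = burst size (100) x the host density increment, and one
  lysogenic vOTU per treatment that tracks its host with no burst — the
  latter confirms the pipeline does not require lysis-shaped dynamics to
  flag an increase;
* quantification denominators generated consistently: FPKM proportional
  to latent particle density with measurement noise (sdlog 0.05),
  non-catalogue scaffolds and unassembled ("potential viral") particles
  as separate pools, so that the calibration formula recovers the latent
  density by construction and the table invariants always hold.

`simulate_environment()` plants correlated host-virus pairs in a
17-point monthly series through a Gaussian copula on a shared seasonal
signal: with strength $a$, both members load $\sqrt{a}$ on the signal, so
their latent Pearson correlation is $a$ and the Spearman correlation
close to it; monotone exponential maps to abundance scales leave Spearman
untouched.

What the generator does *not* emulate: taxonomic structure of the
background (background lineages are arbitrary), substrate competition or
succession among responders, virus-driven host decline (kill-the-winner
feedback), seasonality in the microcosm, or sequence-level artefacts
(chimeras, contamination, mapping ambiguity). Passing recovery tests
therefore shows the inference chain is correct and well-calibrated under
the stated noise model — not that it is robust to upstream bioinformatic
error.

## Problem sizes and reproducibility

The test suite runs every stage at the reference design size (72 amplicon
samples, ~100 ASVs, ~80 vOTUs): recovery of planted responders over 20
generator seeds, environmental pair confirmation over 50 seeds, and null
calibrations of the permutation tests at 1,000 replicates with reduced
permutation counts — sizes chosen so the full suite completes in a few
minutes while keeping Monte-Carlo error well below the margins being
checked. Every stochastic stage takes an explicit seed, identical seeds
give byte-identical output, and generated files record the seed in a
header comment.

## Known limitations

* The abundant-ASV rank rule quorum shrinks when flasks are missing on a
  day; with two of three flasks lost the rule is effectively two-flask.
* The day-0 class of the viral increase test has one observation per
  flask; its power rests on the pooled contrast, and treatments with a
  lost day-0 flask lose power accordingly.
* Exact-test cutoffs (n <= 12 Mann-Whitney, n <= 10 Kruskal-Wallis,
  n <= 7 Spearman) are computational, not statistical, boundaries; just
  above them the approximations are good but not exact.
* Host-unknown screening multiplies comparisons; the joint
  Benjamini-Hochberg correction accounts for the number of tests but not
  for the dependence created by one ASV appearing in many pairs.
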