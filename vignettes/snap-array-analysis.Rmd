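---
title: "Models and methods behind the snapspec pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the snapspec pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapspec)
```

## The measurement and the analysis problem

A SNAP (Specificity and Affinity for Protein) DNA-binding array presents
hundreds of thousands of double-stranded 48-mer probes — genomic windows
tiled at 6-bp steps across ChIP-seq-derived regions, plus combinatorial
control probes — to a purified transcription factor, here Grainyhead-like 2
(GRHL2), whose occupancy is read out as fluorescence. Because the protein
binds naked DNA with no chromatin or cofactors, the array isolates the
intrinsic sequence preferences of the factor. `snapspec` implements the
complete downstream computation: probe-library design, replicate
normalization, motif/mismatch specificity analysis, flanking-base
enrichment, Sequence Specificity Landscapes (SSLs), a torsional-elasticity
phasing model for dimeric sites, and direct-versus-indirect occupancy
classification, together with a synthetic-array simulator that provides
ground truth for every stage.

GRHL2 recognises the palindromic octamer 5'-AACCGGTT-3' (it equals its own
reverse complement), which drives two recurring technical choices: perfect
matches are reported once rather than twice, and mismatch descriptions come
in strand-equivalent pairs (position *i*, base *b* on one strand equals
position *9 − i* with the complementary base on the other) that can be
collapsed to a canonical representative.

## Probe design

Genomic regions (BED intervals with FASTA sequences) are tiled with
48-mers at a 6-bp step; regions longer than 1 kb are excluded and regions
shorter than one probe are skipped. Control classes are built around a
constant carrier sequence chosen — and verified at build time — to contain
no window within two mismatches of the consensus, so control probes carry
no unintended binding sites:

* **Monomer mismatch permutations**: all `choose(8, k) * 3^k` variants at
  exactly *k* mismatches (24, 252, 1512, 5670 for *k* = 1..4).
* **Dimer spacing series**: two consensus copies separated by 0–32 spacer
  bases in forward–forward or reverse–forward orientation. Spacing is
  recorded edge-to-edge; centre-to-centre spacing is *s* + 8 and differs
  only by a constant the phasing fit absorbs into its phase offset.
* **Dimer mismatch combinations**: identical variants in both sites, or
  mismatches confined to one site with the other site consensus.
* **Hairpins**: a 25-bp duplex half, 3-base loop, and the reverse
  complement, folding into a 53-base self-complementary probe.

All enumerations are emitted in lexicographic order so library builds are
bit-reproducible. Coordinates are 0-based half-open throughout (BED
convention).

## Normalization

Replicate arrays differ in overall range and in distribution shape. The
pipeline applies, in order:

1. **Global scaling** — each replicate is multiplied by a single factor
   equalizing the replicate medians. Median-scaling was chosen over
   total-sum scaling (available as an option) because array intensities
   are heavily right-skewed. The standalone operation targets the mean
   of the raw medians (preserving the fluorescence scale); inside the
   pipeline the target is 1, so final intensities are expressed in
   units of the array median. The unit target is what makes the
   pipeline *exactly* invariant to rescaling any single replicate — a
   data-dependent target such as the mean of medians necessarily drifts
   with the rescaled replicate.
2. **Quantile normalization** (via `limma::normalizeQuantiles`, ties
   averaged) — all replicates share the reference distribution, the
   across-replicate mean of sorted columns; ranks within a replicate are
   untouched and tied values stay tied.
3. **Median collapse** — the per-probe median of the normalized
   replicates (with an even replicate count, the mean of the two middle
   values) is the final normalized intensity used by every later stage.

The pipeline is therefore invariant to rescaling any single replicate, and
any monotone transform of raw intensities leaves rank-based downstream
statistics unchanged. Rows with missing replicate values must be removed
beforehand; quantile normalization needs complete columns.

## Flanking-base enrichment

Only genomic probes carrying exactly one perfect consensus, no second
window within one mismatch anywhere on the probe (to exclude dimeric
effects), and a 10-base margin to both probe ends (to exclude constant-
sequence and duplex-terminus effects) are eligible. Probes are split into
the top and bottom quartile by normalized intensity (ties broken by rank
then probe ID) and base frequencies are tabulated at positions −5..−1 and
+1..+5 relative to the octamer.

The published description of the test — each base's enrichment ratio
compared with its background ratio — leaves the exact contingency
construction open. The package reports both of the natural formalisations:

* a per-(position, base) 2×2 chi-squared comparing the base's count in the
  top versus bottom quartile (1 df, no continuity correction) — this is
  the `p` column, is well calibrated under the null (rejection rate ≈ 0.05),
  and drives the significance stars;
* a per-position 3-df chi-squared of the top-quartile base-count 4-vector
  against background proportions from all eligible probes
  (`position_p`), as an omnibus check.

Raw p-values are reported as printed alongside Benjamini–Hochberg
q-values. The descriptive `ratio` column is the top/bottom frequency
ratio; swapping quartiles inverts it exactly.

## Sequence Specificity Landscapes

Each sequence's ring is its minimum window Hamming distance to the
consensus over both strands. Within ring *k* entries are sorted by
canonical mismatch-position tuple, then substituted base (A<C<G<T), then
sequence, and placed at equal angular spacing; ring radii grow by a fixed
increment per populated ring, with no radial gaps for empty rings. A
configuration switch collapses strand-equivalent duplexes, halving the
one-mismatch ring from 24 entries (8 position sections) to 12 entries (4
sections). When several probes share a ring sequence the median intensity
is used, consistent with the pipeline's median collapse; ties among
equally good windows resolve to the smallest offset. The flattened
one-mismatch ring reports entries in ordinal order with the boundaries at
mismatch-position transitions, which is the 2D representation used to
read off position-wise tolerance (steepest losses at octamer positions 3
and 6 in both the real and simulated data).

## The torsional-elasticity phasing model

For probes with two motifs separated by *s* bases the model predicts

$$F(s) = \left[\sum_{n=-N}^{N} K_\mathrm{min}^{-1}
  \exp\!\left(-\frac{(s - (s_\mathrm{min} + n h_r))^2}
                    {2\,\sigma_\mathrm{TW}(s)^2}\right)\right]^{-1},
\qquad
\sigma_\mathrm{TW}(s) = \sqrt{s}\,\sigma_{bp},
\qquad
\sigma_{bp} = \frac{h_r}{2\pi}\sqrt{\frac{\ell k T}{C_\mathrm{app}}},$$

with helical repeat $h_r$ (bp/turn), effective binding strength at a
phasing minimum $K_\mathrm{min}$, phase offset $s_\mathrm{min}$, apparent
torsional modulus $C_\mathrm{app}$ (erg·cm), rise per base
$\ell = 3.4\times10^{-8}$ cm, Boltzmann constant $k$, temperature
$T = 298$ K, and truncation $N = 96$ (numerically indistinguishable from
$N = 10^4$ over the fitted range). $F$ dips to $K_\mathrm{min}$ whenever
the motifs are in phase ($s = s_\mathrm{min} + n h_r$) and rises between
those spacings; growing torsional fluctuations damp the oscillation at
larger spacings. Because the comb sum underflows between minima at small
spacings, all internal computation uses the log-scale form
(`log_predict_F`, a log-sum-exp evaluation); `predict_F` warns and returns
`Inf` where the value exceeds double range.

**Fitting.** The four free parameters are estimated with `nlminb`,
log-parameterizing $K_\mathrm{min}$ and $C_\mathrm{app}$ for positivity,
with multi-start initialization over candidate repeats
$h_r \in \{3.5, 5.25, 7, 10.5\}$, several $\sigma_{bp}$ scales and two
phase starts, because the objective is multimodal in $h_r$
(period-doubling local minima). Residuals are taken on the log-intensity
scale by default: array noise is multiplicative and the observed dynamic
range spans orders of magnitude, so raw-scale least squares (available via
`scale = "raw"`) would be dominated by the brightest spacings. Spacing 0
is excluded — $\sigma_\mathrm{TW}(0) = 0$ makes the model a delta comb
there. A constant series is returned flagged degenerate
($h_r$ unidentifiable); convergence additionally requires a small
numerical gradient norm. On exactly generated curves the fit recovers
$h_r$ to better than $10^{-3}$ bp; with 5% multiplicative noise over
triplicates the median error across seeds stays well below 0.1 bp.

## Direct versus indirect occupancy

Tiled probes are collapsed into regions by transitive interval overlap
(`GenomicRanges::reduce`). A region is **direct** when its maximal
normalized probe intensity strictly exceeds 3.0 — a value exactly at the
threshold is indirect — and **indirect** otherwise; the threshold is
interpreted on the final normalized scale and is configurable. Distinct
binding sites are maximal runs of above-threshold probes in tiling order:
an intervening below-threshold probe splits a run (it demonstrates an
intervening low-affinity window), while runs are merged when nothing lies
between them and their windows overlap. Differential cofactor association
builds the 2×2 table of class against per-region feature presence — an
IUPAC pattern match on either strand (`RGGTCA` for the ER-alpha half
site, `AWTRTTKRYT` for FoxA1) or ≥1-bp ChIP-seq peak overlap — and
applies the Pearson chi-squared test of independence (1 df); when an
expected cell falls below 1 a Fisher exact p-value is reported alongside.

## The synthetic-array simulator

The simulator generates what the analysis assumes: i.i.d.-uniform
background sequence scrubbed of accidental windows within two mismatches
of the consensus, planted consensus/mismatch sites (mismatch count drawn
from a configurable spectrum), an optional preferred flank base, cofactor
sites planted at class-dependent rates (FoxA1 enriched in indirect
regions by a single odds-ratio knob), triplicate intensities with
per-replicate scale factors and multiplicative lognormal noise (mean-1,
configurable CV), and the phasing model driving the dimer spacing series.

Expected log-intensity of a probe is `baseline` plus, when its best
window is within four mismatches of the consensus,
`max(0, plateau - sum(position penalties)) + flank bonus`. The default
penalties (1.4 at edge positions 1, 2, 7, 8; 2.9 at positions 3 and 6;
0.45 at the central 4–5 dinucleotide; plateau `log 40`; flank bonus 0.6)
follow the qualitative specificity ordering the real array exhibits —
steepest losses at positions 3/6, mildest at 4/5 — and were additionally
chosen so that no achievable expected-intensity level lies within about
0.2 log-units of the 3.0 classification threshold. That separation is
what makes the true region class a well-defined quantity the classifier
can be scored against: with noise CV 0.1 and median-of-three collapse,
borderline flips are ~3-sigma events. The recorded ground-truth class is
computed from the noise-free expected intensities of the actual tiled
probes, so chance 3–4-mismatch background windows (genuine weak sites
under the energy model) count toward the direct class; the class implied
by the planted site alone is kept separately as `intended_class`.

What the simulator deliberately does **not** model: spatial array
artifacts, probe secondary structure, synthesis bias, sequence-dependent
shape effects beyond the additive position penalties, and cooperative
occupancy between neighbouring genomic sites. Passing recovery tests on
simulated data therefore demonstrates correctness of the computations
under the stated generative model, not performance on a physical array.

## Problem sizes and numerical choices

The packaged analyses run at desk scale: 200 simulated regions
(~5,500 genomic probes), monomer controls to three mismatches, the 66
dimer spacing probes, 50-seed phasing recovery, and 200-dataset null
calibration of the flank tests. The real array's scale (772,732 probes,
6,151 regions) enters only through printed summary arithmetic. Other
fixed choices: quartile fraction 0.25; significance level 0.05 with raw
p-values starred as printed; deterministic tie-breaks (probe ID order) in
all rankings; all randomness seeded through a single configuration value.

## Known limitations

* The strand-duplicate convention for one-mismatch counts is ambiguous in
  published tallies; both the 24-class and canonical 12-class views are
  available.
* The phasing model is fitted to the forward-forward series only; the
  reverse-forward arrangement is simulated with a shifted, damped variant
  of the same functional form but is not fitted.
* Ring-percentage statistics of the real array (shares of high binders by
  mismatch position) depend on the unreleased production data and are not
  reproduced; the package reports the analogous shares for any supplied
  top fraction.
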