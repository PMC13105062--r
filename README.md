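# snapspec

Analysis of high-density genomic **SNAP** (Specificity and Affinity for
Protein) DNA-binding microarrays measuring the sequence specificity of the
epithelial transcription factor **GRHL2**.

A SNAP array tiles 48-mer probes at 6-bp steps across ChIP-seq-derived
genomic regions, alongside combinatorial control probes, and measures
binding of the purified factor to naked DNA as fluorescence. Because no
chromatin or cofactors are present, the array separates intrinsic,
motif-encoded binding from occupancy that ChIP-seq alone cannot decompose.
`snapspec` implements the complete downstream computation for such an
experiment, for analysts working with protein-binding-microarray data:

* **Probe design** — genomic tiling, all `choose(8,k)·3^k` mismatch
  permutations of the consensus octamer 5'-AACCGGTT-3' (24 / 252 / 1512 /
  5670 for k = 1..4), dimer spacing series (0–32 bp, forward–forward and
  reverse–forward), dimer mismatch combinations, and hairpin controls.
* **Normalization** — global median scaling → quantile normalization →
  per-probe median collapse of the triplicate arrays.
* **Motif & mismatch specificity** — consensus/degenerate (IUPAC)
  scanning with strand canonicalization for the palindromic octamer,
  top-probe ranking and FASTA export for de novo motif discovery,
  flanking-base quartile-enrichment with chi-squared significance, and
  Sequence Specificity Landscapes (concentric mismatch rings, with the
  flattened one-mismatch ring).
* **Helical phasing** — a DNA torsional-elasticity model for dimeric
  motif spacing,

  F(s) = [ Σₙ K_min⁻¹ exp( −(s − (s_min + n·h_r))² / (2σ_TW(s)²) ) ]⁻¹,
  σ_TW(s) = √s·σ_bp, σ_bp = (h_r/2π)·√(ℓkT/C_app),

  fitted for (h_r, C_app, K_min, s_min) by multi-start nonlinear least
  squares; fluorescence oscillates with motif spacing at the period h_r,
  revealing whether two bound dimers prefer the same helical face.
* **Direct vs indirect occupancy** — tiled probes collapse into regions;
  a region whose maximal normalized intensity exceeds 3.0 binds DNA
  directly, otherwise its ChIP-seq signal implies cofactor-tethered
  (indirect) recruitment; distinct-site counting and differential
  cofactor association (ER-alpha half site `RGGTCA`, FoxA1
  `AWTRTTKRYT`; chi-squared independence).
* **A synthetic array simulator** — regions with planted
  consensus/mismatch sites, flank preferences, class-dependent cofactor
  sites, phasing-driven dimer probes, and triplicate lognormal noise,
  with recorded ground truth so every stage's recovery is testable
  without the (unreleased) production array data.

## Worked example: the analysis workflow

The numbered scripts under `analysis/` run the whole study on simulated
data, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # regions, probes, raw intensities
Rscript analysis/02_normalize.R         # global -> quantile -> median
Rscript analysis/03_motif_specificity.R # ranking, flanks, SSL
Rscript analysis/04_dimer_phasing.R     # torsional phasing fit
Rscript analysis/05_direct_indirect.R   # region classification
```

Selected output from a run (seed 20260930):

```
Top-enriched 8-mer among the 1200 top binders: AACCGGTT (472/1200 probes)

Mean ring-1 intensity by mismatch position (lowest = most constrained):
     6      3      2      7      1      8      4      5
 3.640  3.910 16.411 16.966 17.057 18.456 43.786 46.917

Fitted helical periodicity: 5.51 bp per oscillation

5487 probes collapsed into 200 regions: 130 direct, 70 indirect (35.0% indirect)
Classification vs ground truth: sensitivity 1.000, specificity 1.000
ER-alpha half site: X2 = 0.46, p = 0.497 (enriched in direct regions)
FoxA1 consensus:    X2 = 29.55, p = 5.46e-08 (enriched in indirect regions)
```

Reading these numbers: the consensus octamer dominates the top-ranked
probes; one-mismatch binding is weakest when the substitution hits
positions 3 or 6 (the central CxxG that the recognition helix contacts)
and barely affected at the central 4–5 dinucleotide; the dimer spacing
series oscillates with a ~5.5-bp period (about half the 10.5-bp B-DNA
helical repeat, i.e. binding favours motifs on the same helical face);
and region classification recovers the simulator's ground truth, with the
planted FoxA1 enrichment among indirect regions detected and the ER-alpha
half site showing no class difference — mirroring the qualitative
structure of the real-array findings.

A quick interactive taste:

```r
library(snapspec)
truth <- phasing_params(h_r = 5.46, K_min = 1, s_min = 1, sigma_bp = 0.15)
fit <- fit_phasing(1:32, predict_F(1:32, truth))
fit$params$h_r
#> [1] 5.46
```

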