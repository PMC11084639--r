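# memhomology

Multi-evidence remote homology inference for membrane protein families.

## The problem

Transmembrane segments (TMSs) are built from a narrow hydrophobic residue
vocabulary. Between two *unrelated* membrane proteins of similar
architecture, local alignments routinely reach scores and E-values that
would be decisive for soluble proteins — the signal is composition and
topology, not ancestry. Deciding whether two families of channel-like
membrane proteins are homologous therefore requires evidence that this bias
cannot fake.

`memhomology` implements a pipeline of seven independent evidence lines:

1. **Smith–Waterman similarity with a topology-preserving shuffle null.**
   The subject is shuffled so that amino-acid composition, segment
   boundaries, lengths and order (hence inter-TMS distances) are all
   preserved; only within-class residue order is randomized. A generalized
   extreme value (GEV) distribution is fitted to the null alignment scores
   and the observed score gets the analytic tail p-value
   `p = 1 − F_GEV(S_obs; μ, σ, ξ)`.
2. **Architecture compatibility** from hydropathy-based TMS calling
   ("3+1", "3+1+3", ...).
3. **Domain projection** through shuffle-verified alignments.
4. **Conserved motifs**: one-occurrence-per-sequence EM discovery, exact
   convolution null for PWM window scores, per-family recovery rates at
   `E ≤ 10⁻⁴`.
5. **Family-profile comparison** against a shuffled-MSA GEV null
   (columns permuted within consensus-topology segments).
6. **Internal repeat detection**: split the family MSA at a designated
   loop, cross-align the halves, call support from membrane-segment
   coverage plus shuffle-null verification.
7. **Bit-score Ward clustering** with the agglomerative coefficient, and
   structure-space clustering via the TM-score distance `d = (1 − TM)²`
   (average linkage, cut 0.04 ≡ TM ≥ 0.8).

A seeded synthetic-family generator (ancestors with fixed TMS
architectures, class-conditional divergence, loop-only indels, implanted
motifs, tandem duplications, fusions, matched-topology non-homolog
controls, ideal-helix toy structures) provides ground truth for every
stage, so the whole pipeline is testable offline.

## Worked example

```r
library(memhomology)

# two homologous families descending from one 3+1 ancestor
spec <- make_topology_spec("3+1")
root <- sample_ancestor(spec, seed = 21)
ancA <- evolve_family(root, 1, 0.4, seed = 1, indel_rate = 0)$members[[1]]
ancB <- evolve_family(root, 1, 0.4, seed = 2, indel_rate = 0)$members[[1]]
famA <- evolve_family(ancA, 8, 0.3, seed = 101, prefix = "fa")$members
famB <- evolve_family(ancB, 8, 0.3, seed = 102, prefix = "fb")$members

# best cross-family alignment and its shuffle-null significance
smith_waterman(famA[[1]], famB[[1]])
#> fa_m01[3-230] vs fb_m01[3-228]: raw 148, 61.6 bits, E = 1.51e-14, id 28.4%, cov 0.98
shuffle_null_compare(famA[[1]], famB[[1]], n_shuffles = 1000, seed = 7)
#> Shuffle null (1000 shuffles): observed 148.0, GEV(mu 40.61, sigma 5.98, xi 0.005), p = 3.63e-08

# the same comparison for a matched-topology non-homolog pair
ctrl <- make_nonhomolog_pair(spec, seed = 33)
smith_waterman(ctrl[[1]], ctrl[[2]])
#> nhA[23-53] vs nhB[204-234]: raw 47, 22.7 bits, E = 0.00797, id 22.6%, cov 0.13
shuffle_null_compare(ctrl[[1]], ctrl[[2]], n_shuffles = 1000, seed = 8)
#> Shuffle null (1000 shuffles): observed 47.0, GEV(mu 52.19, sigma 7.81, xi -0.057), p = 0.853
```

The homologous pair is decisively significant under the shuffle null
(p ≈ 4 × 10⁻⁸ at 28% identity over nearly the full length), while the
matched-topology control — whose raw E-value of 8 × 10⁻³ might look
suggestive — sits squarely inside the null (p = 0.85). That contrast is the
package's reason to exist.

`run_evidence_pipeline(famA, famB, run_config(...))` runs all seven lines
and returns a structured report (JSON-exportable, byte-reproducible for a
given seed). See the methods vignette (`vignettes/memhomology-methods.Rmd`)
for the models, defaults and their rationale.

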