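---
title: "Methods: multi-evidence homology inference for membrane protein families"
author: "memhomology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-evidence homology inference for membrane protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memhomology)
```

## The problem

Establishing homology between distantly related families of integral
membrane proteins is harder than it is for soluble proteins, for one
specific reason: transmembrane segments (TMSs) are built from a narrow,
strongly hydrophobic residue vocabulary. Two unrelated channel proteins
with, say, a "3+1" architecture — three clustered hydrophobic peaks plus a
fourth behind a long hydrophilic region — will produce local alignments
whose scores and E-values look impressive while reflecting nothing but
shared composition and shared topology. No single statistic survives this
bias, so the package assembles several independent lines of evidence, each
of which either corrects for the bias explicitly or interrogates a signal
the bias cannot produce:

1. pairwise Smith–Waterman similarity, judged against a
   *topology-preserving shuffle null* with a generalized extreme value
   (GEV) tail p-value;
2. compatibility of membrane architecture;
3. domain projection through significant alignments;
4. conserved ungapped motifs with exact-null scanning and per-family
   recovery rates;
5. family-profile comparison against a shuffled-MSA null;
6. internal repeat detection across a split family alignment;
7. bit-score clustering of the combined membership.

`run_evidence_pipeline()` orchestrates all seven; every line can also be
run on its own.

## The shuffle null and its GEV p-value

The centrepiece is the null model of `shuffle_null_compare()`. For a query/subject
pair, the subject is shuffled so that its amino-acid composition, its
segment boundaries, lengths and order — hence the distances between
membrane segments — are all preserved exactly; only the residue order
*within* a segment class is randomized. Membrane residues (TMS and
reentrant loops, which share the hydrophobic vocabulary) are pooled across
segments and redistributed into membrane coordinates, loop residues into
loop coordinates. Pooling across membrane segments is the stronger null of
the two defensible readings (the constraint set also admits per-segment
pooling, available via `per_segment = TRUE`); it is the default because it
randomizes segment-specific order while holding everything the bias
argument relies on fixed.

The observed alignment score is then compared with the scores of the query
against `n_shuffles` shuffled subjects (10,000 by default; calibration
experiments below use 500). Alignment score maxima are well described by
the generalized extreme value family, so a GEV is fitted to the null scores
by maximum likelihood (Nelder–Mead on location/log-scale/shape, initialized
at the Gumbel method-of-moments estimate; if the MLE fails the Gumbel
moments estimate itself is used and tagged). The reported p-value is the
analytic tail probability of the observed score under the fit — not the
empirical rank — so p-values far below `1/n_shuffles` are meaningful to the
extent the fitted tail extrapolates.

The same construction lifts to family level (`family_compare()`): alignment
columns of the subject MSA are permuted within each consensus-topology
segment, the frequency profile is rebuilt, and the profile–profile score of
the query family against each shuffled subject family forms the null.
Because profile construction is column-independent, a column shuffle of the
MSA is a column permutation of the score matrix, which makes the 10,000-MSA
null cheap.

Calibration, regression-tested with fixed seeds: on 100 matched-topology
non-homolog pairs the fraction of GEV p-values at or below 0.05 stays
within [0.02, 0.10]; on 50 homolog pairs at 0.5 substitutions/site, p ≤
10⁻³ in at least 80%.

## Alignment and score statistics

`smith_waterman()` implements the affine-gap Gotoh recurrences in compiled
code; a gap of length *k* costs `gap_open + k * gap_extend`. Ties are
resolved deterministically (optimum ending at the smallest query, then
subject position; traceback prefers diagonal over up over left), so outputs
are identical across platforms. `X` scores zero against everything and is
excluded from composition counts. The default scheme is BLOSUM62 with gaps
11/1 and the standard gapped Karlin–Altschul parameters λ = 0.267,
K = 0.041; a BLOSUM50 10/2 preset mirrors the SSEARCH convention. E-values
are pairwise — `E = K·m·n·exp(−λS)` with the two sequence lengths, not a
database size — because every decision in the pipeline is a pairwise one.
A raw score of zero means no positive-scoring alignment exists; its bit
score is floored at zero and flagged.

## Synthetic families as ground truth

Nothing in the package requires a database: `make_topology_spec()`,
`sample_ancestor()`, `evolve_family()` and friends generate membrane-protein
families with known truth. The defaults are the study conditions and are
not tuned per experiment:

* TMS length 21 residues, short loops 15, long inter-group loops 120,
  reentrant loops ~18 — typical observed segment lengths (TMS of order
  21 ± 4, RLs of order 19 ± 3).
* Membrane-segment composition: 80% of the probability mass on the
  hydrophobic set {I,L,V,F,A,M,W,G,C}, weighted toward I/L/V as in real
  TM helices; the remaining 20% on the small polar residues tolerated in
  the bilayer (S/T-rich, essentially no charges). Loops draw from the
  Robinson–Robinson soluble background. The resulting
  mean Kyte–Doolittle contrast between TMS and loop residues exceeds zero
  in ≥ 99/100 ancestors.
* Divergence is class-conditional resampling: a site hit by mutation
  (probability `1 − exp(−d)` at divergence `d`) is redrawn from its
  class's composition, so families stay compositionally realistic at any
  divergence. Indels are confined to loops (geometric lengths, mean 3),
  which keeps the segment count invariant — the property the shuffle null
  and the coverage filters rely on.
* Matched-topology non-homolog pairs (`make_nonhomolog_pair()`) are two
  independent ancestors of one specification: the exact negative control
  for the shuffle-null calibration.

What the generator deliberately does not emulate: phylogenetic correlation
among members (members are independent draws from the ancestor),
site-rate variation, indel hotspots, and real structural constraints on
loop geometry. Passing tests therefore demonstrate correctness of the
statistical machinery under controlled conditions, not performance on any
particular real superfamily.

## Hydropathy and TMS calling

`hydropathy_profile()` is a sliding-window Kyte–Doolittle mean (positions
with incomplete windows carry the nearest full-window value).
`predict_tms()` keeps the classic threshold of 1.6 KD units and a minimum
segment length of 15 residues, but the run-detection rule required care: a
*w*-residue moving average erodes a hydrophobic stretch by about *w* − 1
positions, so thresholded runs must be dilated by (*w* − 1)/2 on each side
before any length test — with a 19-residue window and a 21-residue TMS no
15-long super-threshold run can exist at all. The shipped detector uses a
7-residue window, dilates runs, rescue-merges adjacent sub-minimum
fragments (the two halves of a helix notched by a weak residue, gap ≤ 6),
requires the dilated segment to keep a mean smoothed hydropathy at or above
the threshold (this rejects brief hydrophobic excursions inside long
loops), and splits segments longer than 35 at internal profile minima (ties
break toward the center). These choices were fixed by a design-time sweep
over window lengths and merge rules on seeded ancestors of the 3+1, 3+1+3
and 4 architectures. Exact segment-count recovery on default-parameter
ancestors is 80–90% depending on architecture; the residual misses are
genuinely weak TMSs whose hydropathy falls below 1.6 — at that threshold,
sequence-only detection cannot do better, which is one reason reentrant
loops (often as hydrophobic as TMSs) are *never* predicted from sequence
here: RL labels come only from annotation or structures.

Architecture labels (`classify_architecture()`) join group sizes of
membrane segments separated by loops shorter than 50 residues ("3+1",
"3+1+3", ...). The 50-residue default is our choice: the long hydrophilic
region of the motivating families is of order 100+ residues, and 50 cleanly
separates it from short connectors.

## Motifs

`discover_motif_oops()` is expectation-maximization under the
one-occurrence-per-sequence model with background pseudocounts (total
weight 0.1), run from data-derived starts. Two refinements proved
necessary on membrane proteins: candidate start windows are screened by a
one-E-step likelihood on a subsample before full EM (plain random restarts
reliably fall into the family-composition local optimum instead of an
implanted motif), and the converged model is register-refined by testing
±1..3-column site shifts, accepting likelihood gains. Scanning
(`scan_sequences()`) uses an exact null: the distribution of window
log-odds under the background is computed by positionwise convolution at
0.01-bit resolution (discretization error far below any threshold in use),
the best window per sequence gets
`p_seq = 1 − (1 − p_window)^(L−w+1)`, and `E = p_seq ×` number of scanned
sequences with one best hit per sequence — which makes
`recovery_rate()` (percentage of members with a hit at `E ≤ 10⁻⁴`) well
defined. Motif quality is reported as information content and
log-likelihood; no attempt is made to reproduce any tool-internal motif
E-value statistic.

## Repeats

`split_msa_at_loop()` cuts a family MSA at the midpoint column of the loop
after a designated membrane segment (midpoint: maximally far from both
flanking segments), degaps the rows in each half, and keeps per-row maps
back to column space. All half-A rows are aligned against all half-B rows;
alignments with pairwise E < 10⁻³ are retained. Support calling requires at
least three membrane segments ≥ 50%-covered in column space on both sides
— and, because unrelated TMS-rich halves routinely clear the E-value filter
on composition alone, each coverage-passing alignment must additionally
beat the topology-preserving shuffle null (200 shuffles, p ≤ 10⁻³). With
that verification the detector finds ≥ 1 supported repeat in ≥ 80% of
seeded tandem families (unit divergence ≤ 0.5) while staying at zero in
≥ 95% of non-duplicated controls.

## Clustering

`bitscore_distance_matrix()` symmetrizes all-vs-all bit scores and applies
the self-normalized transform `d(i,j) = 1 − b(i,j)/min(b(i,i), b(j,j))`,
clipped to [0, 1]; the raw bit-score matrix is attached for users who
prefer another transform, since no published form exists for this step.
`ward_tree()` implements Ward linkage by the Lance–Williams update on
squared dissimilarities (heights reported on the input scale, the
`ward.D2` convention) together with the agglomerative coefficient
`AC = mean(1 − h_first(i)/h_final)`; the implementation agrees with
`stats::hclust` to 10⁻⁹ on random matrices and is checked against a fully
hand-computed four-leaf example. Structure space uses the TM-score distance
`d = (1 − TM)²` — a TM-score of 0.8 maps to `d = 0.04` — with average
linkage and a cut at that threshold. Exported Newick branch lengths are
height differences; as with any score-derived tree, the topology, not the
branch lengths, is the meaningful output.

## Geometry

`kabsch_superpose()` is the SVD least-squares superposition with
reflection correction; degenerate (collinear) correspondences are refused.
`tm_score()` evaluates the usual length-normalized sum with
`d0 = 1.24·(L_ref − 15)^{1/3} − 1.8`, optimizing the superposition for the
TM-score sum by iteratively reweighted Kabsch fits (weights
`1/(1+(d_i/d0)²)²`, 20 fixed iterations, best score kept). The structural
alignment *search* is out of scope: correspondences come from sequence
alignments or are supplied. `refine_segment_assignments()` implements the
proximity rule for adding residues to existing TMSs/RLs literally — CA
within 1.5 Å *and* within three residues of a labeled residue, iterated to
a fixed point with a deterministic N→C scan and TMS preferred over RL on
conflict. Note that 1.5 Å is below the bonded CA–CA distance (~3.8 Å), so
at the default only near-coincident carbons qualify; the cutoff is a
parameter, and ~4 Å is the value to explore if the intent is to absorb
sequence-adjacent residues.

Toy structures (`make_toy_structure()`) are ideal α-helix CA traces (rise
1.5 Å, radius 2.3 Å, 100°/residue) per TMS with 3.8 Å loop arcs; reentrant
loops are hairpins, either helix-then-loop or two sub-helices separated by
a 2-residue Gly/Glu turn. They exist to exercise the geometry layer with
known answers, not to model real folds.

## Numerical and engineering choices

* Coordinates are 1-based inclusive everywhere, matching both the R/
  Bioconductor idiom and the on-disk table convention, so no conversion
  layer exists to get wrong.
* Every random stream derives from one master seed via `subseed()`;
  `with_seed()` restores the caller's RNG state, and two runs with the same
  configuration are byte-identical (regression-tested on the JSON evidence
  report).
* Problem sizes in the shipped tests: shuffle nulls at 300–500 shuffles,
  100 calibration pairs, 100-member motif families, 20 + 20 repeat
  families, 75-sequence clustering scenarios. These sizes were chosen so
  the full suite exercises every claim at meaningful statistical
  resolution; production analyses should use the 10,000-shuffle defaults.
* Known limitations: GEV tail extrapolation below ~1/n_shuffles is model-
  based; the star MSA utility (`quick_msa()`) drops insertions relative to
  the reference and is only meant for closely related synthetic members —
  use a real aligner's MSA for real families; the evidence pipeline's
  verdict thresholds (positive/negative per line) are conventions, and the
  per-line statistics are always reported alongside them.
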