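---
title: "Methods: models, parameters and design choices in c4kit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in c4kit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4kit)
```

`c4kit` reimplements, as tested code, the bespoke computations used in
draft-genome studies of C3 grasses nested inside C4 clades: chloroplast
genome finishing, k-mer genome sizing, leaf developmental-gradient
transcriptomics, a comparative screen for C4-divergent regulators,
diagnostic residue scanning, and A--Ci photosynthesis modeling. Every stage
runs on synthetic data with planted ground truth, so each claim a test makes
is a claim about recovering something the generator knowingly planted.

## Plastome finishing

Chloroplast genomes of grasses are circular and quadripartite: a large and a
small single-copy region (LSC, SSC) separated by two inverted-repeat copies
(IRb, IRa) that are exact reverse complements. The finishing procedure
mirrors manual curation pipelines built on exact read matching:

1. **Trim** 100 bp from every contig end (`trim_ends()`), discarding
   potentially misassembled tips.
2. **Extend** each end iteratively (`extend_contig()`): the terminal 20-mer
   is searched exactly against all reads on both strands, matching reads are
   anchored at the match, and the contig grows by the per-position consensus
   of the bases the reads contribute beyond the end.
3. **Merge** contigs whose ends overlap exactly by at least k, repeat until
   one sequence remains, then circularize on its own terminal overlap
   (`close_gaps()`). Every junction is re-verified by requiring at least
   `min_support` reads spanning a 2k window across it.
4. **Orient** the circle as LSC + IRb + SSC + IRa (`detect_quadripartite()`)
   and **validate** with a per-position 20-mer abundance track
   (`coverage_track()`).

The historical procedure resolved conflicting reads by manual alignment; the
deterministic surrogate here is majority consensus with `min_support = 2`
and explicit termination on ties (`"ambiguous"`) or thin support
(`"insufficient-support"`). With error-free reads these rules coincide with
the manual outcome; with substitution errors at or below 0.5% and coverage
at or above 50x, the majority rule absorbs errors.

Inverted-repeat detection anchors 31-mers of the doubled circular sequence
against the 31-mers of its reverse complement and chains diagonal runs of
matches (modulo the circle length, so repeats spanning the origin chain
correctly). Exact matching is appropriate because plastome IR copies are
treated as identical; inexact-repeat detection is out of scope. Orientation
is resolved deterministically by taking the lexicographically smaller of the
two valid canonical linearizations, which makes the output invariant to the
input's rotation and strand.

Coverage QC uses strand-canonical counting (a k-mer is pooled with its
reverse complement) because shotgun reads are strand-random. Tiling windows
(default 500 bp) are compared against the modal single-copy level (the
median of window means outside IRs); windows fully inside an IR are expected
at twice that level, and windows straddling an IR boundary are exempt
because their expectation is mixed. The flag factor defaults to 1.5.

The plastome generator pins the designed repeat boundaries: a chance
complementary base just outside the repeat would otherwise extend the true
maximal inverted repeat by a base or two and make the recorded "true"
partition ambiguous. The generator resamples the flanking bases so the
designed IR is exactly the maximal repeat; without this, partition recovery
could only be asserted to within a couple of bases.

The contig seeder accepts `avoid` intervals, and the drivers pass the four
quadripartite junction coordinates. This encodes two facts about the world
being emulated: short-read assemblers break plastome contigs *at* repeat
junctions (the collapsed IR ends there), and a gap that straddles an
IR/single-copy junction deep inside the repeat has no unique local closure
-- reads from the two repeat copies support the two flip-flop isomers of the
plastome equally, so exact-match extension would face a genuine tie. The
generator does not create instances whose correct answer is undefined.

## k-mer genome sizing

Single-copy genomic sequence produces a peak in the k-mer multiplicity
histogram centered at the effective sequencing depth
`coverage * (read_len - k + 1) / read_len`; two-copy sequence forms a second
peak at twice that depth. `estimate_genome_size()` implements the standard
total-mass estimator:

* error cutoff = first local minimum of the histogram (after smoothing with
  a 5-wide moving average; raw desk-scale histograms are noisy),
* coverage peak `c` = mass-weighted mean multiplicity over the first peak's
  support `[0.5m*, 1.5m*)` around the modal multiplicity `m*` (the window
  scales with coverage; a fixed-width window biases `c` coverage-dependently
  and breaks the invariance of the estimate to doubling coverage),
* total size = (k-mer mass above the cutoff) / `c`,
* single-copy size = number of distinct k-mers with multiplicity in
  `(cutoff, 1.5c)` -- the midpoint between the 1x and 2x peaks, a
  conventional split since no standard rule exists.

A histogram that only decreases (a pure error slope) raises an
`estimation_failed` condition rather than returning a guess. `k` defaults to
21 for sizing and 20 for plastome QC; odd k avoids palindromic
self-canonicalization. The estimator is the standard rule, not a
reconstruction of any particular study's unpublished procedure; GenomeScope-
style mixture fitting and heterozygosity estimation are intentionally out of
scope (the motivating material is from a selfing, low-heterozygosity line).

## Leaf gradient expression

FPKM is computed from the closed form
`counts * 1e9 / (gene_length * library_size)`. A gene counts as expressed if
any sample reaches 1 FPKM (`filter_expressed()`, boundary inclusive).
Sample correlation uses Spearman's rank correlation on mid-ranks (ties
averaged -- essential for FPKM data with many zeros), with Pearson available
as a cross-check. Clustering is average-linkage on `1 - correlation`; the
source analyses name neither the linkage nor the distance, so both are
recorded here as choices and exposed as arguments. The replicate-coherence
report asks, per segment, whether its replicates form a clade before joining
any other segment's samples.

Cross-species comparisons never use absolute FPKM -- absolute levels are not
comparable across species -- so downstream analysis consumes only
within-species 4-stage mean profiles (`mean_profiles()`). A comparison stage
can map to several native segments (a coarse basal segment of a small leaf
may capture both the base and transition zones of a finer gradient), in
which case the stage value is the mean of those segments' replicate means.

## The comparative C4 regulator screen

`tf_filter()` formalizes a three-stage filter over five species (three C4:
maize as reference plus a second Andropogoneae species and a C4 Paniceae
species; two C3 comparators):

1. membership in the reference photosynthesis co-expression cluster list
   (taken as input, not re-derived);
2. mean FPKM of at least 4 across the four reference-species stages;
3. divergence of a C4 species' max-normalized profile from the C3 consensus
   (the mean of the two normalized C3 profiles) exceeding
   `divergence_tau = 0.3`, with the two C3 species themselves required to be
   mutually consistent (`c3_consistency_tau = 0.3`).

The original comparison was made by eye; the formal surrogate is
`1 - Pearson(p, q)` on max-normalized 4-point profiles, with
`||p - q|| / 2` as an alternative metric. Both thresholds are calibration
choices, not reconstructions of anyone's judgment. A 4-point correlation on
an effectively flat profile is pure noise, so profiles whose minimum exceeds
0.55 of their maximum are compared on the euclidean metric instead
(replicate noise keeps a truly flat profile's range well under 2-fold,
whereas genuinely graded profiles span 4-fold or more; 0.55 separates the
two regimes).

Missing orthologs make a species non-comparable -- recorded, never flagged;
a regulator with no orthologs outside the reference is reported as
reference-specific, mirroring the known case of a maize TF embedded in a
transposable element. Surviving flag patterns classify as
`reference-specific` (reference only), `Andropogoneae-shared` (reference
plus the same-clade C4 species, no others), `pan-C4` (all C4 species), or
`none`.

`assess_induction()` captures what "C4-style induction" of a carbon-shuttle
enzyme means on a 4-stage profile: tip expression of at least 50 FPKM, a
tip/base fold of at least 4, and non-decreasing expression from stage 2
onward (10% tolerance). High-but-flat expression -- the carbonic-anhydrase
pattern typical of C3 leaves -- deliberately fails the fold criterion.

## What the gradient generator emulates

Background genes share a per-gene base profile across species: a log-normal
expression level (median 20 FPKM, sdlog 1.2) times one of four smooth
4-point shapes -- flat, increasing `(0.25, 0.45, 0.67, 1)`, decreasing, and
peaked `(0.3, 1, 0.6, 0.25)` -- raised to a random contrast exponent
`U(0.8, 1.2)`. The graded shapes span roughly a 4-fold base-to-tip dynamic
range with well-separated adjacent values, as developmental-gradient
transcripts do; this matters because the screen's stated operating point
(noise CV 0.2, divergence threshold 0.3) presumes that replicate noise does
not scramble adjacent segment values of unperturbed profiles. Replicate
noise is multiplicative log-normal with CV 0.2 (FPKM noise is
scale-dependent); replicate count defaults to 3 per segment (the source
studies do not print it; it is a parameter).

Planted divergent regulators multiply the two segments where their base
shape is lowest by the stated fold (default 4), only in the species named by
their divergence pattern. Perturbing the lowest segments changes the
*shape* of the profile -- which is what the screen detects -- rather than
its amplitude; with fold 4 and the default shapes, the perturbed segments
rise to or past the former maximum. Planted TFs draw their expression level
truncated below at 10 FPKM, emulating the expressed-TF candidate list the
screen starts from (which is itself conditioned on at least 4 FPKM of leaf
expression); decoys keep the unconditional distribution. The default planted
table mirrors the published 4/3/1 split of divergence patterns.

What the generator does **not** emulate: mapping bias, gene-length effects,
batch structure, correlated noise between replicates, ortholog
misassignment, and cross-species level shifts. A green planted-recovery test
therefore establishes that the screen's logic is correct at its stated
operating point, not that the thresholds are optimal for real data. The
per-seed probability of a perfect precision-and-recall-1 recovery at the
default operating point is about 0.9--0.95; occasional single-decoy flags at
divergence barely above 0.3 are expected noise events, not bugs.

## Residue scanning

Diagnostic sites are numbered on the reference's ungapped sequence (1-based,
matching mutation nomenclature such as A780S), mapped to alignment columns
through `map_reference_positions()`. Classification per sequence and site is
`C4-like` (derived set), `C3-like` (ancestral), `gap`, or `other`; gap sites
are excluded from summary counts. Because numbering is reference-anchored,
inserting gap columns anywhere never changes a classification -- this is a
tested invariant. The bundled table carries only PEPC position 780
(ancestral A, derived S); multi-site tables such as the nine
positively-selected PEPCK residues come from the literature and must be
supplied by the user -- the package never invents coordinates, and the
nine-site table used in tests and the analysis scripts is synthetic and
labelled as such.

## A--Ci modeling

The C3 model is the Farquhar--von Caemmerer--Berry form at saturating light:
`A = min(Ac, Aj) - Rd` with
`Ac = Vcmax (Ci - G*) / (Ci + Kc (1 + O/Ko))` and
`Aj = Jmax (Ci - G*) / (4 Ci + 8 G*)`. Defaults: `Vcmax = 77`,
`Jmax = 144` umol m-2 s-1 (the published curve-matching values), and the
standard 25 degC kinetic constants `Kc = 404` ubar, `Ko = 248` mbar,
`O = 205` mbar, `Gamma* = 38.6` ubar. `Rd` is not printed with published
curves; the default `0.01 * Vcmax` is declared, not inferred.

The C4 model is deliberately the simplified enzyme-limited two-regime form
`A = min(Vp, Vcmax) - Rd`, `Vp = Vpmax Ci / (Ci + Kp)`, with `Vcmax = 35`
(comparable maximum rates), `Vpmax = 120` umol m-2 s-1 and `Kp = 80` ubar
from the standard source tables. Bundle-sheath leakiness (gbs, alpha) is
omitted: the C4 curve serves as a qualitative contrast (steep initial slope,
near-zero compensation point), not as a fitted model.

`compensation_point()` is bracketing bisection on `(0, 200]` ubar to 1e-3
ubar; it matches the algebraic root of `Ac - Rd = 0` where that applies
(about 46.4 ubar at C3 defaults, consistent with the published ~48.2 ubar
given that Rd is unknown) and equals `Gamma*` exactly when `Rd = 0`.
`classify_observations()` compares observed (Ci, A) points against both
fixed-parameter curves by RMSE and reports the better model with its margin;
no parameters are fitted, matching the original practice of choosing values
rather than estimating them. Ci is carried in ubar; measurement pressures
quoted in Pa convert as 1 Pa = 10 ubar.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open on the canonical linearization;
  circular positions are reported modulo the total length.
* All generators are pure functions of their specification and seed.
* Classed conditions (`invalid_spec`, `too_short`, `unresolved_gap`,
  `no_quadripartite`, `estimation_failed`, `out_of_range`,
  `insufficient_range`, ...) separate misuse from statistical failure;
  degenerate inputs (empty read sets, all-gap sequences, constant samples,
  monotone histograms) warn or raise rather than returning silent numbers.
* The read simulator injects substitutions only; the extension algorithm
  relies on exact matching, so substitutions suffice to exercise robustness,
  and indel/chimera simulation is out of scope.

## Known limitations

The finisher assumes exact IR copies and error-free-dominant consensus; it
does not classify organellar vs nuclear reads, annotate genes, or handle
inexact repeats. The sizing estimator has no error-correction mixture model.
The screen takes the co-expression cluster list as given and makes no claim
about the biological function of candidates. The A--Ci module fits nothing
and models neither temperature nor light response nor mesophyll conductance.
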