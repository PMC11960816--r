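---
title: "Detecting large-scale structural variants from a single Hi-C map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting large-scale structural variants from a single Hi-C map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactsv)
```

## The problem and the model

A binned Hi-C contact matrix records, for every pair of fixed-width genomic
windows, how many read pairs link them. Intra-chromosomal contact frequency
falls off roughly as a power law in genomic separation, and beyond a few
megabases the expected contact count is close to zero. A large rearrangement
violates this geometry: the two loci flanking a novel junction become
physical neighbours, so their contact frequency jumps to near-diagonal
levels, producing an off-diagonal block that is far more extreme than any
normal chromatin feature (TADs, loops, compartment stripes) at the same
separation. `contactsv` formalises "find these blocks" as single-image
salient-object detection followed by segmentation, and requires no matched
control — important for tumour samples, where an appropriate normal Hi-C
library usually does not exist and reference panels built from cell lines
transfer poorly.

The caller makes three assumptions worth stating. First, that the
distance-decay is homogeneous enough along a chromosome for distance-stratum
z-scores to be comparable; strong regional coverage biases are only partly
absorbed by this normalization (a covariate-based correction is available
for the coverage profile used in typing). Second, that SV blocks are larger
than one bin and locally coherent — the segmenter deliberately discards
single-cell signals. Third, that events are sparse: each distance stratum's
mean and standard deviation include the SV cells themselves, so a genome
crowded with rearrangements inflates `sigma(d)` and dampens its own signal.
This is visible at small matrix sizes too, where one 1 Mb event is a large
fraction of its distance class; detection power grows with matrix size at
fixed depth density.

## Pipeline and parameters

1. **Distance normalization** (`distance_normalize()`):
   `z = (a - mu(d)) / sigma(d)` per distance class, population (divide-by-N)
   standard deviation, `z = 0` wherever `sigma(d) = 0`. The population
   estimator keeps the identity "constant class gives z = 0" exact, and
   zero-count cells participate in the statistics because an observed zero
   at large distance is informative, not missing. No maximum-distance cap is
   applied: large SVs live at large `d`. Trans matrices use one global
   z-score, since genomic distance is undefined across chromosomes.
   Raw (unbalanced) counts are used throughout — the z-score itself is the
   normalization the method relies on, and matrix balancing would partially
   erase the marginal coverage signal that typing needs.

2. **Saliency** (`saliency_map()`, window half-width `k`, default 10 bins):
   each cell scores `1 - exp(-(1/(2k)^2) * sum d[(i,j),(p,q)])` over its
   `(2k+1)`-square window, where the dissimilarity
   `|z[i,j] - z[p,q]| / (1 + euclidean distance)` discounts remote
   neighbours. The absolute difference makes the dissimilarity non-negative,
   which the `[0, 1]` range of the score presupposes. At 50 kb bins,
   `k = 10` spans about 1 Mb — above the scale of most normal 3D-genome
   organisation, so TADs do not look salient. Borders: the window is
   truncated but the `(2k)^2` normaliser is kept, slightly attenuating edge
   cells while preserving the range; the self-term contributes zero and
   stays in the sum. A brute-force double loop over the window definition is
   kept in the test suite as the oracle for the optimised kernel.

3. **Total-variation segmentation** (`tv_denoise()`, `extract_segments()`):
   `B'` minimises `sum (b - b')^2 + lambda * V(B')` with isotropic TV,
   forward differences and replicate boundary; `lambda = 0.2` is small
   enough that genuine blocks keep their amplitude while isolated noisy
   cells are flattened. The minimiser is computed by Chambolle-type dual
   projection (step 0.248); the solver returns the best iterate seen, so its
   energy trace is non-increasing by construction, and it stops at a
   relative objective change below `tol` (1e-6) or an iteration cap. On
   small problems the solution matches a generic numeric minimiser of the
   same objective to better than 1e-4 per cell. Cells with `b' > t`
   (strictly) are grouped by 8-connectivity; components under `min_cells = 2`
   are dropped as single-pixel noise; intra maps are scanned on the upper
   triangle only so each junction is reported once. The threshold follows
   depth: `t = 0.6` for maps with at least 1e8 total contacts, where domain
   structure is crisp, and `t = 0.5` otherwise; an explicit `t` always wins.

   The genome-scale pipeline caps the solver at 40 iterations
   (`sv_config(max_iter = 40)`) while the low-level `tv_denoise()` default
   remains 200: the dual scheme's objective has a long flat tail, but the
   thresholded segment set is already stable after roughly ten iterations at
   production scale (segment boxes change by at most one bin between 10 and
   200 iterations on 2000-bin chromosomes), so the extra sweeps buy nothing
   downstream.

   One dominant junction object can surface with small satellite fragments —
   most visibly the quarter-plane of an inter-chromosomal translocation,
   which spans hundreds of bins and decays smoothly away from the junction
   corner. `merge_segments()` consolidates segments whose bounding boxes
   overlap after each is expanded by half its own extent: the rule is
   scale-aware, so a large object absorbs its fragments while small,
   well-separated intra-chromosomal junctions (members of a complex chain,
   for instance) stay distinct.

## Breakpoint estimates and refinement

The segment bounding box gives the two breakpoint *regions* (fragment A =
rows, fragment B = columns). The point estimate `bpA`/`bpB` is taken at the
segment's saliency peak, on the edge of the peak bin facing away from the
bulk of the segment — under a decaying contact model the junction sits
exactly there. Ties between the two edges resolve toward the bin start.

`refine_breakpoints()` polishes these estimates with a finer-resolution
submatrix of the junction neighbourhood (default 10 kb): profiles along one
axis are centred, the leading principal-component loading vector along that
axis is computed (eigen-decomposition of the centred cross-product; the
eigenvector sign is fixed by making its first non-zero loading positive),
and the breakpoint moves to the sign change between consecutive loadings.
Sign flips between near-zero loadings (noise wiggles) are ignored when a
flip with real weight on both sides exists; with several candidates the one
nearest the coarse estimate wins; rank-deficient or sub-4x4 submatrices fall
back to the coarse coordinate. Movement is capped at one coarse bin, and the
simulated fine neighbourhood spans two coarse bins on each side so that an
estimate off by a full coarse bin still has the true junction in the window
interior. Rows and columns refine their fragments independently; no
cross-axis reconciliation is attempted.

## SV typing

Typing proceeds in the order the signals are trusted. Chromosome identity
first: cross-chromosome calls are inter-chromosomal translocations. Copy
number second: the mean (optionally covariate-corrected) marginal coverage
over the bins strictly between the two breakpoints is compared with the
genome-wide average `c'` (mean over non-empty bins); below 90% it is a
deletion, above 110% a duplication, both thresholds configurable. When no
bin lies strictly between the breakpoints the two breakpoint bins themselves
are used. The coverage-bias correction fits a generalized additive model
with one smooth term per covariate (GC, mappability, restriction sites) and
divides by the normalised fit; covariates without variation are skipped, so
the correction degrades gracefully to the raw profile.

Copy-neutral calls are typed from the junction geometry: mean z-scores in
four quadrant blocks (side `2k` bins) around the junction point. Two
dominant blocks on the diagonal pair (NW + SE) are the inversion butterfly;
on the anti-diagonal pair (NE + SW), the reciprocal-translocation butterfly;
a single dominant quadrant or an adjacent pair (a one-sided strip) is an
unbalanced junction; three or more hot quadrants, or no quadrant above a
minimum z of 1, is unclassified. The orientation-to-type mapping is a point
where descriptions in the field are easy to get backwards; we derived it
from the generative model itself. Under power-law decay over the rearranged
genome, an inversion of `[s, e)` elevates exactly the cells
`(i < s, j < e)` and `(i >= s, j >= e)` adjacent to the corner `(s, e)` —
the diagonal pair — while a reciprocal translocation joining `x` and `y`
elevates `(i < x, j >= y)` and `(i >= x, j < y)` — the anti-diagonal pair.
Both quadrant-pair assignments are exposed as arguments (`diag_type`,
`antidiag_type`) for users who prefer the opposite convention.

## The simulator: what it emulates, and what it does not

`simulate_contact_matrix()` generates expected counts
`C * (1 + d_new)^(-alpha)` where `d_new` is the bin distance in the
*derived* (rearranged) genome, built by applying the configured events
sequentially (deletions remove bins, duplications insert adjacent copies,
inversions reverse and flip strand, intra-chromosomal translocations
cut-and-paste, inter-chromosomal translocations exchange chromosome tails).
Pairs on different derived chromosomes get a constant trans rate (1% of the
1 Mb intra expectation by default); duplicated bins accumulate the
expectation of every copy pair; `C` scales the genome-wide expectation to
the target depth; observed counts are Poisson draws, symmetrised for intra
maps. Purity mixtures thin tumour and event-free counts binomially at
`purity` and `1 - purity` and sum them. Every run is reproducible from its
seed.

Defaults mirror the benchmark design at desk scale: two 100 Mb chromosomes
at 50 kb bins (about 2000 bins each), seven embedded SVs of 1-2 Mb (one
each of deletion, duplication, inversion, intra- and inter-chromosomal
translocation, plus two complex chains: deletion+inversion and
duplication+deletion), depths of 2, 4 or 6 million contacts and purities
down to 0.2, `alpha = 1` as the canonical intra-chromosomal decay. Events
are spaced at least 10 Mb apart so junction neighbourhoods stay independent.

Ground truth is derived from the map itself: every non-canonical adjacency
of derived bins becomes a junction record with exact reference breakpoints.
Junction types are assigned with the same precedence the classifier uses —
chromosome change, then the copy number of the spanned region (counted from
derived bin copies), then orientation — because the truth should describe
the junction-level signature an ideal classifier could recover. In
particular, a strand-flip junction is labelled an inversion only when both
wings exist at the same coordinates; a solitary flip (for example the
surviving wing of a deletion+inversion chain) is an unbalanced junction,
which is also what its contact pattern shows. An intra-chromosomal
cut-and-paste translocation contributes three junction records (the donor
closure and the two insertion edges) of which a caller merging the two
insertion edges into one strip can match at most two — a structural bound of
about 2/3 recall on that event type that the evaluation deliberately keeps.

What the simulator does *not* emulate: TAD/compartment structure and loops
(the background is a pure power law, so the specificity of the saliency
threshold against structured chromatin noise is not tested here), coverage
biases from GC/mappability/restriction density (the covariate correction is
exercised on synthetic gradients only), read-level artefacts, and
chromosome-scale copy-number aneuploidy. Passing the recovery benchmarks
therefore demonstrates the machinery is correct and calibrated against its
own generative assumptions, not that real-data performance matches it.

## Evaluation conventions

A prediction matches a truth junction when the chromosome pair agrees and
*both* truth breakpoints lie within tolerance of the corresponding predicted
breakpoint region (distance zero if inside it) — 100 kb for intra- and 1 Mb
for inter-chromosomal SVs by default. Matching is one-to-one, greedy by
ascending total gap. Type agreement is not required for a true positive;
typing accuracy is reported separately over the matched pairs. PR curves
sweep descending score thresholds and integrate precision over recall
(anchored at recall zero with the strictest threshold's precision).

## Problem sizes used by the test and benchmark suites

Unit and property tests run on matrices up to 40 bins (oracle comparisons)
and a 400-bin two-chromosome simulation chosen so its strongest junction
types (deletion, duplication, inter-chromosomal translocation) are reliably
detectable — at that scale an inversion's wings are a large fraction of
their own distance stratum and sit at the detection margin, which is itself
documented behaviour of the z-scoring. The benchmark suite and
`scripts/acceptance.R` run the full desk-scale conditions (2000-bin
chromosomes) over several seeds: five at 6M contacts, three at 2M, three
purity-0.2 mixtures, and 10 kb refinement over the matched calls of two deep
runs.

## Known limitations

Events under about 1 Mb at 50 kb bins fall below the saliency window scale
and are unreliable, mirroring the resolution limits of contact maps. Dense
rearrangement clusters violate the sparse-event assumption and mute each
other through the distance statistics. The trans background model is flat,
so trans-matrix specificity against compartment-correlated noise is
optimistic. Cooler/HDF5 containers are not parsed directly — matrices are
read from dense text with a side-car bin table (export from a cooler store
first), and `.hic` files are out of scope.
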