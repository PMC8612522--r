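---
title: "Methods: benchmarking the temporal TF code analyses on synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking the temporal TF code analyses on synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

During neural development, neurons born at different embryonic times
express different cohorts of transcription factors (TFs): Onecut TFs mark
early-born neurons, Zfhx3/Pou2f2 an intermediate cohort, and
Nfia/Nfib/Neurod2 late-born neurons, while late progenitors switch on
Sox9/Nfia/Nfib around the gliogenic switch. This *temporal TF code* can be
read out in several independent ways: EdU birthdating (a thymidine-analog
pulse labels cells in S phase, so EdU–TF colocalization in neurons dates
their birth), flow cytometry of marker-positive neuron fractions,
stage-wise differential expression in single-cell data, comparison of
in-vivo and in-vitro expression dynamics, and pseudotime reconstruction in
which sequentially generated neuronal cohorts appear as successive
expression waves.

`tempocode` implements each of these quantification pipelines together
with synthetic-data generators whose ground truth follows the same
temporal model, so every pipeline can be benchmarked end to end with known
answers. The generators are first-class, tested code: their defaults
define the study conditions under which the acceptance checks run.

## The temporal program

`temporal_program()` assigns each neuronal TF a half-open birthdate window
$[\mathrm{on}, \mathrm{off})$ in embryonic days and each late progenitor
gene an onset day. Defaults: Onecut2 $[e9.0, e10.5)$, Zfhx3
$[e9.0, e11.5)$, Pou2f2 $[e10.5, e11.5)$, Nfia/Nfib/Neurod2
$[e11.5, e13.5)$; progenitor onsets Sox9 e11.0, Nfia/Nfib e11.5. The
half-open convention makes the boundary behaviour exact: a neuron born at
e11.5 is Zfhx3-negative and Nfib-positive. These windows are configuration,
not constants, and encode the qualitative statements of the underlying
biology (Zfhx3 is maintained in neurons born before e11.5 but not in
later-born neurons, which instead express Nfi-family TFs and Neurod2/6).

## Synthetic sections and the imaging pipeline

`generate_section()` renders elliptical nuclei (semi-major axis 5–8 px,
axis ratio 0.7–1.0, random orientation, flat-top profile with a ~1 px
Gaussian edge) into four channels — DAPI, a class marker (HuC in neurons
or Sox2 in progenitors), one temporal TF, and EdU — plus additive Gaussian
noise. Placement is dart-throwing with centre spacing at least
$\max(1.5\,r_{\max},\; r_i + r_j + 2\ \mathrm{px})$: the first term keeps
the historical spacing rule, the second guarantees true non-overlap, which
matters because interpenetrating nuclei cannot be separated by any
watershed and would contaminate the class assignment of their merged
record. Placement gives up after a bounded retry budget and reports the
achievable density.

EdU labeling is modeled without S-phase kinetics: a neuron is labeled iff
its birthdate lies within ±0.25 day (configurable) of the pulse; cycling
progenitors are labeled with an independent Bernoulli (default 0.3),
standing in for the fraction in S phase at the pulse. The ±0.25-day window
is a modeling choice — the effective in-vivo labeling window is not known —
and is exposed in `section_spec()`.

The `snr` parameter is a *guaranteed* contrast-to-noise ratio: the
rendered amplitude is fixed at 0.5 and the noise standard deviation is
$0.5 / (1.4\,\mathrm{snr})$. The 40% headroom absorbs the loss of mean
foreground intensity to the blurred ellipse edge, so the invariant
"mean TF intensity over TF-positive nuclei exceeds TF-negative nuclei by
at least snr noise-sd" holds by construction rather than marginally.
Poisson photon noise is deliberately not modeled (Gaussian only), keeping
this invariant analytic. Consequences for interpretation: passing the
recovery tests shows the pipeline is correct under well-behaved contrast
and realistic density, not that it is robust to uneven illumination,
spectral bleed-through, debris, or 3D sectioning artefacts, none of which
the generator emulates.

The quantification follows the published protocol: nuclei are segmented
from DAPI by an adaptive local-mean threshold (block 51 px, offset 2% of
dynamic range, after 1.5 px Gaussian smoothing) and a watershed on the
Euclidean distance transform (seed separation default 5 px ≈ 0.8 of the
expected radius); objects outside the 40–400 px² area band are discarded;
per-channel mean intensities are min–max normalised to [0, 1] per section
over *all* nuclei; the 0.3% brightest and 0.3% dimmest objects per channel
are trimmed (round-half-up per tail — we read "0.3% of the brightest and
dimmest" as per-tail; both the fraction and the reading are configurable);
neurons are called by HuC presence (or Sox2 absence) at the same 0.25
normalised threshold used for positivity; positivity is strict
(`norm > 0.25`); and the readout is the percentage of EdU-positive neurons
positive for the TF, over untrimmed neurons. The pipeline order is
normalise → classify → call. Trimmed objects keep their records but are
excluded from every downstream count.

Problem sizes: default sections are 512×512 px with 150 nuclei; the
birthdating benchmark quantifies 10 sections per pulse day (e9.5, e10.5,
e11.5, e12.5) at collection e13.5 for Zfhx3 and Nfib. With the default
uniform birthdate grid (e9.0–e13.25 in 0.25-day steps) an e12.5 pulse
labels about 15 neurons per section, all inside the Nfib window, so the
ground-truth Nfib colocalization at e12.5 is 100% and the pipeline is
required to land within 5 percentage points of each section set's truth.

## Flow gating

`generate_flow_events()` draws per-subpopulation Gaussians on a
log10-intensity scale for (viability, FSC, SSC, Sox2, Tubb3, marker), with
10% dead events, 10% scatter outliers, and planted marker-positive
fractions per class. Gating is rectangular throughout (the original 2D
polygon gates are not reproducible from text): live/single gate, then
Sox2-high/Tubb3-low progenitors versus Tubb3-high/Sox2-low neurons, with
double-positive/negative events unassigned.

The dynamic marker threshold is the $1 - f$ empirical quantile (type-7,
linear interpolation) of the sample's progenitor intensities with
$f = 1.5\%$, the midpoint of the published 1–2% rule; the realized
progenitor-positive fraction then sits in [1%, 2%] for any sample with
enough progenitors (we require ≥ 50 and recommend ≥ 1000). Group
comparisons use the unpaired t test, Welch or pooled-variance, via
`stats::t.test`, with the degenerate both-groups-constant case mapped to
p = 1, and the published star mapping (\*\*\* < 0.001, \*\* < 0.01,
\* < 0.05). The global-threshold mode for markers like Nfia that are also
induced in progenitors takes an explicit configured threshold.

## Temporal-marker discovery

Counts are normalised per cell to 10,000 total, stored with
$\log(1 + x)$. For each domain and stage, a one-stage-versus-rest
comparison computes detection fractions on raw counts, the natural-log
fold change of group means of the de-logged normalised values with
pseudocount 1, and a two-sided Wilcoxon rank-sum test on the
log-normalised values for genes passing `min.pct = 0.25` and
`|lnFC| >= 0.25`; p-values are Bonferroni-adjusted over the genes tested
in that comparison and called at 0.05. The rank-sum test is implemented
in the package with an explicit tie policy: for groups of ≤ 8 the null
distribution of the rank sum is enumerated exactly over the tied rank
multiset; larger groups use the normal approximation with tie-corrected
variance and continuity correction. A gene is a *temporal gene* when it is
a significant marker (any stage) in strictly more than 7 of the eligible
domains, with dp6 excluded for its low cell numbers; the TF subset is the
intersection with a TF symbol list (a miniature bundled list of mouse TF
symbols ships in `inst/extdata/mouse_tfs_mini.txt`; users with the full
genome-wide TF annotation can supply it as a file). Heatmap input is the
per-gene z-score across group means of log-normalised expression;
zero-variance genes become zero rows rather than NaNs.

The counts generator plants 15 temporal genes (log-linear 4× ramp up or
down across the five stages e9.5–e13.5) in 9 of the 10 well-populated
domains, among 300 flat genes, with NB dispersion (size) 2 and log-normal
library sizes. The default of 40 cells per domain×stage (dp6: 5) was
sized by a power argument: at a 4× fold the extreme-stage rank-sum
comparison needs roughly 40 vs 160 cells for near-certain per-domain
detection after Bonferroni, and the cross-domain filter compounds
per-domain misses; real datasets of this kind have hundreds of cells per
domain and stage, so this is the small end of realistic.

## Correlation partitioning

Stage profiles are per-gene means on log scale, z-scored across stages.
The in-vivo/in-vitro comparison pairs five stages positionally
(e9.5–e13.5 against differentiation days 5–9), computes the per-gene
Pearson correlation over the five paired values, and classes genes as
correlated (r > 0.5), anticorrelated (r < −0.5) or uncorrelated
(boundary values inclusive; undefined correlations from constant profiles
map to uncorrelated with a flag rather than being dropped). Pearson is
computed on the z-scored log profiles, matching the stated construction
of the compared heatmaps. With only 5 paired points, r is noisy and no
p-value is attached — the partition is descriptive, as published.

The paired-profile generator plants 80% shared-dynamics, 10% independent,
10% sign-flipped genes (roughly the published partition proportions) with
additive noise sd 0.2 on unit-variance profiles. A fundamental limit worth
stating: two *independent* 5-point profiles have |r| > 0.5 about 39% of
the time, so the planted "uncorrelated" class has an irreducible
misclassification rate and overall accuracy plateaus near 96% — the ≥ 95%
recovery check operates close to this statistical ceiling, not to an
implementation tolerance.

## Pseudotime waves

`order_cells()` implements a deliberately minimal lineage ordering rather
than iterated principal curves: the minimum spanning tree over cluster
centroids in the supplied 2D embedding, the unique MST path from the start
cluster (in practice chosen by proneural bHLH expression) to the end
cluster (default: centroid farthest from the start), projection of each
cell of the path's clusters onto the piecewise-linear centroid path, and
arc-length position rescaled to [0, 1]. The downstream protocol — LOESS
(span 0.75, degree 1, the plotting-library default) fitted per gene,
evaluated at the midpoints of 30 pseudotime bins (clamped to the observed
pseudotime range; fewer than 10 points fall back to a global linear fit),
negative fits clamped to 0, then per-gene division by the maximum over
*all* stages' bins — is the tested surface. Curve exclusion is by explicit
user list, mirroring the manual curation of trajectories that curve back
or cross (no algorithmic definition exists); an advisory segment-pair
intersection test warns about self-crossing centroid paths but never
auto-excludes.

The wave-order statistic takes the median argmax bin per TF group (early
Onecut, intermediate Zfhx/Pou2f2, late Nfi/Neurod) and reports TRUE when
early < intermediate < late strictly at every stage with at least one
expressed gene per group. The trajectory generator plants Gaussian bumps
peaked at maturation positions corresponding to bins 5/15/25; note that
span-0.75 LOESS flattens narrow bumps near the boundaries, so recovered
peak bins compress toward 1 and 30 while preserving the order — which is
exactly what the statistic consumes.

## Numerical choices and degenerate inputs

* Constant channels normalise to all-zero with a warning; constant genes
  z-score to zero rows; zero-variance rank-sum data give p = 1.
* Trim counts use round-half-up (so 0.3% of 167 trims 1 per tail, of 100
  trims 0); `round(0.003 N)` per tail exactly.
* All thresholds are strict where the protocol says "greater than"
  (positivity at 0.25, correlation at 0.5, domain filter at 7).
* Quantiles are type-7; pseudotime is invariant to rigid motions of the
  embedding by construction (distances only).
* Every generator is a pure function of (spec, seed): RNG state is
  locally set and restored, and one run seed fans out to stage seeds via
  a counter-based derivation (`derive_seed`), keeping derived seeds below
  $2^{31}$.

## Known limitations

* The synthetic images have uniform background, no illumination field,
  no photon (Poisson) noise and no bleed-through; segmentation parameters
  were chosen for these conditions and real images will need the exposed
  configuration (the original pipeline was manually tuned per image set).
* The flow model omits compensation/spillover and uses rectangular gates.
* The marker pipeline's Bonferroni-over-tested-genes is one defensible
  convention; the tool the published analysis configured adjusts over all
  genes in the dataset, and the package exposes the pieces to reproduce
  either.
* The MST path ordering handles single unbranched lineages only — no
  branch detection, no simultaneous multi-curve fitting.
* Recovering the published gene lists (542 temporal genes / 33 TFs, the
  431/74/36 partition) requires the original external accessions and is
  out of scope; all quantitative checks here are simulation-recovery
  checks under the stated study conditions.
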