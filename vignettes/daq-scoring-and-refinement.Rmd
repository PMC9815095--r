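---
title: "Per-residue amino-acid quality scoring and refinement support: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-residue amino-acid quality scoring and refinement support: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daqrefine)
```

## The score and its assumptions

The package scores each residue of a cryo-EM-derived protein model against
a 20-channel amino-acid probability volume: a regular grid, aligned with
the map frame, whose channels give at every voxel the probability that the
surrounding density corresponds to each of the 20 amino-acid types. Such
volumes are produced by deep-learning classifiers that scan the map with a
small box (the conventional scan interval, 1 Å, is the default grid
spacing); producing them is outside this package's scope — they are an
input.

For residue $i$ with modeled type $aa_i$ and Cα position $x_i$,

$$\mathrm{DAQ(AA)}_i \;=\; \ln\frac{p_{aa_i}(x_i)}{\frac{1}{N}\sum_{j=1}^{N} p_{aa_i}(x_j)},$$

where $p_{aa}(x)$ is the trilinearly interpolated probability of type $aa$
at $x$ and the denominator averages that same type's probability over all
$N$ scored positions of the model. By construction the score is positive
exactly when the classifier sees the assigned type at residue $i$ more
strongly than it sees that type on average along the model. The raw scores
are then smoothed with a 19-residue sliding window; windowed values below
−0.5 flag residues that likely do not fit the density.

The score assumes (i) the model and volume share one coordinate frame
(scoring aborts if more than half the Cα positions fall off the grid);
(ii) per-voxel channel distributions are normalized (validated on load;
worst offending voxel reported; deviations beyond $10^{-3}$ are
rejected); and (iii) one representative point per residue is meaningful —
the Cα. The normalizing average therefore runs over Cα positions by
default, with $N$ the number of scored residues. An all-atom variant of the
denominator (`positions = "all"`) is provided for fidelity experiments,
since a per-atom reading of the normalization is also defensible; the two
differ only through the composition of the average, not the sign logic.
The logarithm is natural: any base rescales all scores by a constant and
preserves signs and rankings, but the −0.5 attention threshold is
base-dependent, so the base is fixed and documented.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `window` | 19 | residues | smoothing window; turns contiguous mis-assignments into coherent negative stretches |
| `threshold` | −0.5 | score (nat. log) | windowed score below which a residue is flagged |
| `trim_rule` | `le0` | — | template trimming removes windowed ≤ 0 (`lt0` keeps exact zeros) |
| `floor` | 10⁻⁶ | probability | value returned for out-of-grid or vanishing lookups; keeps the log finite and makes off-density residues strongly negative |
| `interpolation` | trilinear | — | `nearest` available; at 1 Å spacing both are defensible, trilinear avoids voxel-boundary artifacts |
| GDT thresholds | 0.5/1/2/4 | Å | high-accuracy global distance test |
| `misalign_dist` | 2.0 | Å | displacement beyond which a residue counts as inconsistent |
| `misalign_min_run` | 4 | residues | minimum contiguous inconsistent run |
| capture radius | 5.0 | Å | a nearest reference residue farther than this does not count as "close to a different residue" (the rule's source states no radius; configurable) |

The threshold is applied to the *windowed* score: windowing exists
precisely to expose local register shifts, and an isolated raw dip is not
actionable. Template trimming removes windowed ≤ 0 by default while MSA
masking gaps windowed ≥ 0, so exact-zero positions are removed from the
template *and* masked — they are treated as not confidently correct for
the template, and as not confidently wrong for the alignment signal. Both
literal rules are kept; the strict `lt0` trimming rule is one flag away.
The query row of a masked alignment is never touched, so a predictor
always sees the full target sequence.

## Superposition search for GDT-HA

GDT-style scores require, per distance threshold, the superposition
maximizing the fraction of Cα pairs within the threshold. The package uses
a deterministic seed-and-extend search: superpositions are seeded from the
global Kabsch fit and from every contiguous residue window of lengths 3, 5
and 7, then each seed is refined by refitting on its current inlier set
until that set is stable (at most 20 iterations), keeping the best
fraction seen. On structures of ≤ 12 residues the suite verifies the
search against exhaustive seeding with every window length; replicating
any specific published GDT implementation exactly is a non-goal. The
search can only improve on the single global fit, which the suite asserts
as an invariant. Reports always carry `n_pairs` and coverage, because a
short model can have an excellent r.m.s.d. over few pairs and still a poor
GDT-HA.

Superposition itself is the closed-form Kabsch solution (SVD of the 3×3
covariance with a determinant correction for proper rotations). Fewer than
3 pairs, or collinear/coincident point sets (second singular value below
$10^{-8}$ of the first), raise a degenerate-geometry error rather than
returning an arbitrary rotation.

## The synthetic signal model and its calibration

The generator emulates the classifier output directly rather than
simulating density and a network: each residue imprints a Gaussian bump
(`blur_sigma`, default 1 Å) on its own channel around its Cα, scaled so
the true type carries `peak_prob` (default 0.6) there; far from the model
every voxel is uniform (1/20 per type); voxels are renormalized to sum to
one. Register-shift errors reassign types without touching coordinates;
conformational errors displace coordinates without touching types; a
geometric trace-shift injector moves a region's coordinates onto those of
residues offset by $k$ for exercising the misalignment detector.

The one genuinely open design choice is where the non-true probability
mass sits at a modeled position. Spreading the remaining 0.4 uniformly
over the 19 other types makes every wrong type worth 0.021, and a short
calculation shows that defeats windowed detection of a 10-residue shift:
with $n = 100$ and a roughly uniform 20-type sequence, a type's
model-wide mean probability is about 0.05, so correct residues score
about $\ln(0.6/0.05) \approx +2.5$ and wrong ones only
$\ln(0.021/0.05) \approx -0.9$. Every 19-window centred in a 10-residue
error region contains exactly 10 wrong and 9 correct residues, and
$10 \times 0.9 < 9 \times 2.5$: the window means stay positive no matter
the seed. Real classifiers do not behave like this — their off-true mass
concentrates on *chemically confusable* side chains, and genuinely wrong
types get probabilities far below uniform. The generator therefore places
a fraction `confusion` (default 0.95) of the off-true mass on a fixed
confusable partner (A↔G, V↔I, L↔M, F↔Y, D↔N, E↔Q, K↔R, S↔T, H↔W, C↔P),
leaving each remaining type at about $10^{-3}$. Setting `confusion = 0`
recovers the uniform-background model exactly.

The default of 0.95 is the balance point of a two-sided constraint, chosen
from the same expectation arithmetic before running the experiment: deeper
negatives make error windows more robustly negative, but windows centred
just *outside* the region (which hold up to 9 wrong residues and 10
correct ones) must stay positive for ~90% of unshifted residues. At
`confusion = 0.95` the wrong-type score is about −3.9, error windows are
negative with margin, and only the handful of windows nearest the region
boundary dip below zero. One blind spot is inherent and worth knowing: a
shift that happens to map a type onto itself or onto its confusion partner
is invisible at that residue (probability 2/20 per residue for an
involution partner map); three or more such coincidences inside a
10-residue region — about 7% of random sequences — can keep the whole
windowed region positive. This mirrors the real score's physics: a
confusable side chain in confusable density genuinely cannot be called
wrong from density alone.

What passing the synthetic suite does *not* show about real data: the
generator has no resolution-dependent noise, no disordered regions, no
missing density, no correlation between neighbouring voxels beyond the
Gaussian imprint, and its "classifier" is perfectly calibrated. Results on
the fixtures bound the arithmetic, not the biology.

## Numerical and degenerate-input choices

* Smoothing windows shrink at chain termini (no padding) and never cross a
  numbering gap: windows run over modeled residues in sequence order and a
  jump of more than one in author numbering truncates them.
* Ranking ties keep input order and are recorded in the output; the total
  used for ranking is the sum of windowed scores (a mean-per-residue mode
  exists for unequal-length candidates).
* Altloc resolution: highest occupancy, then first listed; insertion codes
  are part of the residue key; waters and heteroatoms are excluded.
* Probability volumes travel as 20 single-channel MRC (mode 2, float32)
  files plus a JSON manifest; float32 quantization perturbs channel sums
  by up to ~10⁻⁶, so grids are renormalized per voxel after validation on
  load. A per-residue TSV table is accepted as a lighter carrier and
  answers lookups by residue key.
* Out-of-grid or vanishing lookups return the 10⁻⁶ floor and are tallied
  in the track's diagnostics; more than 50% of Cα positions off-grid is a
  hard error suggesting a frame mismatch.
* An empty trimmed template is a warning-grade result with an explicit
  `status`, never a silent success.
* Every generator draw is a pure function of the fixture seed; stage
  functions write a manifest echoing the resolved configuration, and
  identical seed + configuration reproduce outputs byte-for-byte.

## Problem sizes

The test suite and the acceptance script run entirely on generated
fixtures: chains of 5–100 residues, grids of roughly 15×15×160 voxels × 20
channels at the largest, candidate sets of 2–4 models. These sizes keep
the full closed loop — generate, score, trim, mask, superpose, evaluate,
rank — in the regime where the exhaustive oracles (rotation-grid search,
exhaustive GDT seeding, brute-force window means) are cheap enough to run
alongside the implementation.

## Known limitations

* The package evaluates and prepares inputs for structure-prediction-based
  refinement but never runs the predictor, relaxation, or any map-space
  refinement itself; the hand-off is the trimmed template plus masked MSA
  out, candidate models in. (Of the predictor's trained network models,
  only the template-aware ones consume the template — orchestration
  knowledge for the user, not code.)
* Only the amino-acid flavour of the score is implemented; Cα- and
  secondary-structure-flavoured variants are out of scope.
* Correspondence between non-identical sequences must be supplied as an
  explicit residue map; the package does not align sequences silently.
* GDT-HA uses the heuristic search above, validated exhaustively only at
  small sizes; nucleic acids are unsupported; map sharpening and density
  simulation beyond the synthetic imprint model are non-goals.
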