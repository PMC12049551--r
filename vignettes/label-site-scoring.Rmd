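---
title: "Scoring label sites and designing FRET pairs with dyesite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring label sites and designing FRET pairs with dyesite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyesite)
```

## The problem and the model

Covalent fluorophore labeling of a protein — typically by mutating a
residue to cysteine and coupling a maleimide dye — succeeds or fails on
the choice of residue. `dyesite` ranks residues by how much they resemble
residues that have been labeled successfully before, using a naïve-Bayes
construction. For each residue property $s$,

$$PS(s) = \frac{P(s\,|\,l)}{P(s)}$$

is the odds ratio between the property's distribution over labeled
residues and over all residues. The prior probability of labelability is
deliberately not estimated: the literature is biased towards successes,
and the prior only rescales the ranking. Selected parameter scores — one
per category, so that the independence assumption behind naïve Bayes is
plausible — combine by geometric mean into the label score

$$LS = \left(\prod_{i=1}^{n} PS_i\right)^{1/n}.$$

$LS$ is a comparative figure, not a probability. Uniform parameter-score
distributions carry no information; the information content of each
fitted $PS$ is summarized by its mean-square deviation from 1, its Gini
coefficient, and a bin-count-adapted Shannon entropy
($H = 1$ means uninformative), available via `summary()` on a fitted
model and `information_measures()`.

### Uncertainties

$P(s|l)$ and $P(s)$ get Poisson counting errors
$\sigma = \sqrt{P/n}$; the PS error follows by standard propagation,
$\sigma_{PS} = PS\sqrt{\sigma_{sl}^2/P(s|l)^2 + \sigma_s^2/P(s)^2}$.
Bins never seen in the background are excluded from the score (missing,
not infinite); bins with background mass but no labeled observation give
$PS = 0$ with a one-count upper-bound uncertainty, so downstream
consumers can distinguish "suppressed" from "unmeasured".

## The parameter registry

`build_parameter_table()` evaluates 28 per-residue parameters in four
categories:

* **SE, solvent exposure (#1–#12)** — Shrake–Rupley accessible surface
  area with deterministic golden-spiral dot spheres (960 dots per atom by
  default, probe 1.4 Å), relative ASA against the Wilke theoretical
  maxima, half-sphere exposure at 10 and 13 Å, contact number, and
  surface-distance measures built from the solvent-exposed dot cloud
  (surface dots are emitted on the van-der-Waals contact surface, so a
  fully exposed atom sits ~1.6 Å from "the surface" and buried residues
  score several Å). The default SE parameter is #11, the mean distance
  of all residue atoms to the nearest surface dot.
* **CS, conservation (#13–#17)** — ConSurf scores and grades parsed from
  a grades file (sign convention: negative = conserved), or an offline
  fallback from a multiple sequence alignment: per-column Shannon-entropy
  conservation rescaled to mean 0 / SD 1 and sign-flipped, plus the
  homolog-derived parameters (number of distinct amino acids per column;
  cysteine present in homologs).
* **SS, secondary structure (#18–#24)** — an internal Kabsch–Sander
  assignment (electrostatic hydrogen-bond energy with the amide H placed
  from ideal geometry, cutoff −0.5 kcal/mol; n-turns and bridge ladders
  drive an 8-state classification reducible to H/E/C), or an external
  DSSP file; plus backbone dihedrals and segment context.
* **CR, cysteine resemblance (#25–#28)** — identity of the residue to be
  exchanged and its mass, charge-class and volume differences to
  cysteine, from fixed documented tables.

Parameters whose published definitions are anchored by name keep those
definitions; the remaining registry slots are this package's reading of
their names and are flagged `interpretation = TRUE` in
`parameter_registry()`. Missing annotations (no ConSurf file, no MSA)
produce missing values, never errors — missingness is data. The default
four-parameter selection is #11 (SE), #13 (CS), #18 (SS), #25 (CR), one
per category; `ps_fit()` will train any subset.

Glycine receives a virtual C$_\beta$ reconstructed from ideal backbone
geometry wherever an attachment direction is needed (half-sphere
exposure, dye attachment).

### Missing-value policy for LS

The strict policy (default) marks a residue failed ($LS = 0$) when any
selected parameter is missing — conservative, and consistent with a small
failed fraction in routine use. The `reduce` policy takes the geometric
mean over the available parameters and records `n_used`. Both are exact
descriptions of what was computed, so results stay auditable.

## Interdye distances for FRET design

Three estimators of increasing cost predict the distance between two
dyes attached at residues $i, j$:

1. **Cβ distance** — free, but ignores the ~10–20 Å linkers; on dense
   benchmark fixtures it deviates from simulated mean dye positions by
   more than 10 Å (often > 20 Å) and is kept only as a rough first look.
2. **Spherical-sector model (SSM)** — the workhorse screen. With the
   effective linker length $\tilde R = R + \varepsilon$
   ($\varepsilon \approx 0.5$ Å compensates the fluorophore core), the
   dye-inaccessible volume inside the $\tilde R$-ball around the
   attachment C$_\beta$ — the protein atoms dilated by (vdW + dye
   radius) — has center of mass $\vec d'$, and the accessible-volume
   center follows the closed-form sector relation
   $$\vec d = \left(1 - \tfrac{3}{4}\tfrac{\tilde R}{|\vec d'|}\right)\vec d'.$$
   In the physically common regime $|\vec d'| < \tfrac34 \tilde R$ the
   factor is negative: the mean dye position is displaced *away* from
   the blocking mass, which matches the accessible-volume oracle's
   displacement direction on wall fixtures. $\vec d'$ is estimated on a
   deterministic coarse sample (1.7 Å) of the ball with no path search;
   this is what keeps the estimator fast (~1.4 ms per site on a
   120-residue fixture versus ~15 ms for the in-package grid oracle and
   orders of magnitude less than external AV software). Computing
   $\vec d'$ from the bare atom centers instead of the dilated volume
   underestimates the displacement badly — on an analytic half-space
   slab it gives 4.9 Å where the exact accessible-volume centroid is
   10.5 Å, which the volume reading reproduces — so the volume COM is
   the implemented definition.
3. **Grid accessible volume (AV)** — the in-package oracle and
   refinement stage. Grid positions (1.0 Å default) within the linker
   length of the attachment are kept iff a dye sphere there clears every
   protein atom (largest dye radius; conservative single-volume variant)
   *and* the position is linker-reachable: a Dijkstra search over cells
   with linker-width clearance, using a 5×5×5 coprime-offset
   neighbourhood whose chamfer weights are rescaled by 0.9862 so the
   discrete path length brackets the Euclidean geodesic instead of
   always overestimating it. Cells within 4 Å of the attachment are
   always passable — the linker emerges from the attachment atom and
   must thread past the residue's own atoms. Empty AVs (fully buried
   sites) are flagged, not errors.

Mean-position distances systematically underestimate FRET-averaged
distances at short range because averaging $E$ over the dye clouds
weights close approaches more. The conversion
$R_{\langle E\rangle} = R_{MP} + a e^{-R_{MP}/b}$ is calibrated once per
dye pair against the grid-AV oracle's isotropically averaged efficiency
(`calibrate_correction()` / `fit_correction()`); the shipped constants
were fitted on seeded globule benchmarks over mean-position distances of
3–43 Å with RMS residuals of 1.1–1.3 Å (the correction itself decays
below 1 Å beyond ~75 Å, so the short calibration range covers where it
matters). Since $a/b < 1$ the conversion is strictly monotone.
Efficiencies then follow the Förster relation
$E = 1/(1 + (R/R_0)^6)$; parameter sets for Alexa555/647
($R_0 = 51$ Å), ATTO532/643 (58 Å) and Alexa546/647 (65 Å) ship with a
generic default (20 Å linker, 4.5 Å width, 3.5 Å dye radius), all
overridable via `fluorophore_params()`.

### Pair scores and the screen-then-refine workflow

$FS = \sqrt{LS_i LS_j}\,(1 - 2|\tfrac12 - E|)$ rewards pairs that are
labelable *and* maximally sensitive ($E = 0.5$); for two conformations,
$FS_\Delta$ replaces the sensitivity factor with $|E^A - E^B|$.
`screen_pairs()` scores all pairs whose geometric-mean LS passes
`ls_min` (default 1) with SSM efficiencies, then re-scores the top
`refine_top` (default 300) with the grid AV. Two-state mode matches
residues across structures by (chain, number, insertion code) identity —
no sequence alignment is attempted, a documented limitation — and
reports pairs bright in both states with $FS_\Delta < 0.05$ as
negative-control candidates.

## Synthetic fixtures: what they emulate, and what they do not

All tests and benchmarks run on generated structures
(`generate_toy_structure()`): ideal-geometry helices (φ = −57°,
ψ = −47°), hydrogen-bonded antiparallel sheets, jitter-perturbed coils,
and *globules* — residues with realistic per-residue heavy-atom counts
placed on a jittered lattice (4.9 Å spacing) inside a sphere. The
packing was chosen to reproduce protein-like interior atom density
(~0.06 heavy atoms/Å3) and a buried stratum of roughly 30% of residues
with relative ASA < 0.1, giving both strata for enrichment planting.
Wall and shell fixtures provide analytic occlusion geometries for
accessible-volume tests. The synthetic label database
(`generate_label_database()`) samples residues with probability
proportional to planted per-parameter weights and carries curated-style
metadata (≈90% cysteine / 10% unnatural-amino-acid records).

What passing on these fixtures demonstrates: correct estimators,
calibrated statistics, and internal consistency between the SSM and the
AV oracle under controlled geometry. What it does not demonstrate:
performance on real folds (side-chain rotamers, cavities, cofactors),
real conservation signals, or the curated literature database — real
structures and annotations must be supplied for production use.

## Numerical choices and degenerate inputs

* Dot spheres are deterministic golden spirals — results are
  bit-reproducible with no RNG anywhere in the parameter computations;
  stochastic operations (database sampling, bootstrap, benchmarks) take
  explicit seeds.
* Numeric PS binning uses fixed per-parameter default edges (shared
  between background and labeled sets, as the odds ratio requires);
  out-of-range query values clamp to the edge bins with a warning.
* Ties in residue ranking break by (chain, residue number) so control
  selections are reproducible.
* Structures with fewer than two residues yield zero half-sphere
  exposures with a warning; residues with incomplete backbones get the
  unassigned secondary-structure class; empty accessible volumes are
  flagged results.
* First model of multi-model files only; alternate locations resolve to
  the highest-occupancy conformer; waters always removed; author
  numbering (with insertion codes) is the key everywhere and numbering
  gaps are logged, never interpolated.
* Eq.-style set correlation: the 2-norm $\sqrt{\sum r_{ij}^2}$ is the
  default combination of pairwise correlations; the un-squared variant
  is available behind `literal = TRUE` for comparison.

## Benchmark scales

The shipped acceptance benchmark uses 10 globule structures × 10 residue
pairs × 5 dye variants (linkers 10–20 Å, dye radii 3.5–5.5 Å) at 1.0 Å
AV spacing — about a minute on one CPU; the SSM-vs-AV RMSD on it is
≈1.5–1.9 Å across seeds. The full-scale variant (10 × 100 × 35) is
available through `generate_av_test_set()` for longer runs. Bootstrap
envelopes default to 400 replicates with percentile (order-statistic)
bounds, so two replicates degenerate to min/max as expected.

## Known limitations

* The SSM is a single-sector approximation: multi-lobed accessible
  volumes (sites in grooves between domains) are represented by one mean
  position; the refinement stage exists precisely to catch these.
* The grid AV treats the dye as one sphere (largest radius); the
  three-radius weighted variant common in AV software is not implemented.
* κ² orientation effects, dye photophysics and quenching are out of
  scope; efficiencies assume the isotropic average.
* Two-state screening requires consistent author numbering across the
  two structures.
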