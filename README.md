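# dyesite

Picking the residue to which a fluorescent dye is attached is the first —
and often the most error-prone — decision in building a fluorescence assay
on a protein: a poor site compromises expression, labeling efficiency,
dye photophysics or the protein's own function. `dyesite` replaces the
usual trial-and-error with a quantitative ranking of every residue of a
structure, and extends that ranking to the rational design of FRET
experiments.

## The model

For a residue property *s* (solvent exposure, conservation, secondary
structure, amino-acid identity, …), Bayes' law gives the probability that
a residue can be labeled:

P(l | s) = P(s | l) / P(s) · P(l)

The prior P(l) is unknowable from the literature (only successes get
published), but it only rescales the ranking, so each parameter is scored
by the odds ratio

**PS(s) = P(s | l) / P(s)**,

estimated by binning a database of successfully labeled residues against
the full residue background, with Poisson counting-statistics error bars.
Four weakly-correlated parameters — one from each category *solvent
exposure* (mean surface distance), *conservation* (ConSurf score),
*secondary structure* (DSSP class) and *cysteine resemblance* (amino-acid
identity) — combine naïve-Bayes style into the **label score**

**LS = (PS₁ · PS₂ · PS₃ · PS₄)^(1/4)**,

the geometric mean of the selected parameter scores. LS ≈ 1 is
uninformative; residues with LS well above 1 resemble previously
successful labeling sites.

For FRET assays, residue pairs are scored by

**FS = √(LSᵢ LSⱼ) · (1 − 2 |½ − E|)**  (one structure), and
**FSΔ = √(LSᵢᴬ LSᵢᴮ) √(LSⱼᴬ LSⱼᴮ) · |Eᴬ − Eᴮ|** (two conformations),

where E is the predicted FRET efficiency. E comes from one of three
interdye-distance estimators of increasing cost: the Cβ–Cβ distance, a
closed-form **spherical-sector model (SSM)** of the dye's mean position,
or a grid-based **accessible-volume (AV)** simulation with a
linker-reachability search. Mean-position distances are converted to
FRET-averaged distances with a calibrated exponential correction before
applying the Förster relation E = 1 / (1 + (R/R₀)⁶). The standard
workflow screens all pairs with the SSM and refines the best 300 with the
grid AV.

## Worked example

Everything below is synthetic and self-contained — toy structures and a
synthetic label database stand in for curated data:

```r
library(dyesite)

## 1. a toy query structure and a synthetic training background
query <- generate_toy_structure("globule", n_residues = 100, seed = 7)
background <- do.call(rbind, lapply(1:3, function(s)
  build_parameter_table(generate_toy_structure("globule", 100, seed = s),
                        sasa_points = 240)))
attr(background, "registry") <- parameter_registry()
class(background) <- c("parameter_table", "data.frame")

## 2. a synthetic label database enriched for exposed residues
db <- generate_label_database(
  background,
  enrichments = list(list(id = 1, test = function(v) v > 0.4, mult = 3)),
  n_labeled = 120, seed = 11)

## 3. fit the parameter-score model and score the query
fit <- ps_fit(background, db, params = c(11, 18, 25))
print(fit)
query_table <- build_parameter_table(query, sasa_points = 240)
scores <- predict(fit, query_table, selection = c(11, 18, 25),
                  policy = "reduce")
head(rank_residues(scores, 0.05)[, c("key", "aa", "ls")])

## 4. FRET pair screening on the same structure
screen <- screen_pairs(query, scores, pair = dye_pair("AF555-AF647"),
                       ls_min = 1, refine_top = 20)
print(screen, n = 3)
```

which prints:

```
<ps_model> 3 parameter score(s), 300 residues (120 labeled)
  #11 mean_surface_distance [SE, numeric]: 12 bins, PS range 0.00-1.33
  #18 ss8 [SS, categorical]: 8 bins, PS range 0.97-1.13
  #25 aa_identity [CR, categorical]: 20 bins, PS range 0.50-1.25
       key  aa       ls
64   A:64: LYS 1.232156
75   A:75: GLU 1.232156
96   A:96: VAL 1.232156
90   A:90: PHE 1.204143
100 A:100: PHE 1.204143
<fret_screen> 2327 pair(s), dye pair AF555-AF647
  key_i key_j  pair_ls  e_screen score_screen score_refined e_refined     score
1 A:75: A:96: 1.232156 0.6145999    0.9497461     0.8292846 0.6634823 0.8292846
2 A:44: A:89: 1.127186 0.6169993    0.8634260     0.8264448 0.6334035 0.8264448
3 A:80: A:85: 1.156521 0.6200662    0.8788025     0.8175968 0.6465274 0.8175968
```

Reading the output: the fitted model suppresses deeply buried residues
(PS → 0 at large mean surface distance) and mildly favours the planted
exposed stratum; the top-ranked residues are exposed surface sites with
LS ≈ 1.23. The pair screen then ranks residue pairs whose predicted
efficiency with the Alexa555/647 pair (R₀ = 51 Å) is closest to 0.5 while
both partners remain good label sites; the grid-AV refinement shifts the
screening scores only slightly.

Real structures are read with `read_structure()` (PDB or mmCIF),
pre-processed with `preprocess_structure()`, and annotated score PDBs for
molecular viewers are written with `write_score_pdb()`. ConSurf grades
files, DSSP files and multiple sequence alignments plug into
`build_parameter_table()`. A thin command-line wrapper with `score`,
`train`, `fret` and `fixtures` subcommands lives in `inst/cli/dyesite.R`.

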