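---
title: "Screening for convergent CAM evolution: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for convergent CAM evolution: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camconverge)
```

Crassulacean acid metabolism (CAM) evolved repeatedly from C3 ancestors in
distantly related plant lineages. Because the CAM cycle inverts the diel
scheduling of carbon fixation — stomata open and PEPC-mediated CO2 uptake
runs at night — two molecular signatures are expected wherever CAM arose
independently: *re-scheduled diel transcript expression* shared by CAM
lineages but not their C3 relatives, and *convergent amino-acid
substitutions* in the proteins doing the re-scheduled work. `camconverge`
implements one screen for each signature, plus generators that plant both
signals in synthetic data so every stage can be validated against known
truth.

## The expression screen

### Data model

Each species contributes a matrix of FPKM time-courses over the canonical
diel grid: 12 samples at 2-h intervals across a 12 h light / 12 h dark
cycle, expressed as hours after light onset on the circular interval
(0, 24] (hour 24 is hour 0). Replicates are kept per time point. The grid is
partitioned into four windows of three points each — dawn {22, 24, 2},
midday {4, 6, 8}, dusk {10, 12, 14}, midnight {16, 18, 20} — with dawn/dusk
and midday/midnight as opposite pairs.

Species sampled more coarsely (e.g. a 4-h C3 reference series) are brought
onto the 2-h grid by periodic cubic-spline interpolation of the
replicate-mean curve. The periodic boundary is the physically correct
choice for a 24-h cycle: value, slope and curvature match across the
midnight/dawn seam, where a natural spline would flatten artificially.
Interpolation needs at least four distinct time points; values are clipped
at zero because FPKM cannot be negative.

### Statistics

* **Expression filter.** A gene enters the screen when its replicate-mean
  abundance strictly exceeds 0.01 FPKM at six or more of the 12 time points.
* **Correlation.** Scheduling similarity is Spearman's rank correlation
  (average ranks on ties) between replicate-mean curves. Rank correlation is
  invariant to monotone transforms, so it compares timing, not scale.
* **Phase shift.** Both curves are z-scored (mean 0, sd 1 over the 12
  replicate means), upsampled to a 0.5-h circular grid by periodic spline,
  and the signed lag in (−12, 12] maximizing the Pearson correlation of
  `a(t)` with `b(t + lag)` is reported. Ties break toward the smaller |lag|,
  then toward the positive lag. The 0.5-h lag grid resolves
  sub-sampling-interval offsets (the 1–1.5 h shifts typical of co-scheduled
  CAM orthologs). A zero-variance curve cannot be z-scored; such profiles
  are flagged degenerate, excluded from correlation and shift estimation,
  and can never be called convergent.
* **Window contrasts.** For each gene, the three time points of one window
  are pooled across replicates (3 × n observations) and compared with the
  opposite window by a two-sided Welch t-test; both contrasts (midday vs
  midnight, dawn vs dusk) are tested. The paper-scale analysis this mirrors
  does not name its test, so Welch's t on pooled window observations is a
  package design choice: replicate-aware, robust to unequal variances, and
  cheap at genome scale. P-values are Benjamini–Hochberg adjusted
  genome-wide *within species* across both contrasts (2 p-values per gene);
  a gene's enriched window is the larger-mean side of its most significant
  contrast when that contrast has q below the FDR threshold.
* **Flat-line filter.** Time structure is assessed by a nested-model F-test
  of a degree-3 polynomial in time against an intercept-only flat line, on
  `log2(x + 1)`-transformed replicate-resolved values. A constant,
  noise-free series has an undefined F and is reported as p = 1.
* **Clustering.** Ortholog-group profiles can be clustered hierarchically
  with average linkage on the distance 1 − Spearman rho. Profiles are
  ordered by gene id first so results do not depend on input order; with
  exactly tied distances the merge order follows `stats::hclust`.

### The three-criterion classifier

A CAM-dicot (Kalanchoë-like) gene is called convergent in expression when,
within its ortholog group:

1. its diel pattern has Spearman rho > 0.8 with at least one CAM-monocot
   ortholog **and** rho < 0.5 with *every* C3 ortholog (both bounds strict:
   boundary genes fail);
2. it shows a significant opposite-window contrast at genome-wide
   q < 0.01;
3. its shift to the best CAM-monocot ortholog is ≤ 3 h in magnitude, while
   both CAM genes are shifted ≥ 6 h against the best-matched C3 ortholog.

"Best-matched" means highest Spearman correlation with the CAM-dicot gene —
the matching rule is a package decision, as is requiring the significant
window contrast only of the CAM-dicot gene. The *triangle network* is
stricter, as in the figure convention it reproduces: a triangle is emitted
only when both CAM genes are enriched in the same window and the C3
ortholog in the opposite window.

## The sequence screen

### Tribes by Markov clustering

Protein families ("tribes") are built by MCL on a BLASTp-style similarity
graph supplied as an edge list with E-values (BLAST itself is out of
scope). Edges above the 1e-5 E-value cutoff are discarded and weights are
−log10(E) (E floored at 1e-180). Numerical details the original procedure
leaves unstated are fixed here for determinism: self-loops weighted by each
node's maximum incident weight (1 for isolated nodes), pruning threshold
1e-8, convergence when the largest entry change drops below 1e-6, at most
100 iterations, inflation 5.0, clusters read off as connected components of
the converged matrix support.

### CAM-convergence clades

A tribe's gene tree is screened for *maximal* clades containing at least
one CAM-dicot leaf and at least one CAM-monocot leaf but no C3 or C4 leaf
("maximal": the parent clade violates the rule). Leaves of role `other`
(e.g. additional paralogs of a CAM lineage) are tolerated inside, since
real convergence clades contain paralog pairs. Species roles are free
strings declared in configuration; `cam_species_roles()` is a preset, not a
hard-coded species list. Clade membership needs a root: `find_cam_clades()`
refuses unrooted trees, and the screen midpoint-roots unrooted input with a
warning (the inference pipeline whose trees are consumed here does not
record its rooting, so midpoint is applied as the neutral default).

### Shared derived residues

`shared_substitution_sites()` reports alignment columns (1-based) where all
foreground sequences — the clade members — carry one identical non-gap
residue that no background (C3/C4) sequence carries, with at least 80% of
the background non-gap. Foreground unanimity is required because the
empirical examples show complete foreground conservation; the background
may vary internally (the classic case: a foreground aspartate against an
arginine/lysine/histidine background).

### Counting convergent substitutions

Ancestral states come from Fitch parsimony with gaps treated as missing
data. Two branches "substitute convergently" at a column when both differ
from their parent states and end in the same residue; ending in different
residues is divergent. The two branches must not share a node — adjacent
branches cannot carry independent events.

Two tie-break choices matter and are deliberate:

* *Root ties go to the majority residue* (most frequent among the column's
  non-missing leaves), then alphabetical; internal ties prefer the parent's
  state, then alphabetical. When two independent gains and one ancestral
  gain plus losses are equally parsimonious, an arbitrary (alphabetical)
  root choice can attribute a rare derived residue to the deepest ancestor
  and silently erase both substitutions from the compared branches;
  frequency-guided rooting resolves the tie toward the composition of the
  data and is deterministic.
* *Convergence is counted on a species-role reference topology*, built by
  attaching each tribe gene to its species' position in a declared species
  tree (`reference_topology()`; multiple genes of one species form a ladder
  at that tip). This is a structural necessity, not a convenience: genuine
  convergence pulls the CAM genes together in the *inferred* tribe tree, so
  inside that tree they are topological neighbours and parsimony sees a
  single origin on the clade stem. Independent origins are identifiable
  only on the topology where each CAM gene sits with its own relatives.
  The tribe tree answers criterion 1 (did the genes cluster?); the
  reference topology answers criterion 2 (did they get there by independent
  substitutions?).

A frequency null accompanies the counts: the probability that two
independent substitutions drawn from the alignment's residue frequencies
land on the same amino acid, `sum(pi^2)` (0.05 for uniform composition).
It is an interpretive yardstick for the convergent fraction among
double-substitution columns, not a significance test — the probabilistic
convergence model used for the corresponding published figure is not
described in its methods, so no reproduction is attempted.

### The sequence classifier

A CAM-dicot gene is called convergent in sequence when (1) it sits in a
CAM-convergence clade of its tribe tree, (2) the reference-topology
parsimony count between its branch and a clade CAM-monocot branch shows at
least one convergent substitution, and (3) the clade shares at least one
derived residue against the C3/C4 background. Tribes missing the required
species coverage (default: every declared species) are skipped and logged.
The published criterion 2 ("convergent amino-acid changes were detected")
does not state its method; the parsimony count here is an explicit stand-in
decision.

## Synthetic data: what is emulated, what is not

### Diel expression

Each ortholog group draws a peak phase φ ~ Uniform(0, 24) and follows a
log-scale cosinor: `FPKM(t) = exp(B + A·cos(2π(t − φ_s)/24) + ε)`,
ε ~ N(0, noise_sd) per time point and replicate. Multiplicative log-normal
noise around a cosinor mean is the minimal model that makes all three
statistics informative at once (rank correlation, window contrasts, phase
shifts). Convergent groups give both CAM species the shared phase (each
jittered) and offset the C3 species by 12 h; non-convergent groups phase
all three species together; flat groups set A = 0.

Defaults, chosen once as field-realistic: baseline log-FPKM N(2, 1)
(median ≈ 7 FPKM); amplitude N(1.5, 0.4) truncated at 0 (≈ 4- to 20-fold
peak:trough, like strongly cycling CAM transcripts); per-species phase
jitter 0.5 h sd (CAM–CAM offsets mostly within ±1.5 h, matching observed
1–1.5 h shifts); C3 antiphase offset 12 h (headline CAM examples show
9–11 h shifts); noise sd 0.2; triplicates; 10% flat groups.

What the generator does *not* emulate: read-count sampling noise,
non-sinusoidal waveforms (sharp dusk peaks, double peaks), correlated
replicates, missing data, many-to-many ortholog groups, or partially
shifted intermediates. Passing the planted-truth tests therefore shows the
screen recovers the signature it defines under clean periodic signal —
not that real transcriptomes meet these assumptions.

### Sequences

Alignments evolve on a declared eight-species tree (one CAM dicot, two CAM
monocots, three C3, two C4; branch lengths 0.03–0.12 substitutions/site)
under a Poisson process with uniform replacement among the other 19
residues — adequate for exercising parsimony and site logic, with no claim
of empirical realism (no rate heterogeneity, no indels, no substitution
matrix). Planted tribes overwrite the foreground (CAM-dicot gene + one
CAM-monocot gene) at the planted columns with a residue absent from the
background, and emit a tribe tree with the CAM-dicot gene re-grafted
sister to its partner — the topological imprint convergence leaves on
inferred gene trees. Tree inference itself is out of scope; an NJ helper
(`build_nj_tree()`) exists for experimentation but the screens consume
trees as given.

### Similarity graphs

Planted tribes get dense strong in-tribe edges (E ≈ 1e-50) and sparse weak
bridges (E ≈ 1e-3, above the 1e-5 cutoff), so after filtering the graph
decomposes into the planted partition and MCL must recover it exactly.

## Problem sizes and determinism

The validation suite runs the expression screen at 500 ortholog groups
(10% planted convergent, noise sd 0.2, triplicates), the sequence screen at
50 tribes (10 planted), the MCL recovery at 5 tribes of 6 genes, the
flat-line calibration at 2000 flat genes, and the oracle equivalences at
100+ random instances per statistic — sizes at which every check completes
in seconds on one core while leaving no stage untested. All screens are
deterministic given their inputs; every generator is a pure function of its
parameters and seed, and a seed is part of the run configuration, so
rerunning a configuration reproduces its outputs byte for byte.

## Known limitations

* The screens reproduce decision *rules*, not the published gene lists:
  those require the original multi-species genome, transcriptome and
  ortholog resources.
* The Welch/BH window test, the best-match rule, the parsimony stand-in for
  convergent-change detection, the reference-topology choice and the MCL
  numerical constants are package decisions where the source procedure is
  unstated; all are configurable or documented above.
* Fitch parsimony returns one minimum-change labelling; counts at columns
  with genuinely ambiguous reconstructions depend on the documented
  tie-breaks.
* The frequency-based convergence null ignores substitution-rate and
  exchangeability structure; treat the expected convergent fraction as a
  yardstick only.
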