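---
title: "Models and methods behind csfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind csfnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`csfnet` analyzes cerebrospinal-fluid (CSF) proteomic abundance matrices:
log2 protein abundances (rows, labeled `"UniProtAC|GeneSymbol"`) by samples
(columns), with missing values, accompanied by a per-sample trait table
(diagnosis group, age, sex, batch or center, platform). This vignette
explains each model the package implements, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-cohort tests
do and do not demonstrate about real data.

## The synthetic cohort generator

Real CSF cohorts of this design are access-controlled, so the package
treats the data-generating process itself as a first-class, tested
component. A cohort is drawn from a latent-factor model. Each planted
module $m$ has a per-sample factor $f_m \sim N(0,1)$; a member protein $i$
with loading $\lambda_i \sim U(0.4, 0.95)$ has

$$x_{is} = \mu_i + \lambda_i\,(f_{ms} + \delta_{m,g(s)}) +
  \beta_i\,\mathrm{age}_s/10 + \gamma_i\,\mathbb{1}[\mathrm{F}] +
  b_{i,\mathrm{batch}(s)} + \varepsilon_{is},
  \qquad \varepsilon_{is}\sim N(0, 0.4^2)$$

in log2 units. The first principal component of a module's standardized
members is a consistent estimator of $f_m$ under this model, which is what
makes eigenprotein and kME behavior testable: higher-loading members must
have higher kME.

Defaults are the study conditions the package targets. Group sizes, ages
and sex ratios follow the two published cohort designs
(`tmt_reference_design()`: 44/6/10/6/35 in six TMT batches with one
pooled-reference (GIS) channel each, total 101;
`dia_expanded_design()`: 72/59/43/13/22/50 across four centers, total
259). Thirteen modules are planted with sizes geometrically spaced from
384 down to 24 plus one 10-member module that deliberately sits below the
detection minimum of 15 — a built-in negative control. Group effects
mirror the ALS-like pattern: immune/glial-style modules (indices 2, 3, 7,
10) shifted up by 0.8 log2 units of factor scale in symptomatic groups,
neuronal-style modules (1, 4, 11, 12) down by 0.8, muted shifts of 0.3 for
asymptomatic carriers on modules 7 and 10, and zero effects on the rest.
Age slopes (0.1 log2/decade on 20% of proteins), sex offsets (0.2 on 10%),
per-(protein, batch) offsets ($SD$ 0.3), and MCAR (2%) plus
abundance-dependent MNAR missingness (logistic in abundance rank) complete
the picture. Within-group variance and effect sizes are not published for
the real cohorts; these values were chosen once as plausible for CSF
proteomics (per-protein variance explained by co-expression roughly
30–80%, group effects of about one pooled SD) and are deliberately not
tuned per experiment. Well-known ALS CSF markers (NEFL, NEFM, CHIT1,
CHI3L1, CHI3L2, UCHL1, GFAP, and the printed twelve-protein panel members)
are planted by name into appropriately signed modules so fixtures contain
the proteins practitioners look for.

Two design points deserve emphasis:

- **Shared truth across cohorts.** The protein-level realization
  (memberships, loadings, covariate effects) is drawn under its own
  `truth_seed`, separate from the sample-level seed. Cohorts generated
  with the same `truth_seed` but different seeds share one ground truth
  with independent samples — exactly the situation cross-cohort
  preservation assumes. Without shared loadings, intramodular connectivity
  has no reason to correlate across cohorts and preservation statistics
  lose their meaning.
- **The null design plants no modules.** `null_truth_params()` removes all
  systematic effects *and* the co-expression structure. Marginal p-values
  are uniform either way, but with planted modules left in, whole modules
  cross p < 0.05 together and the observed false-positive fraction has
  very high variance; with independent proteins it concentrates tightly
  around 5%, which is the property type-I calibration checks.

The generator emulates quantified log2 abundance matrices only — no
spectra, peptide-spectrum matching, reporter-ion interference, or
platform-specific missingness signatures. Its missingness is MCAR plus a
smooth abundance-dependent term, real DIA missingness is more structured.
Passing tests therefore demonstrate correctness of the statistical
machinery under a known model, not robustness to every artifact of real
LC-MS data.

## TAMPOR normalization

`tampor_normalize()` harmonizes batches (TMT) or centers (label-free) in
two steps. Values are first converted to log2 ratios against a per-batch,
per-protein denominator — the median of the batch's pooled-reference (GIS)
channels (`gis_denominator`) or the median over all samples in the batch
(`all_sample_denominator`). The ratio matrix then undergoes alternating
median polish: subtract per-protein row medians, then per-sample column
medians, ignoring missing values, until both residual median magnitudes
fall below `tol` (default 1e-4 log2 units, maximum 250 iterations — median
polish converges in well under 30 in practice). The global per-protein
median abundance is added back so output stays on the log2-abundance
scale. Missing values are never imputed here: medians are robust, and the
50% missingness filter runs first.

The two denominator modes are the documented axis of tunability for this
family of normalizations; the TMT-like default uses the reference
channels, the label-free default uses all samples of a center. Outside a
single-batch design, the procedure is only approximately idempotent:
re-running re-estimates per-batch medians of an already-polished matrix,
whose residual medians decompose into per-protein and per-batch constants
only up to the nonlinearity of the median, so a second pass reconverges
quickly but can move values by more than `tol`. The test suite asserts
exact idempotence on a single batch and convergence of the residual
medians in general.

One systematic consequence is worth knowing: subtracting per-sample
medians injects the (negated) median of the sample's module factors into
every protein, which induces a mild shared component (correlations around
0.2 in the default synthetic cohort) among otherwise independent
background proteins. This is inherent to median-centering any matrix whose
majority of rows carry real per-sample biology, and it is one of the
scenarios the module-detection noise floor must reject (see below).

## Covariate adjustment

`bootstrap_regress()` fits, per protein, OLS of abundance on protected
terms (diagnosis group by default) plus nuisance covariates (age centered
in years, sex, batch as treatment contrasts) over `n_boot = 200`
case-resampled complete-case datasets. Nuisance coefficients are
summarized by their bootstrap mean; the adjusted value subtracts only the
nuisance fit, never the protected terms — regressing out group would erase
the very signal later stages test. Proteins with fewer than 10 complete
cases pass through unadjusted and flagged (OLS is unstable there);
covariates constant within a protein's complete cases are dropped for that
protein with a warning; a globally rank-deficient design is an error that
names the collinear columns. The bootstrap-mean summary (rather than the
median) and the resample count are pragmatic defaults: with 200 resamples
the Monte-Carlo error of the mean coefficient is a few percent of its
standard error, making adjustment idempotent to within ~0.05 log2 units.

## Differential abundance

`anova_bh()` computes equal-variance one-way ANOVA per protein on the
non-missing values of the groups in each requested comparison. For two
groups this equals the squared pooled-variance t statistic, which the test
suite verifies to 1e-10. Benjamini–Hochberg correction is applied across
all tested proteins *within one comparison* — the correction family the
figure-style output implies. The direction call (`up`/`down`/`ns`) uses
raw p against `alpha = 0.05`, matching the volcano-plot convention of
coloring nominally significant proteins; q-values are reported alongside.
Two-group p-values are computed on the two groups only, not as post-hoc
contrasts of a six-group fit: per-figure sample counts are what the
published legends state. Proteins with fewer than two observations in
either group are reported untested rather than silently dropped.

Cross-platform concordance (`effectsize_concordance()`) restricts to
proteins with p < 0.05 in both comparisons, correlates the log2
differences by bicor with a Student-t p-value at $n-2$ degrees of freedom,
and counts sign-agreement quadrants.

## The signed network

All correlation in the network stage is the biweight midcorrelation:
center at the median, scale by nine times the unscaled MAD, weight by
Tukey's biweight $(1-u^2)^2$ for $|u|<1$. With `max_p_outliers = 0.05`
each side of $u$ is rescaled so at most 5% of observations per side can be
zero-weighted, which keeps the estimator defined for skewed vectors.
Zero-MAD variables fall back to Pearson for all their pairs. Missing data
are handled pairwise-complete via masked cross-products (three matrix
multiplications, so a 2,000-protein matrix takes seconds); entries with
fewer than 4 shared observations are set to 0 and rows with fewer than 4
observations are excluded with a warning.

Adjacency is signed, $a_{ij} = ((1+\mathrm{cor}_{ij})/2)^\beta$ with
$\beta = 4$: anticorrelated proteins get adjacency near zero instead of
being conflated with correlated ones. The topological overlap measure

$$\mathrm{TOM}_{ij} = \frac{\sum_{k \ne i,j} a_{ik}a_{kj} + a_{ij}}
 {\min(k_i, k_j) + 1 - a_{ij}}$$

smooths adjacency by shared neighborhoods; `1 - TOM` is the clustering
dissimilarity.

**Module detection** re-implements the dynamic-hybrid branch cut on the
average-linkage dendrogram. A subtree is a *distinct branch candidate* if
(a) it has at least `min_module_size = 15` members, (b) its mean
within-branch dissimilarity, normalized to the tree's height range, is
below a scatter ceiling mapped from `deep_split` 0–4 (0.64 → 0.95), and
(c) it joins its sibling at least an absolute cohesion gap above its own
top height, with the gap ladder 0.16/0.08/0.04/0.02/0.01 TOM-dissimilarity
units for `deep_split` 0–4. A candidate is accepted whole when its deepest
internal height gap (computed over subtrees of at least half the minimum
size, so that tight sub-minimum cores cannot hide) shows no further
separable structure; otherwise detection descends into it. The absolute
gap is the noise floor: on unstructured data — including the
median-polish-induced equicorrelated background described above —
dendrogram gaps measure an order of magnitude below 0.01, so nothing is
called a module there, while planted structure produces gaps of 0.1 and
more. The optional PAM stage assigns each leftover protein to the module
with the nearest medoid, but only within that module's member-to-medoid
radius, so isolated noise is never swept in. All ties break
lexicographically; the stage is fully deterministic.

Because TOM normalizes by total connectivity, small modules can be masked
by the aggregate background in a 2,000-protein matrix even when their
internal correlation is strong. `build_network()` therefore detects in
*extraction rounds*: after a round's modules are set aside, adjacency and
TOM are recomputed on the remaining proteins and detection repeats until
nothing further emerges. On the default cohort the first round finds the
nine largest planted modules and the second round recovers the three
smallest exactly, with no background contamination; a third round finds
nothing. This recovers resolution without touching any threshold.

Modules whose eigenproteins correlate above `1 - merge_cut_height`
(default 0.07) merge iteratively, eigenproteins recomputed after each
merge; final labels are ranked M1..Mk by decreasing size. Eigenproteins
are the standardized first right-singular vectors of the z-scored member
rows (residual missing values median-imputed for the decomposition only),
sign-aligned so mean member correlation is positive. kME is the bicor of
each protein with each eigenprotein — the same estimator as the network,
for internal consistency, although product-moment kME is common elsewhere.

This is a faithful re-implementation of the published algorithm's core,
not a clone of any particular implementation: exact agreement with other
packages' many undocumented knobs is out of scope, and recovery of planted
structure (adjusted Rand index, assignment fraction, negative controls) is
the correctness standard throughout the tests.

## Module association and enrichment

Eigenprotein–trait association subsets to one disease group plus controls
at a time, codes the trait 0/1, and uses bicor with the Student-t p-value;
star annotations use raw p at 0.05/0.01/0.001 as figure legends
conventionally do, with BH q reported alongside. Asymptomatic carrier
groups are treated as their own traits. Eigenprotein ANOVA tests each
module across all diagnosis groups with BH across modules.

Fisher enrichment is one-tailed (upper hypergeometric tail — enrichment
only), with the background fixed to the detected network proteins' gene
symbols rather than the genome: CSF detectability is itself a strong
filter, and testing against the genome would call nearly everything
enriched. Sets are intersected with the background and skipped outside
5–1000 members; odds ratios use a 0.5 continuity correction when a cell is
zero; BH applies across all (module, set) pairs of a collection. Gene
symbols come from splitting ids at the pipe; ids without a symbol are
dropped and counted.

## Cross-cohort preservation and synthetic eigenproteins

`module_preservation()` computes, per module, on the proteins shared with
the test cohort: density (mean off-diagonal signed adjacency in the test
network), the correlation between reference and test intramodular
connectivity vectors, and the correlation between reference and test
pairwise correlation entries. The null draws `n_perm` same-size protein
sets uniformly from the shared proteins; each statistic is standardized to
$Z = (\mathrm{obs} - \mu_0)/\sigma_0$, `Z_density` is the density Z,
`Z_connectivity` the median of the two connectivity Zs, and
`Z_summary` their mean, with `median_rank` as the size-insensitive
companion. This is a reduced, documented statistic set with the published
compositional rule; the guide thresholds carry over (Zsummary > 10 strong,
2–10 moderate, `zsummary_significance()` maps Z to its normal tail).

A caveat the tests document: in a cohort where most proteins belong to
preserved modules, random null sets also contain preserved structure, so
the connectivity nulls are themselves high and `Z_connectivity` is a weak
(sometimes slightly negative) signal; density carries most of Zsummary.
The decisive contrasts hold regardless — regenerated cohorts score
Zsummary well above 10 for every planted module of 30+ proteins, a
targeted ablation (shuffling one module's test-cohort profiles) drives
that module below 2 while others stay high, and random protein sets score
within the null band.

Synthetic eigenproteins project reference modules into a second cohort
without rebuilding the network: members are ranked by reference kME, the
top 20% (minimum 4, extending down the ranking when hubs are missing from
the test cohort) are taken, and the synthetic eigenprotein is the first
principal component of the standardized hub rows in the test matrix. On
identical data, synthetic and native eigenproteins correlate above 0.9 for
every module, which is the factor-model prediction.

## Biomarker panels

`select_top_daps()` takes the top k = 12 proteins by ascending ANOVA p,
ties broken by larger |log2 difference| then protein id — a pure function
of the DAP table, hence byte-reproducible. Panel PCA z-scores the panel
rows (PCA without scaling would be dominated by variance outliers),
excludes samples missing more than half the panel, and reports two
components with per-group centroids ± SE. Two-way hierarchical clustering
(Euclidean on z-scores, average linkage) cuts the sample tree at exactly
two classes and tabulates group composition per class, supporting
"ALS-enriched" vs "control-enriched" statements.

## Orchestration, determinism, problem sizes

`run_pipeline()` executes simulate → filter → TAMPOR → outlier screen →
bootstrap regression → differential abundance → network (reference
cohort) → association → enrichment → preservation and synthetic
eigenproteins (into the expanded cohort) → panels, writing every table and
a JSON manifest (stage, outputs, parameters, row counts). Configuration is
a validated list or YAML file; unknown keys and missing input paths fail
before any computation. One master seed drives everything; each stochastic
stage derives a child seed from (seed, stage name), so stages are
independently reproducible and a fixed seed makes the whole run
byte-identical — asserted file-by-file in the tests.

The test suite exercises the full study scale once (two cohorts of 2,000
proteins × 101 and 259 samples through the entire pipeline, preservation
at 200 permutations) and otherwise uses cohorts of a few hundred proteins;
the acceptance script runs preservation at the full 500 permutations.
These sizes were chosen so the whole suite completes in minutes on one
CPU while still covering the scale the methods target.

## Known limitations

- The dynamic-hybrid cut matches the published algorithm in spirit and in
  planted-structure behavior, not knob-for-knob; deepSplit values map to
  this implementation's scatter/gap ladders.
- TAMPOR mode semantics beyond the denominator choice (reference channels
  vs all samples) are not modeled.
- Preservation uses three statistics, not the full published set; only
  Zsummary and median rank are reported.
- The generator's missingness and batch models are simple; conclusions
  about robustness to real LC-MS artifacts require real data.
- No continuous clinical covariates (e.g. disease duration) are modeled in
  the association stage; group membership is the only trait.
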