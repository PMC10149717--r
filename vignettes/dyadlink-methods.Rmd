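---
title: "Methods: dyadic analysis of milk and infant gut microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic analysis of milk and infant gut microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dyadlink)
```

`dyadlink` studies the link between a mother's milk microbiome and her
infant's gut microbiome from paired, longitudinally collected 16S ASV
tables. This vignette documents the models, the parameters that matter, the
synthetic-cohort generator used to validate every stage, and the numerical
and design choices a maintainer should know about. Nothing here states an
empirical result beyond what the package's test suite and
`scripts/acceptance.R` compute themselves.

## The data model

The universal input is an integer ASV count matrix with **samples as rows**
(orientation is fixed by contract; silently transposed inputs are a classic
microbiome bug, so no auto-detection is attempted), sample metadata with a
closed visit vocabulary (6w, 4m, 6m, 9m, 12m), and a rooted phylogeny over
the ASVs. Samples with fewer than 1,000 reads are removed before analysis
(strictly fewer: a sample at exactly the threshold is kept). ASVs missing
from the tree are an error, never silently dropped — with denoised ASVs and
a tree built from them this should not occur, so silence would only hide an
upstream mistake.

Within a dyad, a milk sample is paired with every stool sample collected at
the same or a later visit, never earlier; a dyad observed at several
timepoint pairs contributes one record per admissible pair. An alternative
nearest-preceding-milk mode keeps a single milk sample per stool sample.

## Generalized UniFrac and ordination

Between two samples the generalized UniFrac distance weights each branch by
its length and an $\alpha$-power of the total subtree abundance; branches
unoccupied by both samples are excluded from both sums (the 0/0
convention). $\alpha$ interpolates between presence-weighted ($0$) and
abundance-weighted ($1$) variants; the default $\alpha = 0.5$ moderately
weights rare and abundant lineages, the standard choice when typing
communities. Counts are converted to within-sample proportions without
rarefaction: the distance only sees relative abundances, and discarding
reads would only add noise. Subtree proportions are accumulated in one
post-order pass; the test suite checks the result against an independent
brute-force descendant-set enumeration to 1e-10, and the $\alpha = 1$ case
against a separately derived weighted-normalized formulation.

Ordination is classical scaling (double-centering + eigendecomposition).
Community dissimilarities need not be Euclidean, so negative eigenvalues
can appear: they are retained in the eigenvalue report but never yield
coordinates — axes come from positive eigenvalues only.

## Microbiome typing

Types are k-medoids clusters of the distance matrix (PAM operates natively
on dissimilarities; there is no need to go through an embedding first).
Two implementation notes:

- **Exactness.** Single-swap local search (BUILD+SWAP) can terminate in a
  local optimum — verified directly: on a few percent of small random
  instances both this package's BUILD+SWAP and the reference
  `cluster::pam` return the same suboptimal medoid set. `pam_cluster()`
  therefore enumerates all medoid sets whenever
  $\binom{n}{k} \le$ `exact_budget` (default 2,000) and falls back to
  BUILD+SWAP above it. Both paths are deterministic, with ties broken
  toward lower indices.
- **Choosing k.** The number of types is an explicit analyst input: the
  defaults (milk 3; all-stool 6; 6-week stool 4; 12-month stool 2) mirror
  the typing structure commonly reported for these compartments, and the
  mean silhouette width is attached as the quantitative surrogate for
  "least overlap on the ordination plot". The gap statistic is provided as
  a diagnostic; its reference datasets are drawn uniformly over the
  bounding box of the PCoA embedding (distances, not raw features, are the
  primitive), with within-cluster dispersion
  $W_k = \sum_r \frac{1}{2 n_r} \sum_{i,j \in C_r} d_{ij}^2$. The
  suggested k uses the `globalSEmax` rule: the classical
  one-SE-of-the-next rule fires at $k = 1$ whenever clusters are separated
  enough that the gap curve is flat below the true k (measured here:
  on three clouds 30 sigma apart the gap curve is
  $(-0.6, -0.7, +3.7, \ldots)$, and the classical rule stops at the first
  flat step), while `globalSEmax` recovers the planted k on both that
  geometry and a single uniform cloud.

Diversity differences between clusters use the Kruskal–Wallis rank-sum
test; the degenerate all-tied case is reported as $H = 0$, $p = 1$ rather
than NaN.

## The dyad overlap statistic and its null

For a stool sample with counts $c_j$ and the paired milk sample's detected
ASV set $M$ (presence = count at least 1; a `min_presence` knob exists but
no minimum beyond detection is imposed by default), the overlap is
$\sum_{j \in M} c_j / \sum_j c_j$ — the fraction of infant gut reads
attributable to ASVs seen in the mother's own milk. Its null distribution
comes from shuffling the milk–stool pairing across dyads at one visit.
Shuffles are restricted to derangements (no stool keeps its true milk):
"random dyads" that occasionally include true pairs would dilute the very
contrast being tested. The number of draws and the derangement restriction
are both exposed as parameters. Observed and null distributions are
compared with the two-sample Kolmogorov–Smirnov test (asymptotic p; the
pooled null is large, so exact small-sample corrections would be
inconsequential).

Covariate effects on the overlap are estimated on the percentage-point
scale (0–100) with a linear mixed model carrying a random intercept per
dyad, since dyads recur across timepoint pairs. Satterthwaite degrees of
freedom give the p-values; the alternative degrees-of-freedom recipes
differ only in small-sample dof bookkeeping, and the estimand — direction
and magnitude of each coefficient — is unaffected. Records with missing
formula status (an explicit `"missing"` category, mirroring real cohort
reporting) are dropped only from models that include formula exposure.
When every dyad contributes a single record there is nothing repeated and
the model degrades to ordinary least squares.

## Stability scoring

A subject's switching degree counts distinct cluster memberships across
visits — 0 (one type), 1 (two), 2 (three or more) — not transitions:
membership, not adjacency, is the question. Twelve-month stool samples are
excluded from stool stability by default (they cluster apart from earlier
visits and would inflate apparent switching); a flag restores them.
Predictors are screened univariately (Kruskal–Wallis for continuous,
Fisher's exact for categorical; retained at p < 0.1) and then enter a
multinomial logit with degree 0 as reference, adjusted for the age at the
last collected sample, which otherwise confounds switching opportunity.
Complete or quasi-separation is reported with an instability flag on any
odds ratio whose log-scale CI spans more than 10 units — wide, honest
intervals rather than silent penalization.

## Cross-compartment association

Milk-type × stool-type tables are tested with Fisher's exact test,
implemented as a full enumeration over margin-fixed tables (probability
ordering, with the same 1e-7 relative tolerance the standard
implementation uses; every enumeration asserts the table probabilities sum
to 1 within 1e-9) and a Patefield Monte-Carlo fallback with the
$(n\hat p + 1)/(n + 1)$ estimator above an enumeration budget. Any
association — overall or within a stratum — is only tested with at least
10 dyads; smaller strata are skipped and logged, never silently absent.

Community-level concordance uses the Mantel test (Pearson correlation of
off-diagonal dissimilarities; one-sided greater alternative, the
convention for positive concordance), with 10,000 permutations by default
and $p \ge 1/(n_{\text{perm}}+1)$. Confounding is addressed by a partial
Mantel test against a third distance matrix built from covariates:
categoricals binary-coded (one indicator per non-reference level,
missingness as its own level), continuous covariates standardized,
Euclidean distance. A constant covariate matrix carries no information and
falls back to the plain test with a warning. The Mantel correlation is
also echoed as `z_statistic` in reports for traceability against analyses
that label it that way.

The taxa-level screen keeps, per sample type and visit, only taxa whose
relative abundance exceeds 0.5% in strictly more than 10% of subjects
(both inequalities strict — a taxon at exactly either boundary is
removed), then computes Spearman correlations for every milk–stool taxon
pair with Benjamini–Hochberg q-values over the pair family of one
(sample-type, timepoint-pair) table and a q < 0.1 significance flag.
Mean-centering/scaling of relative abundances is a no-op for a rank
statistic, so it is documented rather than recomputed. BH is the default
q-value (the convention of the surrounding ecosystem; the screen's purpose
is ranking); a Storey-type variant with the $\lambda = 0.5$ null-proportion
estimate sits behind `qvalues(method = "storey")`.

## The synthetic cohort generator

The generator emulates exactly the structure the analysis assumes — it is
test scaffolding with controllable truth, not a claim about any real
cohort:

- Each compartment has a small number of community **archetypes**: sparse
  profiles supported on a random quarter of the ASVs
  (`archetype_support_frac = 0.25`), with within-archetype variation
  controlled by a Dirichlet precision (default 50). Subjects keep their
  archetype across visits except for a per-visit switch probability
  (default 0.2).
- A stool composition is a mixture: a fraction $s'$ from the paired milk
  community (restricted to ASVs actually detected in the generated milk
  sample, so sequencing depth realistically attenuates observed sharing —
  transfer acts on compositions, not resampled reads, which keeps the
  expected overlap analytically controllable) and $1 - s'$ from the stool
  archetype. $s'$ is the baseline `transfer_fraction` plus additive
  covariate shifts (cesarean +0.10, male +0.10, formula −0.13 — the
  simplest monotone encoding) plus dyad-level Gaussian noise
  (sd 0.05), clipped to [0, 1] and recorded in the truth slot.
- Defaults are fixed once as study conditions: 150 dyads, 300 ASVs,
  baseline transfer 0.30, visit-inclusion probabilities
  (6w = 1, 4m/6m/9m = 0.12, 12m = 0.7) reproducing a design dominated by
  the 6-week and 12-month visits with sparse intermediate sampling, and
  lognormal depths (meanlog = log 60,000, sdlog = 0.7) of the order of
  real milk/stool median depths. At these settings the median overlap is
  roughly 45–50% for true pairs versus 25–30% under random pairings.
- Covariates are drawn at realistic prevalences (27% cesarean, 52.9% male,
  13% formula-fed with 14% missing, 20% prenatal antibiotics).

What the generator does **not** emulate: taxonomy with real names,
contamination, strain-level transmission, diversity maturation with age,
or longitudinal autocorrelation beyond archetype persistence. Tests that
pass on these cohorts therefore validate the statistical machinery — its
calibration, power and recovery under known truth — not the biology of any
particular cohort.

## Validation studies and their sizes

The test suite runs simulation studies at sizes chosen for tight
replication (all fixed up front; per-test seeds are fixed too):

- Type-I calibration: 500 independent global-null cohorts (40 dyads, 80
  ASVs, transfer 0, no covariate effects, archetypes independent of dyad);
  Fisher type association and Mantel are held to rejection rates in
  [0.03, 0.07] at $\alpha = 0.05$. The K-S true-versus-random comparison is
  *conservative* by construction (measured rejection ~0.003 at nominal
  0.05): the observed and null overlap sets are computed from the same
  milk and stool samples, so their ECDFs are positively correlated and the
  two-sample K-S test, which assumes independent samples, under-rejects.
  This is a property of the published design, not of this implementation
  (verified by swapping in a null built from an independent cohort, which
  removes the sharing); its practical consequence is that significant K-S
  results are trustworthy while null results are weak evidence of absence.
- Power and recovery: 100 cohorts of 100 dyads at transfer 0.6 for the K-S
  test (p < 0.01 required in at least 95), and 100 two-visit cohorts with
  milk and stool archetypes on disjoint ASV blocks for mixed-model
  recovery of a planted +0.10 cesarean shift. The disjoint-support design
  makes the observed overlap equal the realized transfer fraction, so the
  +10 percentage-point estimand is exact; with shared supports the
  baseline random overlap attenuates the marginal effect and the planted
  shift would not equal the regression coefficient.
- Oracle equivalence: 100 random tree/sample instances for generalized
  UniFrac; 100 fuzz instances for k-medoids optimality; exhaustive
  enumeration cross-checks for the exact contingency test.
- Reproducibility: the full pipeline run twice at one seed must produce
  byte-identical output files; the global seed is expanded into fixed
  per-stage streams so stages are also individually reproducible.

## Known limitations

- The mixed models use Satterthwaite (not Kenward-Roger) approximations;
  at these cohort sizes the difference is negligible, but very small
  stratified analyses would deserve care.
- The gap statistic's reference distribution lives in PCoA space; with
  strongly non-Euclidean dissimilarities (large negative eigenvalues) the
  reference box can misrepresent the data's support.
- The exact contingency enumeration is exponential in table size; large
  sparse tables are delegated to the Monte-Carlo path by design.
- Overlap is read-attribution by shared ASV presence; it is not source
  tracking and carries no mixture-model uncertainty.
- The K-S comparison of true versus random pairings is conservative under
  the null (see the calibration note above); interpret non-significant K-S
  results accordingly.
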