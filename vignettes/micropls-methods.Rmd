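---
title: "Methods: compositionally robust multilevel sparse PLS and association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositionally robust multilevel sparse PLS and association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropls)
```

## The problem

Longitudinal microbiome studies of host metabolic disease follow the
same subjects (here, mice under sub-therapeutic antibiotic treatment and
a mid-study switch from normal chow to a high-fat diet) across weeks,
measuring a 16S OTU count table alongside host phenotypes: body fat,
bone mineral content, lean mass, dry mass index, weight, next-timepoint
weight, and an end-of-life liver (NAFLD) score. Three statistical
hazards dominate: counts are *compositional* (only relative information
survives sequencing), the design is *repeated-measures* (stable
between-subject differences swamp perturbation effects), and features
are *high-dimensional and collinear*. The pipeline addresses the three
in order: centered log-ratio transform, within-subject variance
decomposition, and sparse partial least squares with stability-based
model selection.

## Compositional preprocessing

OTUs present in fewer than 10 % of all samples are discarded; the
boundary is strict, so an OTU present in exactly 10 % survives. A single
pseudo-count is added to every raw count before the clr transform,
`clr(c)_ij = ln(c_ij + 1) − mean_j ln(c_ij + 1)`, which maps each sample
into a zero-sum real vector and removes the arbitrary scale of library
size. The pseudo-count is applied to counts, not relative abundances;
the two readings differ only by a per-sample constant that the clr
removes when the pseudo-count scales with depth, and the counts reading
keeps the arithmetic exact. Rarefaction (used only by the
random-forest classifier, at 1000 reads/sample) is a without-replacement
multivariate hypergeometric subsample; samples below the target depth
are dropped with a logged list.

## Within-subject decomposition

Each sample belongs to a cell = (subject, diet period), the period being
the subject's series cut at the diet-switch week. The decomposition

  within = x − mean(cell),  between = mean(cell) − grand mean

is exact (centered x = within + between to machine precision) and
orthogonal, so column variances add. Treatment arm never varies within a
subject and is therefore absorbed — together with cage, sex and other
subject-constant factors — into the between part; this is the
fixed-effect-free analogue of a linear mixed model, extended to
multivariate responses. Responses are decomposed with the identical
operator. Cells with a single sample contribute zero within-cell rows
and are flagged. An alternative reading of the two-factor scheme
(subject-only centering with diet as a within-part covariate) is
available by passing a constant `diet` label; it is exposed, not
endorsed.

## Sparse PLS and its selection

The regression couples within-subject clr features `X` (n x p) to
within-subject phenotypes `Y` (n x q, centered and scaled). Per
component, the dominant left singular vector `u` of the running
cross-covariance `X'Y` is soft-thresholded at `eta * max|u|`, normalized
to a direction `w`; scores `t = Xw` deflate both blocks. K = 7
components are fit (or fewer when the cross-covariance rank is
exhausted, with a warning). `eta = 0` reproduces dense PLS, and at full
rank the coefficients converge to the least-squares fit; both are
asserted in the tests. The support is per OTU: any nonzero weight row.
This soft-thresholded-SVD variant was chosen because the sparse-PLS
literature the approach descends from admits several variants and this
one makes the per-OTU support (the object of inference) explicit.

**Stability selection.** The model is rebuilt over 50 random subsets of
*subjects* (never of samples — repeated measures must move together)
across an eta grid of 0.05–0.95 in steps of 0.05. For each OTU and eta
the selection frequency theta gives the instability `xi = 2 theta (1 −
theta)`, averaged over OTUs into D(eta). D is monotonized by a running
maximum along the path from the sparsest model toward denser ones, and
the least-sparse eta whose monotonized D stays within the variability
threshold (default 0.001, i.e. 0.1 %) is selected. Two numerical
choices deserve note:

* *Subset size.* The usual prescription `10 sqrt(S)` exceeds the cohort
  for any study with at most 100 subjects, and a "subset" equal to the
  full data has zero instability by construction, which silently
  degrades the selection into tie-breaking. Below 145 subjects the
  fraction is therefore 0.8, the standard small-sample convention.
* *Fallback.* The dense end of the path is trivially stable (everything
  is always selected), so when no eta meets the threshold — routine at
  a 0.1 % threshold with a few hundred OTUs, where the entry/exit
  flicker of even one OTU exceeds it — the sparsest (most stable
  non-trivial) model is returned, flagged via `threshold_met = FALSE`.
  Returning the densest model instead would report an unselected,
  unstable support as if it were a selection.

**Significance.** With the selected support fixed, dense PLS models are
refit over subject-level bootstrap resamples (default 2000); the
coefficient estimate is the bootstrap median (the original-fit
coefficient is available via `statistic = "original"`). The null
distribution permutes the subject-to-response assignment (whole response
blocks, preserving the repeated-measures structure) and refits; the
two-sided empirical p-value uses the add-one rule, so p is never 0 and
its floor is 1/(B_null + 1). Significance is declared at alpha = 0.01
per (OTU, phenotype) pair without further multiplicity correction — the
two-stage design (stability selection, then testing only the selected
support) is itself the error control. On null cohorts the pooled
p-values are uniform (Kolmogorov–Smirnov, asserted in the tests).

## Clustering of latent scores

Samples are clustered on their K-dimensional sPLS scores with finite
Gaussian mixtures (EM initialized by model-based agglomerative
clustering, as implemented in mclust), choosing covariance family and
cluster count by BIC = 2 loglik − npar log n. The family list spans
spherical, diagonal, tied-full, ellipsoidal equal-orientation (VVE, the
family selected in the motivating study) and full covariances. Hard
assignments (argmax responsibility) feed the downstream stages.
Transition diagrams tally cluster moves between successive available
weeks per subject; between-cluster edges seen fewer than 6 times are
dropped, while self-loops are reported separately. Cluster-assignment
stability is reported by seed replication (ARI across seeds); no claim
is made that this equals a bootstrap validation.

## Association networks

Within each cluster's sample set the clr is recomputed (composition is
cluster-local) and a signed microbial association network is estimated
by neighborhood selection: an L1-penalized regression of each
standardized clr column on all others, an edge wherever either direction
is nonzero (OR rule; AND available), signed by the larger-magnitude
coefficient. The penalty path has 30 log-spaced values from the largest
absolute off-diagonal correlation down to 1/100 of it. StARS selects the
densest graph whose monotonized edge instability stays within the
variability threshold. The default threshold is 0.0005 (the literal
per-mille reading); the conventional 0.05 is accepted via the
`threshold` argument and is what the recovery tests and the pipeline
use, because at p of a few dozen nodes the per-mille threshold is below
the resolution of 50 subsamples (a single flickering edge among 1225
pairs already exceeds it) and no graph on the path can qualify. The
report names the value used.

## Network topology

Per-node counts of the 15 orbits of connected graphlets on at most four
nodes are computed by exact enumeration of connected 3- and 4-subsets
(each subset visited once, classified by its induced degree sequence;
orbits within a graphlet are numbered by increasing degree). Four orbits
(3, 12, 13, 14) are determined by the others through counting
identities, leaving the 11-orbit non-redundant signature; the identities
are verified exactly in the tests. The graphlet correlation matrix is
the Spearman correlation of the 11 orbit counts across nodes with a
single all-ones dummy row appended (so orbits constant across nodes stay
well-defined; columns still degenerate after the dummy row correlate as
0). The graphlet correlation distance is the Frobenius norm of the
upper-triangle difference — a pseudometric on signatures: identity and
symmetry hold exactly, the triangle inequality is checked empirically
but not asserted. Networks embed into 2-D by classical (Torgerson) MDS
with a sign convention fixing the first network's quadrant.

Robustness is scored by natural connectivity, `ln(mean(exp(lambda_i)))`
over adjacency eigenvalues (log-sum-exp guarded; an edgeless graph
scores 0; edge signs are ignored — the spectral measure needs a simple
graph). Attack curves remove nodes uniformly at random (averaged over 50
repetitions), by degree, or by betweenness centrality, recomputing the
target ranking after each removal by default (a static mode is exposed);
the full-graph spectrum is used after fragmentation since the definition
does not require connectedness. Keystones are ranked by the sum of
degree rank and betweenness rank, ties broken by betweenness then node
id. Summary statistics (diameter of the largest component, mean degree
and betweenness, greedy modularity, phylum assortativity) use igraph.

## Maturity and disease classification

A random-forest regression of age on relative abundances is trained on
control samples only (1000 trees, ceil(d/3) variables per split), and
microbiota age is predicted for every sample — out-of-bag for training
controls, so the control statistics below are not optimistic. Per age
bin (= sampled week; a width parameter accommodates irregular designs):

  MM  = predicted age − median(control predictions in bin)
  MAZ = MM / SD(control predictions in bin)

Control MM medians are exactly zero by construction; bins with fewer
than two controls, or zero SD, flag their samples. Whether the original
analysis used out-of-bag control predictions is not documented; they
are used here to avoid optimism.

Disease classification (label = NAFLD flag OR insulin-resistance flag)
fits one random forest per sampled week on tables rarefied to 1000
reads/sample, repeated over 10 independent rarefaction trials; model
error is leave-one-out misclassification, skipping weeks where a class
has under two members. OTU importance is the mean increase in
leave-one-out error (in %) when the held-out sample's value for that OTU
is replaced by a random training draw — a permutation importance
evaluated on genuinely held-out predictions rather than the forest's
internal estimate.

Host scoring is exact arithmetic: HOMA-IR = glucose x insulin / 405,
elevated strictly above 13.2; insulin resistance = at least 2 of
{elevated HOMA-IR, impaired IPGTT, impaired IPITT} (the tolerance-test
impairments are clinical judgments taken as inputs — no numeric rule is
invented for them); NAFLD = activity score strictly above 5 with
fibrosis; censored glucometer curves clamp at 500 mg/dL (GTT) and 20
mg/dL (ITT rescue). "Weight + 1" is the subject's next later weight
measurement by order, not spacing.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design: two arms (control /
STAT) of 20 subjects each, sampled at weeks 4, 11, 16 and 30 with every
subject switching NC to HFD at week 13; 200 OTUs by default. Latent
log-abundances are baseline + subject random effect (sd 0.5) + sparse
treatment effect (20 OTUs, ±1) + sparse diet effect (20 OTUs, ±1) + age
trend (20 OTUs, ±0.15/week) + correlated Gaussian noise whose covariance
is the inverse of a planted precision matrix (chain, hub or
Erdős–Rényi pattern, unit-diagonal covariance, condition number
adjusted by a uniform diagonal shift). Counts are multinomial draws with
lognormal library sizes (meanlog log 2e4, sdlog 0.3) — the
logistic-normal multinomial, chosen because the clr-based inference
downstream assumes log-ratio Gaussian structure, which makes
parameter-recovery tests well-posed. Phenotypes are linear in the latent
abundances of 10 planted OTUs (each tied to 3 of the 6 base phenotypes
with coefficients ±1), plus a subject effect (sd 1) and noise (sd 0.5);
"Weight + 1" derives from an auxiliary post-study weighing so the last
sampled week keeps a successor. Sex is simulated but given no effect
(the sexes were pooled for community analysis). The generator returns
the planted support, precision matrix, age taxa and coefficients for
recovery testing, and is bitwise reproducible given its seed.

What the generator does *not* emulate: taxon-specific mean-variance
relationships beyond the logistic-normal, read-level sequencing noise
and chimeras, phylogenetic correlation between taxa, and drift in
library-size protocols. Passing recovery tests therefore demonstrates
correctness of the estimators under the model they assume, not
performance guarantees on arbitrary real data.

## Problem sizes and numerical choices

The test suite runs the full recovery battery at deliberately modest
sizes — the default 40-subject / 200-OTU cohort for support recovery
(median precision and recall over 10 seeds), 50 small null cohorts for
calibration, chain networks at p = 50 / n = 500, six planted 7-D
ellipsoidal clusters at n = 240, graphs of at most 8 nodes for the
exhaustive graphlet oracle — so the whole suite completes in a few
minutes on one CPU. Tolerances follow the quantity: exact integer
equality for orbit counts, 1e-9 for spectral quantities, 1e-10 for the
decomposition identity, and distributional checks (KS at 0.01, binomial
SE bands) for stochastic outputs. Ties in targeted attacks and keystone
ranking break deterministically (first index / betweenness / node id) so
runs are reproducible; all randomness flows through explicit seeds, and
each pipeline stage derives its seed from the master seed plus a fixed
stage offset.

## Known limitations

* The sPLS variant fixes one of several reasonable sparse-direction
  constructions; coefficients are reported on the standardized-response
  scale.
* StARS at per-mille thresholds is under-resolved below ~1000 features
  or pairs; the flagged fallback and the configurable threshold are the
  supported remedies.
* The GMM family list covers the major covariance shapes but not the
  full 14-family taxonomy; the ellipsoidal equal-orientation family is
  included.
* Graphlet analysis ignores edge signs and weights.
* The permutation null for significance permutes whole subjects; with
  grossly unbalanced designs it falls back to sample-level permutation
  and exactness degrades.
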