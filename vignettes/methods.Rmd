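---
title: "Natural clusters of binary checklist items: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Natural clusters of binary checklist items: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandclust)
```

## What the pipeline estimates

Given a subjects × items table of yes/no responses, the question is which
items co-occur strongly enough to form stable, interpretable groups. The
pipeline treats this as *variable-mode* clustering: the objects being
clustered are the items, and the distance between two items is one minus
their mean squared contingency coefficient

$$\varphi^2 = \frac{(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)} = \chi^2/n \in [0,1],$$

computed from the $2\times2$ cross-table of the pair over subjects observed
for **both** items (pairwise deletion). Using the squared coefficient rather
than signed $\varphi$ is deliberate: the named coefficient is the squared
mean contingency, it is bounded in $[0,1]$ so $1-\varphi^2$ is a valid
dissimilarity, and the clustering question is about strength, not direction,
of association. The cost is that negatively associated items look similar to
positively associated ones — a caveat that applies equally to the factor
analysis step, which also runs on the $\varphi^2$ matrix (a similarity, not a
signed correlation matrix; the run report records this note).

## Tunable parameters that matter

| parameter | default | why |
|---|---|---|
| `sections` | 3, 5, 7 | the behavioural / academic / neuropsychological sections of the motivating instrument; yields 29 binary items |
| `min_pairs` | 2 | pairwise deletion must never compute $\varphi^2$ from an empty or single-observation overlap |
| dissimilarity form | $1-\varphi^2$ | monotone in $\varphi^2$, so the merge *order* of every linkage is unaffected by the alternative $\sqrt{1-\varphi^2}$ (exposed for sensitivity checks) |
| clustering `method` | `ward_d2` | Ward minimises within-cluster variance increase; the d² variant is the conventional reading of "Ward's method" (see below) |
| `k` | 7 | a *configured* judgement, not an estimate: the silhouette diagnostic is printed alongside but never overrides it |
| bootstrap `B` | 1000 | subject resamples; co-membership proportions have s.e. $\le \tfrac{1}{2\sqrt{B}} \approx 1.6\%$ |
| EFA `m_range` | 4–7 | the a-priori factor-count window the analysis compares |
| loading `cutoff` | 0.35 | display threshold, strict inequality |
| `t_within`, `r_ratio` | 0.10, 2.0 | integration rule: flag an item whose own-cluster co-membership mean is `< 0.10` while another cluster attracts it at `>= 2×` that strength |

## Numerical and design choices

**Ward variant.** Base R's `hclust` exposes `ward.D` (Lance–Williams Ward
coefficients applied to the dissimilarities as given) and `ward.D2` (applied
to squared dissimilarities, heights square-rooted). The method description in
the source literature says only "Ward's method", so both are implemented;
`ward_d2` is the default and the variant is recorded in every output.

**Tie-breaking.** When several pairs share the minimal inter-cluster
distance, the pair with the lexicographically smallest (min leaf index, max
leaf index) merges first. Floating-point distance ties are rare on real data
but common in tests and degenerate inputs; a fixed rule makes every tree
reproducible across platforms. Cluster indices of a cut are assigned by order
of first-appearing leaf for the same reason.

**Own linkage implementation.** Agglomeration, DIANA and FANNY are
implemented in the package rather than delegated, because the deterministic
tie-break above is part of the contract and because the test suite proves the
implementation against a *from-definition* oracle (cluster distances
recomputed from the original matrix at every step — max/mean for
complete/average, a leaf-weight-halving formula for McQuitty/WPGMA, the
closed-form merge cost for Ward) on hundreds of random instances, plus a
cross-check against `stats::hclust` heights on tie-free instances.

**FANNY degeneracy.** With membership exponent $r = 2$ and dissimilarities
compressed into a narrow high range — exactly what $1-\varphi^2$ produces on
weak-to-moderate binary associations — the uniform membership matrix can be
the *genuine* minimiser of the fuzzy objective, and the algorithm correctly
converges to it (normalized Dunn coefficient near 0). This is a property of
the objective, not a failure: lowering `r` (e.g. 1.2) restores crisp
recovery of planted blocks. FANNY and DIANA are diagnostics in the pipeline;
they never determine the reported partition.

**Degenerate margins.** If an item is constant within the complete pairs of
some pair (margins contain a zero), $\varphi^2$ is defined as 0 with a
warning: a constant item carries no association evidence. This matters in
bootstrap replicates, where resampling can flatten an item; defining the
value keeps replicates usable. A replicate is dropped only when a pair has
*zero* complete observations, and the run fails if more than 5% of replicates
drop.

**Congruence and padding.** A factor solution is matched to a cluster
solution by Tucker congruence between loading columns and the
column-normalized cluster indicator (normalization stops large clusters from
inflating congruence). The factor × cluster congruence matrix is zero-padded
to square whenever the counts differ, then rotated by the orthogonal $T$
maximising $\mathrm{trace}(TC)$ (SVD solution; reflections allowed, which
absorbs loading-sign indeterminacy). The aligned diagonal sum equals the
nuclear norm of the padded matrix — asserted against an independent SVD
throughout the tests. We rotate the *congruence matrix*, not the loadings;
the alternative reading (Procrustes-rotating the loadings toward the
indicator) is available as the `cluster_target` rotation, recorded under its
own name. A zero loading column (which arises from zero-padding when
factors < clusters) is given zero congruence with every cluster rather than
raising the zero-vector error that `tucker()` itself enforces.

**Rotations.** Varimax/quartimax are orthomax by pairwise plane rotations
with the closed-form angle; promax is the classical varimax-then-oblique
power-4 target fit; oblimin is quartimin by oblique gradient projection.
`stats::varimax` serves as an independent oracle in the tests, never in the
implementation path. The sign convention (each column's largest-magnitude
loading made positive) makes extraction deterministic across eigensolvers.

**Reliability.** $\alpha = \frac{k}{k-1}(1 - \sum_i s_i^2 / s_T^2)$ from the
item covariance matrix; for binary items this is KR-20. With missing data the
covariance matrix uses pairwise-complete observations by default, mirroring
the association step; listwise deletion is a config alternative. Whether raw
or standardized items should be used is not settled by the method
description; the raw covariance form is the default.

**Integration.** The original analysis integrated clustering, bootstrap and
factor evidence by expert review. The package encodes the reviewable part as
an explicit two-condition rule — reassign a flagged item only when its
strongest factor's aligned cluster *and* its strongest cross-cluster
co-membership agree — and refuses to move an item on conflicting evidence,
logging it for expert review instead. Automation surfaces the disagreement;
it does not adjudicate it.

## What the simulator emulates — and what it does not

`simulate_checklist()` draws zero-mean unit-variance Gaussian latents with
block compound symmetry ($\rho_\text{within}$ inside each planted block,
$\rho_\text{between}$ across), binarizes item $j$ at
$\Phi^{-1}(1-p_j)$, and masks cells missing completely at random. Defaults
state the emulated world: $n = 453$ subjects, block sizes 4, 7, 6, 3, 3, 4, 2
(the seven-cluster structure of the motivating study), $\rho_\text{within} =
0.7$, $\rho_\text{between} = 0.05$ (small but nonzero, to mimic the observed
cross-cluster leakage of bootstrap evidence), prevalence 0.3, missingness 5%.
The within/between correlations and prevalence are calibration choices — the
source study reports no latent-scale effect sizes — chosen so that planted
blocks are strong but not trivial (item-pair $\varphi^2$ within blocks
around 0.2–0.3, near 0 between). One seed drives latent draws and the
missingness mask through independent substreams, so changing `missing_rate`
leaves the latent data untouched.

The simulator does **not** emulate: item-specific difficulty/discrimination
(no IRT structure), informative missingness, age or site effects,
longitudinal dynamics, or negatively associated items. A green
planted-recovery test therefore establishes that the pipeline recovers block
compound-symmetry structure at the stated strength — not that seven clusters
exist in any particular clinical population.

## Known limitations

* $\varphi^2$ discards association *direction*; strongly negatively related
  items would cluster together.
* Factor analysis of a similarity matrix is a faithful replication choice,
  not textbook EFA; eigenvalues are all non-negative contributions of a
  Gram-like matrix and communalities lack their usual interpretation.
* The FANNY objective at $r = 2$ can be minimised by uniform memberships on
  compressed dissimilarity scales (see above).
* The integration rule's thresholds (0.10, 2.0) encode one reading of
  "low inside, higher elsewhere"; they are config values, and the rule's
  output is a *proposal* with an audit log, not a verdict.
* With `B = 0` the integration step runs without bootstrap evidence and can
  only log, never move, items; the report says so explicitly.
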