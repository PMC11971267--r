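---
title: "Estimating and stress-testing gross motor skill networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and stress-testing gross motor skill networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skillnets)
```

## The model

`skillnets` treats the 13 TGMD-3 skill scores of a child as one observation of
a multivariate system and asks which skills are *conditionally* associated:
which pairs remain correlated after controlling for every other skill. Under a
Gaussian graphical model (GGM) the answer is encoded in the precision matrix
$\Theta = \Sigma^{-1}$: skills $i$ and $j$ are conditionally independent
exactly when $\Theta_{ij} = 0$, and the strength of a conditional association
is the partial correlation

$$\rho_{ij} = -\frac{\Theta_{ij}}{\sqrt{\Theta_{ii}\,\Theta_{jj}}}.$$

Estimating $\Theta$ by inverting the sample correlation matrix yields a dense
matrix in which every small entry is noise. The package instead maximizes the
$\ell_1$-penalized log-likelihood

$$\log\det\Theta - \operatorname{tr}(C\Theta) -
  \lambda \sum_{i \neq j} |\Theta_{ij}|,$$

the graphical lasso with an off-diagonal penalty (the diagonal is not
penalized), which sets small partial correlations to exactly zero. The solver
is a block coordinate descent written in C++ (`src/glasso.cpp`): each column
of the working covariance is updated by a lasso regression solved by cyclic
coordinate descent with a cached partial-fit vector, and the whole
descending-$\lambda$ path is computed with warm starts. Convergence is
declared when the largest change in the working covariance falls below
`tol = 1e-4` times the mean absolute off-diagonal of $C$. The solution is
checked in the test suite against three independent oracles: direct matrix
inversion at $\lambda \to 0$, the closed-form bivariate solution
(soft-thresholding of $r$), and the empty-network threshold
$\lambda \ge \max_{i<j}|C_{ij}|$.

## Model selection

The penalty $\lambda$ is chosen over a 100-point log-spaced grid from
$\lambda_{\max} = \max_{i<j}|C_{ij}|$ down to $0.01\,\lambda_{\max}$ by
minimizing the extended Bayesian information criterion

$$\mathrm{EBIC}_\gamma = -2\,\ell(\Theta) + E \log n + 4 E \gamma \log p,$$

where $\ell = (n/2)(\log\det\Theta - \operatorname{tr}(C\Theta))$ and $E$
counts nonzero off-diagonal pairs. `gamma = 0.25` is the default throughout,
the conventional mild-sparsity setting for psychometric networks; `gamma = 0`
recovers the plain BIC. Ties in the EBIC argmin go to the larger $\lambda$,
i.e. the sparser model. Partial correlations below `1e-8` in magnitude are set
to exactly zero; this hard-zero rule is the single definition of an "edge"
used by the edge count and every downstream statistic.

Whether to feed the model Pearson or polychoric correlations of the ordinal
scores is genuinely open; the package defaults to Pearson (the scores have
7–11 levels, where the attenuation is small) and exposes the correlation step
as its own function so another input can be substituted. Unregularized
partial correlations (`partial_correlations_unregularized()`) are provided
for side-by-side comparison with the sparse network.

## Centrality and bridge centrality

Networks are signed and weighted; all statistics use absolute edge weights.
Distances are Dijkstra shortest paths with edge length $1/|w_{ij}|$, the
convention under which a strong partial correlation is a short hop. Per node
the package reports:

* **strength**: $\sum_j |w_{ij}|$;
* **closeness**: inverse of the *summed* distance to all reachable nodes;
* **betweenness**: fractional count of shortest paths through the node
  (Brandes accumulation; equal-length paths share credit).

The bridge versions fix the two instrument communities (Locomotor vs Ball
skills — a theoretical partition, not a data-driven clustering) and restrict
each statistic to cross-community structure: bridge strength sums only edges
to the other community, bridge closeness inverts the *mean* distance to
out-community nodes, and bridge betweenness counts only shortest paths
between nodes of different communities. The sum-vs-mean asymmetry between
closeness and bridge closeness is deliberate and matches the field's bridge
centrality convention. Numerical choices: path-length ties are resolved at
tolerance `1e-12` (scaled by path length); unreachable nodes are excluded
from closeness sums rather than poisoning them, and a node with nothing
reachable scores 0; a "count-all" tie mode (`ties = "count"`) gives every
tied path full credit, for cross-checking against software that counts ties
integrally. The fractional-credit implementation is verified exactly against
exhaustive simple-path enumeration on hundreds of random graphs with
$p \le 7$, and against igraph for the non-bridge statistics.

## Accuracy and stability

Following standard practice for psychometric networks, accuracy is assessed
by a nonparametric bootstrap: resample children with replacement `B = 1000`
times, re-estimate everything, and report replicate means with percentile
CIs (2.5th/97.5th quantiles, linear interpolation). Replicates that fail
estimation (e.g. a constant resampled column) are recorded and excluded; more
than 10% failures aborts the summary, because silent exclusion would bias the
CIs. These intervals describe sampling variability of the *regularized*
estimator; they are not confidence intervals for the latent partial
correlations — shrinkage biases edge estimates toward zero, so their coverage
of the generating values is poor and is not claimed. The tests assert what
the CIs do support: they bracket the full-sample estimate, true edges exclude
zero, and their width shrinks with $n$.

Stability is assessed by the case-dropping subset bootstrap: for each drop
proportion $q$ (default grid 0.05–0.75 in steps of 0.05), subsample
$\lfloor n(1-q)\rceil$ children without replacement `B_per_level = 250` times
(a desk-scale default; the quantity is configurable) and correlate each
subsample's per-node statistic vector with the full-sample vector. The
correlation stability coefficient CS(cor = 0.70) is the largest $q$ such that
at $q$ *and every smaller tabulated proportion* the 5th percentile of these
correlations stays at or above 0.70 — the monotone qualification prevents
non-monotone noise from inflating CS. CS > 0.25 is the conventional
acceptability bar. Group differences are judged by strict CI non-overlap
(touching intervals count as overlapping), with no multiple-testing
correction, mirroring the convention this pipeline follows; the number of
comparisons is carried in the result so users can judge for themselves.

## The synthetic generator

Real TGMD-3 panels of this scale are not openly available, so the package
ships a generator with known ground truth. A `precision_spec` is a sparse
symmetric positive-definite precision matrix over the 13 skills with the
6/7 community split; the default (`default_skill_spec()`) is a fixed,
handcrafted network with dense positive within-community structure, sparse
cross-community structure concentrated on the hubs *run* and
*two-hand catch* (mirroring the centrality pattern reported for real data),
one weak negative edge, and every true partial correlation at least 0.10 in
magnitude. The edge targets are diagonally dominant, so the matrix is
positive definite without repair and the implied partial correlations equal
the targets exactly. The random builder (`build_precision_spec()`) places
within-community edges at a requested density and repairs positive
definiteness, when needed, by adding 0.05 to the diagonal repeatedly (a
simple, monotone, reproducible loading), after which the true partial
correlations are recomputed from the loaded matrix.

Scores are generated by drawing latent vectors from the implied Gaussian and
discretizing each variable into `score_max + 1` equal-probability bins of the
standard normal scale. This is monotone, so ranks are preserved and Pearson
correlations of scores approximate latent correlations; per-skill maxima
default to a configuration summing to the instrument's subscale totals
(46 locomotor, 54 ball). `make_study_panels()` emulates the study design:
age strata of 3525 / 7882 / 5582 children, 51% female, and connectivity
scales 1.0 / 0.7 / 0.5 multiplying all off-diagonal structure, so conditional
associations weaken with age — the developmental trend reported for real
data. The age effect is modelled *only* as connectivity scaling (no mean
shifts), because every stage of the pipeline is location-invariant; mean or
variance effects would change nothing downstream.

What the generator does **not** emulate: item-level scoring (only skill
totals), rater disagreement, floor/ceiling pile-ups of real score
distributions (the equal-probability bins make scores nearly uniform), or
mean age effects. Passing tests therefore show that the pipeline recovers
known conditional structure from bounded integer panels of realistic size —
not that real TGMD-3 data satisfies the GGM.

All randomness flows through one integer seed: every stochastic stage
(per-stratum sampling, per-replicate resampling) derives a deterministic
child seed from (seed, index, stream), so results are bit-reproducible and
independent of execution order.

## Known limitations

* **EBIC-glasso admits tiny spurious edges at large n.** At $n = 5000$ with
  `gamma = 0.25` the selected network recovers essentially every true edge
  but also includes a handful of spurious edges of magnitude $\lesssim 0.02$.
  This is not a solver defect (the solution matches an independent graphical
  lasso implementation to $2\times10^{-5}$, and an independence spec yields
  zero spurious edges); it is the documented non-vanishing false-positive
  behaviour of EBIC-selected graphical lasso when the truth is structured.
  One of the package's end-to-end checks asserts a stricter false-positive
  bound and is expected to fail; it is kept as an honest record of this
  behaviour.
* **Bootstrap CIs are not parameter CIs** (see above); they quantify
  resampling variability of the regularized estimate.
* The CS coefficient is computed within groups; it does not account for
  differences in weight distributions *across* groups, so between-group
  comparisons inherit the usual caveat.
* Betweenness tie conventions differ across software; both the fractional
  and count-all modes are provided, and on networks with near-tied path
  lengths the two can disagree.

## Problem sizes used in the checks

The test suite exercises the stated study conditions directly where that is
cheap (parameter recovery at $n = 5000$ over 50 draws; the three age strata at
their full sizes over 20 draws with `B = 200` bootstraps; stability at
$n = 5000$ with `B_per_level = 100`, truncating the drop grid at 0.35 since
the CS ≥ 0.25 decision only involves proportions up to 0.25) and scales the
remaining long-running properties down (null comparisons and CI-width checks
at $n$ in the low thousands with `B` around 100). The acceptance script
reruns the headline quantities at the same reduced replicate counts.
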