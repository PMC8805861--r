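---
title: "Directed functional connectivity from antisymmetric lagged correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed functional connectivity from antisymmetric lagged correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirconn)
```

## The model

Conventional functional connectivity treats two brain regions as connected
when their activation time series correlate at lag zero. That view is
blind to direction: activation is generated in one region and propagates
to others with a delay, so the information about *who drives whom* lives
in the temporal offset between the signals.

`dirconn` estimates directed connectivity from exactly that offset. For
regions $j$ and $k$ with time courses $x_j$ and $x_k$ of length $N$, the
lagged correlation at delay $d$ is the Pearson correlation between the
first $N-d$ samples of $x_j$ and the last $N-d$ samples of $x_k$:

$$\rho_{j \to k}(d) \;=\; \frac{1}{N-d-1} \sum_{i=1}^{N-d}
  \left(\frac{x_j' - \mu(x_j')}{\sigma(x_j')}\right)
  \left(\frac{x_k' - \mu(x_k')}{\sigma(x_k')}\right),$$

with means and standard deviations taken per segment. Because $x_k$ is
shifted backwards relative to $x_j$, a large $\rho_{j\to k}(d)$ indicates
influence of $j$ on $k$ by temporal precedence. Collecting all pairs gives
the (generally asymmetric) lagged correlation matrix $L$.

$L$ decomposes uniquely into a symmetric and an antisymmetric part,

$$A = L - L^{\mathsf T}, \qquad S = L + L^{\mathsf T},$$

so $A + S = 2L$ exactly. $S$ is undirected connectivity evaluated at lag
$d$ (at $d=0$ it is twice the classical correlation matrix, so the
binarized networks coincide). $A$ is the package's centerpiece: after
zeroing negatives and the diagonal, a surviving entry $(j,k)$ summarizes
both the direction and the magnitude of the net directed influence
$j \to k$ in a single number. Bivariate Granger causality
($F_{j\to k} = \ln(\mathrm{var}\,\epsilon_R / \mathrm{var}\,\epsilon_U)$
from pairwise AR($p$) fits) is included as the standard alternative
estimate of directed coupling.

Negative correlations and self-connections are excluded from all analyses
by setting them to zero — and clipping always happens *after* the full
signed matrix and its decomposition have been computed, since
$A = L - L^{\mathsf T}$ is defined on the signed matrix. The antisymmetric
entries are kept on their raw scale (they can reach 2 for correlations);
every downstream step is rank- or threshold-based, so a global rescaling
would change nothing.

## From matrices to networks

There is no consensus threshold for binarizing a connectivity matrix, so
the package thresholds across the whole attainable density range. An
antisymmetric matrix has at most $n(n-1)/2$ positive entries — for each
pair only one direction survives clipping — which caps the usable density
at 50%. The default grid is 1% to 50% in 1% steps
(`default_densities()`). At each density the strongest
$\lfloor D \cdot n(n-1)\rfloor$ edges are retained, either as 1/0
(`binary`) or keeping their weights (`weighted`). Ties at the cut are
broken deterministically (weight descending, then row, then column
index); the choice is arbitrary but reproducible.

On each thresholded digraph the package computes the directed graph
measures: in-/out-degree, shortest directed path lengths and diameter,
in-/out-global efficiency $e_{out}(i) = \frac{1}{n-1}\sum_{j\ne i}
\vec{D}_{ij}^{-1}$ (unreachable pairs contribute $1/\infty = 0$), local
efficiency (global efficiency of the subgraph induced by a node's
neighbors — taken as the union of in- and out-neighbors, the common
directed convention), the cycle clustering coefficient

$$C_i = \frac{(A^3)_{ii}}{d^{in}_i d^{out}_i - d^{\leftrightarrow}_i},
\qquad d^{\leftrightarrow}_i = (A^2)_{ii},$$

which counts a triangle as complete only when its edges form a directed
cycle, the matching transitivity
$T = \mathrm{trace}(A^3) / \sum_i [d_i(d_i-1) - 2(A^2)_{ii}]$ (the
denominator summed over nodes, the only reading that keeps $T$
dimensionless and $\le 1$), and modularity via a directed
(Leicht–Newman) Louvain optimization at $\gamma = 1$ with 100 seeded
restarts. Weighted-mode generalizations follow the standard conventions:
strengths for degree, inverse-weight path lengths for efficiency, and the
Fagiolo cube-root form for clustering/transitivity with weights
max-normalized so the coefficients stay in $[0,1]$.

Nodal measures are then integrated over the density grid by the
trapezoidal rule (`auc_over_densities`), giving one threshold-robust
value per region and measure.

## Group inference

Group differences are tested nonparametrically. Values are first
residualized on the covariates (age, sex, six motion summary scalars) by
ordinary least squares — the covariate adjustment is applied once to the
dependent variable, then group labels are permuted (a simplified
Freedman–Lane scheme). The two-tailed p-value uses the add-one rule,
$p = (\#\{|\text{null}| \ge |\text{obs}|\} + 1)/(B+1)$, which avoids
$p = 0$ at finite $B$; 10 000 permutations is the confirmatory default.
Per-density global tests report the 2.5th/97.5th percentiles of the null
as a 95% envelope; nodal AUC tests are corrected across regions with
Benjamini–Hochberg FDR at $q = 0.05$. Corrections are *not* applied
across temporal lags by default: each lag probes a different connectivity
scale and is reported as a separate analysis. Brain–behavior associations
(`clinical_correlation`) correlate residualized network values with
residualized clinical scores, with a permutation p-value, and are meant
for regions that survived the group test.

Motion covariates deserve a note: realignment produces six parameters per
volume, but a between-subject model needs one number per subject, so the
subject table carries six per-subject summary scalars (e.g. mean absolute
excursion per parameter).

## What the synthetic cohorts emulate

Real inputs are region-by-time matrices extracted from preprocessed fMRI
(about 200 regions, about 200 retained volumes). Those data are not
redistributable, so validation runs on vector-autoregressive cohorts with
known directed structure: each subject's series follows
$x(t) = \sum_l B_l x(t-l) + \varepsilon(t)$ on a sparse directed
coefficient graph, with white Gaussian innovations, a 500-sample burn-in,
and stability enforced through the companion-matrix spectral radius. The
generator's defaults mirror the motivating study design: 15 controls
versus 95 patients, 207 time points, a lag-1 self-coupling of 0.3 per
region (temporal smoothness), a planted cross-coupling of 0.8,
multiplicative subject-level coefficient jitter of SD 0.1, and a 4-year
group-age confound in the covariates.

The planted group effect of record is a *direction flip*: patients carry
the $j \to k$ coupling, controls the same-magnitude $k \to j$ coupling.
Undirected connectivity strength is then identical between groups by
construction, and only a direction-aware analysis can separate them —
the cleanest test of the package's central claim that the antisymmetric
pipeline detects what zero-lag analysis cannot. A `scale` effect type
(different coefficient magnitudes) is also available.

What the simulator does **not** emulate: hemodynamic convolution,
physiological noise, scanner drift, spatial autocorrelation between
regions, or motion artifacts coupled to the signal. Passing tests
therefore demonstrate the statistical machinery and the direction
recovery under linear lagged coupling; they do not certify performance
on real fMRI, where the hemodynamic response blurs lag structure at the
sampling rates typical of fMRI.

## Numerical choices and degenerate inputs

* Segments with zero variance (flat signal) yield correlation 0 with a
  warning — an absent connection, not a missing value.
* The segment-wise normalization can nominally leave $[-1,1]$ only via
  floating-point rounding; values are clamped with a warning if the
  excess exceeds `1e-8`.
* Granger fits demean and linearly detrend each series; if a series
  still has lag-1 autocorrelation above 0.99 (unit-root heuristic), all
  series are first-differenced — all of them, to preserve the common
  time alignment — with a warning. Near-noiseless fits floor the
  unrestricted residual variance at `1e-12`, so a perfect lagged copy
  gives a large finite $F$ instead of an infinity.
* Requesting a density above the attainable fraction of positive weights
  raises an error naming the attainable maximum; the curve driver skips
  such densities with a warning and integrates over what remains.
* Clustering/transitivity denominators $\le 0$ (too few neighbors)
  return 0; nodes with fewer than two neighbors contribute 0 to local
  efficiency; diameters are taken over finite distances with a
  `disconnected` flag.
* Unreachable pairs contribute 0 to efficiency (the $1/\infty$
  convention).

## Monotonicity across densities — what holds and what only holds at scale

Nested thresholds only ever add edges, so shortest paths can only
shrink: global efficiency is *exactly* nondecreasing in density, at any
network size. Local efficiency, mean clustering and transitivity are
ratios whose numerator and denominator both grow with added edges; they
increase with density as a large-network regularity but can dip at the
lowest densities of small networks, where a handful of triples dominates
the ratio. The test suite reflects this split: exact monotonicity of
efficiency is asserted on small fixtures, the full set of measures on
100-node networks (half the atlas size of the motivating design) over a
5% grid, where the regularity holds with margin.

## Problem sizes used in the validation suite

The test and acceptance runs keep simulation sizes at the smallest scale
that still exercises each property: exhaustive graph-measure checks on
all digraphs of up to 4 nodes plus large random samples at 5 and 10
nodes; direction-recovery cohorts of 15 + 95 subjects, 10 regions and
207 time points over 50 replicates with 1000 permutations; calibration
over hundreds of null datasets at 1000 permutations. The confirmatory
default of 10 000 permutations is reserved for real analyses.

## Known limitations

* Lags are integer multiples of the sampling interval; sub-TR delays are
  invisible.
* The antisymmetric entry is a *net* influence: a strong bidirectional
  coupling with equal strength in both directions cancels to zero.
* Bivariate Granger fits ignore conditioning on the remaining regions;
  chains $j \to m \to k$ can induce apparent $j \to k$ coupling in both
  the lagged and the Granger networks.
* The directed Louvain optimization is a greedy heuristic; restarts
  mitigate but do not eliminate local optima on large graphs.
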