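---
title: "Knowledge-independent tumor sorting with dqcsort: models and methods"
author: "dqcsort authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-independent tumor sorting with dqcsort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dqcsort)
```

## The problem

Given a gene expression matrix (GEM) of bulk RNA-seq abundances for a
mixture of tumor samples — with no use of the sample labels at any stage —
we want to (i) sort the samples into groups that turn out to be enriched
for tumor type and clinical attributes, (ii) identify the small set of
"core" transcripts that drives the sorting, (iii) peel that set off and ask
whether the remainder can still classify (it can: the *background
classification potential*), and (iv) quantify functional signal in each
selected transcript layer against a user-supplied annotation map.

`dqcsort` implements this whole pipeline and ships a synthetic GEM
generator with planted ground truth, so every stage is testable end to end
at desk scale.

## Dynamic Quantum Clustering

Each sample is a point $x_i \in \mathbb{R}^d$ (we work in SVD-reduced
coordinates, below). The Parzen sum
$\varphi(x) = \sum_i e^{-\lVert x - x_i\rVert^2 / 2\sigma^2}$
estimates the data density. DQC constructs the potential

$$V(x) \;=\; E_0 + \frac{\sigma^2}{2}\,
  \frac{\nabla^2 \varphi(x)}{\varphi(x)},$$

whose local minima sit at density maxima ($E_0$ is fixed so
$\min_i V(x_i) = 0$; for a single Gaussian center $V$ reduces exactly to
the harmonic well $\lVert x\rVert^2/2\sigma^2$, which the tests exploit).
Each sample is then treated as a Gaussian wave packet evolving under
$H = -\tfrac{1}{2m}\nabla^2 + V$ via $\psi \mapsto e^{-i\,\delta t\,H}\psi$.
Packet centers flow toward nearby potential minima — an operator form of
gradient descent on the data density, with quantum tunneling letting
packets pass small spurious fluctuations.

Numerically, everything is expanded in the basis of the sample-centered
Gaussians: the overlap matrix is
$S_{ij} = e^{-\lVert x_i - x_j\rVert^2/4\sigma^2}$, kinetic elements are
analytic, potential and position elements use the midpoint rule
$\langle i\lvert A\rvert j\rangle \approx S_{ij} A\!\left(\frac{x_i + x_j}{2}\right)$
(exact for coincident points), and the basis is truncated to overlap
eigenvalues above `basisTol` times the largest, which guards
near-duplicate samples. The propagator is applied in the eigenbasis of the
truncated $H$, so evolution is unitary to rounding error; the `Trajectory`
object records per-frame norm and energy drift as diagnostics. After every
frame the packets are re-centered at their position expectations and the
operators rebuilt, which is what makes points *converge into* clusters
over tens of frames rather than oscillate. Above `maxExactPoints` (2000)
samples, the operator basis is built on a seeded subsample and all packets
are expressed in that basis; exact mode is always available.

### Parameter defaults, and why

* `sigma` (auto): **2.2 × the median nearest-neighbor distance** of the
  reduced coordinates. The median NN distance itself is a substantial
  underestimate of a useful Parzen bandwidth once $d$ exceeds a few: with
  it, every point sits in its own density spike and nothing moves.
  Doubling it merges spikes within a dense region while keeping genuinely
  separate regions distinct. This is the single most influential knob and
  is exposed everywhere.
* `mass` (auto): **$3/\sigma^2$**, i.e. mass 3 in units where $\sigma = 1$.
  Two constraints pin the form: the kinetic matrix elements scale as
  $d/(4 m \sigma^2)$, so invariance of the dynamics under jointly rescaling
  the data and `sigma` — a property the test suite asserts — requires
  $m \propto 1/\sigma^2$; and balancing kinetic against potential (both
  $O(d)$) requires the constant to be $O(1)$. The value 3 keeps enough
  tunneling to cross within-cluster density fluctuations without
  delocalizing packets across distinct clusters; much lower values make
  every packet slide to the global centroid.
* `dt = 0.1`, `stepsPerFrame = 1`, `nFrames = 60`: one recorded frame per
  step; 60 frames is comfortably past the point where planted clusters in
  the synthetic studies have collapsed to well under one `sigma`, and
  matches the frame scale at which extended structures are usually
  segmented. Like all DQC analyses, evolution run long enough merges
  *everything* (the potential always has a deepest well), so trajectories
  are meant to be read at the frame where structure is cleanest, not at
  $t\to\infty$.
* `basisTol = 1e-6` relative: discards numerically dependent overlap
  directions.

Cluster readout uses single linkage at threshold `sigma` on a late frame
(`trajectoryClusters()`), since converged packets sit within a small
fraction of `sigma` of their basin-mates. `separatingDimensions()` scores
each coordinate by $1 - \text{(largest side range)}/\text{(total range)}$
after splitting the sorted 1-D values at their largest gap; structureless
uniform draws stay below ≈0.52 (a few percent graze 0.5, none reach 0.6,
by Monte-Carlo), while genuinely bimodal dimensions score near 1. The 0.5
default cutoff therefore admits a small null false-positive rate, which
the iterative selection tolerates because a noise dimension contributes an
empty or tiny cut. A manual dimension list can override the rule wherever
it is consumed.

## SVD reduction and eigenvector feature selection

The samples × transcripts GEM is factored `X = U diag(S) Vt` (thin SVD,
deterministic sign convention). The truncation rank is chosen by the
relative Frobenius criterion `rankForRelativeError()` — e.g. rank for a
reconstruction better than the 1.5% level — and DQC evolution runs on the
first `N` columns of `U` *unscaled*, following the source convention for
this analysis; whether scaling by `S` would serve better is left as an
explicit user choice (`reducedCoordinates()` returns plain `U` columns).

Feature selection reads the rows of `Vt` for the dimensions where the
evolved data separates: the absolute components, sorted decreasingly,
show a close group of large values, then a gap. `componentCut()` makes the
by-eye rule deterministic: the cut position `p` (restricted to the first
`ceiling(n/2)` positions so a late noise-tail gap cannot win) maximizes
the ratio $a_p/a_{p+1}$ and must reach `minGapRatio` (default 3; use ~1.3
to keep harvesting into the diffuse background layers). `iterateLayers()`
runs select–remove–repeat: SVD of the current GEM, (optionally) DQC
evolution to pick separating dimensions or the expedited first-k-dimensions
mode, gap cuts, layer bookkeeping, column removal, and an optional
callback that re-clusters the selected and remaining sets each round. Layer
thresholds jitter around a strongly declining trend across iterations
rather than decreasing strictly pairwise; the tests assert the trend.

## Embedding ensemble, consensus, enrichment

`embedEnsemble()` computes t-SNE input affinities once per data set
(perplexity 30 by default, entropy bisection) and descends many randomly
initialized 2-D layouts (exact gradients, early exaggeration ×12,
adaptive gains — sized for ensembles over a few hundred samples; 1000
embeddings is the reference protocol, and every run is reproducible from
its seed). Each layout is clustered by an in-package HDBSCAN
(mutual-reachability single-linkage hierarchy, condensed by minimum
cluster size, excess-of-mass selection, noise = −1; the root may be
selected so a single coherent blob is one cluster, not all-noise).

Consensus follows the co-association construction: the fraction of
embeddings placing a pair in the same non-noise cluster (pairs with a
noise member in an embedding are excluded from that pair's denominator),
then average linkage on 1 − co-association, cut either at a fixed k or at
the largest dendrogram lifetime. This realizes the cluster-ensembles idea
with a deterministic, dependency-light consensus function that matches
CSPA's similarity definition; the original hypergraph variants are not
reimplemented.

Attribute enrichment tests each (cluster, attribute level) 2×2 table with
the plain $\sum (O-E)^2/E$ chi-squared (1 df, no continuity correction),
age dichotomized at 40 years, missing values excluded from denominators,
and a cluster flagged only when observed > expected at p < 0.001. Term
over-representation of transcript layers uses the one-sided hypergeometric
tail against a GMT-derived background with Benjamini–Hochberg control at
FDR < 0.01; the background defaults to the GMT universe and can be set to
the GEM transcript set (the two readings of "genomic background"; the
choice is the caller's and is visible in the output columns).
`backgroundExperiment()` wires the same pipeline over random transcript
subsets at the reference protocol sizes (20 replicates at 25–200, 10 at
225–500, 5 at 1000) and records the fraction of consensus clusters
enriched for at least one tumor type.

## The synthetic study

`synthConfig()` defaults describe the reference study used throughout the
tests: 3 classes × 50 samples; expression log-normal,
$\exp\!\left(N(\mu + s,\ 0.5)\right)$ with $\mu = 6$; 10 core markers per
class shifted by $s = 4$ (8 within-sample SDs — unambiguous markers, as
strong tissue-specific transcripts are); 600 background-differential
transcripts with per-class shifts uniform in $[-1, 1]$ (no single one
decisive, the aggregate clearly class-informative); 370 pure-noise
transcripts (1000 total, so subset sizes up to 1000 are drawable); gender
and stage planted as strongly class-skewed attributes; ages drawn at
class means 35/55/60 (SD 8) around the 40-year dichotomy. One global seed
drives fixed-offset sub-streams per stage, so identical configurations are
byte-identical.

What it emulates: the layered marker structure, the diffuse aggregate
signal that survives marker removal, label contamination
(`injectNormals()`), and class-associated metadata. What it does not:
read-count noise models, batch effects, correlated co-expression modules,
or realistic transcript-count scale. Passing tests therefore demonstrate
the machinery recovers planted structure of the stated shape — not
performance on any particular real cohort.

## Numerical choices and degenerate inputs

Quantile normalization replaces each sample's values by the across-sample
mean order statistics; ties get the mean of the means of the positions
they span, which is deterministic, order-independent, and idempotent.
The KS outlier screen compares each sample against the pooled others with
Bonferroni correction (the reference distribution and correction are this
package's choice; the source names only the test). All-zero eigenvectors,
empty selections (two consecutive empty iterations stop the loop with a
warning), coincident points (overlap-basis truncation), constant
dimensions (separation score 0), perplexity ≥ n/3, and Parzen underflow
(error advising a larger `sigma`) are all handled explicitly.

Problem sizes in the reference tests — 150 samples × 1000 transcripts,
ensembles of 8–50 embeddings, 10-seed replication for recovery claims —
were chosen as the smallest sizes at which the planted-structure claims
are comfortably non-marginal.

## Known limitations

* DQC cost is dominated by rebuilding potential matrix elements each
  frame, $O(n_b^2\, n)$ Gaussian evaluations; the seeded-subsample mode
  bounds $n_b$.
* Consensus by co-association is quadratic in samples.
* The gap-cut surrogate for by-eye thresholding is deliberately
  conservative at `minGapRatio = 3`; diffuse layers need a relaxed ratio,
  and there is no automatic schedule for relaxing it.
* t-SNE here is the exact $O(n^2)$ variant: right for ensemble use on
  hundreds of samples, wrong for tens of thousands.
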