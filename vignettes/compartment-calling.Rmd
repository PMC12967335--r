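---
title: "Dropout-aware change-point detection and normalized-cut partitioning for single-cell A/B compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dropout-aware change-point detection and normalized-cut partitioning for single-cell A/B compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schicab)
```

## The problem

A/B compartments are the megabase-scale bipartition of a chromosome into
open, transcriptionally active (A) regions and closed, inactive (B) regions.
In bulk Hi-C they are classically read off the sign of the leading
eigenvector of a correlation matrix derived from the contact map. In
single-cell Hi-C that recipe collapses: a single cell yields on the order of
hundreds to a few thousand intrachromosomal contacts per chromosome, so most
matrix entries are zero and eigenvectors of per-cell correlation matrices
are dominated by sampling noise. The common workaround — imputing the
matrix, or projecting onto an external feature such as CpG density — either
smooths away cell-to-cell variability or imports a signal that is not the
cell's own.

`schicab` annotates compartments from one sparse single-cell matrix
directly. External information (CpG density) enters only at the very last
step, to decide which of the two sides is called "A"; it never drives the
partition itself.

## The model

Write $Y_{ij}$ for the observed contact count between bins $i$ and $j$ of an
$n$-bin chromosome. We model

$$Y_{ij} = R_{ij} \times X_{ij},$$

where $X_{ij} \sim N(\mu_{ij}, \sigma^2)$ is the true contact intensity and
$R_{ij} \sim \mathrm{Bernoulli}(r_{ij})$ is a dropout indicator: a contact
present in the cell is seen ($R = 1$) or missed ($R = 0$), independently
across pairs. Compartment structure enters through a piecewise-constant
assumption: $K$ change points (CPs) on the bin axis cut the matrix into
$(K+1) \times (K+1)$ blocks, and both $\mu$ and $r$ are constant within each
block. Recovering compartments therefore reduces to a two-dimensional
change-point detection problem.

CP configurations are encoded one-hot over the $n-1$ inter-bin gaps with
exactly $K$ ones, the prior over configurations is uniform
($1/\binom{n-1}{K}$), and the per-block parameters are replaced by their
plug-in estimates: $\hat r_{kl} = S_{kl}/N_{kl}$ (nonzero fraction),
$\hat\mu_{kl}$ the mean of nonzero entries, $V_{kl}$ their population
variance, and a single pooled $\hat\sigma^2$ over all nonzero entries of the
matrix. Up to a constant shared by all configurations, the log-posterior is

$$\log P(\text{CPs} \mid Y) = \sum_{k,l} \Big[ S_{kl}\log\hat r_{kl} +
(N_{kl}-S_{kl})\log(1-\hat r_{kl}) \Big] -
\frac{1}{2\hat\sigma^2}\sum_{k,l} S_{kl}V_{kl},$$

with $0\log 0 := 0$. `log_posterior()` evaluates exactly this expression;
the test suite checks it against an independently coded double-loop
transcription to $10^{-10}$.

Some conventions worth stating because they affect the value (not the
ranking behaviour) of the posterior:

* sums run over the full symmetric matrix, diagonal included — off-diagonal
  pairs are counted twice, which shifts every configuration's score equally;
* $\hat\sigma^2$ is pooled across the whole matrix and fixed across
  configurations. A per-block variance would make the Gaussian term nearly
  configuration-independent and destroy the segmentation signal;
* all variances use the population divisor (plug-in maximum-likelihood
  spirit); the divisor choice shifts configurations almost equally;
* masked bins (see below) are excluded from every tally.

## Inference

Enumerating $\binom{n-1}{K}$ configurations is infeasible beyond toy sizes,
so the posterior is explored by Metropolis–Hastings. The proposal picks one
occupied gap and one unoccupied gap uniformly at random and swaps them.
This kernel is symmetric (the acceptance probability is
$\min(1, e^{\Delta \log P})$) and irreducible over the fixed-$K$ state
space. Proposals that would leave a loci group containing only masked bins
are rejected in place, which restricts the chain to the valid subspace
without breaking symmetry. The chain starts from $K$ evenly spaced CPs — a
deterministic, unbiased initialisation — and runs for $20(n-1)$ iterations
by default. Because the quantity of interest is the maximum-a-posteriori
configuration over visited states (not a posterior expectation), no burn-in
is discarded; `map_changepoints()` takes the best visited state, ties to the
earliest visit.

Two oracles keep the sampler honest. `exhaustive_map()` enumerates all
configurations on small instances and must never be beaten by a sampled MAP.
And on a 7-state instance the empirical visit frequencies of a long chain
are compared with the exactly normalized posterior, using the Markov-chain
standard error (batch means) since the chain is autocorrelated.

The per-evaluation cost is $O(n^2)$; the sampler's inner loop is compiled
(Rcpp) and draws from R's own RNG stream, so `set.seed()` — or the `seed`
argument — makes chains exactly reproducible.

## From segmentation to compartments

Distance decay — the strong falloff of contact frequency with genomic
separation — is handled by observed/expected (O/E) normalization, but doing
this directly on one sparse cell amplifies noise. The package therefore
splits the pipeline: CP detection runs on the **raw** matrix, where decay
has limited influence on block contrasts, and graph partitioning runs on the
**O/E** matrix, with the expected per-distance profile estimated from a
pseudo-bulk pool of cells (`pseudo_bulk()` then `expected_profile()`). Bands
with zero expected value map to 0 rather than NaN. When no pool is
available, `annotate_cell()` falls back to the cell's own profile with a
warning.

Given the MAP segmentation, each loci group becomes a node of a weighted
graph; the weight between nodes $k$ and $l$ is the mean O/E value of the
$(k,l)$ block (diagonal blocks become self-loops, which are kept in the
adjacency and counted once in the total edge weight $m$). The graph is
bipartitioned by the normalized cut $\min R/(\kappa_1\kappa_2)$, where $R$
is the cut weight and $\kappa_1, \kappa_2$ the degree masses of the two
sides. The relaxed solution is the second-largest eigenpair
$(\lambda_2, \nu_2)$ of $D^{-1/2}AD^{-1/2}$; nodes are rounded to sides by
the sign of $\nu_2$ at threshold 0 (the discrete solution is known to be
robust to the rounding rule). Numerically, the known top eigenvector
$D^{1/2}\mathbf{1}$ is deflated out before the eigendecomposition, which
returns the correct $\nu_2$ also in the degenerate disconnected case
($\lambda_1 = \lambda_2 = 1$), and $\nu_2$ is normalized with its first
nonzero entry positive so results are sign-deterministic. `brute_force_ncut()`
provides the exact minimizer on up to 20 nodes as a test oracle; on planted
two-community graphs with a 4:1 weight contrast the sign rounding matches it
in well over 90% of draws.

Every bin inherits the $\nu_2$ value of its group. The A/B polarity is then
set by the Pearson correlation between the per-bin values and CpG density:
if negative, the vector is negated (A compartments are CpG-rich); bins with
oriented value $\ge 0$ are labelled A. A small absolute correlation
(default threshold 0.2, configurable) does not suppress the result but sets
a `weak_flag`, since it may indicate weak compartmentalization of that cell.

## Compartmental strength

The optimal relaxed objective can be written $F = (1-\lambda_2)/(2m)$. The
package reports $-\log_2(F)$ as a per-cell **compartmental strength**:
larger values mean the contact graph splits more cleanly into two
compartments ($F = 0$, a disconnected graph, maps to $+\infty$). Strength is
averaged over the MH repeats of a cell. Its validity as a strength measure
is checked by a permutation experiment: `shuffle_mix()` permutes the matrix
entries within each distance band (destroying compartment structure while
preserving the distance-decay marginal — a global shuffle would confound the
two) and blends a fraction of the shuffled matrix into the original. Mean
strength decreases monotonically in the mix fraction across
$\{0, 0.25, 0.5, 0.75, 1\}$ on planted matrices. In practical use a
reference cutoff of 17.3 is conventionally quoted for real datasets; the
command-line `strength` subcommand reports each cell against that line but
never filters.

## Choosing K

$K$ is a hyperparameter. The package chooses it per dataset by an annotation-
stability rule (`select_K()`): for each of the first `cells_for_K` cells
(default 5), candidates are scanned in increasing order (default 10 to 200
in steps of 10) and annotations at consecutive candidates are compared by
Pearson correlation of the real-valued profiles and intersection of the
binary labels. The first candidate whose successor agrees beyond both
thresholds (defaults 0.8 and 0.9) is selected; if none qualifies the largest
candidate is taken with a warning. The dataset-level $K$ is the maximum over
the examined cells and is then fixed for all cells, keeping profiles
comparable. Each candidate annotation uses a single MH repeat — scanning 20
candidates at full repeat depth would dominate the runtime of the whole
pipeline while the stability comparison only needs one segmentation per
candidate.

Two points the defaults encode: the correlation leg of the rule is computed
on the real-valued profiles because binary agreement is already covered by
the intersection leg; and the candidate grid should be scaled with
resolution — roughly 100 CPs are appropriate at 100 kb and 20–40 at 1 Mb,
which the default grid (10–200) covers at its midpoint.

Note that the rule selects the **earliest stable** candidate. On data whose
dominant A/B split is already captured by a very coarse segmentation, it
will legitimately return a small $K$; the planted-structure test of the rule
therefore uses equal-sized alternating blocks, where stability is only
reachable at or beyond the true block count.

## The synthetic-data generator

`make_truth()` plants a checkerboard: CP positions drawn uniformly (or given
explicitly), groups labelled alternately A/B, block means
`mu_within`/`mu_between` and dropout rates per block. `sample_matrix()`
draws each unordered pair once — Gaussian signal truncated at zero and
rounded to an integer count, then Bernoulli dropout — so matrices are
symmetric integer-count objects that feed the same I/O paths as real data
(the inference model still treats values as Gaussian). Defaults are the
regime the test-suite measures: $n = 100$ bins, 7 CPs, a 5:1 contrast
(`mu_within = 10`, `mu_between = 2`), 70% dropout, unit noise, no decay.

Three degradation protocols emulate experimental sparsity:

* `downsample(rate =)` thins every count binomially — the regime of
  downsampling a deep pseudo-bulk at rates like 1/400 to 1/3200;
* `downsample(target_contacts =)` draws an exact number of contacts without
  replacement (multivariate hypergeometric) — the regime of fixed-contact
  single cells (250–10 000 contacts);
* `shuffle_mix()` as described above.

What the generator does **not** emulate: distance decay is optional and off
by default (real matrices always have it; the O/E step exists for that
reason), dropout is homogeneous per block rather than coverage-dependent,
and there is no translocation / copy-number structure. Passing the planted-
recovery tests therefore demonstrates correctness of the inference under
the stated model, not performance on any particular real dataset.

## Numerical choices and edge cases

* Bins with row sum below `min_marginal` (default 1 raw contact) are masked:
  fully unobserved bins make block statistics degenerate. Masking is
  idempotent and propagates to every downstream tally, graph weight and
  correlation; masked bins report NA labels.
* $0\log 0 = 0$ throughout the Bernoulli term (covers $\hat r \in \{0,1\}$).
* $\hat\sigma^2 = 0$ (all nonzero entries identical) defines the Gaussian
  term as 0, with a warning.
* O/E bands with zero expected value map to 0, keeping everything finite.
* Eigen-rounding at exactly 0 assigns the bin to side A.
* Ties in the MAP are broken by earliest visit; ties in the brute-force cut
  by the lexicographically smallest side vector.
* All random components (sampler, generators, per-cell and per-repeat seeds)
  derive deterministically from user seeds; derived seeds stay below
  $2^{31}$.

## Problem sizes in the test suite

The suite validates on planted instances sized to exercise every code path
at full statistical strength: $n = 100$ bins with $K = 7$ and 70% dropout
for end-to-end recovery (25 replicates), 30-bin two-block matrices for
MAP-vs-enumeration (20 replicates), 4–10-node graphs for spectral-vs-exact
normalized cut (100 draws), a $2\times10^5$-step chain on a 7-state space
for stationarity, and 20-replicate shuffle-mix ladders for strength
monotonicity. These sizes are the package's validation regime, chosen so
each property is measured with comfortable margins; the method itself runs
at chromosome scale (hundreds to thousands of bins) with the same code.

## Limitations

* One chromosome at a time; inter-chromosomal contacts are out of scope.
* The block model assumes two-level (A/B) structure; subcompartments are
  not modelled, although the real-valued profile retains graded signal.
* Cooler (HDF5) files are not read directly; export the chromosome to a
  dense or triplet text dump first.
* The stability rule for $K$ inherits the resolution of its candidate grid;
  a grid that skips the true block count can stabilize early.
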