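# schicab

A/B chromatin compartment annotation from individual, sparse single-cell
Hi-C contact matrices — without imputation and without letting external
genomic features drive the call.

## Who this is for

Single-cell Hi-C measures chromosome conformation in individual cells, but
a single cell yields only hundreds to thousands of intrachromosomal
contacts per chromosome, so the classical bulk recipe — the sign of the
leading eigenvector of a correlation matrix — drowns in sampling noise.
Existing workarounds impute the matrix (homogenizing cells) or project onto
CpG density (importing a universal signal that is not the cell's own).
`schicab` is for anyone who wants per-cell compartment calls that preserve
cell-to-cell heterogeneity: it infers the partition from the cell's own
contacts and uses CpG density only to decide which side is named "A".

## The method

For observed counts $Y_{ij}$ the package fits a dropout-aware block model

$$Y_{ij} = R_{ij} \times X_{ij}, \qquad
X_{ij} \sim N(\mu_{ij}, \sigma^2), \qquad
R_{ij} \sim \mathrm{Bernoulli}(r_{ij}),$$

where $K$ change points on the bin axis cut the matrix into
$(K+1)\times(K+1)$ blocks with block-constant $\mu$ and $r$. With plug-in
estimates $\hat r_{kl} = S_{kl}/N_{kl}$, nonzero-entry variances $V_{kl}$
and a pooled $\hat\sigma^2$, the log-posterior over change-point
configurations (uniform prior, exactly $K$ change points) is

$$\sum_{k,l}\Big[S_{kl}\log\hat r_{kl} + (N_{kl}-S_{kl})\log(1-\hat r_{kl})\Big]
- \frac{1}{2\hat\sigma^2}\sum_{k,l} S_{kl}V_{kl}.$$

It is maximized by Metropolis–Hastings over configurations (symmetric
move-one-change-point proposals), on the **raw** matrix. The resulting loci
groups are collapsed — on the **observed/expected-normalized** matrix, with
the expected profile taken from a pseudo-bulk pool — to a small weighted
graph, which is bipartitioned by the normalized cut
$\min R/(\kappa_1\kappa_2)$ via the second eigenpair $(\lambda_2,\nu_2)$ of
$D^{-1/2}AD^{-1/2}$. Bins inherit their group's $\nu_2$ value; the sign of
the Pearson correlation with CpG density orients the two sides into A
(CpG-rich) and B. The per-cell compartmental strength is
$-\log_2 F$ with $F = (1-\lambda_2)/(2m)$.

The package also ships the surrounding apparatus: planted-structure
simulators (Gaussian signal, Bernoulli dropout, binomial downsampling,
exact-contact subsampling, band-preserving shuffle mixing), evaluation
metrics (intersection, per-locus accuracy, binary compartment variance,
stable/variable classification), and a data-driven stability rule for
choosing $K$. See the methods vignette
(`vignettes/compartment-calling.Rmd`) for the full account.

## Worked example

Plant a 100-bin chromosome with 7 compartment boundaries, sample five cells
at 70% dropout, and annotate them jointly:

```r
library(schicab)

truth <- make_truth(n = 100, K_true = 7, seed = 11)
cells <- lapply(1:5, function(s) sample_matrix(truth, seed = s))
cpg   <- cpg_from_truth(truth, seed = 11)

cells[[1]]
#> ContactMatrix: chr1, 100 bins @ 100,000 bp (raw)
#>   usable bins: 100/100; total signal: 2.014e+04; cells pooled: 1

cm <- annotate_dataset(cells, cpg, run_config(K = 7, n_repeats = 5, seed = 1))
cm
#> CompartmentMatrix: 5 cells x 100 bins (chr1 @ 100,000 bp), K = 7

cm$profiles[[1]]
#> CompartmentProfile: chr1 @ 100,000 bp, 100 bins (A: 28, B: 72, masked: 0)
#>   K = 7, CpG correlation 0.977, strength 4.770
```

The profile says: of 100 bins, 28 were called A and 72 B; the oriented
$\nu_2$ correlates 0.977 with CpG density (a confident orientation — values
below 0.2 would set the `weak_flag`); and the mean compartmental strength
over the 5 sampler repeats is 4.77 ($F \approx 0.037$, a clear two-block
separation). Comparing each cell with the planted truth:

```r
sapply(1:5, function(i)
  intersection(cm$binary[i, ], as.numeric(truth_labels(truth) == "A")))
#> [1] 1 1 1 1 1
```

Every cell recovers the planted compartments exactly at this contrast and
dropout level. `write_compartments(cm$profiles, "out", "tsv")` writes the
cells-by-bins label and value tables; `plot_compartments(cm)` draws the
heatmap.

A thin command-line wrapper over the same functions lives at
`inst/scripts/schicab.R` (subcommands `annotate`, `select-k`, `strength`,
`simulate`, `metrics`).

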