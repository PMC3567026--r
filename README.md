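# rmtnet

Gene co-expression networks from expression matrices, thresholded by random
matrix theory (RMT), with a perturbation harness for measuring how robust
the resulting network's topology and biology are to changes in the input
data.

## What it does

Co-expression network construction has two steps: correlate all pairs of
gene expression profiles into a similarity matrix, then choose the cutoff
separating biologically meaningful correlations from noise. rmtnet chooses
that cutoff without any annotation knowledge, using the spectral signature
of noise. As the pruning threshold *t* descends, the nearest-neighbour
spacing distribution (NNSD) of the pruned matrix's unfolded eigenvalues is
tested against the exponential law with a 60-bin chi-square (df = 59). A
modular, signal-dominated matrix gives Poisson spacings (chi-square low); a
noise-dominated matrix gives Gaussian-orthogonal-ensemble spacings —
`P(s) = (pi/2) s exp(-pi s^2/4)` — and a large chi-square. The scan confirms
the transition when the statistic reaches 100 (p ~ 0.001) and subsequently
200 without falling back, and cuts the network one step above that point,
in the last Poisson (signal) regime.

Around that core the package provides:

* `read_expression_matrix()` / `subset_expression()` — tab-delimited
  expression matrix I/O with missing values;
* `build_similarity_matrix()` — all-pairs pairwise-complete Pearson
  correlation, plus a compact lower-triangle float32 binary format
  (`write_similarity_binary()`);
* `find_threshold()` — the RMT threshold scan (S3 object with `print`,
  `summary`, `plot` methods);
* `extract_network()` and topology metrics (shared nodes/edges, average
  degree, clustering coefficient, maximum-likelihood power-law exponent);
* `detect_link_communities()` — overlapping modules by edge clustering
  under partition density, so multi-functional genes may sit in several
  modules;
* `enrichment_profile()` / `average_module_kappa()` — hypergeometric term
  enrichment at p <= 0.001 and Cohen's-kappa functional comparison of two
  networks' module profiles (best match per module, then averaged);
* `run_robustness()` — the random sample/probe-set removal experiment
  (25/50/75/100% ladders, >= 10 seeded replicates per cell) comparing every
  perturbed network to the global one;
* `generate_modular_expression()` — a seeded synthetic-data generator with
  planted co-expression modules and known ground truth.

A thin command-line wrapper with `synth`, `ccm`, `rmm`, `extract` and
`robustness` subcommands is installed at `inst/scripts/rmtnet`.

## Worked example

```r
library(rmtnet)

d <- generate_modular_expression(n_genes = 600, n_samples = 100,
                                 n_modules = 5, module_size = 20,
                                 loading = 0.92, seed = 1)
sm <- build_similarity_matrix(d$expression, min_obs = 30)
fit <- find_threshold(sm)
fit
#> RMT threshold scan
#>   scanned 88 thresholds from 0.92 (step 0.001)
#>   divergence at 0.838 (chi2 >= 100 confirmed at chi2 >= 200)
#>   selected network threshold: 0.839

net <- extract_network(sm, fit$threshold)
net
#> <coexp_network> 93 nodes, 581 edges
planted_edge_precision_recall(net, d$truth)
#> $precision
#> [1] 1
#> $recall
#> [1] 0.6115789
```

The scan descended from 0.92, watched the spacing chi-square, and confirmed
the Poisson-to-GOE divergence at 0.838; the network is cut one step above,
at 0.839. Every one of the 581 extracted edges joins two genes planted in
the same module (precision 1.0), recovering 61% of all planted pairs —
the pairs whose sample correlation exceeds the cutoff.

The robustness protocol, with annotations marking each planted module:

```r
ann <- generate_annotation_fixture(d$truth, seed = 1)
rob <- run_robustness(d$expression, ann, sample_fractions = 0.75,
                      replicates = 2, base_seed = 100, min_obs = 20)
rob
#> <robustness_report> global: 93 nodes / 581 edges at threshold 0.839
#>   2 replicate runs (0 failed threshold search)
#>   sample_fraction probe_fraction n_ok n_edges_mean shared_edges_mean
#> 1            0.75              1    2          800               563
#>   edges_lost_mean edges_new_mean n_modules_mean average_kappa_mean
#> 1              18            236              9              0.773
```

With 25% of samples removed, the rebuilt networks keep 563 of the global
network's 581 edges on average, and the average best-match Cohen's kappa
between the perturbed and global module enrichment profiles is 0.77 —
above the 0.6 floor customarily required to call module biology conserved.

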