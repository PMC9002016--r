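# sentinet

Regularized partial-correlation networks for social-media topic attention.

During a public emergency, posts on a platform such as Weibo can be labeled
with topic indicators — government actions (prevention measures, science
popularization, research, rumor-refuting, negligence, image), public emotion
(positive, negative), and media activity (online help-seeking, epidemic
recordings, foreign comparisons). The daily share of posts per topic is a
compositional time series, and the question of interest is which topics
covary *conditionally on all the others*: a pairwise Markov random field
over topics, estimated as a sparse Gaussian graphical model.

`sentinet` is aimed at computational social scientists and applied
statisticians who want that pipeline as tested, reusable R functions rather
than a one-off script.

## The method

For daily proportions $x_{tj}$ ($t = 1..n$ days, $j = 1..p$ topics):

1. **Marginal normalization.** Each column is rank-transformed to normal
   scores $\Phi^{-1}((r - 0.5)/n)$ (nonparanormal), then a Pearson
   correlation matrix $S$ is formed and repaired to positive definiteness
   (the sum-to-one closure makes the raw matrix exactly singular).
2. **Sparse precision estimation.** The graphical lasso maximizes
   $\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda\sum_{i\ne j}|\theta_{ij}|$
   (block coordinate descent in C++, diagonal unpenalized, warm starts).
3. **EBIC model selection.** $\lambda$ is chosen over a 100-point log-spaced
   path by $\mathrm{EBIC} = -2\ell + E\log n + 4E\gamma\log p$ with
   $\gamma = 0.5$; edges below the replicability threshold
   $\sqrt{\log(p(p-1)/2)/n}$ are dropped by default. Reported weights are
   partial correlations $\rho_{ij} = -\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}$.
4. **Network description.** Strength, closeness and betweenness centrality
   (weighted, tuning parameter $\alpha$), the Zhang–Horvath clustering
   coefficient, and per-metric z-scores.
5. **Stability.** A day-resampling bootstrap of all edge weights with
   percentile intervals, a bootstrapped edge-weight difference test, and the
   case-drop subsampling CS coefficient (largest droppable fraction keeping
   subsample/full statistic correlation ≥ 0.7 with 95% certainty).

A logistic-normal multinomial simulator (`generator_spec()`,
`simulate_corpus()`) generates corpora — by default 11 topics, 40 days,
about 68,000 posts — whose daily proportions carry a known sparse
partial-correlation structure, so the whole pipeline is testable by
parameter recovery without any private data.

## Worked example

```r
library(sentinet)

## a corpus-scale synthetic data set: 11 topics x 40 days
corpus <- simulate_corpus(generator_spec(seed = 42))
corpus$series
#> topic_series: 40 days x 11 topics, 67995 posts
#>   dates: 2020-01-23 .. 2020-03-02
#>   topics: G1 G2 G3 G4 G5 G6 P1 P2 M1 M2 M3

## at 40 days the conservative defaults select nothing -- the small-sample
## regime; the same estimator on 1000 latent draws recovers the truth
truth <- make_partial_corr_model(generator_spec(seed = 42))
set.seed(7)
z <- matrix(rnorm(1000 * 11), 1000) %*% chol(truth$true_covariance)
colnames(z) <- truth$topics
net <- ebic_glasso_select(correlation_matrix(z))
net
#> network_estimate: 11 topics, 12 edges (gamma = 0.5, lambda* = 0.03244, n = 1000)

edge_recovery_metrics(truth$true_partial, net$partial)
#>   true_edges est_edges tp fp fn precision recall sign_accuracy fp_rate
#> 1         12        12 12  0  0         1      1             1       0

head(centrality_table(net)[order(-centrality_table(net)$strength),
                           c("topic", "strength", "betweenness", "clustering")], 3)
#>    topic strength betweenness clustering
#> 10    M2    1.418          25      0.202
#> 7     P1    1.105          14      0.196
#> 9     M1    0.914           0      0.579
```

All twelve true edges are recovered with no false positives; topic M2
(epidemic recordings) has the highest strength and betweenness — the kind of
"bridge" diagnosis the centrality table is for. A full run with bootstrap
and CS reports is one call:

```r
cfg <- analysis_config(series = corpus$series, seed = 1)   # B = 1000 bootstrap
res <- run_analysis(cfg, "out/")                           # writes 7 report files
```

or from the shell via the thin CLI:

```sh
Rscript inst/cli/sentinet.R simulate --out-dir sim --seed 1
Rscript inst/cli/sentinet.R analyze --posts sim/posts.csv --out-dir out --seed 1
Rscript inst/cli/sentinet.R benchmark --reps 10 --days 1000 --seed 1
```

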