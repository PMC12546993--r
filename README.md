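# microstnet

Forecasting longitudinal microbial abundance with a two-stream
spatio-temporal graph convolutional network fused with a stacked LSTM.

Daily 16S time series of closed habitats (gut, saliva) are multivariate
and interaction-driven: a genus's trajectory depends on its neighbours in
the community as much as on its own past. Per-taxon forecasters (pure
LSTMs and classical time-series models) ignore those cross-taxon
dependencies and hallucinate peaks. `microstnet` is for microbiome
researchers who have a taxa-by-time abundance table and want
short-horizon forecasts of every taxon at once, with the community
structure built into the model.

## Method

1. **Co-occurrence network.** For each taxon pair, Spearman's
   `rho = cor(R(x_i), R(x_j))` with a two-sided permutation p-value;
   Benjamini–Hochberg correction over the D(D−1)/2 pairs; edges with
   adjusted p > 0.05 removed. The graph blocks use the symmetric
   normalization `Âhat = D^{-1/2} (|A| + I) D^{-1/2}`.
2. **Preprocessing.** All-zero taxa dropped; per-taxon Z-score
   `(x − mu_i)/sigma_i` (population sd, training segment only); sliding
   windows of width W = 8 with chronological 80/20 (or 7:3) splits; a
   first-difference change stream per window.
3. **Model.** Two streams (abundance, change) of causal gated temporal
   convolutions sandwiching graph-aggregation blocks
   `lfs[b,c,i,t] = sum_j Âhat_ij x[b,c,j,t]`, plus a five-layer LSTM
   branch on the abundance stream; features are concatenated per taxon
   and a shared fully connected head emits the next H standardized
   abundances. Ablation variants: `stgcn2s` (no LSTM branch), `lstm`
   (LSTM branch only).
4. **Training.** Mean-absolute-error loss, Adam, per-epoch validation
   MAE, the best epoch's weights returned. Metrics: MAE and sMAPE
   (bounded at 200%). Multi-step forecasts recurse one step at a time,
   rebuilding the change stream.

Everything — including the forward/backward passes of all blocks — is
implemented in base R and verified against brute-force oracles and
finite-difference gradients in the test suite.

## Worked example

```r
library(microstnet)
# a mutualistic 12-taxon community observed daily for 200 days
graph <- abs(generate_graph(12, density = 0.25, seed = 42))
spec <- simulator_spec(n_taxa = 12, n_steps = 200, graph = graph,
                       rho_self = 0.5, gamma = 0.15, noise_sd = 0.3,
                       seed = 42)
series <- simulate_series(spec)
fit <- microstnet(series, window = 8, epochs = 20, channels = 8,
                  n_blocks = 1, batch_size = 16, n_perm = 5000, seed = 1)
summary(fit)
#> variant microstnet: 12 taxa, 153 training / 39 validation windows, 3705 parameters
#> network edges: 1
#> validation MAE 0.71600 (standardized), 0.24684 (original scale)
#> validation sMAPE 127.20% (standardized)
predict(fit, h = 3)
#> forecast_result (microstnet): 12 taxa, 3 step(s) ahead
#>            step_1    step_2    step_3
#> taxon_1 10.078991 10.090285 10.103117
#> taxon_2 10.104245 10.130518 10.023341
#> taxon_3  9.716219  9.827164  9.894815
#> ...
```

The validation MAE of 0.247 on the original abundance scale sits just
above the analytic optimum for this simulation,
`optimal_one_step_mae(spec)` = 0.3·sqrt(2/pi) ≈ 0.2394 — the best any
forecaster can do against Gaussian innovations of sd 0.3. Forecasts are
returned on both the standardized and the original scale (here the
simulator's stationary mean is 10).

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/microstnet.R simulate --outdir run --seed 1
Rscript inst/cli/microstnet.R build-network --input run/abundance.tsv --outdir run
Rscript inst/cli/microstnet.R train --input run/abundance.tsv --outdir run
Rscript inst/cli/microstnet.R predict --checkpoint run/checkpoint.json \
        --input run/abundance.tsv --out run/forecast.tsv --h 8
```

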