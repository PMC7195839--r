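# nlgrn — non-linear reverse engineering of gene regulatory networks

`nlgrn` reconstructs small gene regulatory networks from time-course
expression data, for systems where *pairs* of regulators may act together —
as protein heterodimers or through synergistic co-regulation. The motivating
system is hematopoietic stem-cell fate choice (erythrocyte vs neutrophil
differentiation), where modules such as Gata1–PU.1 act as dimers and simple
additive models miss the biology.

The pipeline has four stages:

1. **Structure search (top-down).** For `m` genes the data are augmented
   with all `n = m(m-1)/2` non-linear terms (NLTs), the product series
   `y_kl(t) = x_k(t) x_l(t)`. A Gaussian graphical model forward search adds
   one edge at a time: each candidate edge is scored by the deviance
   difference between the constrained maximum-likelihood covariance fits
   with and without it (iterative proportional scaling under the graph's
   zero pattern), referred to a χ²(1) tail; the smallest p-value below the
   cutoff (default 0.1) enters. Stage one searches gene–gene edges and
   orients them into a DAG (`m1` edges); stage two searches NLT→gene edges
   starting from that graph, capped at `n1 ≤ m1` so product terms cannot
   dominate. NLT–NLT edges are never considered.
2. **Dynamics (bottom-up).** The selected network parameterises the ODE
   model

   ```
   dx_i/dt = Σ_{j→i} α_ij x_j + Σ_{(j,k)→i} β_ijk x_j x_k − k_i x_i
   ```

   with no auto-regulation (`α_ii = 0`) and no squared terms
   (`β_ijj = 0`). Simulation uses an adaptive Dormand–Prince RK45
   integrator (compiled) started from the observed first time point.
3. **Parameter estimation.** A real-coded elitist genetic algorithm
   minimises the simulation error `E = sqrt(Σ_ij (x_ij − x*_ij)²)` over a
   bounded box, with multi-start (default 200 restarts, keep the best 10)
   and a deterministic local polish of each run's best individual.
4. **Robustness and pruning.** Each fitted model is scored by perturbing
   all parameters multiplicatively, `θ → θ(1 + μ ε)`, `ε ~ N(0,1)`,
   `μ = 0.4`, `N = 5000` draws: `RA`/`RSTD` are the mean and sd of the
   trajectory displacement from the unperturbed simulation. A greedy
   deletion loop then removes the regulations whose loss changes the
   simulation error least (product terms first, then gene edges), stopping
   when both error and robustness become markedly worse than the original
   model.

A synthetic-data module generates ground-truth worlds on the 30-point /
168-hour microarray sampling schedule (dense early sampling, sparse late),
with three multiplicative log-normally noised replicates averaged — so the
whole pipeline is testable without any external data.

## Worked example

```r
library(nlgrn)

spec  <- synthetic_spec(m = 5, m1 = 5, n1 = 3, seed = 1)
truth <- generate_network(spec)          # ground-truth DAG + parameters
world <- generate_dataset(truth, spec)   # 3 noisy replicates, averaged
world$dataset
#> <gene_dataset> 5 genes x 30 time points (0-168 h)

net <- run_efsa(world$dataset)           # two-stage forward search
net
#> <grn_network> 5 genes, 9 gene->gene edges, 9 NLT->gene edges, 1 isolated NLTs
head(net$gene_edges, 3)
#>   source target rank      p_value
#> 1    G02    G04    1 8.927385e-41
#> 2    G02    G01    2 1.426968e-40
#> 3    G04    G05    3 5.987515e-16

cfg <- ga_config(generations = 100, population = 40, n_restarts = 4,
                 top_k = 2, bounds = list(alpha = c(-3, 3)/168,
                                          beta = c(-3, 3)/168, k = c(0, 1)),
                 base_seed = 1)
fits <- multi_start(net, world$dataset, cfg)
fits[[1]]
#> <fit_result> E = 0.126795 (seed 4, 100 generations)

dsn <- normalize_dataset(world$dataset, "per_gene_max")
robustness(net, fits[[1]]$params, dsn,
           robustness_config(mu = 0.4, n_perturb = 1000, seed = 1))
#> <robustness_report> RA = 2.55557, RSTD = 23.9695, failed 14/1000

trace <- greedy_prune(net, fits[[1]], world$dataset,
                      robustness_config(mu = 0.4, n_perturb = 500, seed = 1),
                      screen_n = 100)
as.data.frame(trace)[1:4, ]
#>   Model             RR        SE       RA      RSTD
#> 1   OES            N/A 0.1267951 1.584525  4.531564
#> 2  DEL1 G01:G04 -> G05 0.1268010 1.586848  4.586052
#> 3  DEL2 G01:G05 -> G05 0.1282155 1.324849  2.299892
#> 4  DEL3 G01:G02 -> G05 0.1317645 4.396320 64.069370
```

Reading the output: the forward search kept 9 gene edges and 9 product-term
edges (rank = order of selection; p\_value = χ²(1) tail of the deviance
difference). The best of four GA restarts reproduces the normalized data
with total error `E ≈ 0.13`. The robustness report says a 40% multiplicative
parameter jolt displaces trajectories by `RA ≈ 2.6` on average, with 14 of
1000 perturbed systems diverging (excluded and counted). The deletion trace
mirrors the published table layout (`Model`, `RR` = removed regulation,
`SE`, `RA`, `RSTD`): the first two removals are inert product terms
(`SE` essentially unchanged), after which removals start to cost accuracy.

## Command line

```sh
Rscript -e 'nlgrn::nlgrn_cli()' run-all --out out_dir --seed 1
Rscript -e 'nlgrn::nlgrn_cli()' synth --config config.json --out out_dir
```

Subcommands `synth`, `efsa`, `fit`, `robust`, `prune`, `run-all`; JSON
configuration (see `desk_preset()` / `paper_preset()`); every run writes a
config snapshot and log beside its artifacts (expression TSVs, network
edge-table/SIF, ranked fits, parameter documents, robustness JSON, deletion
trace CSV).

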