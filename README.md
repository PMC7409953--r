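# idpscore

Bayesian maximum-log-likelihood scoring and Monte Carlo selection of
conformer ensembles for intrinsically disordered proteins (IDPs) and
unfolded protein states.

## The problem

Disordered proteins have no single structure; what an experiment measures is
an ensemble average. Given a pool of candidate conformers and heterogeneous
solution data — NMR chemical shifts, three-bond J-couplings, NOE and PRE
distance restraints, residual dipolar couplings, hydrodynamic radius, mean
smFRET transfer efficiency, and SAXS intensity curves — the task is to find
size-N sub-ensembles whose averages agree with the data *to within what the
experimental and back-calculation uncertainties allow*, and no further.

## The model

For an ensemble X and M restraints the score is

    log p(X, xi | D, I) = log p(X | I)
                        + sum_j log[ p(d_j | X, xi_j, I) p(xi_j | I) ] + C

with an uninformative structural prior. Every uncertainty is an explicit
Gaussian nuisance parameter xi_j, maximized in closed form per restraint:

* **Offset model** (CS, NOE, PRE, RDC, R_h, FRET, SAXS points): a
  back-calculation offset q ~ N(0, sigma_q) plus a residual
  eps = d - q - <o> ~ N(0, sigma_ex); the optimum is
  q\* = sigma_q^2 (d - \<o\>) / (sigma_q^2 + sigma_ex^2).
* **Karplus model** (JC): J = A\<cos^2(phi-phi0)\> + B\<cos(phi-phi0)\> + C
  with A, B, C Gaussian around the Vuister–Bax means (6.51, -1.76, 1.60) and
  a residual term with sigma = 0.5 Hz; the quadratic objective is maximized
  by a 3x3 linear solve.

Ensemble averages are arithmetic except NOE/PRE, which use the r^-6
convention (mean d^-6)^(-1/6). SAXS totals are multiplied by the Shannon
weight min(1, N_s/N_q) with N_s = D_max (q_max - q_min) / pi, so an
oversampled curve cannot drown single-restraint data types. Sub-ensembles
(multisets of N = 100 conformers by default) are refined by conformer-swap
Monte Carlo — greedy (strictly increasing score) or Metropolis with
acc = min(1, exp(beta * delta)), beta = 0.1 — using cached running sums that
make each swap O(restraints), independent of N.

## Worked example

A synthetic two-population pool (compact/helical "A" vs expanded "B"),
pseudo-experimental data generated at a 75/25 ground-truth mixture, and a
joint local + long-range (JC + PRE) greedy optimization:

```r
library(idpscore)
truth <- synthetic_truth(n_pool = 1000)
pool  <- make_pool(truth, seed = 1)
exper <- make_experimental(pool, c(A = 0.75, B = 0.25), seed = 2)

ctx <- synthetic_context(pool, exper[c("JC", "PRE")])
run <- run_replicates(ctx,
                      optimizer_config(n_steps = 10000, ensemble_size = 100,
                                       n_replicates = 20),
                      master_seed = 3)
print(score_report(run))
```

```
score_report: greedy optimization of JC+PRE, 20 replicates x 10000 steps, N = 100
  JC    score   230.98 (0.34)   rmsd   0.2300 (0.0081)
  PRE   score   385.14 (0.27)   rmsd   3.2984 (0.0170)
  composition: A = 0.754, B = 0.246
```

The report gives, per data type, the replicate mean (sd) of the maximized
log-likelihood and of the RMSD between ensemble-averaged back-calculated
values and the targets. The optimizer recovers the ground-truth dominant
population fraction (0.754 vs 0.75) from the two restraint types alone:
J-couplings pin the local backbone mixture while PREs pin the long-range
contact mixture. The PRE RMSD of ~3.3 Å sits below the experimental
sigma of 3.75 Å, i.e. the fit is as good as the restraint widths warrant.

Scoring real data uses the same path: `load_restraints()` +
`load_backcalc()` per data type (TSV tables; SAXS also accepts 3-column
`.dat`), `read_pool()` for multi-model PDB pools with
`jc_table_from_pool()` / `distance_table_from_pool()` /
`fret_table_from_pool()` for the observables computed from coordinates,
then `scoring_context()` and `run_replicates()`.

## Documentation

The methods vignette (`vignettes/ensemble-scoring.Rmd`) documents the
likelihood models, default uncertainties and their units, the averaging
conventions, the SAXS information weighting, the optimizer, what the
synthetic generator does and does not emulate, and known limitations.
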