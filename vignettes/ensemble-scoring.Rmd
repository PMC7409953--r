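---
title: "Bayesian scoring and Monte Carlo selection of disordered-protein ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian scoring and Monte Carlo selection of disordered-protein ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpscore)
```

## The problem

An intrinsically disordered protein (IDP), or the unfolded state of a
foldable domain, is not a structure but a distribution over conformations.
Solution experiments constrain that distribution only through averages: a
chemical shift is an ensemble-averaged shift, an NOE is an r^-6-weighted
average distance, a SAXS curve is an average scattering profile. Selecting a
sub-ensemble of conformers that "agrees with the data" therefore requires a
model of *how well agreement can even be expected*, given that both the
experiments and the back-calculators that predict observables from
coordinates carry substantial, type-specific uncertainty.

This package scores a candidate sub-ensemble `X` of `N` conformers against
`M` restraints by a maximum log-likelihood in which every uncertainty is an
explicit Gaussian nuisance parameter:

$$\log p(X, \xi \mid D, I) \;=\; \log p(X \mid I) \;+\;
  \sum_{j=1}^{M} \log\!\big[\, p(d_j \mid X, \xi_j, I)\, p(\xi_j \mid I) \,\big] + C .$$

The structural prior is uninformative (the constant `C` is fixed to 0), so
the score is the sum over restraints of a per-restraint term maximized over
its nuisance parameters. Because all densities are Gaussian, every
maximization has a closed form; scoring is exact and fast, and the same
closed forms drive the Monte Carlo selection described below.

## The two likelihood models

**Offset model** (chemical shifts, NOE/PRE distances, RDCs, R~h~, mean FRET
efficiency, individual SAXS intensity points). The back-calculation error is
an additive offset `q ~ N(0, sigma_q)`, and the residual
`eps = d - q - <o>` between the target `d` and the ensemble-averaged
observable `<o>` is `N(0, sigma_ex)`. Maximizing over `q` gives

$$q^\ast = \frac{\sigma_q^2\,(d - \langle o\rangle)}{\sigma_q^2 + \sigma_{ex}^2},
\qquad
\epsilon^\ast = d - q^\ast - \langle o\rangle ,$$

with the stationarity identity `q* sigma_ex^2 = eps* sigma_q^2`. The
maximized log-density collapses to a single Gaussian in the discrepancy with
variance `sigma_q^2 + sigma_ex^2` plus the two normalization constants; the
constants are kept (scores are absolute log-likelihoods of mixed sign across
types), and keeping `q` explicit, rather than folding the two sigmas
together, lets `sigma_ex` vary per measurement while `sigma_q` stays a
property of the back-calculator.

**Karplus model** (three-bond J-couplings). The back-calculation is the
Karplus relation `J = A <cos^2(phi - phi0)> + B <cos(phi - phi0)> + C` with
the coefficients themselves Gaussian nuisance parameters around the
Vuister–Bax values (`mu_A = 6.51, sigma_A = 0.14; mu_B = -1.76, sigma_B =
0.03; mu_C = 1.60, sigma_C = 0.08`), plus a residual term with `sigma_ex =
0.5` Hz. The objective is quadratic in `(A, B, C)`, hence the optimum is the
solution of a 3-by-3 linear system, implemented in closed form
(`optimize_karplus`). Note the quadratic term uses the ensemble average of
the *squared* cosine, `a2 = <cos^2>`, alongside `a1 = <cos>`; per conformer
`a2 = a1^2`, and for ensembles Jensen's inequality `a2 >= a1^2` is enforced
as a precondition.

Ensemble averaging conventions per type: arithmetic means for chemical
shifts, the JC cosine terms, RDCs, R~h~, FRET efficiency (fast-exchange
regime: efficiencies are averaged, not distances) and SAXS intensities; the
r^-6 mean `(mean d_i^-6)^(-1/6)` for NOE and PRE distances, which weights
short conformer distances heavily, as the underlying relaxation physics
does.

## Default uncertainties

All defaults live in `uncertainty_config()` and every value is overridable
from a YAML file (`read_config()`). Units follow the data type: ppm (CS), Hz
(JC, RDC), Angstrom (NOE, PRE, R~h~), dimensionless efficiency (FRET),
relative intensity (SAXS).

* CS: `sigma_ex` 0.3 ppm for carbons, 0.03 ppm for hydrogens; `sigma_q` is
  published as a band (0.3–0.5 ppm H, 1.2–1.4 ppm C) without a per-atom
  assignment, so the band midpoints (0.4 / 1.3 ppm) are the defaults.
* NOE/PRE: restraint ranges are converted at load time — the target is the
  mid-range value and `sigma_ex` is the range divided by 2 (NOE) or 4 (PRE),
  e.g. a "< 8 Å" NOE becomes target 4 Å, sigma 4 Å; a 10–25 Å PRE becomes
  target 17.5 Å, sigma 3.75 Å. `sigma_q = 1e-4` Å for both: the "back-
  calculation" is a direct coordinate measurement, so its error is a near-
  zero sentinel. This makes the offset prior contribute a large constant
  per restraint (about `-log(1e-4 * sqrt(2*pi)) ≈ 7.8`), which dominates
  absolute NOE/PRE score magnitudes — comparisons should always be between
  ensembles under the same configuration, never across configurations.
* RDC: `sigma_q = 0.9` Hz, `sigma_ex = 1.0` Hz; per-conformer RDCs are
  consumed as an external back-calculation table.
* R~h~: `sigma_q = 0.8` Å, `sigma_ex = 0.30` Å; external table.
* FRET: `sigma_q = 0.007`, `sigma_ex = 0.02`. These two values are used on
  the dimensionless efficiency scale, although the source material prints
  them with distance units; an efficiency uncertainty is the only reading
  under which they are usable, and they are configurable.
* SAXS: `sigma_q = 0.006`; `sigma_ex` decreases linearly from 0.002 at the
  lowest Q to 0.0008 at the highest when not supplied per point.

`phi0` defaults to 60 degrees — the standard 3J(HN–HA) convention for the
Vuister–Bax parameterization — and is configurable because conventions
differ between Karplus parameter sets.

The FRET dye model (`fret_distance_scaled`) scales the CA–CA distance by
`((N + N_linker)/N)^upsilon`. Defaults `N_linker = 9`, `upsilon = 0.55` and
Förster radius `r0 = 52` Å are typical values for common dye pairs on
unfolded chains; they matter only when efficiencies are computed from
coordinates rather than supplied as a table, and all three are configurable.

## SAXS information weighting

A SAXS curve with `N_q` points is not `N_q` independent observations:
neighbouring intensities are strongly correlated. The effective number of
independent points is the Shannon channel count
`N_s = D_max (q_max - q_min) / pi` (`shannon_channels`). The SAXS
log-likelihood total is multiplied by `min(1, N_s / N_q)`, so an oversampled
curve cannot overwhelm single-restraint types such as R~h~ or mean FRET
efficiency in a joint optimization. The factor multiplies the entire
per-point sum, normalization constants included — the simplest reading of a
rescaled log-likelihood; scaling only the chi-square residual part is
available via `cfg$saxs$weight_mode = "residual"` for users who prefer to
keep the constants unweighted. On the default synthetic grid (37 points,
0.01–0.17 1/Å, D_max 60 Å) the weight is about 3/37, reproducing the
oversampling regime of typical unfolded-domain curves.

## Monte Carlo sub-ensemble selection

The unit being optimized is a size-`N` multiset of pool indices (the same
conformer may be selected repeatedly — a selected-multiplicity is how a
discrete pool expresses population weight). Each step proposes replacing a
uniformly chosen member with a uniformly chosen pool conformer and accepts
either greedily (strictly increasing score; ties rejected) or by the
Metropolis rule `min(1, exp(beta * delta))` with `beta = 0.1` by default.
The working defaults are `N = 100` and 10,000 exchange attempts; replicate
runs (default 1000; tests and examples use fewer) draw fresh initial
sub-ensembles from independent seeds spawned from one master seed
(Mersenne-Twister), making an entire run a pure function of inputs plus
master seed.

Scoring is incremental: the state caches per-restraint running sums (raw
values for linear averages, `d^-6` for NOE/PRE, the two cosine sums for JC),
so a swap costs O(restraints), independent of `N` and of the pool size. To
bound floating-point drift the cache is rebuilt from scratch every 1000
accepted swaps, and `audit_state()` verifies cache integrity at any time;
after 10^4 random swaps the cached objective agrees with full recomputation
to better than 1e-8.

Alongside the log-likelihood score, reports carry a per-type RMSD between
ensemble-averaged back-calculated values and targets (absolute deviation for
the single-restraint types), which is easier to read across types than
absolute scores.

## What the synthetic generator emulates — and what it does not

`synthetic_truth()` describes a pool partitioned into labelled populations
with distinct observables: different backbone phi preferences (local
structure), contact-distance scales (compaction), chemical-shift and RDC
offsets, R~h~, dye-to-dye distances and SAXS size. `make_pool()` realizes
per-conformer observable tables directly — phi angles drawn wrapped-normal
and passed through the Karplus cosine; distances log-normal; FRET
efficiencies induced from distances through the polymer-scaled Förster
relation; SAXS curves Guinier-shaped per population. Restraint counts
default to the scale of a well-studied unfolded SH3 domain data set (267
CS, 47 JC, 93 NOE, 68 PRE, 28 RDC, 37 SAXS points, one R~h~, one FRET).
`make_experimental()` forms targets as mixture averages of the empirical
population observables under chosen ground-truth weights (r^-6 convention
for NOE/PRE, efficiency averaging for FRET) plus Gaussian noise at the
per-type `sigma_ex`.

Two properties make the generator a sharp test instrument. First,
*self-consistency*: with zero within-population spread, zero noise and
target weights equal to the realized label frequencies, scoring the full
pool drives every residual to zero and the total equals the analytic score
ceiling (`score_upper_bound`). Second, *recoverability*: with target
weights (0.75, 0.25) and informative local + long-range restraints (JC +
PRE), greedy optimization over 100 replicates recovers the dominant
population fraction to within ±0.1.

What passing these tests does **not** show about real data: synthetic
observables are conditionally independent given the population, whereas real
conformers couple all observables through one geometry; real back-calculator
errors are systematic, not Gaussian offsets; NOE distances here ignore
dynamics (no relaxation-matrix treatment); and pool insufficiency — the
dominant failure mode with real conformer libraries — is only present in the
synthetic world if you construct it. The generator validates the inference
machinery, not any claim about a particular protein.

## Numerical choices and degenerate inputs

* Closed-form optima are verified against numerical maximization oracles
  (1-D golden-section for the offset model, 3-D BFGS for Karplus) to 1e-6
  in log-likelihood over thousands of random instances; stationarity
  identities hold to 1e-10.
* `sigma_q = 0` pins the offset at zero and drops the degenerate prior
  density term rather than returning an infinite constant.
* Empty restraint sets score exactly 0 (vacuous sum); empty ensembles are an
  error.
* Greedy ties (`delta = 0`) are rejected — the acceptance inequality is
  strict — so an identity swap can never be "accepted".
* Torsion angles follow the IUPAC sign convention, validated against an
  independent structural-bioinformatics implementation; collinear atom
  quadruples raise an error rather than returning an arbitrary angle.
* Problem sizes in tests (pools of 120–1000 conformers, 100 replicates in
  the recovery study) were chosen as the smallest sizes at which the
  statistical assertions are stable under the fixed seeds.

## A small worked run

```{r example, eval = FALSE}
truth <- synthetic_truth(n_pool = 1000)
pool  <- make_pool(truth, seed = 1)
exper <- make_experimental(pool, c(A = 0.75, B = 0.25), seed = 2)

ctx <- synthetic_context(pool, exper[c("JC", "PRE")])
run <- run_replicates(ctx,
                      optimizer_config(n_steps = 10000, ensemble_size = 100,
                                       n_replicates = 20),
                      master_seed = 3)
print(run)
score_report(run)
```

The printed composition should sit near the ground-truth 0.75/0.25 split,
and per-type RMSDs drop well below their unoptimized counterparts.

## Known limitations

* NOE/PRE scoring treats restraints as static distance targets; no
  dynamical (relaxation-matrix) treatment.
* Chemical shifts, RDCs, R~h~ and SAXS intensities require externally
  back-calculated per-conformer tables; only phi/Karplus terms, distances,
  FRET efficiencies and R~g~ are computed from coordinates here.
* No Boltzmann-weighted structural prior; the pool is the prior.
* Absolute score magnitudes depend on configuration constants (notably the
  NOE/PRE sentinel `sigma_q`); only differences under a fixed configuration
  are meaningful.
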