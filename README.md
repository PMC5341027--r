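# ibclust — individual-based clustering of movement data

`ibclust` clusters **individuals** — marked birds, tagged animals, geolocated
social-media users — by the locations at which they were observed, instead of
clustering the locations themselves. Because groups are defined over
individuals, a location can belong to several groups at once, which is what
makes it possible to find *mixed-membership sites*: the critical connectivity
sites through which otherwise separate subpopulations are linked. The same
machinery tracks how the *same* individuals shift their visitation between
time windows, and estimates where visitors come from.

## The model

The data are a matrix `w` with one row per individual and one column per
location; `w[j, l]` counts how often individual `j` was seen at location `l`
(`n_j` observations in total for individual `j`). The generative model is a
Bayesian multinomial mixture:

- `z_j ~ Categorical(β)` — individual `j` belongs to latent group `z_j`;
- `w_j | z_j = k ~ Multinomial(n_j, ψ_k)` — its counts follow the group's
  visitation profile `ψ_k`, a probability vector over the L locations;
- `ψ_k ~ Dirichlet(ε, …, ε)` — a vague prior on each profile (`ε = 0.1`);
- `β` has a **truncated stick-breaking prior**: `V_k ~ Beta(1, α)` for
  `k < K`, `V_K = 1`, and `β_k = V_k ∏_{m<k} (1 − V_m)` (`α = 0.1`,
  `K = 25`).

The stick-breaking prior favours few occupied groups, so only the truncation
level `K` is fixed in advance and the number of *effective* groups `k* < K`
emerges from the data. Fitting is by a blocked Gibbs sampler (conjugate
draws of `ψ | z`, `V/β | z`, and categorical draws of `z | β, ψ`), with
collapsed label-swap Metropolis moves to mix between label modes. The inner
loop is C++ (Rcpp).

Downstream of the fit:

- `effective_groups()` — the occupied groups and the fraction of individuals
  they cover;
- `mixed_membership_sites()` — classify each site as unvisited / single /
  mixed at a visitation cutoff (default 0.02);
- `group_edges()` — per-group site networks (sites with `ψ_kl` above 0.05
  linked pairwise);
- `conditional_refit()` + `delta_visitation()` — re-estimate `ψ` on a later
  window with memberships frozen, and flag sites whose visitation change has
  a 95% credible interval excluding 0;
- `origin_shares()` — the share of individuals "from" location `l`, read off
  as `β_{k*}` for the group `k*` that visits `l` the most;
- `cohort_composition()` — cross-tabulate group membership against
  individual traits the model never saw.

`scenario_preset()` and `simulate_counts()` generate benchmark datasets with
known ground truth, including two four-group designs (9 of 50 and 27 of 50
mixed-membership sites) and a two-period invasion design.

## Worked example

```r
library(ibclust)

spec <- scenario_preset("scenario1")      # 4 groups, 50 sites, 9 mixed
sim  <- simulate_counts(spec, seed = 1)
fit  <- relabel_samples(run_gibbs(sim$counts, seed = 2))

effective_groups(fit, min_share = 0.01)
#>   group occupancy beta_mean n_members
#> 1     1      0.25 0.2495729       100
#> 2     2      0.25 0.2509060       100
#> 3     3      0.25 0.2494839       100
#> 4     4      0.25 0.2496873       100

sites <- mixed_membership_sites(psi_mean(fit), 1:4, cutoff = 0.02)
table(sites$status)
#> unvisited    single     mixed
#>         0        41         9
```

The fit recovers the four designed groups exactly — each holding 25% of the
400 simulated individuals — and classifies all 50 sites correctly: the 9
sites designed to be shared by two groups come out `mixed`, the rest
`single`.

A temporal analysis freezes the memberships and refits the later window:

```r
refit <- conditional_refit(counts_t2, posterior_modes(fit))
delta <- delta_visitation(fit, refit, level = 0.95)
subset(delta, significant)   # sites with credible change in visitation
```

A thin command-line driver wraps the same functions
(`system.file("cli/ibc.R", package = "ibclust")`) with subcommands
`simulate`, `fit`, `refit`, `summarize`, and `pipeline`; `run_pipeline()`
executes the whole workflow from a JSON/YAML config and writes a manifest
with checksums, so runs are reproducible bit-for-bit from (inputs, config,
seed).

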