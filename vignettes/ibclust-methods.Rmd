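---
title: "Methods: the individual-based clustering model and its implementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the individual-based clustering model and its implementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibclust)
```

## The model and its assumptions

`ibclust` treats each **individual** as the sampling unit. The data are a
J × L matrix of nonnegative counts: how often each of J individuals was
observed at each of L locations. The model assumes that

1. each individual belongs to exactly one latent group `z_j`, drawn from
   group weights `β`;
2. given its group, an individual's counts are multinomial over locations
   with the group's visitation profile `ψ_k` — observations are exchangeable
   within an individual, and the total effort `n_j` is treated as fixed
   (conditioned on, not modelled);
3. profiles are a priori `Dirichlet(ε)` and the weights follow a truncated
   stick-breaking construction, `V_k ~ Beta(1, α)` for `k < K`, `V_K = 1`,
   `β_k = V_k ∏_{m<k}(1 − V_m)`.

Assumption 2 is the crucial simplification: the model clusters *where*
individuals are seen, not their movement trajectories. Transition-level
structure (which site follows which) is invisible to it, and detection is
assumed perfect — an individual absent from a site's counts is taken to not
use the site, not to have been missed there. Both caveats matter when
interpreting results on field data.

Membership is hard (one group per individual), but *site* membership is
soft: any number of groups can place visitation mass on the same location.
That asymmetry is what lets the method identify mixed-membership sites that
location-clustering algorithms, which must give each site one label, cannot
represent.

## Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `K` | 25 | truncation level: the maximum number of groups. Not constrained by L; it only needs to comfortably exceed the number of groups the data support. |
| `alpha` | 0.1 | stick concentration. Small values make early sticks long, i.e. favour few occupied groups; the prior-predictive number of occupied groups grows with `alpha` (a property the test suite checks). |
| `epsilon` | 0.1 | per-location Dirichlet concentration; 0.1 keeps the profile prior vague while guaranteeing strictly positive `ψ`, so no likelihood term can be exactly zero. |

All three are dimensionless. The defaults are the package's standard
operating point and are echoed by every interface.

## The sampler

Fitting is by a blocked Gibbs sampler over `(ψ, V/β, z)`:

- `ψ_k | z, w ~ Dirichlet(ε + c_k1, …, ε + c_kL)`, with `c_kl` the summed
  counts of group k at location l (empty groups draw from the prior);
- `V_k | z ~ Beta(1 + n_k, α + s_k)` with `n_k` the occupancy and `s_k` the
  number of individuals in later groups; `V_K = 1`;
- `z_j | β, ψ, w_j` categorical with
  `p_k ∝ β_k ∏_l ψ_kl^{w_jl}`, evaluated in log space with per-row
  max-subtraction (counts in the hundreds underflow direct products).

Design choices where the construction was genuinely open:

- **Initialisation.** `z` starts uniform at random over the K groups from
  the seeded generator; a uniform start avoids biasing early sweeps toward
  few groups.
- **Scan order** is `ψ`, then `V/β`, then `z`, fixed for reproducibility;
  any fixed order is a valid Gibbs scan.
- **Label-swap moves.** Before each sweep the sampler proposes K
  Metropolis swaps of group labels on the collapsed membership posterior.
  Swapping the contents of two groups permutes the (label-invariant)
  Dirichlet-multinomial factors, so the acceptance ratio reduces to the
  stick-prior term `∏_{k<K} B(1 + n_k, α + s_k)`. Because `ψ` and `β` are
  freshly conjugate-drawn from `z` immediately afterwards, the joint chain
  remains exact. Without these moves the chain crosses between label modes
  only through rare single-individual excursions, and on small instances the
  relative mass of mirror modes converges too slowly for the
  exact-enumeration checks in the test suite.
- **Schedule defaults** are 10,000 sweeps, 5,000 burn-in, thinning 10 (500
  kept draws). These are comfortable for the benchmark problem sizes used
  throughout (hundreds of individuals, 50 locations); larger datasets mix
  more slowly per sweep but also average over more rows, and the stored
  log-likelihood trace (multinomial coefficients included, so traces are
  comparable across runs) is the first diagnostic to consult.
- Individuals with a zero row total are rejected up front rather than
  silently dropped: a never-observed individual carries no information and
  breaks the multinomial.

### Relabeling

The mixture posterior is invariant to permuting group labels, so stored
draws are aligned before any per-group summary. Within each draw, groups are
sorted by decreasing occupancy (ties keep original index order), matching
the convention of presenting "group 1" as the largest. Across draws, each
draw's groups are then greedily matched to the running posterior mean — the
matching distance is the total variation distance between `ψ` rows **plus
the absolute difference in occupancy fraction**. The occupancy term is a
deliberate addition: when profiles are nearly indistinguishable (notably
the empty groups, whose `ψ` rows are all prior draws), pure profile distance
makes the matching arbitrary from draw to draw and smears occupancy across
slots; the occupancy term pins the matching without affecting well-separated
groups, for which the profile term dominates. Stick fractions are recomputed
from the permuted `β` by inverting the stick construction.

### Conditional refit

Temporal comparisons freeze each individual's membership at the value
learned from the first window (the posterior mode after relabeling) and
rerun the sampler on the second window's counts with the `z`-update
disabled. By default `β` is re-drawn as well — weights are period-specific —
and a flag can freeze it. Individuals present in only one window are dropped
with a warning. With `z` fixed the `ψ` posterior is exactly the per-group
conjugate Dirichlet, which the test suite verifies against the closed form.

## Posterior summaries

- **Effective groups**: posterior mean occupancy fraction ≥ `min_share`,
  default 0.01. The inclusion rule for "main groups" is not canonical;
  1% of individuals reproduces a "drop the near-empty groups" reading
  without a dataset-specific magic number, and the threshold is exposed.
- **Site classification** uses cutoff 0.02 and **edge drawing** 0.05 on the
  posterior mean `ψ` (point estimates of visitation are posterior means
  throughout). Both cutoffs are flags.
- **Temporal change** `Δψ = ψ^{t2} − ψ^{t1}` is summarised per (group,
  site) by the posterior mean and an **equal-tailed** credible interval from
  empirical percentiles (2.5/97.5 at the default level) — the simplest
  defensible reading of an unqualified "95% credible interval"; HPD
  intervals are not used. A site is flagged significant when the interval
  excludes 0. Draws are paired by index when the two chains keep equally
  many draws (they then share a seed lineage), otherwise by independent
  resampling, which widens intervals slightly; the pairing rule is
  deterministic given the stored draws, so flags are exactly reproducible.
- **Origin shares** report `β_{k*}` where `k*` is the effective group with
  the largest posterior mean visitation at the location; ties go to the
  lowest group index with a message.

## The synthetic generator

`scenario_preset()` encodes four benchmark designs on 50 abstract locations
(locations are labels, not coordinates — the model itself is non-spatial):

- **scenario1**: 4 groups of 100 individuals; 41 sites visited by exactly
  one group (11/10/10/10 across groups) and 9 shared by adjacent group
  pairs (3 + 3 + 3).
- **scenario2**: 4 groups of 100; 23 single-group sites and 27 mixed sites —
  26 shared by two groups spread over all six group pairs, plus one site
  shared by three groups to exercise overlap beyond pairs.
- **invasion_t1 / invasion_t2**: 2 groups of 100 on disjoint 25-site halves
  at t1; at t2 the invading group moves 50% of its mass, spread evenly, onto
  10 of the resident group's sites (`invaded_sites`), while the resident
  profile is unchanged — only one community expands.

Within a group, true visitation mass is uniform over the group's designed
sites. Only the structural facts of the designs (50 locations; 4 and 2
groups; 9, 27 mixed sites; one-sided invasion) are fixed by the benchmark
definitions; the exact profile values, 100 individuals per group, and a
fixed effort of 20 observations per individual are this package's choices —
large enough for reliable recovery, small enough that a full fit takes
seconds. `simulate_counts()` assigns individuals to groups in deterministic
blocks so realised group sizes are exact (cleaner recovery tests); a flag
restores the categorical membership draw of the generative model.

What passing the benchmark tests does **not** show about field data: the
generator has no imperfect detection, no site-level observation bias (e.g.
platform-penetration differences), equal effort across individuals, and
within-group homogeneity of visitation. Real recoveries will degrade with
unequal effort and detection gaps in ways these tests do not measure.

## Numerical choices

- Simplex invariants (`β`, `ψ` rows, true profiles) are enforced to 1e-12;
  gamma-normalisation underflow in a profile draw (possible only at extreme
  `ε`) falls back to a uniform row rather than dividing by zero.
- The membership conditional and the log-likelihood use max-subtracted log
  sums; an all-`-Inf` row aborts with a diagnostic (unreachable for
  `ε > 0`).
- All randomness flows through R's RNG, so a single integer seed reproduces
  a run bit-for-bit, including in the C++ inner loop.
- The exact-enumeration oracle used in the tests computes
  `p(z) ∝ ∏_{k<K} B(1 + n_k, α + s_k) × ∏_k DirMult(c_k)` over all `K^J`
  assignment vectors; it is tractable only for toy sizes (J ≤ 3 in the
  suite) and is deliberately implemented apart from the sampler.
- Test problem sizes: full-scale scenario fits use the default schedule;
  the enumeration checks run 50,000 kept draws at thinning 2 per instance.

## Known limitations

- No trajectory modelling (pairwise-movement profiles would square the
  parameter count), no detection-probability layer, no covariate regression
  on membership — attribute associations are assessed descriptively via
  `cohort_composition()`.
- Hard individual membership: an individual splitting time between two
  communities is forced into one group, with its profile absorbing the
  mixture.
- The truncation `K` must exceed the true number of groups; if
  `effective_groups()` returns a count at or near `K`, refit with larger
  `K`.
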