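---
title: "Methods: resemblance, parental types and transmission biases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resemblance, parental types and transmission biases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cultnet)
```

# The data model

The unit of analysis is a *network*: one focal student plus up to nine
further agents (a second questionnaire sitting by the same student, two
parents, two friends, four grandparents), each holding a real-valued
score on each of several latent attitude/behaviour factors. Scores are
assumed to be centred factor scores, so 0 is the sample mean of each
factor — this matters because dichotomisation thresholds at 0.

Networks are ragged. The package therefore treats the long format
(`network_id, role, factor, score`) as canonical, validates key
uniqueness and the presence of a student in every network, and makes
absence explicit: a relationship component (Vertical = mean of available
parents, Horizontal = mean of available friends, grandparental likewise)
is `NA` when no member is present, never silently zero. When only one
member of a pair is available the component is that member's score — the
mean over *available* members — which keeps single-parent networks in the
analysis rather than discarding them.

Three inclusion rules are provided. `student_plus_any` drops networks in
which nobody beyond the student (and their second sitting) responded;
`parent_and_friend` is the composition the parental-type analysis needs;
`parent_friend_and_grandparent` supports grandparent-mediation questions.
Imputation is deliberately simple and pluggable: the default
`column_mean` imputer affects on the order of 2% of values at the
missingness rates these surveys show, and anything cleverer can be
supplied as a function. Imputation refuses factors that are half missing
or worse rather than fabricating data.

# Resemblance

For a role pair and factor, the veridical Pearson correlation `r` is
computed over the networks where both scores exist (pairwise deletion per
role pair, which maximises the n available to each pair). The null is
built by permuting the *second* role's vector across networks `n_perm`
times: this destroys the pairing while preserving both marginal
distributions, which is exactly the hypothesis of interest ("does a
student resemble *their* mother more than a random mother?"). Permuting
both vectors would be redundant under exchangeability, so only one is
permuted, and the direction is documented so runs are seed-reproducible.

The statistic is `z = (r − mean(r_null)) / sd(r_null)`. A two-sided
Monte-Carlo p-value is attached with the add-one correction
`(#{|r_null| ≥ |r|} + 1) / (n_perm + 1)`, which cannot be zero; the
z-score is the primary quantity, the p-value a convenience. Note the
permutation null of `r` is not centred at zero exactly — its mean is
about `−1/(n−1)` — which the z-score definition absorbs.

Degenerate inputs error early: fewer than 3 complete pairs, or zero
variance in either vector (a constant role cannot be correlated with
anything). In `resemblance_graph()` these become logged skips instead of
errors, because whole-graph runs routinely contain untestable pairs
(e.g. a grandparent role absent from every network). Edge tiers use the
conventional two-sided normal cuts 1.96 and 3.3 (p ≈ 0.05 and 0.001);
tie categories are derived from role identities, with lineage respected —
a maternal grandmother is the mother's parent (direct vertical with the
mother) but an in-law to the father ("other"). The friend–friend pair is
categorised "other" rather than horizontal: both friends are chosen by
the student, and their mutual tie is not itself a student transmission
channel.

Defaults: `n_perm = 10000`. The test suite uses 200–4,000 permutations
per edge, which keeps whole-suite runtime in minutes while leaving
Monte-Carlo error well inside the asserted tolerances.

# Parental types and transmission coefficients

Within each network that passed `parent_and_friend`, the student,
Vertical and Horizontal component scores are dichotomised at 0
(inclusive: a score of exactly 0 counts as having the trait; the
threshold is configurable but defaults to 0 as the field convention).
The network's *cultural parental type* is the joint trait status of its
components — VH, Vh, vH, vh — and the transmission coefficient of type i
is `B_i = N_i / P_i`, the proportion of that type's students holding the
trait.

Every factor has two complementary readings: the trait and the opposite
trait (religious / non-religious, right-wing / left-wing, ...). Switching
polarity maps each type to its inverse (VH ↔ vh, Vh ↔ vH) and each
coefficient to `1 − B`. The package computes the opposite table by this
complement construction rather than re-tabulating, so the invariant
`B′_inverse(i) = 1 − B_i` holds bit-exactly, not merely to rounding.

Bootstrap intervals resample whole networks with replacement — the
network, not the individual, is the sampling unit — recompute all counts
per resample, and take percentile 2.5/97.5 bounds. Types empty in the
original data are flagged with `NA` bounds. For a population consisting
of a single type this reduces to binomial resampling, which is how the
implementation is cross-checked against exact binomial quantiles in the
tests.

# Bias estimation

The additive model expresses the four trait-cell counts (and the four
opposite-trait cells) as binomial draws with probabilities

    p_VH = O + V + H,  p_Vh = O + V,  p_vH = O + H,  p_vh = O

with Vertical (V) and Horizontal (H) shared between polarities and a
separate Other (O) per polarity — complementarity makes the shared V and
H a structural fact, while the two Others are free. All four parameters
are constrained non-negative with `O + V + H ≤ 1` in each polarity, so
every cell probability is a valid Bernoulli parameter.

Because the phrase "lowest amount of error" admits several readings,
three objectives are provided and reported side by side:

* `binomial_loglik` (default): the joint binomial log-likelihood of the
  eight cell counts — the likelihood-principled reading, and the one
  whose objective value is comparable across tables;
* `sse_proportions`: squared error on the coefficients `B_i`;
* `sse_counts`: squared error on the counts `N_i` (weights big cells
  more).

On exactly additive input all three agree; on real tables they differ in
the third decimal at most in our experience. Optimisation is an
*exhaustive grid search* at `grid_resolution` (default 0.01, the scale at
which such biases are reported; refinable to 0.001). Exhaustive search
was chosen over a numerical optimiser because the objective surface can
plateau, the feasible region is a simple simplex, and bit-reproducibility
across platforms matters more here than speed. The implementation
exploits the separability of the objective (the trait term depends on
`O_trait`, the opposite term on `O_opposite`, for any fixed `(V, H)`) to
scan the grid in vectorised passes; the arg-minimum and its deterministic
tie-break — lexicographically smallest `(V, H, O_trait, O_opposite)` —
are identical to a naive four-loop enumeration, which the test suite
verifies directly at a coarse grid. At the default 0.01 grid a fit takes
well under a second; at 0.001 it takes tens of seconds.

`triangle_coords()` renormalises each polarity's `(V, H, O)` to sum 1
and places it in the 2-simplex (corners Vertical, Horizontal, Other) for
the conventional triangle rendering; an all-zero triple falls back to
the centroid.

# The synthetic generator

The generator exists so that every stage has a testable ground truth. It
produces two kinds of population from one validated `generator_config`:

**Binary populations** forward-simulate the additive model itself. Per
network and factor, the Vertical component's trait indicator `v` and the
Horizontal component's `h` are drawn from a bivariate Bernoulli with
configurable marginals (default 0.5 each, matching dichotomisation of
centred scores) and a configurable phi coefficient (`parent_friend_corr`,
default 0.2 — a mildly clustered network). The correlated pair is
constructed directly from its 2×2 joint probability table, which
preserves both marginals exactly for any feasible phi; infeasible
combinations are rejected at config time. The student then holds the
trait with probability `O + V·v + H·h`. Couple members and friends copy
their component's value with a concordance probability defaulting to 1;
lowering it models imperfect within-couple agreement but attenuates how
cleanly the component trait can be read off the observed members, and
with it the recoverability of the generating biases. Trait values are
emitted as scores in {−1, +1} so that downstream dichotomisation at 0
recovers them exactly.

**Continuous populations** draw each network's role scores from a
zero-mean unit-variance multivariate Gaussian whose correlation matrix is
the `corr_targets` configuration (a Gaussian copula with normal margins —
the simplest construction that satisfies the Pearson-correlation
assumptions of the resemblance stage). The matrix is checked for positive
semi-definiteness up front, with the most implausible pair named in the
error. Default targets follow the qualitative ordering such surveys
show: retest ≈ 0.85, within-couple ≈ 0.5–0.55, parent–student 0.35,
lineage grandparent–parent 0.35, friend–student 0.30, unlinked pairs
0.10. Default role-presence probabilities are loosely calibrated to
student-centred recruitment (mother 0.45, father 0.37, friends ~0.5
each, grandparents 0.05–0.14), and 2% of scores are knocked out
completely at random.

Seeding is hierarchical: the master seed spawns one deterministic
sub-stream per network, so enlarging a population extends it without
reshuffling earlier networks, and identical configs give bit-identical
tables.

What the generator does **not** emulate: non-normal and skewed response
distributions, informative missingness, within-network dependence beyond
the single correlation structure (e.g. different couple concordance per
factor), reverse transmission dynamics, and any agent acting as an
explicit "oblique" source — Other is a rate, not an agent. Passing tests
therefore demonstrate that the estimators recover the truth *under the
model's own assumptions*; they cannot certify behaviour under real
survey pathologies.

# Problem sizes and calibration checks

The test suite runs the statistical properties at sizes chosen to keep
Monte-Carlo error far inside the asserted tolerances while completing in
a few minutes: permutation-null calibration uses 1,000 independent
datasets of 200 pairs at 1,000 permutations (rejection rate asserted in
0.05 ± 0.02); Monte-Carlo-versus-exhaustive agreement uses 6 pairs, where
all 720 pairings can be enumerated, at 10,000 permutations over 100
seeds (|Δz| < 0.15); bias recovery uses 5,000 networks with full parent
and friend presence, truth `(V, H, O_t, O_o) = (0.42, 0.18, 0.10,
0.30)`, recovered within ±0.03 by all three objectives; bootstrap
coverage uses 500 replicates of 582 networks with 500 resamples each
(coverage asserted in 95% ± 3%).

# Limitations

* Dichotomisation at the mean discards information by construction; the
  coefficients and biases inherit that loss.
* The additive model uses parents and friends only; grandparents enter
  resemblance and filtering but not the bias fit.
* Resemblance is symmetric and agnostic about direction: it cannot
  separate transmission from homophily, assortative mating or shared
  environment.
* The grid search returns a point estimate; uncertainty on the biases is
  best obtained by bootstrapping the whole fit, which is possible with
  the provided pieces but not packaged as a one-liner.
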