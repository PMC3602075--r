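---
title: "Least-squares inference of admixed population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Least-squares inference of admixed population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`admixls` infers discrete admixture structure from a matrix `G` of
biallelic SNP genotypes: `g_li ∈ {0, 1, 2}` copies of the reference
allele at locus `l` (of M) in individual `i` (of N).  The generative
model assumes Hardy–Weinberg equilibrium within each of K ancestral
populations and linkage equilibrium between loci, so that each genotype
is an independent binomial draw,

    g_li ~ Binomial(2, m_li),     m_li = Σ_k p_lk q_ki,

where `p_lk ∈ [0, 1]` is the reference-allele frequency in population
`k` and `q_ki ≥ 0`, `Σ_k q_ki = 1`, is the fraction of individual `i`'s
genome originating from population `k`.

The binomial log-likelihood of `(P, Q)` has score `(g − 2m)/(m(1 − m))`
in each `m_li`.  Linearizing that score around `m = 1/2` — the point
that biases the approximation toward neither allele — gives `4(g − 2m)`,
which is exactly the negative gradient of the squared-error criterion
`||2PQ − G||²`.  The package therefore minimizes

    ||2 P Q − G||²  +  K² (α − 1) ||Q − 1/K||²
    subject to  0 ≤ P ≤ 1,  Q ≥ 0,  colSums(Q) = 1.

The penalty is the same linearization applied to the log-density of a
symmetric Dirichlet(α) prior on each admixture column, expanded around
its mean `1/K`.  With `α = 1` (the default) the penalty vanishes and the
criterion is the plain least-squares surrogate; `α < 1` rewards sparse
(nearly pure) individuals, `α > 1` pulls columns toward even admixture.
When a study population's degree of admixture is known — or estimated
from a reference fit via `effective_alpha()`, which converts a general
Dirichlet's total variance into the matching symmetric shape — supplying
it typically improves the admixture estimate without further tuning.

The criterion is a surrogate, not the likelihood: its linearization is
accurate for `m` roughly in `[0.35, 0.65]` and degrades toward the
boundaries.  In practice this shows up as a mild reluctance to place
individuals exactly on the simplex boundary compared to methods that
maximize the binomial likelihood directly; `binom_loglik()` is provided
for monitoring fits on the likelihood scale (with success probabilities
floored at `1e-10` so the value stays finite at degenerate `m`).

## The optimizer

`fit_admixture()` is two-block coordinate descent.  Q is initialized by
normalizing K iid uniform deviates per column (seed-controlled), and the
algorithm alternates:

* **P-step** (`update_P()`): each locus row solves an independent
  bounded-variable least-squares problem `min ||2Q'p − g_l||²` over the
  box `[0, 1]^K`.  All M rows share the design `2Q'`, so the solver
  (`bvls_multirhs()`) forms one K × K Gram matrix and processes all
  right-hand sides together, grouping columns with identical bound
  patterns into a single equality-constrained solve.
* **Q-step** (`update_Q()`): each column solves the penalized problem
  over the probability simplex.  `build_normal_equations()` assembles
  the shared Gram matrix `4P'P + K²(α − 1)I` and right-hand sides
  `2P'G + K(α − 1)`; the sum-to-one constraint is eliminated in closed
  form by a Lagrange multiplier, `q = aUj + (U − aUJU)r` with
  `U = gram⁻¹`, `a = 1/sum(U)`, applied to each column's passive set,
  and nonnegativity is enforced by an active set.

Both kernels use full-exchange pivoting: every bound-violating passive
variable is clamped and every clamped variable with an inward-pointing
gradient is released in the same sweep.  Full exchange is fast but not
provably finite, so each column tracks its projected objective and falls
back to single-variable exchange — which does terminate — after two
sweeps without decrease.  Numerical policies, chosen once:

* KKT/feasibility tolerance `1e-8` (absolute), appropriate for
  double-precision Gram systems of modest condition number.
* Variables exactly at a bound count as clamped, making the
  active/passive partition deterministic.
* Rank deficiency is detected on the Cholesky diagonal (plain `chol()`
  can succeed numerically on a singular Gram matrix) and reported as an
  error suggesting more individuals or smaller K.
* For `α < 1` the penalty subtracts from the Gram diagonal.  With
  realistic locus counts `4P'P` dominates and the system stays positive
  definite; if it does not (tiny M with a strong sparsity prior), the
  Q-step raises an error rather than returning a saddle point.
* Returned admixture columns are cleaned to machine precision: residual
  negatives from the final solve are zeroed and the column renormalized,
  so `colSums(Q) = 1` holds to 1e-12 and entries are exactly nonnegative.

Each block update attains the global optimum of its convex subproblem,
so the penalized criterion is non-increasing across sweeps — asserted on
every fit in the test suite.  Convergence is declared when the absolute
change over one full sweep drops below `ε`.  The default
`ε = M·N·10⁻¹⁰` scales with the number of residuals, giving `1e-4` at
the common scale M = 10000, N = 100; the cap of 2000 sweeps is a
safeguard, and hitting it is reported as `converged = FALSE` rather than
an error, because coordinate-descent iteration counts are strongly
data-dependent.  The update order — P first, from the random initial
Q — makes the first sweep a pure function of the seed.

Population labels are identified only up to permutation.
`align_populations()` resolves this by exhaustive search over the K!
relabelings (practical for K ≤ 8), minimizing squared error against a
reference and breaking ties lexicographically; evaluation applies the
permutation found on Q to the columns of P as well, and RMSE is computed
over all entries of each matrix.

## Partial problems and variance bounds

When Q is known, the estimator analyzed by the theory module is the
per-locus normal-equations solution

    p̂ = ½ G Q' (Q Q')⁻¹     (estimate_p_known_Q()),

deliberately unconstrained — its entries can leave `[0, 1]`, and that is
what makes it exactly unbiased: `E[p̂] = p` under the binomial model.
Since `var[g] = 2m(1 − m) ≤ ½`, the total variance obeys

    trace cov(p̂) ≤ (1/8) trace((QQ')⁻¹)    (empirical_p_variance_bound()),

and as N grows with iid Dirichlet(α) columns this approaches
`K²(1 + (K − 1)α)/(8N)` (`asymptotic_p_variance_bound()`; the general-K
closed form is pinned in the tests to the numeric trace of the inverse
Dirichlet second-moment matrix).  The mirror-image bound for the
known-P problem is `(1/8) trace((P'P)⁻¹)`, decreasing like 1/M.  These
bounds are validated empirically by `run_empirical_cov()`, which fixes
one drawn Q, replicates single-locus genotypes, and compares the sample
covariance of the estimates to both bounds.  Because Q is drawn once,
the realized covariance trace varies from draw to draw by roughly ±10%;
results of that experiment should be read with that spread in mind.

`ml_estimate_p_known_Q()` provides the comparison arm: a box-constrained
numerical maximization of the binomial likelihood for one locus, started
from the clamped least-squares estimate (cheap, deterministic, and in
the right basin in all tested cases; the optimizer's result is only
accepted if it does not decrease the likelihood).

## The simulator and what the tests can show

`simulate_admixture()` draws `P` with iid Uniform(0, 1) entries (or uses
a supplied frequency panel), admixture columns iid Dirichlet via
normalized Gamma deviates, and genotypes binomially — one seed, consumed
in the fixed order P, Q, G.  Defaults mirror the regimes under which the
method was developed: M = 10000 loci, N ∈ {100, 1000, 10000}, K ∈ {2, 3,
4}, α ∈ {0.1, 0.5, 1, 2} in the factorial harness.

The simulator deliberately omits several features of real data: linkage
disequilibrium (loci are independent, as the model assumes — real
panels should be LD-pruned first), genotyping error and missingness
(the reader's `mean_impute` policy exists for real files, but simulated
data are complete), realistic allele-frequency spectra (uniform
frequencies are more informative than the skewed spectra of real
panels; the `panel` argument exists to substitute real frequencies),
and any relation between populations (frequencies are independent
across populations, i.e. maximal divergence).  Passing tests therefore
demonstrate correctness of the optimization and calibration of the
estimators *under the model*, not performance on LD-structured or
error-prone real genotypes.

Problem sizes in the test suite are chosen to keep the default run
short while leaving the Monte-Carlo checks statistically sharp: solver
oracles run on 6 × 3 instances against exhaustive bound-configuration
and support enumeration; recovery and trend properties use M up to 1600
with ≥ 10 seeds and assert monotone error decrease in M and N; the
reference-value checks run the full M = 10000, 50-trial protocols.
Stochastic assertions use 3–4 standard-error tolerances at fixed seeds
chosen in advance.

## Known limitations

* The criterion is non-convex jointly in (P, Q); the fit finds a local
  minimum that depends on the seed.  Multiple restarts are advisable for
  reporting; the noiseless-recovery tests accept success on any of five
  seeds for exactly this reason.
* Estimates of admixture for individuals near the simplex boundary are
  biased inward relative to likelihood-based fits (the linearization is
  weakest at extreme `m`).
* K is an input, not inferred; consistency across seeds or held-out fit
  can guide its choice but no machinery for that ships here.
* Loci are assumed independent; applying the fit to dense, unpruned
  marker panels violates the model in proportion to the LD present.
* The `.P`/`.Q` writers emit six decimals — round-tripping is exact to
  5e-7, sufficient for plotting and downstream comparison but not for
  restarting a fit at machine precision.
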