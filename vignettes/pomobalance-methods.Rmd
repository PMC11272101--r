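---
title: "Inferring balancing selection with polymorphism-aware phylogenetic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring balancing selection with polymorphism-aware phylogenetic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomobalance)
```

## The model

Polymorphism-aware phylogenetic models (PoMos) treat each branch of a
species tree as carrying a virtual haploid population of size `N` whose
state at a genomic site is either *monomorphic* (all `N` copies carry the
same nucleotide) or *biallelic polymorphic* (`n` copies of one nucleotide,
`N - n` of another). With four nucleotides there are `4 + 6(N - 1)` states:
4 boundary states plus, for each of the six unordered nucleotide pairs
(`AC, AG, AT, CG, CT, GT`), one state per interior frequency
`n = 1, ..., N - 1` of the pair's first allele.

Evolution is a continuous-time Markov chain in Moran time (events, not
generations). It is a *boundary mutation* model: mutations only leave
monomorphic states, at rates `mu[ij]`, entering the adjacent polymorphic
state with `N - 1` copies of the resident allele. In the reversible
parameterization the 12 mutation rates factor into 6 symmetric
exchangeabilities and 4 base frequencies, `mu[ij] = rho[ij] * pi[j]`.
Interior states take unit frequency steps at rate

    drift           selection        balancing
    n(N - n)/N   *   phi[a]    *   beta[ij]^e(n, m)

where `phi[a]` is the relative fitness of the allele *gaining* a copy
(under GC-biased gene conversion, `phi = (1, 1 + sigma, 1 + sigma, 1)` with
`sigma` the GC-bias rate), and the balancing-selection term multiplies the
rate by `beta[ij]` exactly when the step moves the frequency toward the
pair's preferred frequency `B[ij]`, an integer with `0 < B < N`. The
exponent `e(n, m) = (|n - B| - |m - B| + 1)/2` is always 0 or 1 for unit
steps, so `beta` acts as a clean "toward-the-peak" multiplier. With all
`beta = 1` the model reduces exactly to the directional-selection
(PoMoSelect) model; `beta < 1` models *purging*, the removal of
polymorphism faster than drift. Diagonals are assembled as negative row
sums, never from a formula, so the generator property holds by
construction.

Two structural facts drive the package's diagnostics:

* the stationary distribution of the chain is the model's expected site
  frequency spectrum (SFS), with balancing selection visible as an
  interior peak at `B`;
* the chain is reversible exactly when the exchangeabilities are symmetric
  and every `B = N/2` (even `N`); the directional-selection model with
  symmetric exchangeabilities is always reversible.
  `detailed_balance_residual()` measures both.

Stationary distributions are computed by a null-space least-squares solve
and cross-checked in the tests against `exp(10^6 Q)`; closed-form
stationary frequencies are not used anywhere. Matrix exponentials use
dense scaling-and-squaring (state spaces stay below ~120 x 120 even at
`N = 20`, so sparse machinery would buy nothing).

## Likelihood

`tree_log_likelihood()` runs Felsenstein pruning over the PoMo state
space with per-node column rescaling against underflow. Observed data are
per-population allele counts; the tip conditionals use *binomial*
(with-replacement) sampling of the `S` observed alleles from the virtual
population, which smooths the bias by which polymorphic sites in small
samples masquerade as monomorphic. Fully missing sites are uninformative
(all-ones conditionals); sites with three or more observed alleles lie
outside the biallelic state space and are dropped with a logged count.
Identical joint count patterns are collapsed with multiplicities before
any likelihood work.

Root state frequencies default to the stationary distribution of the
current rate matrix. The choice is an assumption, not a theorem - for
nonreversible models one could equally argue for uniform frequencies, so
the engine exposes `root_freq = "uniform"` as a switch.

## Priors, moves, and the sampler

The priors follow standard practice for this model family: Dirichlet(0.25)
on base frequencies; Exponential(10) on exchangeabilities, mutation rates
and the GC-bias rate; Exponential(1) on the balancing-selection strengths;
Uniform(0, N) on each preferred frequency, carried as a *continuous
latent* that is rounded to an integer at every likelihood evaluation (the
latent lives in (0.5, N - 0.5) so the rounded value stays interior);
Exponential(10) on branch lengths when they are sampled.

The sampler is random-scan Metropolis-Hastings; one iteration applies
every active move once. Scalar positives get multiplicative scale moves
(Hastings term `log m`); the simplex gets a Dirichlet-centered whole-vector
move, per-component Beta moves, and an independent draw from the Dirichlet
prior (near-certain acceptance when the data are weak, where random-walk
simplex moves crawl); the latent `B` gets slide, scale and
independent-uniform redraw moves, with out-of-support proposals rejected
through the prior rather than reflected. On top of the component moves, an
adaptive multivariate-normal move proposes jointly over all transformed
continuous parameters (log scales, log-ratio simplex; the simplex and log
Jacobians enter the acceptance ratio), applied several times per sweep -
this is the move that actually traverses the strong
GC-bias/base-frequency/exchangeability ridges, where single-coordinate
updates give effective sample sizes an order of magnitude lower. Its
covariance comes from burn-in samples, or - with the posterior-mode warm
start - from the Laplace approximation at the mode: the inverse Hessian
knows the nearly-flat ridge directions (the GC-bias rate's profile
likelihood can vary by only a few log units across its whole plausible
range) that burn-in samples cannot discover on their own. The Laplace
shaping raised the GC-bias rate's effective sample size roughly
eightfold at fixed chain length in the reference scenario and is what
makes the credible intervals honest at the few-hundred-iteration scale. During
burn-in, step sizes autotune toward 44 percent acceptance (25 percent for
the multivariate move) and are then frozen; concentration-type tunings
adapt faster (fourth power of the error signal) because posterior
concentrations sit orders of magnitude above the prior scale. An optional
Metropolis-coupled mode runs a heated quartet (ladder `1/(1 + 0.1(i - 1))`,
swap proposal every 10 iterations) and records the cold chain.

Two design points deserve emphasis:

* **The `(B, beta)` geometry is bimodal.** A wrong preferred frequency can
  be locally compensated by `beta < 1` (purging), creating a mode the
  single-coordinate moves cannot leave: moving `B` alone or `beta` alone
  is always rejected. The sampler therefore includes a joint jump move
  (redraw `B` uniformly *and* rescale `beta`), and the optional
  moment-matched initialization (`init = "empirical"`) starts each `B` at
  the empirical interior peak of its pair's frequency spectrum - which is
  where balancing selection, if present, announces itself.
* **`init = "empirical"`** sets base frequencies from pooled counts and
  calibrates one shared exchangeability by bisection so the model's
  stationary polymorphic mass matches the observed polymorphic fraction.
  **`init = "map"`** goes further: quasi-Newton ascent on the log
  posterior over the continuous parameters, alternated with conditional
  sweeps over the discrete preferred frequencies, plus a multi-start
  stage over shared-`B` candidates. Each candidate's base frequencies are
  re-derived by a fixed-point inversion matching the model's stationary
  monomorphic masses to the observed pooled composition - the observed
  composition is *not* `pi` once selection acts, and without the
  inversion every candidate starts in the wrong basin. Chains are
  jittered so multi-chain starts stay distinct. The default remains
  over-dispersed prior draws, which is what convergence diagnostics want;
  the warm start is for production runs where burn-in dominates cost.

Convergence follows the usual effective-sample-size rule (ESS above ~200
per parameter, Geyer initial-positive-sequence estimator); multi-chain
agreement can be checked by comparing between-chain mean differences with
within-chain posterior spread.

## Model comparison

`bayes_factor()` contrasts the balancing-selection model against the
directional-selection-only model through stepping-stone marginal
likelihoods: 32 power posteriors spaced as quantiles of Beta(0.3, 1)
(concentrating stones near the prior, where the integrand changes
fastest), each stone warm-started from its colder neighbour, with
importance-weight ESS diagnostics per stone. The stone count and spacing
are package choices - the estimator is validated in the tests against 1-D
quadrature on a model with a single free parameter, to 0.1 nats.

## Simulator

`simulate_counts()` draws each site's root state from the stationary
distribution (or a fixed state), then samples each child state from the
matrix-exponential row of its branch - exact in law and much faster than
stepping individual Moran events; an event-by-event Gillespie realization
(`gillespie_branch`) is kept purely as a testing oracle, cross-checked by
chi-square against the matrix-exponential law. Sites are independent: no
linkage, recombination or demography, which is precisely the idealization
the likelihood assumes. Tests passing on this simulator therefore validate
the *inference machinery*, not robustness to linked or demographically
structured real data. Leaf states can be binomially downsampled to
realistic sample sizes.

## The reference scenario

`bs_scenario()` pins down the package's standard test bed: five species on
a fixed tree (depth 120 Moran units - deep enough that each population's
state distribution is near stationarity, the long-term regime balancing
selection lives in), `N = 6`, GC-bias rate 0.1, balancing selection of
strength 2 toward a common preferred frequency 2, base frequencies
(0.3, 0.2, 0.2, 0.3) and exchangeabilities 0.04. The exchangeability value
puts roughly 9 percent of sites in a polymorphic state, a diversity level
typical of multi-individual population samples; ten alleles are sampled
per population. The default 20,000 sites keep a full inference run in the
minutes range on one CPU while leaving the generating values comfortably
inside the posterior's reach.

## Calibration

`run_sbc()` implements simulation-based calibration: draw parameters (and
branch lengths, optionally a topology) from the priors, simulate an
alignment, run the sampler, and record whether each central credible
interval contains the generating value - a calibrated pipeline covers at
the nominal rate, up to binomial noise. Coverage intervals are central
quantile intervals, matching `summarize_trace()` (HPD would be the other
defensible choice). The default SBC holds the topology fixed at a reduced
scale; the package's routine checks use on the order of a hundred
replicates with a few hundred sites and short chains, far below
cluster-scale calibration, so they probe calibration coarsely (within a
few binomial standard errors), not asymptotically.
`sbc_exact_stub()` swaps the MCMC for an exact conjugate normal-normal
posterior, isolating the interval/coverage bookkeeping itself, which must
then hit nominal coverage exactly up to binomial error.

A practical limitation worth stating plainly: quantile credible intervals
computed from short chains are systematically a little too narrow, so the
full simulate-infer loop undercovers until per-parameter effective sample
sizes reach several tens - at a hundred 300-site replicates that means
hour-scale, not minute-scale, chain budgets for nominal coverage. The
routine checks therefore pin the hard nominal-coverage assertion on the
exact-posterior oracle and treat the full loop's coverage as a
convergence-monitoring quantity: it climbs toward nominal as chains
lengthen, and the discrete preferred frequencies (whose posteriors short
chains do integrate well) sit at nominal already.

Robinson-Foulds distances (via the standard bipartition implementation in
phangorn, unrooting first) score topology recovery where topologies vary.

## Numerical choices and limitations

* Rate matrices are left in raw Moran time by default; `normalize = TRUE`
  rescales to one expected event per site at stationarity. Branch lengths
  are interpreted in whatever units the matrix carries - the package never
  silently rescales.
* Tolerances: generator row sums are held to 1e-10; pruning is compared to
  brute-force enumeration at 1e-8; compression invariance at 1e-10.
* Degenerate inputs: a reducible mutation graph (some alleles unreachable)
  raises an error naming the disconnected alleles rather than returning a
  non-unique stationary vector; a zero-likelihood chain start is re-drawn
  a bounded number of times before failing.
* `K = 4` nucleotides is fixed; there is no rate heterogeneity across
  sites, no ambiguity codes, and no tree-topology search (topologies can
  be sampled from the prior for calibration, but the sampler holds the
  topology fixed). Mapping virtual-population parameters onto effective
  population sizes is out of scope.
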