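---
title: "Clustered balanced networks of binary neurons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustered balanced networks of binary neurons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`clusternet` studies networks of $N_E$ excitatory and $N_I$ inhibitory
*binary* units with asynchronous updates. Each unit carries a state
$\sigma_i \in \{0, 1\}$ and an independent exponential update clock with
mean interval $\tau_\alpha$ ($\alpha \in \{E, I\}$ its population). When a
unit updates, its new state is
$$\sigma_i \leftarrow \Theta\Big(\sum_j J_{ij}\sigma_j - \theta_i
  + J_{\alpha X} m_X\Big),$$
with $\Theta$ the Heaviside function, $J_{ij}$ the realized synaptic
weights, $\theta_i$ the threshold and $m_X$ a constant external drive. A
"spike" is a $0 \to 1$ transition; the *activity rate* $m_\alpha$ is the
population average of the instantaneous states, not a firing rate.

Weights are drawn independently: $J_{ij} = J_{\alpha\beta}$ with
probability $p_{\alpha\beta}$, zero otherwise, and scale as
$J_{\alpha\beta} = j_{\alpha\beta}/\sqrt{N}$ so that input fluctuations
stay comparable to the threshold as $N$ grows. Requiring (i) that
$\sqrt{K}$ excitatory inputs within one time constant reach threshold and
(ii) that excitation and inhibition cancel at equal rates (with an excess
inhibition factor $g$) determines all four $j_{\alpha\beta}$ in closed
form; `derive_weights()` implements this. With the default parameter set
($N_E = 4000$, $N_I = 1000$, $p_{EE} = 0.2$, other probabilities $0.5$,
$g = 1.2$, $\theta = 1$, $J_{EX} = \sqrt{p_{EE}N_E}$,
$J_{IX} = 0.8\sqrt{p_{EE}N_E}$, $m_X = 0.03$, $\tau_I = 0.5\,\tau_E$) this
gives $j_{EE} = 2.5$, $j_{EI} = -4.8$, $j_{IE} \approx 1.581$,
$j_{II} \approx -6.325$.

A note on bookkeeping: we define $n_\alpha = N_\alpha/N$ (population
*fraction*). Some printed accounts give $n_E = N/N_E$; that form is
inconsistent with the threshold condition (it does not reproduce
$\sqrt{p_{EE}N_E}\,J_{EE} = \theta$), so we treat it as a typo. With
fractions, the threshold and cancellation identities hold exactly, which
the test suite asserts at machine precision.

## Mean-field theory

For large $N$ the input to a unit is treated as Gaussian with mean
$\mu_\alpha = \sum_\beta \bar J_{\alpha\beta} m_\beta + J_{\alpha X} m_X -
\theta_\alpha$ and variance $s^2_\alpha = \sum_\beta
\bar J^{(2)}_{\alpha\beta} m_\beta$, where $\bar J_{\alpha\beta} =
j_{\alpha\beta} p_{\alpha\beta} n_\beta \sqrt N$ and
$\bar J^{(2)}_{\alpha\beta} = p_{\alpha\beta}(1 - p_{\alpha\beta})
j^2_{\alpha\beta} n_\beta$ (Bernoulli connectivity variance; input
correlations are neglected). The population rates evolve as
$$\tau_\alpha \dot m_\alpha = -m_\alpha + H(-\mu_\alpha/s_\alpha), \qquad
H(z) = \tfrac{1}{2}\,\mathrm{erfc}(z/\sqrt 2),$$
and fixed points satisfy $m_\alpha = H(-\mu_\alpha/s_\alpha)$. In the
balanced large-$N$ limit the $O(\sqrt N)$ input components must cancel,
which yields closed-form rates linear in $m_X$ (`balanced_rates()`); they
are positive and finite exactly when $g > 1$ and $J_{EX}/J_{IX} >
g\sqrt{p_{EE}/p_{IE}}$ (or the mirrored $g < 1$ branch).

**Finite-size behaviour matters here.** The closed form is only the
leading order: at $N = 5000$ the full fixed point of the rate equations is
roughly *half* the limit value (0.0295 vs 0.0589 for $m_E$), because an
$O(1)$ self-consistent input residual divided by the $O(\sqrt N)$ coupling
shifts the rates by $O(1/\sqrt N)$ — a 50% effect at this size. Below
$N \approx 4000$ at these parameters the shift extinguishes the balanced
state altogether. Simulations track the *full* solution, and their
distance to the closed form shrinks as $N$ grows; the tests assert exactly
that (sizes 5000, 10000, 20000), rather than the fiction that a 5000-unit
simulation reproduces the $N \to \infty$ formula.

### Stability

Linearizing the rate dynamics gives the Jacobian in closed form, including
the variance path (a rate change moves $s_\alpha$ and hence the effective
threshold); `mf_jacobian()` implements it and is verified against central
finite differences at $10^{-6}$. For the two-population system the trace
and determinant produce three critical inhibitory-to-excitatory
time-constant ratios $r_1 \le r_2 \le r_3$ (`critical_ratios()`): below
$r_1$ the balanced fixed point is a stable node, between $r_1$ and $r_2$ a
stable spiral, above $r_2$ it is unstable. For the default parameters
$r_2 \approx 1.50$, so $\tau_I/\tau_E = 0.5$ is a node and ratio 2 is
unstable.

One consequence the package is explicit about: with sub-threshold external
drive ($J_{EX} m_X < \theta$) the all-silent state is *absorbing*, in both
the mean field ($s = 0$, gain steps to 0) and the binary network. Above
$r_2$ the escaping oscillation grows until its down-phase reaches rates
indistinguishable from zero, and the system ends in silence — in
simulations the network dies after one or a few large excursions. Tests
therefore characterize the unstable regime by escape amplitude and
collapse, not by a sustained spectral peak.

## Clustered architectures

`build_matrix()` realizes five architectures. Weight clustering multiplies
within-cluster $EE$ weights by $J_{E+}$ and across-cluster weights by
$J_{E-} = (Q - J_{E+})/(Q - 1)$, which keeps every expected row sum
unchanged ("balance of weights"); $J_{E+} = 1$ is homogeneous and
$J_{E+} = Q$ decouples the clusters. Joint EI clustering divides the
inhibitory population into $Q$ partner clusters and applies a single
multiplier $J_{I+} = 1 + R_J (J_{E+} - 1)$ to the within-pair $EI$, $IE$
and $II$ connections (with its own $J_{I-}$). Two published alternatives
are included for comparison: an unstructured background population
(renormalization among clustered units only) and probability clustering
($p_{in}/p_{out} = R_{EE}$ with the mean probability preserved, plus a
within-cluster weight factor, default 1.9 after the construction it
mimics — not part of the acceptance surface).

`reduce_network()` folds the multipliers into $\bar J$ (linearly) and
$\bar J^{(2)}$ (squared) and returns the population system: 2 populations
(unclustered), $Q{+}1$ (E clusters), $2Q$ (EI clusters), $Q{+}2$
(background).

## Attractor analysis

Three independent routes to the fixed-point landscape, cross-checked
against each other in the tests at $10^{-5}$:

* `sample_fixed_points()` — the stochastic route: random initial rates,
  relaxation by integration (50 $\tau_E$, Euler, $dt = 0.05\min\tau$),
  then root polishing; finds stable states with their basin-weighted
  discovery probability.
* `solve_constrained()` — the symmetric route: with $n$ active clusters
  imposed, permutation symmetry reduces the steady state to 3 equations
  (E clustering: focus, rest, I) or 4 (EI: focus E/I pair, rest E/I pair);
  solutions, stable *and* unstable, are lifted back to the full system,
  re-verified (residual $< 10^{-9}$) and re-classified with the full
  Jacobian.
* `effective_response()` — the graphical route: the focus rate is imposed,
  the slave populations are relaxed to steady state, and the implied
  output $\Phi_{\mathrm{eff}}(\bar m_1)$ is traced; diagonal crossings are
  fixed points, refined by bisection, with on-curve slope stability and
  full-Jacobian classification both reported (the 1-D reduction cannot see
  time-constant effects).

Numerical choices, and why:

* **Polishing is damped Newton** on $H(\cdot) - m$ with the analytic
  Jacobian, not a derivative-free simplex: in 40 dimensions Newton reaches
  residuals near machine precision in a handful of iterations where the
  simplex is slow and plateaus; the two-stage structure (integrate, then
  polish) is retained. Iterates are clamped to $[0,1]$ (outside it the
  input variance turns negative).
* **Fixed-point locations do not depend on $\tau$** — only their stability
  does. Relaxations inside `solve_homogeneous()`/`solve_constrained()`
  therefore run with $\tau \equiv 1$, which makes states reachable that
  are unstable at the physical ratio; classification afterwards uses the
  true $\tau$.
* **Degenerate states**: any candidate with $s^2_\alpha = 0$ (the absorbed
  all-off state and its relatives) is excluded from landscapes — the
  Gaussian linearization is meaningless there.
* **Deduplication** rounds rates to $10^{-4}$, sorts the E-cluster block
  descending (carrying I partners through the same permutation), and
  counts a cluster "active" if its rate exceeds the midpoint between the
  largest and smallest E-cluster rate (0 for homogeneous states). The
  midpoint rule is our choice; the source material labels states by
  active-cluster counts without giving a threshold.
* **Critical clustering strengths** (`critical_clustering_strength()`)
  scan $J_{E+}$ in 0.1 steps — the granularity at which the reference
  results are quoted — and report the first grid value meeting the
  criterion (homogeneous state linearly unstable, or the single-focus
  EFR gaining more than one diagonal crossing); an optional bisection
  refines to 0.01. Marginality tolerance on $\mathrm{Re}\,\lambda$ is
  $10^{-8}$, two orders above the solver residual.

Two honest discrepancies with the quoted landmark values. First, the EFR
up-state emergence: our curves first gain three diagonal crossings between
$J_+ = 1.85$ and $1.9$ (checked on an 801-point grid), so the 0.1-grid
answer is 1.9 against a quoted "$\sim 1.8$". Second, at $J_+ = 1$ the EFR
is not exactly constant: the slave network re-balances against the imposed
focus rate, leaving a shallow slope of about $-0.05$ at this $N$; "flat"
is an idealization. Both are properties of the equations, not tuning
targets, and the tests assert what the mathematics gives.

## Simulation and the competition statistic

The simulator is event-driven (Gillespie): total event rate
$\Lambda = \sum_\alpha N_\alpha/\tau_\alpha$, population chosen
proportionally to its rate, unit uniformly, time advanced exponentially.
This realizes exponential per-unit update intervals and the update-
probability ratio $P_{UE}/P_{UI} = \tau_I/\tau_E$ simultaneously. The
recurrent input vector is maintained incrementally (one sparse-column
update per state flip), which makes a 1 s run of the 5000-unit network a
sub-second computation. Only flips are logged; any binning or grouping is
reconstructed from the flip log exactly. $\tau_E = 10$ ms is a unit
convention, nothing more.

Winnerless competition is quantified by $\sigma^2_m$: per-cluster rates in
10 ms bins (state sampled at bin ends), first 100 ms discarded, variance
over time per cluster, averaged over clusters. Bin width and transient are
our defaults — the reference analysis does not state its estimator — so
sweep comparisons are made on *location and shape* (a sharp rise near
$J_+ \approx 2$, collapse into winner-take-all beyond $\approx 2.4$), not
amplitude. The same caveat applies to maximum instantaneous cluster rates:
with 200-unit clusters a bin-end snapshot carries binomial noise of
standard deviation $\approx 0.035$ at rate 0.6, so observed maxima sit a
few such deviations above the stable mean-field up-state rates.

## What the generator emulates, and what it does not

The synthetic networks are themselves the object of study: fixed random
Bernoulli connectivity, hard clusters of equal size, binary units, constant
external drive. Passing tests therefore show that the implementation
reproduces the *model's* behaviour — metastable cluster switching, its
onset in clustering strength, moderation of up-state rates by partnered
inhibition — not that real cortex behaves this way. Known idealizations:
no spiking dynamics or refractoriness (binary states; spike statistics are
not interpretable), no input correlations in the mean field, no overlapping
or heterogeneous clusters, no spatial structure, no plasticity.

## Problem sizes used by the test and acceptance runs

Mean-field computations run at the full study size ($Q = 20$, $N = 5000$
equivalent populations) since they are cheap. The reproduction script
(`scripts/acceptance.R`) uses the study-scale budgets: 5 realizations × 5
trials of 1 s for the variance sweep, 20 realizations for the EI rate
bound, 200 restarts per landscape grid point. The test suite asserts the
same properties at reduced budgets chosen once for a comfortable single-
core run — 3 × 3 trials on a grid bracketing the variance onset, 10 EI
realizations, 100 restarts, sizes 5000/10000/20000 for the finite-size
trend — and a 500-unit network for connectivity statistics. Every
headline quantity is still computed at the default network size.
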