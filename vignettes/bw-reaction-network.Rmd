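---
title: "The Baum–Welch reaction network: model, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Baum–Welch reaction network: model, numerics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwcrn)
```

## 1. What this package computes

`bwcrn` studies one question: can the Baum–Welch (BW) algorithm — the EM
algorithm for hidden Markov models — be carried out by the deterministic
mass-action dynamics of a chemical reaction network, and when do the two
computations agree? The package therefore contains two complete
implementations of HMM parameter learning:

* the **discrete algorithm**: forward and backward recursions, E-step,
  M-step, iterated by `bw_fit()`;
* the **reaction network**: an explicit species/reaction object built by
  `build_bw_network()` whose mass-action ODE system is executed under
  three semantics (`run_bw1()`, `run_bw2()`, `run_bw3()`).

Everything else — sequence sampling, file formats, decoding, plots,
the command line — is plumbing around this pair.

## 2. The discrete algorithm and its domain

For parameters (π, θ, ψ) and an observed word $v_1\dots v_L$ ($L \ge 2$),
the forward table is $\alpha_{1h} = \pi_h\psi_{hv_1}$,
$\alpha_{\ell+1,h} = \sum_g \alpha_{\ell g}\theta_{gh}\psi_{hv_{\ell+1}}$;
the backward table is $\beta_{Lh} = 1$,
$\beta_{\ell h} = \sum_g \theta_{hg}\psi_{gv_{\ell+1}}\beta_{\ell+1,g}$.
The E-step forms
$\gamma_{\ell h} \propto \alpha_{\ell h}\beta_{\ell h}$ and
$\xi_{\ell gh} \propto \alpha_{\ell g}\theta_{gh}\psi_{hv_{\ell+1}}\beta_{\ell+1,h}$,
both normalized by $\sum_f \alpha_{\ell f}\beta_{\ell f}$, and the M-step
re-estimates $\theta'$ and $\psi'$ as row-normalized expected counts
(`m_step()`, pooled over sequences with an optional π update in
`m_step_multi()`).

Division by zero is excluded on the region where
$\sum_\ell \alpha_{\ell h}\beta_{\ell h} > 0$ for every hidden state
(`check_theta_region()`). That printed condition does not by itself rule
out a zero denominator in the θ′ rows (whose sums run only to $L-1$), so
the M-step guards its own denominators independently and raises a typed
out-of-domain error naming the offending row. Strictly positive
parameters with every symbol observed keep all updates strictly positive,
which is the regime in which all cross-dynamics guarantees below hold.

**Numerical stability.** The raw forward recursion underflows near
$L \approx 100$ for typical parameters, so `forward_algorithm()` rescales
each row to sum 1 and accumulates the log-normalizers; the log-likelihood
is their sum. The backward table is scaled compatibly, and since every
E-step quantity is a ratio that is invariant to positive row rescalings,
the results are unchanged — a property the test suite checks directly. A
likelihood of exactly zero yields `-Inf` (never an exception), so
boundary experiments can proceed.

## 3. The network

Every algorithmic quantity is one species; `enumerate_species()` indexes
$L|H|$ each of α, β, γ, $(L-1)|H|^2$ of ξ, the parameter matrices and
their primed copies, and $L|V|$ indicator catalysts $E_{\ell w}$ whose
concentrations (1 exactly at the observed symbol, 0 elsewhere) inject the
data. With several sequences the trellis and E species are duplicated per
sequence while parameter species are shared.

Each subnetwork is a catalytic mono-molecular *star*: each species
exchanges single molecules with a hub (the species indexed by the
reference states $h^\*$, or $(h^\*,h^\*)$ for ξ, or $v^\*$ for ψ′), at a
rate equal to the product of the reaction's catalyst concentrations. At a
positive equilibrium the pairwise balance between each leaf and the hub
reproduces the corresponding BW ratio, and the conserved class total (the
sum over each position row, slice or parameter row) fixes the scale. Two
reading choices deserve a note:

* The reverse ξ reaction carries catalysts
  $\alpha_{\ell g}, \theta_{gh}, \beta_{\ell+1,h}, \psi_{hw}, E_{\ell+1,w}$ —
  the β catalyst is indexed by the *target* state $h$, which is the unique
  choice for which the subnetwork equilibrium satisfies the E-step ratio;
  the equilibrium tests pin this down.
* The terminal row $\beta_L$ is touched by no reaction; it is initialized
  uniform (the terminal condition $\beta_{Lh} = 1$ up to scale). With any
  other initialization of $\beta_L$ the downstream posteriors would be
  distorted, so "initial conditions of the other species are irrelevant"
  holds under this convention.

No-op reactions (transformed species equal to its own hub) are omitted:
they have zero net effect, and dropping them only shrinks the ODE. All
rate constants are 1; the `rate` field exists for generality.
`mass_action_rhs()` evaluates the ODE right-hand side; internally
reactions are compiled to index vectors plus a sparse stoichiometry
matrix, and reactions catalysed by an `E` species that is identically
zero are dropped before integration (they can never fire; the dynamics
are unchanged).

**Reference states.** Defaults are $h^\* = H_1$ and, at run time,
$v^\* =$ the first alphabet symbol that occurs in the data — the ψ′
subnetwork routes all flow through the $v^\*$ hub, so an unobserved
$v^\*$ would freeze it. Positive equilibria are invariant to these
choices (tested); *boundary* limits are not — see section 6 below.

## 4. The three executions

**BW1** (`run_bw1`) walks the $4L$ subnetworks in the algorithm's order,
freezing every catalyst at its previously obtained value. The default
equilibration is `closed_form`: each star's equilibrium is solved exactly
from the balance equations (pairwise leaf–hub flux balance, scaled to the
conserved total). When rates vanish the limit is computed structurally
from the star's linear dynamics — mass from cut-off leaves drains through
the hub, dead-end leaves absorb it, with the split among dead ends given
by the time-integral of the hub trajectory, obtained from the absorbing
linear subsystem (a small exact `solve()`, never a matrix exponential).
An `integrate` mode that runs each subnetwork ODE numerically is kept for
validation. After each sweep the primed species are promoted to the
unprimed ones; each sweep reproduces one discrete EM iteration, which the
suite verifies to $10^{-7}$ over randomized instances (it holds at
machine precision).

**BW2** (`run_bw2`) alternates the inference module (all α, β, γ, ξ
subnetworks jointly) and the learning module (θ′, ψ′, π′). In closed
form the joint equilibrium is computed by cascading the subnetwork
solutions — the dependency structure is acyclic, so the cascade *is* the
joint equilibrium. In `integrate` mode the module ODEs are run to
numerical equilibrium and the learning-module trajectory is recorded; the
fitted log-residual slope (`estimate_convergence_rate()`) is strictly
negative, the signature of exponential convergence.

**BW3** (`run_bw3`) identifies θ with θ′ and ψ with ψ′ (and π with π′
when learning π) and integrates the full autonomous system. Solutions
exist globally for any simplex initialization; all concentrations are
bounded by their conserved class totals, and the row sums of θ′(t), ψ′(t)
are constant in time (both tested along trajectories). Convergence is
declared on the *parameter* species only — the trellis species
equilibrate implicitly.

**Stopping rules and tolerances.** The integrator is `deSolve::lsoda`
(stiff-capable, automatic switching) with relative tolerance $10^{-8}$
and absolute $10^{-10}$ by default. Equilibrium is declared when the
max-abs vector-field component on the watched species falls below
`equil_tol` ($10^{-8}$ default). Near boundary equilibria some linear
modes have eigenvalues that are themselves near zero, and a small vector
field then badly underestimates the distance to the limit; module
equilibration therefore additionally requires two successive
(geometrically growing) integration windows to end within $10^{-9}$ of
each other. Default horizon `t_max` is $10^4$ time units; the BW2
validation runs use up to $10^{8}$ because those slow modes are exactly
what is being measured. Negative concentrations from integrator drift are
clamped only when reading parameters out of a final state, never inside
the dynamics.

## 5. Synthetic data: what the generator emulates

`sample_hmm()` draws exact joint samples (hidden path + emissions) from
any HMM, seeded and reproducible; `run_symmetric_fixed_point()` builds
fixed-count binary sequences; `run_casino_experiment()` samples from the
dishonest-casino generator
$\pi = (1,0)$, $\theta = [[0.95, 0.05], [0.25, 0.75]]$,
$\psi = [[0.34, 0.33, 0.33], [0.01, 0.01, 0.98]]$ (300 rolls by default,
train on the first 150, decode the held-out 150). These generators
produce exactly the data-generating processes of the validation
experiments — what they do *not* emulate is any feature of real
biochemical data (measurement noise, model misspecification, unknown
state-space size), so passing tests demonstrate correctness of the
computation, not robustness of HMM inference on real data.

Randomized suite instances draw rows from flat or mildly concentrated
Dirichlet distributions (`random_hmm()`; concentration 2 where the suite
needs instances away from the extreme boundary, stated in the tests).
Decoding is posterior decoding — the per-position argmax of γ, with ties
broken to the lowest state index — since γ is already computed by the
machinery; Viterbi decoding is deliberately out of scope. For trained
models, whose state labels are arbitrary, decoding agreement is scored up
to label permutation.

## 6. Boundary behaviour: where the dynamics split

All equivalence guarantees are for strictly positive equilibria. The
package's sharpest illustration is the alternating length-5 sequence
$v_2 v_1 v_2 v_1 v_2$ (`run_length5_example()`): discrete EM locks onto
the deterministic alternating machine
$\theta^\* = \psi^\* = [[0,1],[1,0]]$, while the coupled ODE reaches a
*different* boundary equilibrium with the same emissions, the same second
transition row, and an interior first transition row. Restarted at the
ODE limit, discrete EM falls to its own equilibrium — the ODE limit is
inside the valid region yet is not an EM fixed point.

Two facts about this regime, established numerically while building the
package and worth recording:

* the interior entry of the ODE's boundary limit depends on the full
  network initialization — the trellis species included, not only
  (θ₀, ψ₀); published runs of this example are therefore reproducible
  digit-for-digit only with the exact initialization used;
* boundary limits are *not* invariant to the reference states
  $h^\*, v^\*$ (positive equilibria are): the hub choice decides which
  transition row freezes with an interior value.

The package default for this experiment is the fixed asymmetric positive
start θ₀ = [[0.6, 0.4], [0.4, 0.6]], ψ₀ = [[0.4, 0.6], [0.6, 0.4]],
π = (0.5, 0.5), uniform trellis, $h^\* = H_2$, which lands the ODE at
θ′₁₁ ≈ 0.160. The qualitative structure — two distinct boundary
equilibria, identical emissions, one interior row — is robust across all
initializations tried. Boundary runs are always flagged
(`report$boundary`), and no cross-dynamics agreement is asserted there.

## 7. Experiment conditions and problem sizes

The validation experiments run at the study conditions they model: the
symmetric fixed point on a length-100 sequence with 49/51 counts from
uniform starts; the boundary example on the printed length-5 word; the
casino on 300 sampled rolls with a flat-Dirichlet random initialization
(logged seeds). The randomized equivalence suites use $|H|, |V| \in \{2,3\}$,
$L \in 3..10$ with 50 instances for the sweep-equivalence check, and
smaller subsets (3–5 instances, stated per test) for the ODE-based
checks, which are the expensive ones; the unit suite completes in a few
minutes on one core. The casino's reference log-likelihoods from the
original study belong to one specific deposited roll sample and
initialization; `run_casino_experiment()` accepts those through
`rolls_file`/`init_file` and otherwise regenerates the experiment with
its own sample, so its numbers are comparable in distribution (the
training log-likelihood lands in the −145..−165 range) but not
digit-for-digit.

## 8. Known limitations

* Stochastic (discrete molecule count) semantics are not simulated; the
  dynamics here are the deterministic mass-action ODEs.
* Compilation to DNA strand-displacement chemistry is out of scope; the
  network is formal. SBML level-3 export (`export_network()`) is provided
  for interoperability, with the plain-text reaction format as the
  round-trippable interchange format.
* Near boundary equilibria the ODE route converges sub-geometrically in
  wall-clock terms (slow modes), and integrate-mode agreement checks at
  tight tolerances become expensive; the closed-form route is exact and
  should be preferred except when the transient itself is of interest.
* Model selection (choosing $|H|$), Viterbi training, continuous
  emissions and priors/MAP variants are out of scope.
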