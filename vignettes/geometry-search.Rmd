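---
title: "Gradient-free geometry search with Bayesian optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient-free geometry search with Bayesian optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conventional molecular geometry optimization follows energy gradients from
quantum-chemical calculations. When the energies come from noisy hardware --
most prominently near-term quantum computers, whose measured electronic
energies carry stochastic errors of a few kcal/mol -- the potential energy
surface (PES) seen by the optimizer is non-smooth and gradient following
breaks down. The same problem arises for high-accuracy methods without
analytic gradients.

`bogeom` implements a gradient-free alternative: Bayesian optimization (BO)
over Z-matrix internal coordinates, with two search targets:

* the **global minimum (GM)** of the ground-state energy $E(S_0)$, and
* the **most stable conical intersection (MECI)** between the ground state
  $S_0$ and the first singlet excited state $S_1$.

## The search loop

One campaign repeats five steps until a termination rule fires:

0. *Initial dataset.* A set of structurally diverse geometries with their
   energies. Any cheap generator works; the package ships a seeded random
   generator (`generate_initial_set()`), and real datasets (e.g. from
   automated reaction-path searches) can be imported as XYZ plus an energy
   table.
1. *Surrogate fit.* A Gaussian-process regression (GPR) model with an RBF
   kernel is refit from scratch on all data so far (`gp_fit()`). Inputs and
   objective are standardized; the kernel hyperparameters are optimized by
   exactly 100 full-batch Adam steps at learning rate 0.2 from a fixed
   initialization (length-scale 1, signal variance 1, noise variance 0.01 in
   standardized units). Refitting from scratch each iteration keeps campaigns
   exactly reproducible from one master seed.
2. *Proposal.* 2000 uniform random geometries are scored by the acquisition
   function (AF); the top 200 are refined by bounded L-BFGS-B maximization of
   the AF with analytic posterior gradients; the best refined geometry
   without an atomic collision (any pair closer than 0.5 Å) becomes the
   candidate. If every refined geometry collides, the whole proposal is
   regenerated (at most 10 times).
3. *Evaluation.* The energy oracle is called at the candidate. Oracles are
   plain functions `geometry -> energy record`, so any backend can be
   plugged in; the shipped oracles are analytic two-state surfaces.
4. *Termination check* (below).

## Objectives and acquisition functions

BO maximizes, so the GM objective is $-E(S_0)$. A conical intersection must
satisfy two conditions at once -- degeneracy and low energy -- which the
penalty cost function combines:

$$C = \frac{E(S_0) + E(S_1)}{2} + \frac{\left(E(S_1) - E(S_0)\right)^2}{\alpha},$$

and the MECI objective is $-C$. The weight $\alpha$ (kcal/mol) controls the
balance: small $\alpha$ over-weights degeneracy and tolerates high-energy
degenerate structures; large $\alpha$ lets the penalty vanish so the argmin
drifts toward the minimum of the average energy. Moderate values
($\alpha \approx 25$--$75$, default 50) recover the MECI best, and the
package reproduces that trend on its benchmark surfaces.

Two acquisition functions are provided. The probability of improvement is
the probability that the objective at $x$ exceeds the incumbent best
$f(x^*)$,

$$\mathrm{PI}(x) = P\!\left(f(x) \ge f(x^*)\right)
               = \Phi\!\left(\frac{\mu(x) - f(x^*)}{\sigma(x)}\right),$$

with $\mu$, $\sigma$ the GPR posterior mean and standard deviation. (PI is
sometimes printed with the argument of $\Phi$ negated, which is the
complement of the stated probability; this package implements the
probability as defined.) When $\sigma = 0$ the improvement is certain or
impossible; ties return 0 so an exactly interpolated incumbent is not
re-proposed. The upper confidence bound is
$\mathrm{UCB}(x;\beta) = \mu(x) + \beta\,\sigma(x)$; $\beta = 0.1$ is the
only setting observed to give stable searches, and PI is the default. The
incumbent is always the best *observed* objective value, noisy or not.

## Termination rules

* **GM:** at every iteration that is a multiple of 5, store the lowest
  observed $E(S_0)$ among candidates. Stop once the stored value has
  remained unchanged over 3 consecutive checks (strict improvement resets
  the count; ties do not).
* **MECI:** at every multiple of 50, filter candidates with observed gap
  $E(S_1)-E(S_0) < 3.0$ kcal/mol (strict) and store the lowest-$E(S_1)$
  member, ties resolved to the earliest iteration. Stop after 3 consecutive
  checks without strict improvement of the stored $E(S_1)$. If no candidate
  ever qualifies, the campaign runs to the cap and reports a
  `no_ci_found` status instead of failing.
* Both targets stop unconditionally at 1000 iterations (configurable).

The reported result is the lowest-$E(S_0)$ candidate (GM) or the stored
gap-filtered candidate (MECI).

## Noise model

`with_uniform_noise()` adds independent uniform draws on
$[-2, +2]$ kcal/mol (configurable half-width) to each state energy,
emulating the error scale measured on superconducting quantum devices.
Noise on $S_0$ and $S_1$ is drawn independently; whether real-device errors
are correlated between states is unknown, and independence is the neutral
choice. The wrapper draws from the campaign RNG stream, so noisy campaigns
are reproducible, and subtracting a regenerated stream recovers the clean
energies exactly.

## Benchmark surfaces

Electronic-structure backends are out of scope, so the package ships
analytic two-state diabatic models (`two_state_model()`): quadratic diabats
$V_1$, $V_2$ coupled linearly through one coordinate, with adiabatic
energies $E_\pm = \bar V \pm \sqrt{(\Delta V/2)^2 + W^2}$. Degeneracy holds
exactly where $V_1 = V_2$ and $W = 0$, which makes reference optima
independently computable.

* `benchmark_2d()` -- two abstract coordinates. The GM sits at the origin
  ($E = 0$); the zero-coupling line carries two conical intersections, at
  $(0.9, 0)$ with $E = 12.15$ and $(1.7, 0)$ with $E = 43.35$ kcal/mol, and
  a shallow avoided-crossing local minimum near $(0.96, \pm 0.7)$ at about
  4 kcal/mol gives the GM search a competing basin. The MECI is the lower
  intersection: interior, well separated from the GM, within ~45 kcal/mol
  of it. The crossing is steep relative to the mean-energy slope, so the
  argmin of $C$ sits essentially on the degeneracy for $\alpha = 1$ and
  drifts toward the adjacent mean-energy minimum as $\alpha$ grows -- the
  $\alpha$ dependence of the cost landscape is directly observable on a
  grid, and $\alpha = 50$ campaigns reliably produce gap-qualified
  candidates.
* `formaldehyde_like_6d()` -- six coordinates (three distances, two angles,
  one dihedral) on a real Z-matrix topology with formaldehyde-sized search
  bounds, coupling on the dihedral and vanishing at planarity. Here the
  degeneracy seam is a four-dimensional manifold whose energy varies by
  hundreds of kcal/mol, restoring the scaling behaviour of molecular
  searches.

Two regimes of the $\alpha$ trade-off are worth distinguishing, because the
benchmarks exhibit both.

When a single degeneracy region is accessible -- as on the 6-D surface,
whose seam is one connected manifold -- a gap-dominated objective is not
pathological on a smooth landscape: restricted to the degeneracy set, $C$
reduces exactly to the mean energy, so small $\alpha$ acts as an effective
constrained optimizer and descends the seam accurately. Conversely, a
moderate $\alpha$ places the cost argmin a finite gap off the seam
(roughly $\alpha\,|\nabla \bar V| / (2\,g')$, with $g'$ the gap slope), and
when the mean-energy slope along the seam is comparable to the gap slope
that displacement can exceed the 3 kcal/mol storage filter -- the search
then reports early, poorly converged candidates. Both behaviours are
observable on the 6-D surface and motivate the steepness of the 2-D
benchmark's crossing.

When *several* intersections compete -- the 2-D benchmark carries a second,
43 kcal/mol crossing -- small $\alpha$ fails the way it does on real
molecules: the squared-gap term inflates the objective's range by orders of
magnitude, the standardized surrogate can no longer rank the degenerate
regions by their (comparatively tiny) energy differences, and campaigns
lock onto whichever intersection they happen to sample: degenerate but
unstable. The energy-weighted moderate-$\alpha$ cost discriminates and
recovers the true MECI; the shipped validation reproduces this ordering
over paired seeds.

One property deliberately *not* claimed: at the level of the exact cost
landscape, the small-$\alpha$ argmin always lies at (and the moderate-
$\alpha$ argmin strictly above it in) excited-state energy whenever the
latter's gap is below $\alpha/4$ -- the optimality condition bounds the
mean-energy drop by $2\,\mathrm{gap}^2/\alpha$. The campaign-level
advantage of moderate $\alpha$ is a sampling/surrogate phenomenon, not an
argmin property, and the tests treat it as such.

Reference optima come from deliberately brute-force oracles, independent of
the BO machinery: `reference_gm()` (dense grid scan plus bounded local
refinement; multistart for $d > 2$), `analytic_meci()` (closed-form roots in
2-D), and `reference_meci()` (escalating-penalty multistart seam search).

## Geometry handling

Z-matrix internals convert to Cartesians with the convention: atom 1 at the
origin, atom 2 on +z, atom 3 in the xz-plane; dihedral signs follow the
IUPAC right-hand rule. Angles and dihedrals are stored in degrees, matching
how search bounds are usually quoted, and converted to radians only inside
trigonometry. Dihedral bounds $[-180^\circ, 180^\circ]$ are treated as a
plain box -- no periodic wrap -- during sampling and AF optimization.
Colinear reference frames (an angle of exactly $0^\circ$ or $180^\circ$
upstream of a dihedral-bearing atom) are an error in strict mode, since the
dihedral is undefined there; collision screening uses the non-strict mode,
which completes the frame with an arbitrary perpendicular, because atom
*positions* remain well defined at the angle bounds that L-BFGS-B can
legitimately reach.

Deviation from a reference is quantified by energy differences and the
Kabsch RMSD (determinant-corrected SVD superposition). Mirror-image
reference conformers are handled by also superposing against a reflected
copy and keeping the smaller RMSD. Atoms are matched by Z-matrix identity;
no permutation search is attempted.

## Numerical choices

* GP noise variance is floor-bounded at $10^{-6}$ (standardized units);
  an observation-noise term is always present, which both conditions the
  kernel matrix and is essential for noisy campaigns. Whether the original
  noiseless experiments carried a nugget is not documented; including one
  is the numerically robust choice.
* Kernel Cholesky failures trigger jitter escalation before erroring.
* The 2000-to-200 pool reduction is a deterministic top-k by AF value
  (the upstream implementation delegates this step to a library whose exact
  initializer heuristic is not documented in the main text; top-k is the
  reproducible choice).
* L-BFGS-B convergence tolerance is $10^{-6}$ on the AF value with at most
  200 iterations per start; posterior gradients are analytic.
* "100 epochs" is interpreted as 100 full-batch gradient steps.
* Duplicate candidate geometries are legal dataset rows; the GP nugget
  absorbs them.
* Constant-objective degenerate fits fall back to unit objective scale.

## Validation problem sizes

The shipped test-suite and acceptance campaigns use reduced proposal pools
(400--500 random draws, 15--20 L-BFGS-B starts) and initial sets of 20
(2-D) or 71 (6-D) structures, with iteration caps of 200 (GM) and 250
(MECI): on the smooth analytic benchmarks, larger pools change the
proposals negligibly while the reduced sizes keep a full three-repeat
validation protocol quick on one CPU. Campaign repeats run with seeds
derived from one master seed by fixed offsets, so "campaign 2" is the same
everywhere.

## What the synthetic benchmarks do and do not show

The analytic surfaces are smooth, low-dimensional, and exactly quadratic in
their diabats; real PESs have anharmonic wells, dissociation plateaus,
multiple conformers and seams of intersection with richer topology. Passing
the shipped validation shows that the machinery -- surrogate, acquisition,
penalty, proposal, termination, noise robustness -- behaves as designed on
landscapes with known answers; it does not certify accuracy for any
particular molecule or electronic-structure method. The 6-D surface
deliberately restores one hard feature (an extended, energy-varying
degeneracy seam); what no smooth analytic surface restores is the
near-intersection ruggedness of linear-response excited states, which is
the regime where moderate $\alpha$ earns its accuracy advantage over small
$\alpha$ (see the caution in the benchmark section).

## Known limitations

* No redundant/delocalized internal coordinates and no automatic Z-matrix
  construction; the Z-matrix (and hence atom correspondence for RMSD) is
  user-supplied.
* Single-output GP: $E(S_0)$ and $E(S_1)$ enter only through the scalar
  objective, not as jointly modelled outputs.
* One candidate per iteration; no batch proposals.
* RMSD has no atom-permutation or symmetry-group awareness beyond the
  mirror option.
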