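# bogeom — gradient-free Bayesian optimization for molecular geometry search

`bogeom` locates two kinds of critical structure on molecular potential
energy surfaces **without energy gradients**:

* the **global minimum (GM)** of the ground-state energy E(S₀), and
* the **most stable conical intersection (MECI)** between the ground state
  S₀ and the first singlet excited state S₁.

Gradient-free search matters when the energies come from noisy hardware —
most prominently near-term quantum computers, whose measured electronic
energies carry stochastic errors of a few kcal/mol — or from high-accuracy
methods without analytic gradients. The package is aimed at computational
chemists who want to drive such an oracle from R, and at method developers
who want a self-contained, fully reproducible testbed: it ships analytic
two-state surfaces with independently computed reference optima, so every
claim can be checked against a known answer.

## The method

A campaign iterates five steps. Given data $D_{0:i-1}$ (geometries in
Z-matrix internal coordinates with their energies):

1. fit a Gaussian-process surrogate with an RBF kernel to the standardized
   data (Adam, learning rate 0.2, 100 epochs);
2. propose a candidate by maximizing an acquisition function: 2000 uniform
   random geometries, top-200 by acquisition value, bounded L-BFGS-B
   refinement from each, then the best refined geometry with no atom pair
   closer than 0.5 Å;
3. evaluate the energy oracle there;
4. check termination: stored-best checks at every 5th (GM) or 50th (MECI)
   iteration, stopping after 3 consecutive checks without improvement,
   with a hard cap of 1000 iterations.

The GM objective is $-E(S_0)$. The MECI objective is $-C$ with the penalty
cost function

$$C = \frac{E(S_0)+E(S_1)}{2} + \frac{\bigl(E(S_1)-E(S_0)\bigr)^2}{\alpha},$$

whose squared-gap term drives the states to degeneracy while the average
drives them down; α ≈ 25–75 kcal/mol (default 50) balances the two. The
default acquisition function is the probability of improvement
$\mathrm{PI}(x) = \Phi\!\left((\mu(x) - f(x^*))/\sigma(x)\right)$; the
upper confidence bound $\mu + \beta\sigma$ is also available. A uniform
±2 kcal/mol noise wrapper emulates quantum-device measurements. Found
geometries are compared to references by energy differences and
mirror-aware Kabsch RMSD.

See `vignettes/geometry-search.Rmd` for the full model description,
parameter meanings, and design choices.

## Worked example

A GM search on the shipped 2-D benchmark surface (true GM at the origin
with E = 0; a conical intersection at (0.9, 0) with E = 12.15 kcal/mol):

```r
library(bogeom)

bench <- benchmark_2d()
init <- generate_initial_set(initial_set_spec(n_structures = 20),
                             bench$space, bench$oracle, rng_seed = 1)
camp <- run_campaign(bench$space, bench$oracle, objective_spec("GM"), init,
                     config = campaign_config(n_random = 400, n_select = 20),
                     seed = 42)
camp
#> BO campaign (GM target): 25 iterations, status 'converged'
#> final geometry (iteration 11): 0.011471, -0.0035392
#> E(S0) = 0.0022, E(S1) = 127.5285, gap = 127.5263 kcal/mol
```

The campaign stopped at iteration 25: the stored best (found at iteration
11) survived the checks at iterations 15, 20 and 25 unchanged — three
consecutive checks, the patience rule. The final geometry sits 0.012
coordinate units from the true GM with an energy error of 0.002 kcal/mol:

```r
ref <- bench$gm()   # independent grid-scan + refinement oracle
evaluate_against_reference(
  list(values = camp$final$values, record = bench$oracle(camp$final$values)),
  list(values = ref$values,        record = bench$oracle(ref$values)),
  bench$space, reference_id = "grid-oracle GM")
#> vs grid-oracle GM: dE(S0) = 0.0022 kcal/mol, dE(S1) = -2.5215,
#>   gap = 127.5263, RMSD = 0.0120 A
```

(The large gap is expected: at the ground-state minimum the two states are
far apart; degeneracy is a property of the MECI, which you would search
with `objective_spec("MECI", alpha = 50)`.)

For a MECI search, configuration-file-driven runs with three repeats,
α sweeps, CSV logs and XYZ output, use `run_from_config()` or the CLI:

```sh
exec/bogeom run --config run.yaml --seed 1 --out results/
exec/bogeom evaluate --found found.xyz --ref ref.xyz --mirror
```

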