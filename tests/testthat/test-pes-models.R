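test_that("adiabatic energies match an independent 2x2 eigensolver", {
  b <- benchmark_2d()
  set.seed(31)
  X <- sample_uniform(b$space, 50)
  e <- adiabatic_energies(b$model, X)
  for (i in seq_len(nrow(X))) {
    dv <- bogeom:::diabats(b$model, X[i, , drop = FALSE])
    ev <- eigen(matrix(c(dv$v1, dv$w, dv$w, dv$v2), 2, 2),
                symmetric = TRUE)$values
    expect_equal(e$e_s0[i], min(ev), tolerance = 1e-10)
    expect_equal(e$e_s1[i], max(ev), tolerance = 1e-10)
  }
  # noiseless gap is never negative
  expect_true(all(e$e_s1 - e$e_s0 >= 0))
})

test_that("degeneracy occurs exactly where both conditions hold", {
  # symmetric crossing: V1 = x^2, V2 = (x-2)^2, W = y
  m <- two_state_model(k1 = c(1, 1e-8), a = c(0, 0),
                       k2 = c(1, 1e-8), b = c(2, 0),
                       delta = 0, coupling = 1, coupling_coord = 2)
  e <- adiabatic_energies(m, c(1, 0))
  expect_equal(e$e_s0, e$e_s1)
  expect_equal(e$e_s0, 1)
  mec <- analytic_meci(m)
  expect_equal(mec$values, c(1, 0), tolerance = 1e-10)
  expect_equal(mec$energy, 1, tolerance = 1e-10)
  # off the seam the gap is strictly positive
  set.seed(77)
  for (i in 1:1000) {
    x <- c(runif(1, -3, 3), runif(1, -3, 3))
    if (abs(x[1] - 1) < 1e-6 || abs(x[2]) < 1e-6) next
    e <- adiabatic_energies(m, x)
    expect_gt(e$e_s1 - e$e_s0, 0)
  }
})

test_that("uncoupled limit returns the sorted diabats", {
  m <- two_state_model(k1 = c(2, 1), a = c(0, 0), k2 = c(1, 1), b = c(1, 0),
                       delta = -3, coupling = 0, coupling_coord = 2)
  set.seed(5)
  X <- matrix(runif(40, -2, 2), ncol = 2)
  dv <- bogeom:::diabats(m, X)
  e <- adiabatic_energies(m, X)
  expect_equal(e$e_s0, pmin(dv$v1, dv$v2))
  expect_equal(e$e_s1, pmax(dv$v1, dv$v2))
})

test_that("analytic MECI matches a constrained grid-plus-refinement search", {
  b <- benchmark_2d()
  mec <- analytic_meci(b$model)
  # independent oracle: dense scan for near-degenerate points on the
  # zero-coupling line, then bisection refinement of each sign change of the
  # diabatic splitting; the MECI is the lowest-energy degeneracy found
  xs <- seq(b$space$lower[1], b$space$upper[1], length.out = 20001)
  G <- cbind(xs, 0)
  e <- adiabatic_energies(b$model, G)
  dv <- bogeom:::diabats(b$model, G)
  split <- dv$v1 - dv$v2
  flips <- which(diff(sign(split)) != 0)
  expect_gt(length(flips), 0)
  roots <- vapply(flips, function(i)
    uniroot(function(x) {
      d <- bogeom:::diabats(b$model, cbind(x, 0)); d$v1 - d$v2
    }, c(xs[i], xs[i + 1]), tol = 1e-12)$root, numeric(1))
  energies <- adiabatic_energies(b$model, cbind(roots, 0))$e_s0
  expect_equal(mec$values[1], roots[which.min(energies)], tolerance = 1e-8)
  expect_equal(mec$energy, min(energies), tolerance = 1e-8)
})

test_that("parallel diabats that never cross raise a no-intersection error", {
  m <- two_state_model(k1 = c(1, 1), a = c(0, 0), k2 = c(1, 1), b = c(0, 0),
                       delta = 5, coupling = 1, coupling_coord = 2)
  expect_error(analytic_meci(m), "never cross")
})

test_that("grid-refined reference GM is stable under grid-halving", {
  b <- benchmark_2d()
  g1 <- reference_gm(b$model, b$space, n_grid = 101)
  g2 <- reference_gm(b$model, b$space, n_grid = 201)
  expect_equal(g1$values, g2$values, tolerance = 1e-6)
  expect_equal(g1$energy, g2$energy, tolerance = 1e-6)
  # single deep well without coupling sits at the diabatic minimum
  m <- two_state_model(k1 = c(1, 1), a = c(0.3, -0.2), k2 = c(1, 1),
                       b = c(0, 0), delta = 100, coupling = 0,
                       coupling_coord = 2)
  sp <- search_space(c("x", "y"), c("abstract", "abstract"), c(-1, -1), c(1, 1))
  g <- reference_gm(m, sp, n_grid = 51)
  expect_equal(g$values, c(0.3, -0.2), tolerance = 1e-6)
  expect_equal(g$energy, 0, tolerance = 1e-8)
  # bounds excluding the unconstrained minimum put the GM on the boundary
  sp2 <- search_space(c("x", "y"), c("abstract", "abstract"), c(0.5, -1), c(1, 1))
  g <- reference_gm(m, sp2, n_grid = 51)
  expect_equal(g$values[1], 0.5, tolerance = 1e-8)
})

test_that("uniform noise respects its range, mean, determinism and recoverability", {
  rec <- energy_record(-10, -5)
  # zero half-width changes nothing but the flag
  r0 <- add_uniform_noise(rec, half_width = 0, rng_seed = 1)
  expect_equal(r0$e_s0, rec$e_s0)
  expect_equal(r0$e_s1, rec$e_s1)
  expect_true(r0$noisy)
  expect_false(rec$noisy)

  # bounds are exact, mean within 3 standard errors of zero
  set.seed(9)
  eps <- replicate(100000, add_uniform_noise(energy_record(0), 2.0)$e_s0)
  expect_gte(min(eps), -2.0)
  expect_lte(max(eps), 2.0)
  expect_lt(abs(mean(eps)), 3 * (2 / sqrt(3)) / sqrt(100000))

  # same seed, same perturbation; and the clean record is recoverable by
  # regenerating the noise stream
  r1 <- add_uniform_noise(rec, 2.0, rng_seed = 42)
  r2 <- add_uniform_noise(rec, 2.0, rng_seed = 42)
  expect_identical(r1, r2)
  noise <- add_uniform_noise(energy_record(0, 0), 2.0, rng_seed = 42)
  expect_equal(r1$e_s0 - noise$e_s0, rec$e_s0)
  expect_equal(r1$e_s1 - noise$e_s1, rec$e_s1)

  expect_error(add_uniform_noise(rec, -1), "non-negative")
})

test_that("noisy oracle wrapper preserves the underlying oracle", {
  b <- benchmark_2d()
  noisy <- with_uniform_noise(b$oracle, 2.0)
  x <- c(0.5, 0.5)
  set.seed(3)
  r <- noisy(x)
  clean <- b$oracle(x)
  expect_true(r$noisy)
  expect_lte(abs(r$e_s0 - clean$e_s0), 2.0)
  expect_lte(abs(r$e_s1 - clean$e_s1), 2.0)
})

test_that("6-coordinate benchmark has a collision-free GM and a degenerate seam minimum", {
  f <- formaldehyde_like_6d()
  gm <- f$gm()
  expect_equal(gm$energy, 0, tolerance = 1e-6)
  expect_false(has_collision(gm$values, f$space))
  mec <- f$meci()
  e <- adiabatic_energies(f$model, mec$values)
  expect_lt(e$e_s1 - e$e_s0, 1e-3)
  expect_gt(mec$energy, gm$energy)
  expect_false(has_collision(mec$values, f$space))
})
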