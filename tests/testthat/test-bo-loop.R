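# Drive the termination rules over a constructed per-iteration energy history.
run_gm_rule <- function(e_s0, config) {
  state <- bogeom:::new_campaign_state()
  for (i in seq_along(e_s0)) {
    state$iter <- i
    state$e_s0 <- e_s0[seq_len(i)]
    state <- check_termination_gm(state, config)
    if (state$stop) break
  }
  state
}

run_ci_rule <- function(e_s0, e_s1, config) {
  state <- bogeom:::new_campaign_state()
  for (i in seq_along(e_s0)) {
    state$iter <- i
    state$e_s0 <- e_s0[seq_len(i)]
    state$e_s1 <- e_s1[seq_len(i)]
    state <- check_termination_ci(state, config)
    if (state$stop) break
  }
  state
}

test_that("GM rule stops after three unchanged multiple-of-five checks", {
  cfg <- campaign_config()
  # best found at iteration 4, never improved: checks at 5, 10, 15 see the
  # same stored minimum -> stop at iteration 15
  e <- c(5, 4, 3, 1, rep(2, 20))
  st <- run_gm_rule(e, cfg)
  expect_true(st$stop)
  expect_equal(st$iter, 15)
  expect_equal(st$status, "converged")
  expect_equal(st$stored_value, 1)
  expect_equal(st$stored_iter, 4)

  # an improvement at iteration 12 resets the patience at the check of 15
  e2 <- c(5, 4, 3, 1, rep(2, 6), 2, 0.5, rep(2, 20))
  st2 <- run_gm_rule(e2, cfg)
  expect_equal(st2$iter, 25)  # checks 15 (reset), 20, 25 unchanged
  expect_equal(st2$stored_value, 0.5)
  tr <- st2$trace
  counter_at <- function(tr, it)
    vapply(tr, function(r) r$check_iter == it, logical(1))
  expect_equal(tr[[which(counter_at(tr, 15))]]$counter, 1L)

  # strictly equal values never reset the patience
  e3 <- c(1, rep(1, 30))
  expect_equal(run_gm_rule(e3, cfg)$iter, 15)
})

test_that("GM rule falls back to the hard iteration cap", {
  cfg <- campaign_config(max_iterations = 40)
  e <- seq(100, by = -1, length.out = 60)  # improves forever
  st <- run_gm_rule(e, cfg)
  expect_true(st$stop)
  expect_equal(st$iter, 40)
  expect_equal(st$status, "max_iterations")
})

test_that("CI rule stores the gap-filtered lowest E(S1) and stops on stagnation", {
  cfg <- campaign_config()
  n <- 400
  e0 <- rep(50, n); e1 <- rep(60, n)        # gap 10: never qualifies
  # one qualifying structure at iteration 60, none better afterwards:
  # first stored at the check of 100, unchanged at 150 and 200 -> stop at 200
  e0[60] <- 20; e1[60] <- 22
  st <- run_ci_rule(e0, e1, cfg)
  expect_true(st$stop)
  expect_equal(st$iter, 200)
  expect_equal(st$status, "converged")
  expect_equal(st$stored_iter, 60)
  expect_equal(st$stored_value, 22)

  # equal E(S1) ties break to the earlier iteration and do not reset patience
  e0b <- e0; e1b <- e1
  e0b[120] <- 20; e1b[120] <- 22
  stb <- run_ci_rule(e0b, e1b, cfg)
  expect_equal(stb$iter, 200)
  expect_equal(stb$stored_iter, 60)

  # the gap filter is strict: a gap of exactly 3.0 does not qualify
  e0c <- rep(50, n); e1c <- rep(53, n)
  stc <- run_ci_rule(e0c, e1c, campaign_config(max_iterations = 250))
  expect_equal(stc$status, "no_ci_found")
  expect_equal(stc$iter, 250)
  expect_true(is.na(stc$stored_value))
})

test_that("proposals are deterministic given seed and model", {
  b <- benchmark_2d()
  set.seed(60)
  X <- sample_uniform(b$space, 12)
  y <- -adiabatic_energies(b$model, X)$e_s0
  fit <- gp_fit(X, y, epochs = 30)
  cfg <- campaign_config(n_random = 100, n_select = 8)
  p1 <- propose_candidate(fit, b$space, max(y), acquisition_spec("PI"),
                          cfg, rng_seed = 9)
  p2 <- propose_candidate(fit, b$space, max(y), acquisition_spec("PI"),
                          cfg, rng_seed = 9)
  expect_identical(p1, p2)
})

test_that("a single interior acquisition maximum is located precisely", {
  sp <- search_space("x", "abstract", 0, 2)
  X <- matrix(c(0.1, 0.5, 0.9, 1.3, 1.7), ncol = 1)
  y <- -(drop(X) - 1.3)^2
  fit <- gp_fit(X, y, epochs = 50)
  acq <- acquisition_spec("UCB", beta = 0.5)
  # dense-grid scan as the independent maximizer
  grid <- matrix(seq(0, 2, length.out = 200001), ncol = 1)
  p <- gp_predict(fit, grid)
  af <- upper_confidence_bound(p$mu, p$sigma, 0.5)
  x_star <- grid[which.max(af), 1]
  prop <- propose_candidate(fit, sp, max(y), acq,
                            campaign_config(n_random = 200, n_select = 10),
                            rng_seed = 2)
  expect_lt(abs(prop$values[["x"]] - x_star), 1e-3)
})

test_that("colliding acquisition maxima are skipped for the best collision-free geometry", {
  sp <- diatomic_space(lower = 0.2, upper = 2.5)
  # objective with its top peak inside the collision region (r < 0.5 A) and
  # a secondary collision-free peak near 1.5 A
  X <- matrix(c(0.2, 0.3, 0.4, 0.7, 1.0, 1.3, 1.5, 1.7, 2.0, 2.3), ncol = 1)
  y <- 3 * exp(-((drop(X) - 0.3) / 0.1)^2) +
       2.5 * exp(-((drop(X) - 1.5) / 0.35)^2)
  fit <- gp_fit(X, y, epochs = 60)
  acq <- acquisition_spec("UCB", beta = 0.2)
  grid <- matrix(seq(0.2, 2.5, length.out = 20001), ncol = 1)
  p <- gp_predict(fit, grid)
  af <- upper_confidence_bound(p$mu, p$sigma, 0.2)
  # precondition of the scenario: the unconstrained maximizer collides
  expect_lt(grid[which.max(af), 1], 0.5)
  prop <- propose_candidate(fit, sp, max(y), acq,
                            campaign_config(n_random = 300, n_select = 15),
                            rng_seed = 3)
  expect_gte(min_pair_distance(prop$values, sp), 0.5)
  # and it is the best collision-free acquisition maximizer (near 1.5 A)
  feasible <- grid[, 1] >= 0.5
  expect_lt(abs(prop$values[["r1"]] - grid[feasible, ][which.max(af[feasible])]),
            2e-3)
})

test_that("an all-colliding space fails the proposal with a clear error", {
  sp <- diatomic_space(lower = 0.2, upper = 0.45)
  X <- matrix(c(0.22, 0.3, 0.38, 0.44), ncol = 1)
  y <- c(0, 1, 0.5, 0.2)
  fit <- gp_fit(X, y, epochs = 20)
  expect_error(
    propose_candidate(fit, sp, max(y), acquisition_spec("PI"),
                      campaign_config(n_random = 50, n_select = 4,
                                      retry_cap = 2), rng_seed = 1),
    "proposal failure")
})

test_that("a one-iteration campaign is well-formed and datasets grow by one per iteration", {
  b <- benchmark_2d()
  init <- generate_initial_set(initial_set_spec(n_structures = 8),
                               b$space, b$oracle, rng_seed = 14)
  cfg <- campaign_config(n_random = 60, n_select = 5, max_iterations = 1)
  camp <- run_campaign(b$space, b$oracle, objective_spec("GM"), init,
                       config = cfg, seed = 5)
  expect_equal(camp$iterations, 1)
  expect_equal(nrow(camp$history), 1)
  expect_equal(nrow(camp$X), 1)
  expect_equal(camp$status, "max_iterations")
  expect_false(is.null(camp$final))
  expect_equal(camp$final$e_s0,
               adiabatic_energies(b$model, camp$final$values)$e_s0)
})

test_that("campaigns are bitwise reproducible from one master seed", {
  b <- benchmark_2d()
  cfg <- campaign_config(n_random = 80, n_select = 6, max_iterations = 20)
  run_once <- function() {
    set.seed(77)
    init <- generate_initial_set(initial_set_spec(n_structures = 10),
                                 b$space, b$oracle)
    run_campaign(b$space, with_uniform_noise(b$oracle, 2.0),
                 objective_spec("GM"), init, config = cfg, seed = 123)
  }
  c1 <- run_once()
  c2 <- run_once()
  expect_identical(c1$history, c2$history)
  expect_identical(c1$trace, c2$trace)
})

test_that("the stored GM trace is monotone and the dataset bookkeeping is exact", {
  b <- benchmark_2d()
  init <- generate_initial_set(initial_set_spec(n_structures = 10),
                               b$space, b$oracle, rng_seed = 21)
  cfg <- campaign_config(n_random = 80, n_select = 6, max_iterations = 60)
  camp <- run_campaign(b$space, b$oracle, objective_spec("GM"), init,
                       config = cfg, seed = 31)
  expect_equal(nrow(camp$history), camp$iterations)
  expect_true(all(diff(camp$trace$stored_value) <= 0))
  expect_equal(camp$final$e_s0, min(camp$history$e_s0))
})
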