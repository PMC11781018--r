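#' Campaign configuration
#'
#' Collects every tunable of the five-step search loop. The defaults are the
#' published working values: 2000 random structures reduced to the 200 best
#' acquisition-function starts, each locally optimized with L-BFGS-B; a
#' 0.5-Angstrom atomic-collision exclusion; convergence checks at every 5th
#' (GM) or 50th (MECI) iteration with a patience of 3 consecutive checks; a
#' 3.0 kcal/mol energy-gap filter for the stored conical-intersection
#' candidate; a hard cap of 1000 iterations; and a surrogate refit with 100
#' Adam epochs at learning rate 0.2 every iteration.
#'
#' @param n_random random structures generated per proposal.
#' @param n_select acquisition-ranked structures kept for local optimization.
#' @param collision_threshold atomic-collision distance, Angstrom.
#' @param gm_check_interval,ci_check_interval iterations between stored-best
#'   checks for the GM and MECI termination rules.
#' @param patience consecutive checks without improvement before stopping.
#' @param gap_threshold E(S1)-E(S0) filter (kcal/mol, strict `<`) for the
#'   stored MECI candidate.
#' @param max_iterations hard iteration cap.
#' @param fit_epochs,fit_learning_rate surrogate refit schedule.
#' @param lbfgs_maxit iteration cap per local acquisition maximization.
#' @param af_tol convergence tolerance on the acquisition value.
#' @param retry_cap full-proposal regenerations allowed when every optimized
#'   structure collides.
#' @return A list of class `bo_campaign_config`.
#' @export
campaign_config <- function(n_random = 2000, n_select = 200,
                            collision_threshold = 0.5,
                            gm_check_interval = 5, ci_check_interval = 50,
                            patience = 3, gap_threshold = 3.0,
                            max_iterations = 1000,
                            fit_epochs = 100, fit_learning_rate = 0.2,
                            lbfgs_maxit = 200, af_tol = 1e-6,
                            retry_cap = 10) {
  stopifnot(n_select <= n_random, n_select >= 1,
            gm_check_interval >= 1, ci_check_interval >= 1,
            patience >= 1, max_iterations >= 1, collision_threshold >= 0)
  structure(as.list(environment()), class = "bo_campaign_config")
}

#' Propose the next candidate geometry
#'
#' The two-stage acquisition maximization of the search loop: draw `n_random`
#' uniform geometries, rank them by acquisition value, keep the deterministic
#' top `n_select` as starts, locally maximize the acquisition from each with
#' bounded L-BFGS-B (analytic posterior gradients), and return the optimized
#' geometry with the highest acquisition value among those free of atomic
#' collisions. If every optimized geometry collides, the whole procedure is
#' repeated with fresh random draws, up to `retry_cap` times.
#'
#' Random draws come from the current RNG stream; pass `rng_seed` for a
#' stand-alone deterministic call.
#'
#' @param model fitted [gp_fit()] surrogate on the current dataset.
#' @param space the [search_space()].
#' @param incumbent best observed objective value.
#' @param acq an [acquisition_spec()].
#' @param config a [campaign_config()].
#' @param rng_seed optional seed (preserves the caller's RNG state).
#' @return A list with `values` (the proposal), `af`, `mu`, `sigma`, and
#'   `retries`.
#' @export
propose_candidate <- function(model, space, incumbent, acq,
                              config = campaign_config(), rng_seed = NULL) {
  if (!is.null(rng_seed))
    return(with_preserved_seed(rng_seed,
      propose_candidate(model, space, incumbent, acq, config)))
  factr <- config$af_tol / .Machine$double.eps
  for (try in seq_len(config$retry_cap)) {
    X0 <- sample_uniform(space, config$n_random)
    p0 <- gp_predict(model, X0)
    af0 <- af_value(p0$mu, p0$sigma, incumbent, acq)
    starts <- X0[order(af0, decreasing = TRUE)[seq_len(config$n_select)], ,
                 drop = FALSE]
    opt <- vector("list", nrow(starts))
    for (s in seq_len(nrow(starts))) {
      cache <- new.env(parent = emptyenv())
      eval_at <- function(par) {
        key <- get0("par", cache)
        if (is.null(key) || !identical(key, par)) {
          assign("par", par, cache)
          assign("vg", af_value_grad(model, par, incumbent, acq), cache)
        }
        get("vg", cache)
      }
      res <- stats::optim(starts[s, ],
                          fn = function(par) eval_at(par)$value,
                          gr = function(par) eval_at(par)$grad,
                          method = "L-BFGS-B",
                          lower = space$lower, upper = space$upper,
                          control = list(fnscale = -1,
                                         maxit = config$lbfgs_maxit,
                                         factr = factr))
      opt[[s]] <- list(par = res$par, value = res$value)
    }
    vals <- vapply(opt, `[[`, numeric(1), "value")
    for (s in order(vals, decreasing = TRUE)) {
      par <- opt[[s]]$par
      if (!has_collision(par, space, config$collision_threshold)) {
        pr <- gp_predict(model, par)
        return(list(values = stats::setNames(unname(par), space$names),
                    af = vals[s], mu = pr$mu, sigma = pr$sigma,
                    retries = try - 1L))
      }
    }
  }
  stop("proposal failure: every optimized geometry collided in ",
       config$retry_cap, " regenerations")
}

new_campaign_state <- function() {
  list(iter = 0L, e_s0 = numeric(0), e_s1 = numeric(0),
       stored_value = NA_real_, stored_iter = NA_integer_, counter = 0L,
       stop = FALSE, status = "running",
       trace = list())
}

#' Termination check for the global-minimum search
#'
#' At every iteration that is a multiple of the check interval, the lowest
#' observed E(S0) among all candidates is stored. The campaign stops once the
#' stored value has remained unchanged (no strictly lower energy found) for
#' `patience` consecutive checks, or unconditionally at the iteration cap.
#'
#' @param state campaign state: a list with `iter` (current iteration),
#'   `e_s0` (observed candidate energies, one per iteration), and the
#'   bookkeeping fields `stored_value`, `stored_iter`, `counter`.
#' @param config a [campaign_config()].
#' @return The updated state; `state$stop` and `state$status` hold the
#'   decision.
#' @export
check_termination_gm <- function(state, config = campaign_config()) {
  if (state$iter %% config$gm_check_interval == 0 &&
      length(state$e_s0) > 0) {
    best_i <- which.min(state$e_s0)
    best <- state$e_s0[best_i]
    if (is.na(state$stored_value) || best < state$stored_value) {
      state$stored_value <- best
      state$stored_iter <- best_i
      state$counter <- 1L
    } else {
      state$counter <- state$counter + 1L
    }
    state$trace[[length(state$trace) + 1L]] <-
      list(check_iter = state$iter, stored_value = state$stored_value,
           stored_iter = state$stored_iter, counter = state$counter)
    if (state$counter >= config$patience) {
      state$stop <- TRUE
      state$status <- "converged"
      return(state)
    }
  }
  if (state$iter >= config$max_iterations) {
    state$stop <- TRUE
    state$status <- "max_iterations"
  }
  state
}

#' Termination check for the conical-intersection search
#'
#' At every iteration that is a multiple of the check interval, candidates
#' whose observed energy gap E(S1)-E(S0) is strictly below the gap threshold
#' are filtered, and the one with the lowest E(S1) is stored (earliest
#' iteration wins ties). The campaign stops once the stored E(S1) has not
#' strictly improved for `patience` consecutive checks. If no candidate ever
#' qualifies, the campaign runs to the iteration cap and reports that no
#' conical intersection was found.
#'
#' @inheritParams check_termination_gm
#' @export
check_termination_ci <- function(state, config = campaign_config()) {
  if (state$iter %% config$ci_check_interval == 0 &&
      length(state$e_s1) > 0) {
    gap <- state$e_s1 - state$e_s0
    qual <- which(gap < config$gap_threshold)
    if (length(qual) > 0) {
      best_i <- qual[which.min(state$e_s1[qual])]
      best <- state$e_s1[best_i]
      if (is.na(state$stored_value) || best < state$stored_value) {
        state$stored_value <- best
        state$stored_iter <- best_i
        state$counter <- 1L
      } else {
        state$counter <- state$counter + 1L
      }
    }
    state$trace[[length(state$trace) + 1L]] <-
      list(check_iter = state$iter, stored_value = state$stored_value,
           stored_iter = state$stored_iter, counter = state$counter)
    if (state$counter >= config$patience) {
      state$stop <- TRUE
      state$status <- "converged"
      return(state)
    }
  }
  if (state$iter >= config$max_iterations) {
    state$stop <- TRUE
    state$status <- if (is.na(state$stored_value)) "no_ci_found"
                    else "max_iterations"
  }
  state
}

#' Run a Bayesian-optimization geometry-search campaign
#'
#' Executes the five-step loop: refit the Gaussian-process surrogate on all
#' data so far, propose the acquisition-maximizing collision-free candidate,
#' evaluate the energy oracle there, append the result, and apply the
#' target-specific termination rule. One master seed fixes every random draw
#' (sampling, proposal and any noise wrapper), so two runs with the same seed
#' produce identical histories.
#'
#' @param space a [search_space()].
#' @param oracle a `function(values) -> energy_record` (see
#'   [two_state_oracle()], [with_uniform_noise()]).
#' @param objective an [objective_spec()].
#' @param initial initial training set: a list with `X` (matrix of
#'   geometries) and `records` (list of [energy_record()]s); see
#'   [generate_initial_set()].
#' @param acq an [acquisition_spec()] (probability of improvement by
#'   default).
#' @param config a [campaign_config()].
#' @param seed master RNG seed for the campaign.
#' @return An object of class `bo_campaign`: per-iteration `history`, the
#'   stored-best `trace`, the `final` reported geometry and energies (for GM,
#'   the lowest-E(S0) candidate; for MECI, the stored gap-filtered
#'   lowest-E(S1) candidate), the termination `status`, and the evaluated
#'   candidate matrix `X`.
#' @export
run_campaign <- function(space, oracle, objective, initial,
                         acq = acquisition_spec("PI"),
                         config = campaign_config(), seed = NULL) {
  stopifnot(inherits(objective, "bo_objective"))
  if (is.null(initial$X) || nrow(initial$X) == 0)
    stop("the initial dataset must be non-empty")
  if (!is.null(seed)) set.seed(seed)

  D_X <- as.matrix(initial$X)
  D_y <- vapply(initial$records, objective_value, numeric(1), spec = objective)
  if (objective$target == "MECI" &&
      any(vapply(initial$records, function(r) is.null(r$e_s1), logical(1))))
    stop("MECI campaigns need both state energies in every initial record")

  check <- if (objective$target == "GM") check_termination_gm
           else check_termination_ci
  state <- new_campaign_state()
  cand_X <- matrix(numeric(0), ncol = n_coords(space),
                   dimnames = list(NULL, space$names))
  records <- list()
  log_rows <- vector("list", config$max_iterations)

  repeat {
    i <- state$iter + 1L
    model <- gp_fit(D_X, D_y, epochs = config$fit_epochs,
                    learning_rate = config$fit_learning_rate)
    incumbent <- max(D_y)
    prop <- tryCatch(
      propose_candidate(model, space, incumbent, acq, config),
      error = function(e)
        stop(sprintf("iteration %d: %s", i, conditionMessage(e)),
             call. = FALSE))
    rec <- tryCatch(oracle(prop$values),
                    error = function(e)
                      stop(sprintf("oracle failed at iteration %d: %s", i,
                                   conditionMessage(e)), call. = FALSE))
    obj <- objective_value(rec, objective)

    D_X <- rbind(D_X, prop$values)
    D_y <- c(D_y, obj)
    cand_X <- rbind(cand_X, prop$values)
    records[[i]] <- rec
    state$iter <- i
    state$e_s0 <- c(state$e_s0, rec$e_s0)
    state$e_s1 <- c(state$e_s1, if (is.null(rec$e_s1)) NA_real_ else rec$e_s1)
    log_rows[[i]] <- data.frame(
      iteration = i, t(prop$values), af = prop$af, mu = prop$mu,
      sigma = prop$sigma, e_s0 = rec$e_s0,
      e_s1 = if (is.null(rec$e_s1)) NA_real_ else rec$e_s1,
      gap = if (is.null(rec$e_s1)) NA_real_ else rec$e_s1 - rec$e_s0,
      objective = obj, noisy = rec$noisy)

    state <- check(state, config)
    if (state$stop) break
  }

  final <- campaign_final(objective, state, cand_X, records)
  structure(list(
    history = do.call(rbind, log_rows[seq_len(state$iter)]),
    trace = do.call(rbind, lapply(state$trace, as.data.frame)),
    X = cand_X, records = records, initial = initial,
    final = final, status = state$status, iterations = state$iter,
    objective = objective, acquisition = acq, config = config,
    seed = seed), class = "bo_campaign")
}

campaign_final <- function(objective, state, cand_X, records) {
  if (objective$target == "GM") {
    i <- which.min(state$e_s0)
    list(values = cand_X[i, ], iteration = i,
         e_s0 = state$e_s0[i], e_s1 = state$e_s1[i])
  } else if (!is.na(state$stored_iter)) {
    i <- state$stored_iter
    list(values = cand_X[i, ], iteration = i,
         e_s0 = state$e_s0[i], e_s1 = state$e_s1[i])
  } else {
    NULL
  }
}

#' @export
print.bo_campaign <- function(x, ...) {
  cat(sprintf("BO campaign (%s target): %d iterations, status '%s'\n",
              x$objective$target, x$iterations, x$status))
  if (!is.null(x$final)) {
    cat(sprintf("final geometry (iteration %d): %s\n", x$final$iteration,
                paste(signif(x$final$values, 5), collapse = ", ")))
    cat(sprintf("E(S0) = %.4f%s kcal/mol\n", x$final$e_s0,
                if (!is.na(x$final$e_s1))
                  sprintf(", E(S1) = %.4f, gap = %.4f", x$final$e_s1,
                          x$final$e_s1 - x$final$e_s0) else ""))
  } else {
    cat("no qualifying conical-intersection candidate was found\n")
  }
  invisible(x)
}
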