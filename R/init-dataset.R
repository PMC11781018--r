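#' Initial-set specification
#'
#' Describes how the initial training dataset (step 0 of the loop) is
#' generated. In the published workflow this set came from an automated
#' reaction-path search; any cheap generator of structurally diverse
#' geometries serves the same role, and the shipped default is seeded random
#' sampling. Modes: `uniform` draws every coordinate uniformly within bounds;
#' `perturbed-seed` adds Gaussian perturbations (per coordinate kind) to a
#' seed geometry, clipped to bounds; `mixed` alternates the two.
#'
#' @param mode `"uniform"`, `"perturbed-seed"` or `"mixed"`.
#' @param n_structures number of collision-free structures to produce.
#' @param perturb named perturbation scales per coordinate kind
#'   (`distance` in Angstrom, `angle`/`dihedral` in degrees).
#' @param seed_geometry seed geometry for perturbation modes.
#' @return A list of class `bo_initial_spec`.
#' @export
initial_set_spec <- function(mode = c("uniform", "perturbed-seed", "mixed"),
                             n_structures = 71,
                             perturb = c(distance = 0.15, angle = 15,
                                         dihedral = 30, abstract = 0.25),
                             seed_geometry = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_structures >= 1, all(perturb >= 0))
  if (mode != "uniform" && is.null(seed_geometry))
    stop("perturbation modes need a seed geometry")
  structure(list(mode = mode, n_structures = as.integer(n_structures),
                 perturb = perturb, seed_geometry = seed_geometry),
            class = "bo_initial_spec")
}

#' Generate the initial training set
#'
#' Draws structures according to the specification, discards any with atom
#' pairs closer than the collision threshold (0.5 Angstrom), and attaches
#' oracle energies. Deterministic given the seed.
#'
#' @param spec an [initial_set_spec()].
#' @param space a [search_space()].
#' @param oracle a `function(values) -> energy_record`.
#' @param rng_seed integer seed (optional; otherwise the current RNG stream
#'   is used).
#' @param collision_threshold exclusion distance in Angstrom.
#' @param retry_cap maximum draws attempted per accepted structure.
#' @return A list with `X` (n x d matrix) and `records` (list of
#'   [energy_record()]s), directly usable as `initial` in [run_campaign()].
#' @export
generate_initial_set <- function(spec, space, oracle, rng_seed = NULL,
                                 collision_threshold = 0.5,
                                 retry_cap = 100) {
  if (!is.null(rng_seed))
    return(with_preserved_seed(rng_seed,
      generate_initial_set(spec, space, oracle,
                           collision_threshold = collision_threshold,
                           retry_cap = retry_cap)))
  d <- n_coords(space)
  n <- spec$n_structures
  X <- matrix(NA_real_, n, d, dimnames = list(NULL, space$names))
  for (i in seq_len(n)) {
    use_uniform <- spec$mode == "uniform" ||
      (spec$mode == "mixed" && i %% 2 == 1)
    ok <- FALSE
    for (try in seq_len(retry_cap)) {
      cand <- if (use_uniform) {
        drop(sample_uniform(space, 1))
      } else {
        scales <- unname(spec$perturb[space$kinds])
        scales[is.na(scales)] <- 0
        v <- as.numeric(spec$seed_geometry) + stats::rnorm(d, 0, scales)
        pmin(pmax(v, space$lower), space$upper)
      }
      if (!has_collision(cand, space, collision_threshold)) {
        X[i, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not draw a collision-free structure within the retry cap")
  }
  records <- lapply(seq_len(n), function(i) oracle(X[i, ]))
  list(X = X, records = records)
}

#' Remove near-duplicate structures
#'
#' Greedy deduplication in internal-coordinate space: structures are scanned
#' in order and kept only if their Euclidean coordinate distance to every
#' previously kept structure exceeds the tolerance.
#'
#' @param X n x d matrix of internal-coordinate values.
#' @param tolerance positive distance threshold.
#' @return The kept rows of `X` (attribute `kept` holds their indices).
#' @export
deduplicate <- function(X, tolerance) {
  stopifnot(is.matrix(X), tolerance > 0)
  kept <- integer(0)
  for (i in seq_len(nrow(X))) {
    if (length(kept) == 0) { kept <- i; next }
    dmin <- min(sqrt(rowSums(
      (X[kept, , drop = FALSE] - matrix(X[i, ], length(kept), ncol(X),
                                        byrow = TRUE))^2)))
    if (dmin > tolerance) kept <- c(kept, i)
  }
  out <- X[kept, , drop = FALSE]
  attr(out, "kept") <- kept
  out
}
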