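#' Two-state diabatic model surface
#'
#' An analytic stand-in for a quantum-chemical energy oracle: two quadratic
#' diabatic potentials coupled linearly through one designated coordinate.
#' The diabats are
#' \deqn{V_1(x) = \sum_j k^{(1)}_j (x_j - a_j)^2, \qquad
#'       V_2(x) = \sum_j k^{(2)}_j (x_j - b_j)^2 + \Delta,}
#' and the coupling is \eqn{W = c\,(x_c - c_0)} on the coupling coordinate
#' \eqn{x_c}. The adiabatic energies are the eigenvalues of the 2x2 diabatic
#' matrix,
#' \deqn{E_\pm = \tfrac{V_1+V_2}{2} \pm \sqrt{\left(\tfrac{V_1-V_2}{2}\right)^2 + W^2},}
#' so the two states are exactly degenerate where \eqn{V_1 = V_2} and
#' \eqn{W = 0}. Energies are in kcal/mol.
#'
#' @param k1,k2 positive per-coordinate force constants (kcal/mol per unit^2).
#' @param a,b per-coordinate positions of the two diabatic minima.
#' @param delta energy offset of the second diabat (kcal/mol).
#' @param coupling strength `c` (kcal/mol per unit of the coupling coordinate).
#' @param coupling_coord index of the coupling coordinate.
#' @param coupling_origin value of the coupling coordinate at which the
#'   coupling vanishes (0 by default).
#' @return An object of class `bo_two_state_model`.
#' @export
two_state_model <- function(k1, k2, a, b, delta = 0, coupling = 1,
                            coupling_coord = length(k1),
                            coupling_origin = 0) {
  d <- length(k1)
  stopifnot(length(k2) == d, length(a) == d, length(b) == d,
            coupling_coord >= 1, coupling_coord <= d)
  if (any(k1 <= 0) || any(k2 <= 0))
    stop("force constants must be strictly positive")
  structure(list(k1 = as.numeric(k1), k2 = as.numeric(k2),
                 a = as.numeric(a), b = as.numeric(b),
                 delta = as.numeric(delta), coupling = as.numeric(coupling),
                 coupling_coord = as.integer(coupling_coord),
                 coupling_origin = as.numeric(coupling_origin),
                 dim = d),
            class = "bo_two_state_model")
}

#' @export
print.bo_two_state_model <- function(x, ...) {
  cat(sprintf("Two-state diabatic model: %d coordinate(s), coupling %.3g on coordinate %d\n",
              x$dim, x$coupling, x$coupling_coord))
  invisible(x)
}

# Diabatic potentials for an m x d matrix of geometries.
diabats <- function(model, X) {
  X <- coord_matrix(X, model$dim)
  v1 <- colSums(model$k1 * (t(X) - model$a)^2)
  v2 <- colSums(model$k2 * (t(X) - model$b)^2) + model$delta
  w <- model$coupling * (X[, model$coupling_coord] - model$coupling_origin)
  list(v1 = v1, v2 = v2, w = w)
}

coord_matrix <- function(X, d) {
  if (!is.matrix(X)) X <- matrix(X, ncol = d, byrow = TRUE)
  stopifnot(ncol(X) == d)
  X
}

#' Adiabatic energies of a two-state model
#'
#' @param model a [two_state_model()].
#' @param values a geometry (numeric vector) or an m x d matrix of geometries.
#' @return For a single geometry, a list with `e_s0` and `e_s1`; for a matrix,
#'   a data.frame with columns `e_s0`, `e_s1`.
#' @export
adiabatic_energies <- function(model, values) {
  single <- !is.matrix(values)
  if (single && length(values) != model$dim)
    stop("geometry dimensionality does not match the model")
  dv <- diabats(model, values)
  mean_ <- (dv$v1 + dv$v2) / 2
  half <- sqrt(((dv$v1 - dv$v2) / 2)^2 + dv$w^2)
  if (single) list(e_s0 = mean_ - half, e_s1 = mean_ + half)
  else data.frame(e_s0 = mean_ - half, e_s1 = mean_ + half)
}

#' Energy record
#'
#' One or two electronic state energies for a geometry, with noise provenance.
#' For noiseless adiabatic oracles `e_s1 >= e_s0`; added noise may violate the
#' ordering, and the `noisy` flag records that provenance.
#'
#' @param e_s0 ground-state energy E(S0), kcal/mol.
#' @param e_s1 optional excited-state energy E(S1), kcal/mol.
#' @param noisy logical noise flag.
#' @return A list of class `bo_energy_record`.
#' @export
energy_record <- function(e_s0, e_s1 = NULL, noisy = FALSE) {
  stopifnot(is.finite(e_s0), is.null(e_s1) || is.finite(e_s1))
  structure(list(e_s0 = as.numeric(e_s0),
                 e_s1 = if (is.null(e_s1)) NULL else as.numeric(e_s1),
                 noisy = isTRUE(noisy)),
            class = "bo_energy_record")
}

#' Energy oracle from a two-state model
#'
#' Wraps a model as a callable oracle `function(values) -> energy_record`,
#' the interface [run_campaign()] consumes. Any user function with the same
#' signature (e.g. backed by a semiempirical or quantum-chemical code) can be
#' used in its place.
#'
#' @param model a [two_state_model()].
#' @return A function mapping a geometry to an [energy_record()].
#' @export
two_state_oracle <- function(model) {
  force(model)
  function(values) {
    e <- adiabatic_energies(model, values)
    energy_record(e$e_s0, e$e_s1)
  }
}

#' Add uniform random noise to an energy record
#'
#' Emulates energies measured on noisy quantum hardware: independent draws
#' from the uniform distribution on \[-half_width, +half_width\] kcal/mol are
#' added to each state energy. The default half-width of 2.0 kcal/mol matches
#' the error scale reported for superconducting-device measurements.
#'
#' @param record an [energy_record()].
#' @param half_width noise half-width in kcal/mol (>= 0).
#' @param rng_seed optional integer seed for a deterministic draw (the
#'   caller's RNG state is preserved).
#' @return A perturbed [energy_record()] with `noisy = TRUE`.
#' @export
add_uniform_noise <- function(record, half_width = 2.0, rng_seed = NULL) {
  if (half_width < 0) stop("noise half-width must be non-negative")
  draw <- function() {
    n <- if (is.null(record$e_s1)) 1L else 2L
    eps <- stats::runif(n, -half_width, half_width)
    energy_record(record$e_s0 + eps[1],
                  if (n == 2L) record$e_s1 + eps[2],
                  noisy = TRUE)
  }
  if (is.null(rng_seed)) draw() else with_preserved_seed(rng_seed, draw())
}

#' Wrap an oracle with uniform energy noise
#'
#' Noise draws come from the current RNG stream, so a campaign seeded once is
#' fully reproducible. S0 and S1 noise draws are independent.
#'
#' @param oracle a `function(values) -> energy_record`.
#' @param half_width noise half-width in kcal/mol.
#' @return A noisy oracle with the same interface.
#' @export
with_uniform_noise <- function(oracle, half_width = 2.0) {
  if (half_width < 0) stop("noise half-width must be non-negative")
  force(oracle)
  function(values) add_uniform_noise(oracle(values), half_width)
}

#' Analytic minimum-energy conical intersection of a 2D model
#'
#' For a two-coordinate model with linear coupling, the degeneracy set is
#' \{coupling coordinate at its origin\} intersected with \{V1 = V2\}; on that
#' set V1 = V2 reduces to a quadratic equation in the tuning coordinate. The
#' real root with the lower energy is the MECI.
#'
#' @param model a 2-coordinate [two_state_model()].
#' @return A list with `values` (geometry) and `energy` (kcal/mol).
#' @export
analytic_meci <- function(model) {
  if (model$dim != 2)
    stop("analytic_meci() requires a 2-coordinate model")
  tc <- if (model$coupling_coord == 1L) 2L else 1L
  cc <- model$coupling_coord
  c0 <- model$coupling_origin
  K <- model$k1[cc] * (c0 - model$a[cc])^2 -
       model$k2[cc] * (c0 - model$b[cc])^2
  # V1 - V2 restricted to the coupling origin, as a quadratic in x_t
  A <- model$k1[tc] - model$k2[tc]
  B <- -2 * (model$k1[tc] * model$a[tc] - model$k2[tc] * model$b[tc])
  C <- model$k1[tc] * model$a[tc]^2 - model$k2[tc] * model$b[tc]^2 +
       K - model$delta
  roots <-
    if (abs(A) < 1e-12) {
      if (abs(B) < 1e-12) stop("diabats never cross at zero coupling: no conical intersection")
      -C / B
    } else {
      disc <- B^2 - 4 * A * C
      if (disc < 0) stop("diabats never cross at zero coupling: no conical intersection")
      (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    }
  geoms <- lapply(roots, function(r) {
    g <- numeric(2); g[tc] <- r; g[cc] <- c0; g
  })
  energies <- vapply(geoms, function(g) adiabatic_energies(model, g)$e_s0,
                     numeric(1))
  i <- which.min(energies)
  list(values = geoms[[i]], energy = energies[[i]])
}

#' Reference global minimum by dense grid scan plus local refinement
#'
#' The test oracle for the ground-state global minimum: a dense grid scan of
#' E(S0) over the search-space box followed by bounded local refinement
#' (`nlminb`) from the best grid points. For more than two coordinates the
#' scan is replaced by a seeded multistart (uniform starts plus both diabatic
#' minima). This is deliberately brute-force and independent of the Bayesian
#' optimization machinery.
#'
#' @param model a [two_state_model()].
#' @param space a [search_space()] matching the model dimensionality.
#' @param n_grid grid points per coordinate (d <= 2) or number of multistart
#'   points (d > 2).
#' @return A list with `values` and `energy`.
#' @export
reference_gm <- function(model, space, n_grid = 201) {
  d <- model$dim
  stopifnot(n_coords(space) == d)
  e0 <- function(x) adiabatic_energies(model, x)$e_s0
  if (d <= 2) {
    axes <- lapply(seq_len(d), function(j)
      seq(space$lower[j], space$upper[j], length.out = n_grid))
    grid <- as.matrix(expand.grid(axes))
    ee <- adiabatic_energies(model, grid)$e_s0
    ord <- order(ee)[seq_len(min(5, length(ee)))]
    starts <- grid[ord, , drop = FALSE]
  } else {
    starts <- rbind(sample_uniform(space, n_grid, rng_seed = 20260101),
                    pmin(pmax(model$a, space$lower), space$upper),
                    pmin(pmax(model$b, space$lower), space$upper))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::nlminb(starts[i, ], e0,
                         lower = space$lower, upper = space$upper)
    if (is.null(best) || fit$objective < best$energy)
      best <- list(values = unname(fit$par), energy = fit$objective)
  }
  best
}

#' Reference MECI by penalized multistart search
#'
#' The test oracle for the most stable conical intersection of models with
#' more than two coordinates, where the degeneracy seam is a manifold rather
#' than isolated points. The coupling coordinate is pinned at its origin
#' (where the coupling vanishes) and the seam minimum of the energy is found
#' by minimizing \eqn{V_1 + P (V_1 - V_2)^2} with an escalating penalty
#' weight P, warm-started, from many seeded uniform starts plus both diabatic
#' minima. Independent of the Bayesian-optimization machinery.
#'
#' @param model a [two_state_model()].
#' @param space a matching [search_space()].
#' @param n_starts number of multistart points.
#' @return A list with `values` and `energy` (kcal/mol).
#' @export
reference_meci <- function(model, space, n_starts = 40) {
  d <- model$dim
  cc <- model$coupling_coord
  free <- setdiff(seq_len(d), cc)
  embed <- function(th) {
    x <- numeric(d)
    x[free] <- th
    x[cc] <- model$coupling_origin
    x
  }
  starts <- rbind(sample_uniform(space, n_starts, rng_seed = 20260102),
                  pmin(pmax(model$a, space$lower), space$upper),
                  pmin(pmax(model$b, space$lower), space$upper))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th <- starts[i, free]
    for (P in c(1, 10, 1e2, 1e3, 1e4, 1e5, 1e6)) {
      obj <- function(t_) {
        dv <- diabats(model, embed(t_))
        dv$v1 + P * (dv$v1 - dv$v2)^2
      }
      th <- stats::nlminb(th, obj, lower = space$lower[free],
                          upper = space$upper[free])$par
    }
    x <- embed(th)
    dv <- diabats(model, x)
    if (abs(dv$v1 - dv$v2) > 1e-3) next  # start never reached the seam
    if (is.null(best) || dv$v1 < best$energy)
      best <- list(values = unname(x), energy = unname(dv$v1))
  }
  if (is.null(best))
    stop("no degeneracy seam found within the search-space bounds")
  best
}

#' Built-in benchmark surfaces
#'
#' `benchmark_2d()` is the default two-coordinate benchmark: a ground-state
#' well at the origin (E = 0), a steep diabatic crossing producing conical
#' intersection points at (0.9, 0) and (1.7, 0) with energies 12.15 and
#' 43.35 kcal/mol, and a shallow avoided-crossing local minimum near
#' (0.96, +-0.7) at about 4 kcal/mol. The MECI is the lower intersection,
#' well separated from the global minimum and within ~45 kcal/mol of it;
#' because the crossing is steep relative to the mean-energy slope, the
#' argmin of the penalty cost stays near the intersection for small alpha
#' and drifts toward the adjacent mean-energy minimum as alpha is relaxed.
#' `formaldehyde_like_6d()` is
#' a six-coordinate abstract analogue on a molecular Z-matrix space (three
#' distances, two angles, one dihedral; coupling on the dihedral, vanishing
#' at planarity) used to exercise scaling with dimensionality.
#'
#' @return A list with `model`, `space`, `oracle`, and reference optima
#'   accessors `gm` and (2D only) `meci`.
#' @export
benchmark_2d <- function() {
  model <- two_state_model(
    k1 = c(15, 20), a = c(0, 0),
    k2 = c(100, 20), b = c(1.105, 0),
    delta = 7.9475, coupling = 25, coupling_coord = 2)
  space <- search_space(c("x", "y"), c("abstract", "abstract"),
                        lower = c(-1, -1.5), upper = c(3, 1.5))
  list(model = model, space = space, oracle = two_state_oracle(model),
       gm = function() reference_gm(model, space),
       meci = function() analytic_meci(model))
}

#' @rdname benchmark_2d
#' @export
formaldehyde_like_6d <- function() {
  space <- formaldehyde_like_space()
  model <- two_state_model(
    k1 = c(150, 300, 300, 0.030, 0.030, 0.004),
    a  = c(1.21, 1.10, 1.10, 121.9, 121.9, 180),
    k2 = c(80, 260, 260, 0.025, 0.025, 0.003),
    b  = c(1.45, 1.08, 1.08, 115.0, 115.0, 180),
    delta = 40, coupling = 0.35, coupling_coord = 6,
    coupling_origin = 180)
  list(model = model, space = space, oracle = two_state_oracle(model),
       gm = function() reference_gm(model, space, n_grid = 400),
       meci = function() reference_meci(model, space))
}

# Formaldehyde-like Z-matrix space: C, O (r1), H (r2, a1), H (r3, a2, d1),
# with the search-space bounds used for formaldehyde-sized molecules.
formaldehyde_like_space <- function() {
  topo <- zmatrix_topology(
    element = c("C", "O", "H", "H"),
    r_ref = c(NA, 1, 1, 1), a_ref = c(NA, NA, 2, 2), d_ref = c(NA, NA, NA, 3),
    r_coord = c(NA, "r1", "r2", "r3"),
    a_coord = c(NA, NA, "a1", "a2"),
    d_coord = c(NA, NA, NA, "d1"))
  search_space(
    names = c("r1", "r2", "r3", "a1", "a2", "d1"),
    kinds = c("distance", "distance", "distance", "angle", "angle", "dihedral"),
    lower = c(0.5, 0.5, 0.5, 0, 0, -180),
    upper = c(2.0, 2.5, 2.5, 180, 180, 180),
    topology = topo)
}

#' Oracle registry
#'
#' Built-in surfaces addressable by name from run configurations.
#'
#' @param name registry key; `pes_registry()` with no argument lists the keys.
#' @return The registry entry (see [benchmark_2d()]) or the key names.
#' @export
pes_registry <- function(name = NULL) {
  entries <- list(benchmark_2d = benchmark_2d,
                  formaldehyde_like_6d = formaldehyde_like_6d)
  if (is.null(name)) return(names(entries))
  if (!name %in% names(entries))
    stop(sprintf("unknown oracle '%s'; available: %s", name,
                 paste(names(entries), collapse = ", ")))
  entries[[name]]()
}
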