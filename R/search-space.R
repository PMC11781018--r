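#' Define a search space over internal coordinates
#'
#' A search space is the feasible box over which geometries are sampled and
#' acquisition functions are maximized. Each coordinate is a bond distance
#' (Angstrom), a bond angle or dihedral (degrees), or an abstract coordinate
#' (for non-molecular model surfaces). Molecular spaces additionally carry a
#' Z-matrix topology mapping coordinates to atoms, so that geometries can be
#' converted to Cartesians and screened for atomic collisions.
#'
#' @param names character vector of coordinate labels (e.g. `r1`, `a1`, `d1`).
#' @param kinds per-coordinate tag, one of `"distance"`, `"angle"`,
#'   `"dihedral"` or `"abstract"`.
#' @param lower,upper numeric bounds per coordinate. Distances must be
#'   positive, angles within \[0, 180\] degrees, dihedrals within
#'   \[-180, 180\] degrees.
#' @param topology optional Z-matrix topology (see [zmatrix_topology()]).
#'   Required for Cartesian conversion and collision screening.
#' @return An object of class `bo_search_space`.
#' @examples
#' sp <- search_space(c("x", "y"), c("abstract", "abstract"),
#'                    lower = c(-1, -1.5), upper = c(3, 1.5))
#' sample_uniform(sp, 5, rng_seed = 1)
#' @export
search_space <- function(names, kinds, lower, upper, topology = NULL) {
  kinds <- match.arg(kinds, c("distance", "angle", "dihedral", "abstract"),
                     several.ok = TRUE)
  d <- length(names)
  stopifnot(length(kinds) == d, length(lower) == d, length(upper) == d)
  if (anyDuplicated(names)) stop("coordinate names must be unique")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite")
  if (any(lower >= upper)) stop("every lower bound must be < its upper bound")
  if (any(kinds == "distance" & lower <= 0))
    stop("distance bounds must be strictly positive")
  if (any(kinds == "angle" & (lower < 0 | upper > 180)))
    stop("angle bounds must lie within [0, 180] degrees")
  if (any(kinds == "dihedral" & (lower < -180 | upper > 180)))
    stop("dihedral bounds must lie within [-180, 180] degrees")
  sp <- structure(
    list(names = as.character(names), kinds = kinds,
         lower = as.numeric(lower), upper = as.numeric(upper),
         topology = topology),
    class = "bo_search_space")
  if (!is.null(topology)) validate_topology(topology, sp)
  sp
}

#' @export
print.bo_search_space <- function(x, ...) {
  cat(sprintf("Search space: %d coordinate(s)%s\n", length(x$names),
              if (is.null(x$topology)) " (abstract)" else
                sprintf(", %d atoms", nrow(x$topology))))
  print(data.frame(name = x$names, kind = x$kinds,
                   lower = x$lower, upper = x$upper))
  invisible(x)
}

#' Z-matrix topology
#'
#' One row per atom. Atom 1 is placed at the origin; atom 2 along +z at its
#' reference distance; atom 3 in the xz-plane; later atoms use a distance,
#' an angle and a dihedral. Internal degrees of freedom refer to search-space
#' coordinates by name. References may only point at previously defined atoms.
#'
#' @param element character vector of element symbols.
#' @param r_ref,a_ref,d_ref integer atom indices defining the distance, angle
#'   and dihedral references (`NA` where not applicable: atom 1 has none,
#'   atom 2 only `r_ref`, atom 3 `r_ref` and `a_ref`).
#' @param r_coord,a_coord,d_coord names of the search-space coordinates
#'   supplying each degree of freedom (`NA` where not applicable).
#' @return A `data.frame` usable as the `topology` of [search_space()].
#' @export
zmatrix_topology <- function(element, r_ref = NA, a_ref = NA, d_ref = NA,
                             r_coord = NA, a_coord = NA, d_coord = NA) {
  n <- length(element)
  data.frame(element = as.character(element),
             r_ref = rep_len(as.integer(r_ref), n),
             a_ref = rep_len(as.integer(a_ref), n),
             d_ref = rep_len(as.integer(d_ref), n),
             r_coord = rep_len(as.character(r_coord), n),
             a_coord = rep_len(as.character(a_coord), n),
             d_coord = rep_len(as.character(d_coord), n),
             stringsAsFactors = FALSE)
}

validate_topology <- function(topo, space) {
  n <- nrow(topo)
  if (n < 1) stop("topology needs at least one atom")
  for (i in seq_len(n)) {
    refs <- c(topo$r_ref[i], topo$a_ref[i], topo$d_ref[i])
    need <- min(i - 1L, 3L)
    used <- refs[seq_len(need)]
    if (any(is.na(used)) || any(used >= i) || any(used < 1))
      stop(sprintf("atom %d: references must point at previously defined atoms", i))
    if (length(unique(used)) != need)
      stop(sprintf("atom %d: duplicated reference atoms", i))
    coords <- c(topo$r_coord[i], topo$a_coord[i], topo$d_coord[i])[seq_len(need)]
    if (any(is.na(coords)) || !all(coords %in% space$names))
      stop(sprintf("atom %d: internal coordinates must name search-space coordinates", i))
  }
  expected_kind <- c(r = "distance", a = "angle", d = "dihedral")
  for (dof in c("r", "a", "d")) {
    used <- stats::na.omit(topo[[paste0(dof, "_coord")]])
    k <- space$kinds[match(used, space$names)]
    if (any(k != expected_kind[dof]))
      stop(sprintf("coordinate kind mismatch for %s entries", dof))
  }
  invisible(TRUE)
}

n_coords <- function(space) length(space$names)

is_molecular <- function(space) !is.null(space$topology)

#' Draw geometries uniformly within the search-space bounds
#'
#' Each coordinate is drawn independently and uniformly within its bounds.
#' Dihedral bounds are treated as a plain box with no periodic wrap.
#'
#' @param space a [search_space()].
#' @param n number of geometries.
#' @param rng_seed optional integer seed; when supplied the draw is
#'   deterministic and the caller's RNG state is untouched.
#' @return An `n` x `d` numeric matrix, columns named by coordinate.
#' @export
sample_uniform <- function(space, n, rng_seed = NULL) {
  stopifnot(n >= 1)
  draw <- function() {
    d <- n_coords(space)
    m <- matrix(stats::runif(n * d), nrow = n)
    m <- sweep(m, 2, space$upper - space$lower, `*`)
    m <- sweep(m, 2, space$lower, `+`)
    colnames(m) <- space$names
    m
  }
  if (is.null(rng_seed)) draw() else with_preserved_seed(rng_seed, draw())
}

# Evaluate expr under set.seed(seed) and restore the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
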