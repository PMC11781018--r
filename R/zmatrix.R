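#' Convert internal coordinates to Cartesian coordinates
#'
#' Builds Cartesian atomic positions from a Z-matrix. The placement
#' convention is: atom 1 at the origin, atom 2 on the +z axis, atom 3 in the
#' xz-plane with non-negative x. Dihedral signs follow the IUPAC right-hand
#' rule (looking along the B-A axis, positive rotation is clockwise from the
#' far reference).
#'
#' @param values named numeric vector (or single-row matrix) of internal
#'   coordinate values aligned with `space`.
#' @param space a molecular [search_space()] (with a Z-matrix topology).
#' @param strict if `TRUE` (default), a colinear reference frame (an angle of
#'   exactly 0 or 180 degrees upstream of a dihedral-bearing atom) is an
#'   error, because the dihedral is then undefined. With `strict = FALSE` an
#'   arbitrary perpendicular completes the frame: atom positions are still
#'   geometrically valid (the affected dihedral merely loses its origin),
#'   which is what collision screening needs at the angle bounds.
#' @return An N x 3 matrix of positions in Angstrom, row names = elements.
#' @export
to_cartesian <- function(values, space, strict = TRUE) {
  if (!is_molecular(space))
    stop("to_cartesian() requires a molecular search space with a topology")
  values <- as_coord_vector(values, space)
  if (any(!is.finite(values))) stop("geometry values must be finite")
  topo <- space$topology
  n <- nrow(topo)
  xyz <- matrix(0, n, 3)
  val <- function(name) unname(values[[name]])
  if (n >= 2) xyz[2, ] <- c(0, 0, val(topo$r_coord[2])) + xyz[topo$r_ref[2], ]
  if (n >= 3) {
    r  <- val(topo$r_coord[3])
    th <- val(topo$a_coord[3]) * pi / 180
    p1 <- xyz[topo$r_ref[3], ]
    p2 <- xyz[topo$a_ref[3], ]
    u <- unit3(p2 - p1)
    # in-plane perpendicular: +x direction (atoms 1-2 are on the z axis)
    xyz[3, ] <- p1 + r * (cos(th) * u + sin(th) * c(1, 0, 0))
  }
  if (n >= 4) for (i in 4:n) {
    r   <- val(topo$r_coord[i])
    th  <- val(topo$a_coord[i]) * pi / 180
    phi <- val(topo$d_coord[i]) * pi / 180
    A <- xyz[topo$r_ref[i], ]   # bonded reference
    B <- xyz[topo$a_ref[i], ]   # angle reference
    C <- xyz[topo$d_ref[i], ]   # dihedral reference
    bc <- A - B
    if (sqrt(sum(bc^2)) < 1e-12)
      stop("degenerate frame: coincident reference atoms")
    bc <- unit3(bc)
    nv <- cross3(B - C, bc)
    nn <- sqrt(sum(nv^2))
    if (nn < 1e-10) {
      if (strict)
        stop("degenerate frame: colinear reference atoms (angle of 0 or 180 degrees)")
      e <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      nv <- cross3(e, bc)
      nv <- nv / sqrt(sum(nv^2))
    } else {
      nv <- nv / nn
    }
    m <- cross3(nv, bc)
    d2 <- r * c(-cos(th), sin(th) * cos(phi), -sin(th) * sin(phi))
    xyz[i, ] <- A + d2[1] * bc + d2[2] * m + d2[3] * nv
  }
  rownames(xyz) <- topo$element
  xyz
}

as_coord_vector <- function(values, space) {
  if (is.matrix(values)) {
    stopifnot(nrow(values) == 1)
    values <- values[1, ]
  }
  if (is.null(names(values))) {
    stopifnot(length(values) == n_coords(space))
    names(values) <- space$names
  }
  values[space$names]
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate frame: zero-length reference vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Measure a distance, angle or dihedral from Cartesian coordinates
#'
#' Companions to [to_cartesian()]: recover internal coordinates from an
#' N x 3 coordinate matrix. Angles are returned in degrees; the dihedral sign
#' follows the IUPAC right-hand rule.
#'
#' @param xyz N x 3 coordinate matrix.
#' @param i,j,k,l atom indices.
#' @return Numeric scalar (Angstrom or degrees).
#' @export
measure_distance <- function(xyz, i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))

#' @rdname measure_distance
#' @export
measure_angle <- function(xyz, i, j, k) {
  u <- xyz[i, ] - xyz[j, ]
  v <- xyz[k, ] - xyz[j, ]
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' @rdname measure_distance
#' @export
measure_dihedral <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, ] - xyz[i, ]
  b2 <- xyz[k, ] - xyz[j, ]
  b3 <- xyz[l, ] - xyz[k, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Recover all Z-matrix internal coordinates from Cartesians
#'
#' @param xyz N x 3 coordinate matrix.
#' @param space a molecular [search_space()].
#' @return Named numeric vector aligned with the space's coordinates.
#' @export
measure_internal <- function(xyz, space) {
  topo <- space$topology
  out <- stats::setNames(rep(NA_real_, n_coords(space)), space$names)
  n <- nrow(topo)
  for (i in seq_len(n)) {
    if (i >= 2) out[topo$r_coord[i]] <- measure_distance(xyz, i, topo$r_ref[i])
    if (i >= 3) out[topo$a_coord[i]] <- measure_angle(xyz, i, topo$r_ref[i], topo$a_ref[i])
    if (i >= 4) out[topo$d_coord[i]] <-
        measure_dihedral(xyz, i, topo$r_ref[i], topo$a_ref[i], topo$d_ref[i])
  }
  out
}

#' Minimum interatomic distance of a geometry
#'
#' @inheritParams to_cartesian
#' @return Minimum over all unordered atom pairs of the Euclidean distance (Angstrom).
#' @export
min_pair_distance <- function(values, space, strict = TRUE) {
  xyz <- to_cartesian(values, space, strict = strict)
  if (nrow(xyz) < 2) stop("min_pair_distance() needs at least two atoms")
  min(stats::dist(xyz))
}

#' Atomic-collision screen
#'
#' A geometry collides when any interatomic distance is strictly smaller than
#' the threshold (0.5 Angstrom by default); a distance exactly equal to the
#' threshold is kept. Abstract (non-molecular) spaces never collide.
#'
#' @inheritParams to_cartesian
#' @param threshold collision distance in Angstrom.
#' @return Logical scalar.
#' @export
has_collision <- function(values, space, threshold = 0.5) {
  if (threshold < 0) stop("collision threshold must be non-negative")
  if (!is_molecular(space)) return(FALSE)
  min_pair_distance(values, space, strict = FALSE) < threshold
}

# Vectorized screen over rows of a geometry matrix.
collision_mask <- function(X, space, threshold = 0.5) {
  if (!is_molecular(space)) return(rep(FALSE, nrow(X)))
  vapply(seq_len(nrow(X)),
         function(i) has_collision(X[i, ], space, threshold), logical(1))
}

#' Read and write XYZ files
#'
#' Standard XYZ format: atom count, comment line, then `element x y z` rows
#' (coordinates in Angstrom).
#'
#' @param xyz N x 3 coordinate matrix with element row names.
#' @param file path.
#' @param comment comment-line text.
#' @return `read_xyz()` returns a list with `elements` and `xyz`.
#' @export
write_xyz <- function(xyz, file, comment = "") {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3)
  lines <- c(nrow(xyz), comment,
             sprintf("%-3s %16.10f %16.10f %16.10f",
                     rownames(xyz), xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  el <- vapply(rows, `[[`, character(1), 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  rownames(xyz) <- el
  list(elements = el, xyz = xyz)
}
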