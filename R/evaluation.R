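#' Mirror-aware Kabsch RMSD
#'
#' Root-mean-square deviation of atomic positions after optimal translation
#' and proper rotation (determinant-corrected SVD superposition). With
#' `allow_mirror = TRUE` the reference is additionally reflected (one
#' Cartesian axis negated) before superposition and the smaller RMSD is
#' returned -- the treatment used when a reference structure has two
#' mirror-image conformers. Atoms are matched by position in the arrays; no
#' permutation search is attempted.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices (Angstrom) with
#'   matching atom order; element row names, when present on both, must
#'   agree.
#' @param allow_mirror also evaluate against the reflected reference.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(coords_a, coords_b, allow_mirror = FALSE) {
  stopifnot(is.matrix(coords_a), is.matrix(coords_b),
            ncol(coords_a) == 3, ncol(coords_b) == 3)
  if (nrow(coords_a) != nrow(coords_b))
    stop("structures have different atom counts")
  ea <- rownames(coords_a); eb <- rownames(coords_b)
  if (!is.null(ea) && !is.null(eb) && !identical(ea, eb))
    stop("structures have mismatched element order")
  r <- kabsch_core(coords_a, coords_b)
  if (allow_mirror) {
    refl <- coords_b
    refl[, 1] <- -refl[, 1]
    r <- min(r, kabsch_core(coords_a, refl))
  }
  r
}

kabsch_core <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(B, A))
  sgn <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, sgn))
  R <- s$u %*% D %*% t(s$v)
  sqrt(mean(rowSums((A - B %*% R)^2)))
}

#' Evaluate a found geometry against a reference
#'
#' Quantifies the deviation of a search result from a reference structure by
#' the state-energy differences (found minus reference, kcal/mol), the energy
#' gap at the found geometry, and the mirror-aware Kabsch RMSD of the atomic
#' positions (Angstrom). For abstract (non-molecular) spaces the RMSD field
#' is the Euclidean distance in coordinate space.
#'
#' @param found,ref lists with `values` (internal coordinates) and `record`
#'   (an [energy_record()]).
#' @param space the shared [search_space()].
#' @param allow_mirror passed to [kabsch_rmsd()].
#' @param reference_id optional label for the reference.
#' @return A list of class `bo_evaluation` with `delta_e_s0`, `delta_e_s1`,
#'   `gap`, `rmsd` and `reference_id`.
#' @export
evaluate_against_reference <- function(found, ref, space,
                                       allow_mirror = FALSE,
                                       reference_id = "reference") {
  d_s0 <- found$record$e_s0 - ref$record$e_s0
  d_s1 <- if (!is.null(found$record$e_s1) && !is.null(ref$record$e_s1))
    found$record$e_s1 - ref$record$e_s1 else NA_real_
  gap <- if (!is.null(found$record$e_s1))
    found$record$e_s1 - found$record$e_s0 else NA_real_
  rmsd <- if (is_molecular(space)) {
    kabsch_rmsd(to_cartesian(found$values, space),
                to_cartesian(ref$values, space),
                allow_mirror = allow_mirror)
  } else {
    sqrt(sum((as.numeric(found$values) - as.numeric(ref$values))^2))
  }
  structure(list(delta_e_s0 = d_s0, delta_e_s1 = d_s1, gap = gap,
                 rmsd = rmsd, reference_id = reference_id),
            class = "bo_evaluation")
}

#' @export
print.bo_evaluation <- function(x, ...) {
  cat(sprintf("vs %s: dE(S0) = %.4f kcal/mol", x$reference_id, x$delta_e_s0))
  if (!is.na(x$delta_e_s1)) cat(sprintf(", dE(S1) = %.4f", x$delta_e_s1))
  if (!is.na(x$gap)) cat(sprintf(", gap = %.4f", x$gap))
  cat(sprintf(", RMSD = %.4f A\n", x$rmsd))
  invisible(x)
}
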