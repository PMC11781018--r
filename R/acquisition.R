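#' Conical-intersection penalty cost function
#'
#' Weighted sum of the average and squared gap of the two state energies,
#' \deqn{C = \frac{E(S_0)+E(S_1)}{2} + \frac{(E(S_1)-E(S_0))^2}{\alpha},}
#' whose minimum targets the most stable conical intersection: the squared-gap
#' term drives the two states to degeneracy while the average drives them
#' down. `alpha` (kcal/mol) weights the degeneracy constraint -- small values
#' over-weight degeneracy, large values let the penalty vanish. The Bayesian
#' optimization objective for the MECI search is `-C`.
#'
#' @param e_s0,e_s1 state energies in kcal/mol (vectorized).
#' @param alpha positive degeneracy weight, kcal/mol.
#' @return C in kcal/mol.
#' @export
cost_C <- function(e_s0, e_s1, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a positive scalar")
  (e_s0 + e_s1) / 2 + (e_s1 - e_s0)^2 / alpha
}

#' Probability of improvement
#'
#' The probability that the objective at a point exceeds the incumbent best
#' \eqn{f(x^*)}: \eqn{\mathrm{PI}(x) = \Phi\big((\mu(x) - f(x^*))/\sigma(x)\big)}
#' with the posterior mean and standard deviation of the surrogate. For a
#' degenerate posterior (`sigma = 0`) the improvement is certain when
#' `mu > incumbent` and impossible otherwise; ties give 0, so an exactly
#' interpolated incumbent point is not re-proposed.
#'
#' @param mu,sigma posterior mean and standard deviation (`sigma >= 0`),
#'   vectorized.
#' @param incumbent best objective value observed so far.
#' @return Probability in \[0, 1\].
#' @export
probability_of_improvement <- function(mu, sigma, incumbent) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  out <- ifelse(sigma > 0,
                stats::pnorm((mu - incumbent) / pmax(sigma, 1e-300)),
                as.numeric(mu > incumbent))
  pmin(pmax(out, 0), 1)
}

#' Upper confidence bound
#'
#' \eqn{\mathrm{UCB}(x;\beta) = \mu(x) + \beta\,\sigma(x)}; `beta` balances
#' exploitation (small) against exploration (large). A working value of 0.1
#' is the only one found to give stable geometry searches.
#'
#' @inheritParams probability_of_improvement
#' @param beta non-negative exploration weight.
#' @return Acquisition value in objective units.
#' @export
upper_confidence_bound <- function(mu, sigma, beta) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (beta < 0) stop("beta must be non-negative")
  mu + beta * sigma
}

#' Objective specification
#'
#' Defines the scalar objective the campaign maximizes: `-E(S0)` for the
#' ground-state global-minimum (GM) search, `-C` (see [cost_C()]) for the
#' most-stable-conical-intersection (MECI) search.
#'
#' @param target `"GM"` or `"MECI"`.
#' @param alpha degeneracy weight in kcal/mol (MECI only; ignored for GM).
#' @return An object of class `bo_objective`.
#' @export
objective_spec <- function(target = c("GM", "MECI"), alpha = 50) {
  target <- match.arg(target)
  if (target == "MECI" && (!is.numeric(alpha) || alpha <= 0))
    stop("alpha must be positive for the MECI objective")
  structure(list(target = target,
                 alpha = if (target == "MECI") as.numeric(alpha) else NA_real_),
            class = "bo_objective")
}

#' Acquisition specification
#'
#' @param kind `"PI"` (probability of improvement) or `"UCB"` (upper
#'   confidence bound).
#' @param beta exploration weight for UCB (0.1 by default; ignored for PI).
#' @return An object of class `bo_acquisition`.
#' @export
acquisition_spec <- function(kind = c("PI", "UCB"), beta = 0.1) {
  kind <- match.arg(kind)
  if (kind == "UCB" && beta < 0) stop("beta must be non-negative")
  structure(list(kind = kind, beta = as.numeric(beta)),
            class = "bo_acquisition")
}

#' Objective value of an energy record
#'
#' @param record an [energy_record()].
#' @param spec an [objective_spec()].
#' @return `-e_s0` for GM; `-C(e_s0, e_s1, alpha)` for MECI.
#' @export
objective_value <- function(record, spec) {
  if (spec$target == "GM") return(-record$e_s0)
  if (is.null(record$e_s1))
    stop("MECI objective requires both state energies in the record")
  -cost_C(record$e_s0, record$e_s1, spec$alpha)
}

# Acquisition value from posterior moments (vectorized).
af_value <- function(mu, sigma, incumbent, acq) {
  switch(acq$kind,
         PI = probability_of_improvement(mu, sigma, incumbent),
         UCB = upper_confidence_bound(mu, sigma, acq$beta))
}

# Acquisition value and gradient at one raw-coordinate point.
af_value_grad <- function(model, x, incumbent, acq) {
  p <- gp_predict_grad(model, x)
  if (acq$kind == "PI") {
    if (p$sigma <= 1e-12) {
      val <- as.numeric(p$mu > incumbent)
      return(list(value = val, grad = rep(0, length(x))))
    }
    z <- (p$mu - incumbent) / p$sigma
    dz <- p$dmu / p$sigma - z * p$dsigma / p$sigma
    list(value = stats::pnorm(z), grad = stats::dnorm(z) * dz)
  } else {
    list(value = p$mu + acq$beta * p$sigma,
         grad = p$dmu + acq$beta * p$dsigma)
  }
}
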