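# Shared fixtures built in code.

# Minimal molecular spaces
diatomic_space <- function(lower = 0.2, upper = 2.5) {
  topo <- zmatrix_topology(element = c("N", "N"),
                           r_ref = c(NA, 1), r_coord = c(NA, "r1"))
  search_space("r1", "distance", lower, upper, topology = topo)
}

triatomic_space <- function() {
  topo <- zmatrix_topology(
    element = c("O", "H", "H"),
    r_ref = c(NA, 1, 1), a_ref = c(NA, NA, 2),
    r_coord = c(NA, "r1", "r2"), a_coord = c(NA, NA, "a1"))
  search_space(c("r1", "r2", "a1"), c("distance", "distance", "angle"),
               lower = c(0.2, 0.2, 0), upper = c(2.5, 2.5, 180),
               topology = topo)
}

formaldehyde_space <- function() bogeom:::formaldehyde_like_space()

# Independent closed-form GP posterior: dense linear algebra with solve(),
# no Cholesky reuse, written from the textbook formulas. Standardization is
# applied the same way the package documents it.
oracle_gp_posterior <- function(X, y, Xq, log_l, log_sf2, log_sn2,
                                ard = FALSE) {
  X <- as.matrix(X); Xq <- as.matrix(Xq)
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, sd); x_sd[x_sd < 1e-12] <- 1
  y_mean <- mean(y); y_sd <- sd(y); if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  Qs <- sweep(sweep(Xq, 2, x_mean), 2, x_sd, "/")
  ys <- (y - y_mean) / y_sd
  l <- exp(log_l); if (length(l) == 1) l <- rep(l, ncol(X))
  sf2 <- exp(log_sf2); sn2 <- exp(log_sn2)
  kfun <- function(A, B) {
    K <- matrix(0, nrow(A), nrow(B))
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
      K[i, j] <- sf2 * exp(-0.5 * sum((A[i, ] - B[j, ])^2 / l^2))
    K
  }
  K <- kfun(Xs, Xs) + diag(sn2, nrow(Xs))
  Ks <- kfun(Qs, Xs)
  Kinv <- solve(K)
  mu_s <- Ks %*% Kinv %*% ys
  var_s <- pmax(sf2 - diag(Ks %*% Kinv %*% t(Ks)), 0)
  list(mu = y_mean + y_sd * drop(mu_s), sigma = y_sd * sqrt(var_s))
}

# GP with hyperparameters frozen at their documented initialization
gp_fixed <- function(X, y) gp_fit(X, y, epochs = 0)
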