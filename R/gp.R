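#' Fit a Gaussian-process regression surrogate
#'
#' Fits a GP with a radial-basis-function (squared-exponential) kernel to
#' internal-coordinate/objective pairs. Explanatory and objective variables
#' are standardized (zero mean, unit variance; constant columns fall back to
#' unit scale). Kernel hyperparameters -- length-scale, signal variance and
#' observation-noise variance -- are obtained by maximizing the log marginal
#' likelihood with the Adam optimizer for exactly `epochs` full-batch steps
#' at the given learning rate, from the fixed initialization
#' length-scale 1, signal variance 1, noise variance 1e-2 (standardized
#' units). The noise variance is floor-bounded at 1e-6 for conditioning. The
#' fit is deterministic given the data.
#'
#' @param X n x d matrix of raw internal-coordinate values.
#' @param y length-n vector of objective values (e.g. -E(S0), -C).
#' @param epochs number of Adam steps (100 by default).
#' @param learning_rate Adam learning rate (0.2 by default).
#' @param ard if `TRUE`, one length-scale per input dimension; the default is
#'   a single shared isotropic length-scale.
#' @return An object of class `bo_gp` with fitted hyperparameters, cached
#'   training decomposition and standardizers. `lml_initial` / `lml_final`
#'   record the log marginal likelihood before and after optimization.
#' @export
gp_fit <- function(X, y, epochs = 100, learning_rate = 0.2, ard = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); d <- ncol(X)
  if (n < 2) stop("gp_fit() needs at least two training points")
  stopifnot(length(y) == n, epochs >= 0)

  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  x_sd[!is.finite(x_sd) | x_sd < 1e-12] <- 1
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, `/`)
  ys <- (y - y_mean) / y_sd

  # squared distances (standardized units); per dimension only under ARD
  nl <- if (ard) d else 1L
  D2j <- if (ard)
    lapply(seq_len(d), function(j) outer(Xs[, j], Xs[, j], `-`)^2)
  else
    list(sqdist_cross(Xs, Xs))
  theta <- c(rep(0, nl), 0, log(1e-2))  # log l, log sf2, log sn2
  floor_sn2 <- log(1e-6)

  lml_grad <- function(theta) {
    l2 <- exp(2 * theta[seq_len(nl)])
    sf2 <- exp(theta[nl + 1L])
    sn2 <- exp(theta[nl + 2L])
    S <- 0
    for (j in seq_len(nl)) S <- S + D2j[[j]] / l2[j]
    R <- exp(-0.5 * S)
    K <- sf2 * R
    diag(K) <- diag(K) + sn2
    ch <- chol_jitter(K)
    U <- ch$U
    alpha <- backsolve(U, backsolve(U, ys, transpose = TRUE))
    lml <- -0.5 * sum(ys * alpha) - sum(log(diag(U))) - 0.5 * n * log(2 * pi)
    Kinv <- chol2inv(U)
    A <- tcrossprod(alpha) - Kinv
    sfR <- sf2 * R
    g <- numeric(nl + 2L)
    for (j in seq_len(nl)) {
      Dl <- if (ard) D2j[[j]] / l2[j] else S  # S = D2/l^2 when isotropic
      g[j] <- 0.5 * sum(A * (sfR * Dl))
    }
    g[nl + 1L] <- 0.5 * sum(A * sfR)
    g[nl + 2L] <- 0.5 * sn2 * sum(diag(A))
    list(lml = lml, grad = g, U = U, alpha = alpha, jitter = ch$jitter)
  }

  cur <- lml_grad(theta)
  lml_initial <- cur$lml
  m <- numeric(nl + 2L); v <- numeric(nl + 2L)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  if (epochs > 0) for (t in seq_len(epochs)) {
    g <- cur$grad
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    theta <- theta + learning_rate * mh / (sqrt(vh) + eps)
    theta[nl + 2L] <- max(theta[nl + 2L], floor_sn2)
    cur <- lml_grad(theta)
  }

  structure(list(
    Xs = Xs, x_mean = x_mean, x_sd = x_sd,
    y_mean = y_mean, y_sd = y_sd,
    ard = ard, nl = nl, d = d, n = n,
    log_l = theta[seq_len(nl)], log_sf2 = theta[nl + 1L],
    log_sn2 = theta[nl + 2L],
    U = cur$U, alpha = cur$alpha,
    lml_initial = lml_initial, lml_final = cur$lml),
    class = "bo_gp")
}

chol_jitter <- function(K, max_tries = 7) {
  jit <- 0
  base <- mean(diag(K)) * 1e-10
  for (t in seq_len(max_tries)) {
    U <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, jitter = jit))
    jit <- if (jit == 0) base else jit * 100
  }
  stop("kernel matrix is numerically singular even after jitter escalation")
}

#' @export
print.bo_gp <- function(x, ...) {
  cat(sprintf("GP surrogate: n = %d, d = %d, l = %s, sf2 = %.4g, sn2 = %.4g\n",
              x$n, x$d, paste(signif(exp(x$log_l), 4), collapse = "/"),
              exp(x$log_sf2), exp(x$log_sn2)))
  cat(sprintf("log marginal likelihood: %.4f -> %.4f\n",
              x$lml_initial, x$lml_final))
  invisible(x)
}

# |a - b|^2 between all row pairs, clamped at 0 against cancellation
sqdist_cross <- function(A, B) {
  S <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  S[S < 0] <- 0
  S
}

# cross-kernel between query rows (standardized) and training rows
gp_cross_kernel <- function(model, Qs) {
  l2 <- exp(2 * model$log_l)
  sf2 <- exp(model$log_sf2)
  S <- if (model$ard) {
    acc <- 0
    for (j in seq_len(model$d))
      acc <- acc + outer(Qs[, j], model$Xs[, j], `-`)^2 / l2[j]
    acc
  } else {
    sqdist_cross(Qs, model$Xs) / l2
  }
  sf2 * exp(-0.5 * S)
}

#' Posterior mean and standard deviation of a fitted GP
#'
#' Standard GP posterior of the latent objective, de-standardized to
#' objective units. The posterior variance is clamped at zero if numerically
#' negative.
#'
#' @param model a fitted [gp_fit()] surrogate.
#' @param X query point (vector) or m x d matrix.
#' @return A data.frame with columns `mu` and `sigma` (objective units).
#' @export
gp_predict <- function(model, X) {
  if (!is.matrix(X)) X <- matrix(X, ncol = model$d, byrow = TRUE)
  if (ncol(X) != model$d)
    stop("query dimensionality does not match the training data")
  Qs <- sweep(sweep(X, 2, model$x_mean), 2, model$x_sd, `/`)
  Ks <- gp_cross_kernel(model, Qs)
  mu_s <- drop(Ks %*% model$alpha)
  Vt <- backsolve(model$U, t(Ks), transpose = TRUE)
  var_s <- pmax(exp(model$log_sf2) - colSums(Vt^2), 0)
  data.frame(mu = model$y_mean + model$y_sd * mu_s,
             sigma = model$y_sd * sqrt(var_s))
}

# Posterior mean/sd and their gradients w.r.t. the raw coordinates at a
# single query point; used for gradient-based acquisition maximization.
gp_predict_grad <- function(model, x) {
  xs <- (x - model$x_mean) / model$x_sd
  ks <- drop(gp_cross_kernel(model, matrix(xs, nrow = 1)))
  l2 <- exp(2 * model$log_l)
  mu_s <- sum(ks * model$alpha)
  v <- backsolve(model$U, backsolve(model$U, ks, transpose = TRUE))
  var_s <- max(exp(model$log_sf2) - sum(ks * v), 0)
  sigma_s <- sqrt(var_s)
  # dk_i/dxs_j = k_i (Xs_ij - xs_j) / l_j^2
  Dif <- sweep(model$Xs, 2, xs)           # n x d
  Lj <- if (model$ard) l2 else rep(l2, model$d)
  kD <- ks * Dif                          # n x d
  dmu_s <- colSums(model$alpha * kD) / Lj
  dvar_s <- -2 * colSums(v * kD) / Lj
  dsig_s <- if (sigma_s > 1e-12) dvar_s / (2 * sigma_s) else rep(0, model$d)
  list(mu = model$y_mean + model$y_sd * mu_s,
       sigma = model$y_sd * sigma_s,
       dmu = model$y_sd * dmu_s / model$x_sd,
       dsigma = model$y_sd * dsig_s / model$x_sd)
}

#' Save or load a GP surrogate as a plain-text key-value file
#'
#' Serializes hyperparameters, standardizers and training data so a campaign
#' can be checkpointed; `gp_load()` refits the cached decomposition from the
#' stored state without re-optimizing.
#'
#' @param model a fitted [gp_fit()] surrogate.
#' @param file path to a text file.
#' @return `gp_load()` returns a `bo_gp` object.
#' @export
gp_save <- function(model, file) {
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(
    paste("ard", as.integer(model$ard)),
    paste("n", model$n), paste("d", model$d),
    paste("x_mean", num(model$x_mean)), paste("x_sd", num(model$x_sd)),
    paste("y_mean", num(model$y_mean)), paste("y_sd", num(model$y_sd)),
    paste("log_l", num(model$log_l)),
    paste("log_sf2", num(model$log_sf2)),
    paste("log_sn2", num(model$log_sn2)),
    paste("Xs", num(as.vector(model$Xs))),
    paste("ys_alpha_source", num(recover_ys(model))))
  writeLines(lines, file)
  invisible(file)
}

recover_ys <- function(model) {
  K <- gp_cross_kernel(model, model$Xs)
  diag(K) <- diag(K) + exp(model$log_sn2)
  drop(K %*% model$alpha)
}

#' @rdname gp_save
#' @export
gp_load <- function(file) {
  lines <- readLines(file)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, " ")[[1]]
    kv[[parts[1]]] <- as.numeric(parts[-1])
  }
  n <- kv$n; d <- kv$d
  model <- structure(list(
    Xs = matrix(kv$Xs, n, d), x_mean = kv$x_mean, x_sd = kv$x_sd,
    y_mean = kv$y_mean, y_sd = kv$y_sd,
    ard = as.logical(kv$ard), nl = length(kv$log_l), d = d, n = n,
    log_l = kv$log_l, log_sf2 = kv$log_sf2, log_sn2 = kv$log_sn2,
    lml_initial = NA_real_, lml_final = NA_real_), class = "bo_gp")
  K <- gp_cross_kernel(model, model$Xs)
  diag(K) <- diag(K) + exp(model$log_sn2)
  ch <- chol_jitter(K)
  model$U <- ch$U
  model$alpha <- backsolve(ch$U, backsolve(ch$U, kv$ys_alpha_source,
                                           transpose = TRUE))
  model
}
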