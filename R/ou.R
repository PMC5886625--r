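## Ornstein-Uhlenbeck surrogate data: linear stochastic dynamics
## dx = A x dt + dW with drift A = (G - I)/tau, exactly discretized, then
## optionally passed through a canonical hemodynamic response filter and
## corrupted with observation noise -- a minimal BOLD-like signal model.

#' Ornstein-Uhlenbeck network model
#'
#' Couples a connectivity matrix `G` into the drift \eqn{A = (G - I)/\tau}
#' of the linear stochastic differential equation
#' \eqn{dx = A x\, dt + dW} with unit-intensity Wiener process.  Stability
#' requires all eigenvalues of \eqn{A} in the left half plane, i.e. the
#' spectrum of `G` left of 1.
#'
#' @param G coupling matrix (zero diagonal; row = target).
#' @param tau single-node relaxation time constant in seconds.
#' @param dt sampling interval in seconds.
#' @param T total duration in seconds; the simulated series has
#'   `round(T / dt)` samples.
#' @return an object of class `ou_model`.
#' @export
#' @examples
#' m <- ou_model(sample_er_network(20, 0.1, 0.5, seed = 1), tau = 0.1,
#'               dt = 0.1, T = 100)
ou_model <- function(G, tau = 0.1, dt = 0.1, T = 350000) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G), tau > 0, dt > 0, T >= dt)
  A <- (G - diag(nrow(G))) / tau
  if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0)
    stop("drift is not stable: some eigenvalue of G has real part >= 1")
  structure(list(G = G, tau = tau, dt = dt, T = T, A = A,
                 n_nodes = nrow(G), n_steps = as.integer(round(T / dt))),
            class = "ou_model")
}

#' @export
print.ou_model <- function(x, ...) {
  cat(sprintf(
    "Ornstein-Uhlenbeck network model: %d nodes, tau = %g s, dt = %g s, T = %g s (%d samples)\n",
    x$n_nodes, x$tau, x$dt, x$T, x$n_steps))
  invisible(x)
}

## Continuous Lyapunov equation A S + S A' = -Q, written here because no
## installed package provides a solver.  The solution S = int_0^inf
## e^{As} Q e^{A's} ds is accumulated as sum_k E^k W E'^k with
## E = e^{Ah} and W = int_0^h e^{As} Q e^{A's} ds (one Van Loan block
## exponential), summed by doubling.  Unlike diagonalization this also
## handles defective drifts, which sparse networks produce routinely
## (near-nilpotent coupling gives repeated eigenvalues).
expm_mat <- function(M) as.matrix(Matrix::expm(M))

lyap_solve <- function(A, Q = diag(nrow(A))) {
  n <- nrow(A)
  if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0)
    stop("unstable drift: no stationary solution")
  h <- 1 / max(1, norm(A, "2"))
  B <- rbind(cbind(-A, Q), cbind(matrix(0, n, n), t(A))) * h
  Fb <- expm_mat(B)
  F3 <- Fb[(n + 1):(2 * n), (n + 1):(2 * n)]   # e^{A' h}
  W <- t(F3) %*% Fb[1:n, (n + 1):(2 * n)]       # int_0^h e^{As} Q e^{A's} ds
  X <- (W + t(W)) / 2
  M <- t(F3)                                    # e^{A h}
  for (i in 1:100) {
    X <- X + M %*% X %*% t(M)
    M <- M %*% M
    if (norm(M, "F") < 1e-9) break
  }
  X <- (X + t(X)) / 2
  resid <- max(abs(A %*% X + X %*% t(A) + Q))
  if (resid > 1e-8 * max(abs(Q)))
    stop("Lyapunov solve failed (residual ", format(resid), ")")
  X
}

#' Stationary covariance of the OU process
#'
#' Solves the continuous Lyapunov equation
#' \eqn{A \Sigma + \Sigma A^\top = -I} (unit-intensity driving noise) for
#' the stationary covariance of the network activity.
#'
#' @param model an [ou_model()], or a stable drift matrix `A`.
#' @return the symmetric positive definite stationary covariance.
#' @export
stationary_covariance <- function(model) {
  A <- if (inherits(model, "ou_model")) model$A else model
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  lyap_solve(A)
}

#' Multivariate time-series container
#'
#' Light container for node-by-time activity used across the package:
#' a numeric matrix (rows = nodes, columns = samples) plus the sampling
#' interval and processing annotations.
#'
#' @param values nodes x time-points numeric matrix.
#' @param dt sampling interval in seconds.
#' @param hrf_applied has the hemodynamic filter been applied?
#' @param sigma_obs standard deviation of observation noise added so far.
#' @param snr recorded signal-to-noise ratio (variance ratio), if any.
#' @param standardized have rows been scaled to mean 0, variance 1?
#' @return an object of class `zlconn_ts`.
#' @export
zlconn_ts <- function(values, dt, hrf_applied = FALSE, sigma_obs = 0,
                      snr = NULL, standardized = FALSE) {
  stopifnot(is.matrix(values), dt > 0)
  structure(list(values = values, dt = dt, hrf_applied = hrf_applied,
                 sigma_obs = sigma_obs, snr = snr,
                 standardized = standardized),
            class = "zlconn_ts")
}

#' @export
print.zlconn_ts <- function(x, ...) {
  cat(sprintf("time series: %d nodes x %d samples, dt = %g s%s%s%s\n",
              nrow(x$values), ncol(x$values), x$dt,
              if (x$hrf_applied) ", HRF-filtered" else "",
              if (x$sigma_obs > 0)
                sprintf(", obs. noise sd %g", x$sigma_obs) else "",
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Simulate the OU process by exact discretization
#'
#' Iterates \eqn{x(t + \Delta t) = e^{A \Delta t} x(t) + n(t)}.  With
#' `noise = "exact"` (default) the innovation covariance is
#' \eqn{\Sigma_\Delta = \Sigma - e^{A\Delta t} \Sigma e^{A^\top \Delta t}},
#' which makes every marginal of the discrete chain identical to the
#' continuous process; `noise = "stationary"` instead draws
#' \eqn{n(t) \sim N(0, \Sigma)} with the stationary covariance itself
#' (kept for comparison; it inflates the marginal variance).  The initial
#' state is drawn from the stationary law, so no burn-in is needed.
#'
#' @param model an [ou_model()].
#' @param seed integer seed; the run is bit-reproducible given the seed.
#' @param noise innovation covariance convention, see above.
#' @return a [zlconn_ts()] with `round(T/dt)` samples.
#' @export
simulate_ou <- function(model, seed = NULL,
                        noise = c("exact", "stationary")) {
  stopifnot(inherits(model, "ou_model"))
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  n <- model$n_nodes
  E <- expm_mat(model$A * model$dt)
  Sig <- stationary_covariance(model)
  Sd <- if (noise == "exact") Sig - E %*% Sig %*% t(E) else Sig
  Sd <- (Sd + t(Sd)) / 2
  L <- tryCatch(t(chol(Sd)), error = function(e)
    stop("innovation covariance is not positive definite; ",
         "reduce dt relative to tau"))
  Ls <- t(chol((Sig + t(Sig)) / 2))
  x0 <- as.vector(Ls %*% stats::rnorm(n))
  X <- ou_simulate_cpp(E, L, x0, model$n_steps)
  zlconn_ts(X, model$dt)
}

#' @importFrom stats simulate
#' @export
simulate.ou_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, simulate_ou(object), simplify = FALSE)
  if (nsim == 1) out[[1]] else out
}

#' Canonical hemodynamic response kernel
#'
#' Double-gamma impulse response sampled at `dt` on \eqn{[0, 32]} s: a
#' gamma density with shape 6 and unit scale (response, mode at 5 s) minus
#' one sixth of a gamma density with shape 16 (undershoot), normalized to
#' unit peak.
#'
#' @param dt sampling interval in seconds.
#' @param duration kernel support in seconds.
#' @return numeric vector of kernel weights.
#' @export
hrf_kernel <- function(dt, duration = 32) {
  stopifnot(dt > 0)
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

#' Filter a time series with the hemodynamic response
#'
#' Causal convolution of each node's activity with [hrf_kernel()] (or a
#' supplied kernel), truncated to the input length — the linear BOLD
#' forward model applied to the simulated neural activity.
#'
#' @param ts a [zlconn_ts()].
#' @param kernel optional replacement kernel.
#' @return the filtered series with `hrf_applied` set.
#' @export
apply_hrf <- function(ts, kernel = NULL) {
  stopifnot(inherits(ts, "zlconn_ts"))
  if (ts$hrf_applied) stop("HRF already applied to this series")
  if (is.null(kernel)) kernel <- hrf_kernel(ts$dt)
  out <- ts
  out$values <- fir_filter_cpp(ts$values, as.numeric(kernel))
  out$hrf_applied <- TRUE
  out
}

#' Add Gaussian observation noise
#'
#' Adds i.i.d. \eqn{N(0, \sigma_{obs}^2)} measurement noise to every
#' sample and records the signal-to-noise ratio
#' \eqn{SNR = \sigma_X^2 / \sigma_{obs}^2} with the signal variance
#' averaged over nodes.
#'
#' @param ts a [zlconn_ts()].
#' @param sigma_obs noise standard deviation (0 is a no-op).
#' @param seed optional integer seed.
#' @return the noisy series with `sigma_obs` and `snr` recorded.
#' @export
add_observation_noise <- function(ts, sigma_obs, seed = NULL) {
  stopifnot(inherits(ts, "zlconn_ts"), sigma_obs >= 0)
  if (sigma_obs == 0) { ts$snr <- Inf; return(ts) }
  if (!is.null(seed)) set.seed(seed)
  v <- ts$values
  sig_x <- mean(rowMeans(v^2) - rowMeans(v)^2)
  ts$values <- v + matrix(stats::rnorm(length(v), sd = sigma_obs),
                          nrow(v), ncol(v))
  ts$sigma_obs <- sqrt(ts$sigma_obs^2 + sigma_obs^2)
  ts$snr <- sig_x / sigma_obs^2
  ts
}

#' Zero-lag correlation of a long surrogate run, computed by streaming
#'
#' Runs the full surrogate pipeline — exact OU simulation, optional HRF
#' filtering, optional observation noise, standardization, zero-lag sample
#' covariance — while accumulating only running first and second moments,
#' so recordings of millions of samples need no large allocations.  With
#' `sigma_obs = 0` the result is bit-identical to composing
#' [simulate_ou()], [apply_hrf()], [standardize_ts()] and
#' [sample_covariance()] under the same seed (with noise the draw
#' interleaving differs, but the distribution is the same).
#'
#' @param model an [ou_model()].
#' @param hrf apply the canonical hemodynamic filter?
#' @param sigma_obs observation-noise standard deviation.
#' @param seed optional integer seed.
#' @param noise innovation convention, see [simulate_ou()].
#' @param block internal accumulation block size.
#' @return a list with `C` (the correlation matrix the estimator consumes),
#'   `C_raw` (covariance before standardization), `snr` (recorded
#'   signal-to-noise ratio, `Inf` without noise) and `n_samples`.
#' @export
surrogate_covariance <- function(model, hrf = TRUE, sigma_obs = 0,
                                 seed = NULL,
                                 noise = c("exact", "stationary"),
                                 block = 1024) {
  stopifnot(inherits(model, "ou_model"), sigma_obs >= 0)
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  n <- model$n_nodes
  E <- expm_mat(model$A * model$dt)
  Sig <- stationary_covariance(model)
  Sd <- if (noise == "exact") Sig - E %*% Sig %*% t(E) else Sig
  L <- t(chol((Sd + t(Sd)) / 2))
  Ls <- t(chol((Sig + t(Sig)) / 2))
  x0 <- as.vector(Ls %*% stats::rnorm(n))
  k <- if (hrf) hrf_kernel(model$dt) else 1
  mom <- ou_moments_cpp(E, L, x0, model$n_steps, as.numeric(k), hrf,
                        sigma_obs, as.integer(block))
  M <- mom$n_steps
  m <- mom$sum / M
  C <- mom$S / M - tcrossprod(m)
  C <- (C + t(C)) / 2
  cm <- mom$clean_sum / M
  sig_var <- mom$clean_sq / M - cm^2
  list(C = stats::cov2cor(C), C_raw = C,
       snr = if (sigma_obs > 0) mean(sig_var) / sigma_obs^2 else Inf,
       n_samples = M)
}

#' Restrict a recording to a random subset of nodes
#'
#' Models partial observability (e.g. fNIRS covering part of the brain):
#' keeps a uniformly random fraction of the nodes.  The returned index map
#' selects the matching submatrix of a ground-truth connectivity for
#' evaluation.
#'
#' @param ts a [zlconn_ts()].
#' @param fraction fraction of nodes retained, in (0, 1].
#' @param seed optional integer seed.
#' @return list with elements `ts` (reduced series) and `nodes` (sorted
#'   indices of the retained nodes).
#' @export
observe_subset <- function(ts, fraction, seed = NULL) {
  stopifnot(inherits(ts, "zlconn_ts"), fraction > 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ts$values)
  k <- max(1L, round(fraction * n))
  idx <- sort(sample.int(n, k))
  out <- ts
  out$values <- ts$values[idx, , drop = FALSE]
  list(ts = out, nodes = idx)
}
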