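## Geodesic L1 descent on the orthogonal/unitary group.
##
## The estimation core: given a factor B with B'B = C^-1, every U B with
## unitary U is an equally valid factor.  Sparsity of the true connectivity
## singles out the rotation with minimal off-diagonal L1 norm, found by
## gradient descent along geodesics U -> exp(-t a) U with skew-Hermitian a.

ct <- function(x) Conj(t(x))

#' Optimizer control parameters
#'
#' Tolerances and step-size constants for [unitary_minimize()].  The descent
#' stops when the Riemannian gradient norm falls below `gtol`, or when the
#' iterate and cost both stall (`xtol` on \eqn{\|U - U_{old}\|_F / N},
#' `ftol` on the relative cost change), or at `max_iter`.
#'
#' @param xtol tolerance on the per-node Frobenius change of the rotation.
#' @param ftol tolerance on the relative change of the cost.
#' @param gtol tolerance on the gradient norm \eqn{\|d - U d^* U\|_F}.
#' @param kappa step-size divisor: each step moves \eqn{1/\kappa} of the
#'   geodesic period \eqn{2\pi/|\lambda_{max}|} of the descent direction.
#' @param max_iter iteration cap.
#' @param reorth_every re-orthonormalize the rotation (polar projection)
#'   every this many accepted steps, against numerical drift.
#' @param max_halvings step halvings allowed before declaring a stall.
#' @param line_search apply a one-dimensional search along the last descent
#'   direction whenever the stall criterion fires, and restart the descent
#'   from the polished point while that still lowers the cost.
#' @param restart_tol relative cost improvement below which a whole
#'   descent + line-search cycle counts as converged and no restart is
#'   attempted.
#' @param max_cycles cap on descent + line-search cycles per continuation
#'   phase.
#' @param smooth_eps0,smooth_shrink,smooth_eps_min smoothing continuation
#'   schedule: the absolute-value kinks are smoothed at scale
#'   `eps = smooth_eps0 * max(|B0|)`, shrunk by `smooth_shrink` per phase
#'   until `smooth_eps_min * max(|B0|)`, then the exact cost is
#'   minimized.  `smooth_eps0 = 0` disables the continuation.
#' @param smooth_kappa step-size divisor used during smoothed phases
#'   (their landscape is differentiable, so larger steps are safe).
#' @param include_diag if `TRUE` (default) the engine minimizes the full
#'   L1 norm of the rotated factor; `FALSE` restricts the objective to
#'   off-diagonal entries.
#' @return a list of class `zlconn_control`.
#' @export
unitary_control <- function(xtol = 0.7e-2, ftol = 0.7e-4, gtol = 0.7e-2,
                            kappa = 500, max_iter = 10000,
                            reorth_every = 100, max_halvings = 20,
                            line_search = TRUE, restart_tol = 1e-7,
                            max_cycles = 60,
                            smooth_eps0 = 0.3, smooth_shrink = 0.25,
                            smooth_eps_min = 1e-6, smooth_kappa = 50,
                            include_diag = TRUE) {
  stopifnot(xtol > 0, ftol > 0, gtol > 0, kappa > 0, max_iter >= 1,
            reorth_every >= 1, restart_tol >= 0, smooth_eps0 >= 0)
  structure(list(xtol = xtol, ftol = ftol, gtol = gtol, kappa = kappa,
                 max_iter = as.integer(max_iter),
                 reorth_every = as.integer(reorth_every),
                 max_halvings = as.integer(max_halvings),
                 line_search = isTRUE(line_search),
                 max_cycles = as.integer(max_cycles),
                 restart_tol = restart_tol, smooth_eps0 = smooth_eps0,
                 smooth_shrink = smooth_shrink,
                 smooth_eps_min = smooth_eps_min,
                 smooth_kappa = smooth_kappa,
                 include_diag = isTRUE(include_diag)),
            class = "zlconn_control")
}

#' Off-diagonal L1 cost of a rotated factor
#'
#' \eqn{\Gamma(U) = \sum_{i \ne j} |(UB)_{ij}|}.  The diagonal is excluded
#' throughout the package: self-connections are not modelled, so the
#' diagonal of the factor carries no information about connectivity.
#'
#' @param U unitary (orthogonal) matrix.
#' @param B factor matrix.
#' @return the nonnegative cost.
#' @export
l1_cost <- function(U, B) {
  if (ncol(U) != nrow(B)) stop("dimension mismatch between U and B")
  M <- abs(U %*% B)
  sum(M) - sum(diag(M))
}

## eps-smoothed cost (continuation device); include_diag selects the full
## L1 norm of the rotated factor rather than its off-diagonal part
l1_cost_eps <- function(U, B, eps, include_diag = FALSE) {
  M <- if (eps <= 0) abs(U %*% B) else sqrt(Mod(U %*% B)^2 + eps^2) - eps
  if (include_diag) sum(M) else sum(M) - sum(diag(M))
}

#' Subgradient of the L1 cost with respect to the rotation
#'
#' With \eqn{S} the entrywise phase (sign, in the real case) of \eqn{UB},
#' zeroed on the diagonal and at exact zeros (minimal-norm subgradient),
#' the gradient is \eqn{d = S B^*}.  Validated against finite differences
#' in the test suite.
#'
#' @inheritParams l1_cost
#' @return the gradient matrix, same shape as `U`.
#' @export
l1_gradient <- function(U, B) {
  if (ncol(U) != nrow(B)) stop("dimension mismatch between U and B")
  UB <- U %*% B
  m <- Mod(UB)
  S <- ifelse(m > 0, UB / pmax(m, .Machine$double.xmin), 0)
  if (is.complex(UB)) S[m == 0] <- 0 + 0i
  diag(S) <- 0
  S %*% ct(B)
}

#' Skew-Hermitian descent direction
#'
#' Translates the raw gradient `d` at the point `U` into the tangent
#' direction \eqn{a = (d U^* - U d^*)/2}, which is skew-Hermitian so that
#' \eqn{\exp(-t a)} is unitary and \eqn{U \mapsto \exp(-t a) U} stays on the
#' group.  The Frobenius norm of the Riemannian gradient
#' \eqn{\|d - U d^* U\|_F} equals \eqn{2 \|a\|_F}.
#'
#' @param d gradient matrix from [l1_gradient()].
#' @param U current rotation.
#' @return a skew-Hermitian matrix.
#' @export
descent_direction <- function(d, U) {
  (d %*% ct(U) - U %*% ct(d)) / 2
}

## Spectral decomposition of a skew-Hermitian direction: H = i a is
## Hermitian, a = V diag(-i lambda) V^*, so exp(-t a) = V diag(e^{i t l}) V^*.
## One Hermitian eigendecomposition yields |lambda_max|, the geodesic period
## and cheap evaluation of exp(-t a) for every trial step t.
skew_eigen <- function(a) {
  H <- 1i * a
  e <- eigen(H, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors,
       lambda_max = max(abs(e$values)))
}

## evaluates the geodesic point exp(-t a) U from the decomposition of a
skew_expm_apply <- function(se, t, U, real = TRUE) {
  E <- se$vectors %*% (exp(1i * t * se$values) * ct(se$vectors))
  out <- E %*% U
  if (real) Re(out) else out
}

#' Adaptive geodesic step size
#'
#' The cost along a geodesic \eqn{t \mapsto \Gamma(\exp(-t a) U)} is close
#' to periodic with period \eqn{2\pi / |\lambda_{max}(a)|}; the step is a
#' fixed fraction \eqn{1/\kappa} of that period:
#' \eqn{\delta = 2\pi / (|\lambda_{max}| \kappa)}.
#'
#' @param a skew-Hermitian descent direction (nonzero).
#' @param kappa period fraction divisor.
#' @return the positive step size.
#' @export
step_size <- function(a, kappa = 500) {
  lam <- max(abs(skew_eigen(a)$values))
  if (lam == 0) stop("zero descent direction: already converged, no step")
  2 * pi / (lam * kappa)
}

#' One-dimensional search along a geodesic
#'
#' Minimizes \eqn{\Gamma(\exp(-t a) U)} over one geodesic period
#' \eqn{t \in [0, 2\pi/|\lambda_{max}|]} by a 50-point coarse grid followed
#' by local refinement ([stats::optimize()], relative tolerance 1e-6)
#' around the best grid point.  Applied once after the gradient descent
#' stops, because near convergence the cost oscillates along the descent
#' direction and the iterate may sit at a random phase of that oscillation.
#' The returned rotation never has higher cost than the input.
#'
#' @param U current rotation.
#' @param a skew-Hermitian direction (nonzero).
#' @param B factor being rotated.
#' @param grid_points number of coarse grid points.
#' @param eps smoothing scale of the cost evaluated along the geodesic
#'   (0 = exact L1 cost).
#' @param include_diag include the diagonal in the cost.
#' @return the rotation with minimal cost found on the geodesic.
#' @export
line_search <- function(U, a, B, grid_points = 50, eps = 0,
                        include_diag = FALSE) {
  se <- skew_eigen(a)
  if (se$lambda_max == 0) return(U)
  realU <- !is.complex(U) && !is.complex(a) && !is.complex(B)
  period <- 2 * pi / se$lambda_max
  ## cost along the geodesic: (exp(-t a) U) B = V diag(e^{i t l}) W with
  ## W = V^* U B precomputed, so each trial point costs one matrix product
  W <- ct(se$vectors) %*% (U %*% B)
  f <- function(t) {
    M <- abs(se$vectors %*% (exp(1i * t * se$values) * W))
    if (eps > 0) M <- sqrt(M^2 + eps^2) - eps
    if (include_diag) sum(M) else sum(M) - sum(diag(M))
  }
  ts <- seq(0, period, length.out = grid_points)
  fs <- vapply(ts, f, numeric(1))
  i <- which.min(fs)
  lo <- ts[max(1, i - 1)]; hi <- ts[min(length(ts), i + 1)]
  opt <- stats::optimize(f, lower = lo, upper = hi, tol = period * 1e-6)
  if (opt$objective < fs[i]) {
    t_best <- opt$minimum; f_best <- opt$objective
  } else {
    t_best <- ts[i]; f_best <- fs[i]
  }
  if (f_best >= fs[1]) return(U)
  skew_expm_apply(se, t_best, U, realU)
}

polar_orthonormalize <- function(U) {
  s <- svd(U)
  s$u %*% ct(s$v)
}

#' Minimize the off-diagonal L1 norm over the unitary group
#'
#' Geodesic gradient descent for \eqn{\Gamma(U) = \|UB\|_1} (off-diagonal)
#' starting at \eqn{U_0 = I}.  Each iteration computes the subgradient,
#' translates it to a skew-Hermitian tangent direction, and steps along the
#' geodesic \eqn{U \mapsto \exp(-\delta a) U} with
#' \eqn{\delta = 2\pi/(|\lambda_{max}| \kappa)}; a step that would increase
#' the cost is halved up to `max_halvings` times, so the cost sequence is
#' non-increasing.  Convergence when the gradient norm drops below `gtol`,
#' or when both the rotation and the cost stall (`xtol`, `ftol`); a final
#' [line_search()] along the last direction polishes the oscillation phase.
#'
#' Real input runs in the orthogonal group with real arithmetic (compiled
#' fast path); complex Hermitian-derived input runs in U(n) via the R
#' reference path.
#'
#' @param B0 initial factor (typically the symmetric square root of a
#'   precision matrix, see [initial_factor()]).
#' @param control a [unitary_control()] list.
#' @param engine `"auto"` (compiled for real input), `"cpp"`, or `"r"`
#'   (reference implementation).
#' @return a list with elements `U` (the rotation), `B_opt = U %*% B0`,
#'   `gamma` (final cost), `iterations`, `converged` (one of `"gtol"`,
#'   `"xftol"`, `"stall"`, `"maxiter"`), and `trace`, a data frame of
#'   per-iteration cost, gradient norm and step size.
#' @export
unitary_minimize <- function(B0, control = unitary_control(),
                             engine = c("auto", "cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(is.matrix(B0), nrow(B0) == ncol(B0))
  if (engine == "auto") engine <- if (is.complex(B0)) "r" else "cpp"
  if (engine == "cpp" && is.complex(B0))
    stop("compiled path supports real input only; use engine = 'r'")
  n <- nrow(B0)
  U <- diag(n); if (is.complex(B0)) U <- U + 0i
  ## continuation schedule: descend on progressively less smoothed costs,
  ## finishing with the exact L1 objective (eps = 0)
  schedule <- 0
  if (control$smooth_eps0 > 0) {
    b <- max(Mod(B0))
    eps <- control$smooth_eps0 * b
    sch <- numeric(0)
    while (eps > control$smooth_eps_min * b) {
      sch <- c(sch, eps)
      eps <- eps * control$smooth_shrink
    }
    schedule <- c(sch, 0)
  }
  total_iter <- 0L
  conv <- "maxiter"
  traces <- list()
  incd <- isTRUE(control$include_diag)
  for (eps in schedule) {
    gamma <- l1_cost_eps(U, B0, eps, incd)
    cycles <- 0L
    repeat {
      cycles <- cycles + 1L
      if (cycles > control$max_cycles) break
      budget <- control$max_iter - total_iter
      if (budget <= 0) { conv <- "maxiter"; break }
      kap <- if (eps > 0) control$smooth_kappa else control$kappa
      if (engine == "cpp") {
        res <- unitary_descent_cpp(B0, control$xtol, control$ftol,
                                   control$gtol, kap, budget,
                                   control$reorth_every,
                                   control$max_halvings, U, eps, incd)
        conv <- c("maxiter", "gtol", "xftol", "stall")[res$status + 1]
        tr <- data.frame(gamma = as.numeric(res$gamma_trace),
                         grad_norm = as.numeric(res$grad_trace),
                         delta = as.numeric(res$delta_trace))
        U <- res$U; a_last <- res$a_last
      } else {
        ctl <- control; ctl$kappa <- kap
        ref <- unitary_minimize_ref(B0, ctl, U0 = U, max_iter = budget,
                                    eps = eps, include_diag = incd)
        conv <- ref$converged; tr <- ref$trace[-1]; U <- ref$U
        a_last <- ref$a_last
      }
      tr$eps <- eps
      total_iter <- total_iter + nrow(tr)
      traces[[length(traces) + 1]] <- tr
      gamma_start <- gamma
      gamma <- l1_cost_eps(U, B0, eps, incd)
      if (conv == "gtol" || is.null(a_last)) break
      ## for large problems, smoothed phases are left unpolished (their
      ## stall points are genuine local optima of the differentiable
      ## surrogate, and the line searches dominate runtime); small
      ## problems keep the full polish, which costs nothing and protects
      ## against the narrower basins of low-dimensional landscapes
      if (eps > 0 && n > 40) break
      if (control$line_search) {
        ## final step of each descent cycle: a line search along the last
        ## direction, escaping the oscillation phase the stall criterion
        ## detects
        U_ls <- line_search(U, a_last, B0, eps = eps,
                            include_diag = incd)
        g_ls <- l1_cost_eps(U_ls, B0, eps, incd)
        if (g_ls <= gamma) { U <- U_ls; gamma <- g_ls }
      }
      if (conv == "maxiter") break
      ## resume descent while whole cycles (descent until the stall
      ## detector fires, then a line search) still lower the cost; the
      ## restart tolerance sits far below ftol so the final accuracy is
      ## set by the geometry, not by the plateau detector
      if ((gamma_start - gamma) <= control$restart_tol * (abs(gamma_start) + 1))
        break
    }
    if (conv == "maxiter") break
  }
  ## small problems: deterministic polish by cyclic exact line searches
  ## along the coordinate (Givens) tangent directions, escaping the kink
  ## points where full-gradient descent stalls; unaffordable and
  ## unnecessary at large n, where the landscape is smooth enough
  if (n <= 10 && control$line_search) {
    for (sweep in 1:100) {
      g0 <- l1_cost_eps(U, B0, 0, incd)
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        a <- matrix(0, n, n)
        a[i, j] <- 1; a[j, i] <- -1
        U <- line_search(U, a, B0, grid_points = 90, eps = 0,
                         include_diag = incd)
      }
      g1 <- l1_cost_eps(U, B0, 0, incd)
      if (g0 - g1 <= 1e-12 * (abs(g0) + 1)) break
    }
  }
  tr <- do.call(rbind, traces)
  tr$iteration <- seq_len(nrow(tr)) - 1L
  if (conv == "maxiter")
    warning("unitary descent reached max_iter without convergence; ",
            "returning best iterate")
  list(U = U, B_opt = U %*% B0, gamma = l1_cost(U, B0),
       iterations = nrow(tr), converged = conv, trace = tr)
}

## Reference implementation in plain R; handles real and complex input.
unitary_minimize_ref <- function(B0, control = unitary_control(),
                                 U0 = NULL, max_iter = control$max_iter,
                                 eps = 0, include_diag = FALSE) {
  n <- nrow(B0)
  cplx <- is.complex(B0)
  U <- if (is.null(U0)) diag(n) else U0
  if (cplx) U <- U + 0i
  gamma <- l1_cost_eps(U, B0, eps, include_diag)
  conv <- "maxiter"
  a_last <- NULL
  tr_g <- tr_n <- tr_d <- numeric(0)
  for (it in seq_len(max_iter)) {
    d <- if (eps > 0 || include_diag) {
      UB <- U %*% B0
      m <- Mod(UB)
      S <- if (eps > 0) UB / sqrt(m^2 + eps^2)
           else ifelse(m > 0, UB / pmax(m, .Machine$double.xmin), 0)
      if (!include_diag) diag(S) <- 0
      S %*% ct(B0)
    } else l1_gradient(U, B0)
    a <- descent_direction(d, U)
    gnorm <- 2 * sqrt(sum(Mod(a)^2))  # == ||d - U d^* U||_F
    tr_g <- c(tr_g, gamma); tr_n <- c(tr_n, gnorm)
    if (gnorm < control$gtol) { tr_d <- c(tr_d, 0); conv <- "gtol"; break }
    a_last <- a
    se <- skew_eigen(a)
    delta <- 2 * pi / (se$lambda_max * control$kappa)
    accepted <- FALSE
    for (h in 0:control$max_halvings) {
      U_new <- skew_expm_apply(se, delta, U, !cplx)
      g_new <- l1_cost_eps(U_new, B0, eps, include_diag)
      if (g_new <= gamma) { accepted <- TRUE; break }
      delta <- delta / 2
    }
    tr_d <- c(tr_d, delta)
    if (!accepted) { conv <- "stall"; break }
    stalled <- sqrt(sum(Mod(U_new - U)^2)) / n < control$xtol &&
      abs(gamma - g_new) / (abs(gamma) + 1) < control$ftol
    U <- U_new; gamma <- g_new
    if (it %% control$reorth_every == 0) U <- polar_orthonormalize(U)
    if (stalled) { conv <- "xftol"; break }
  }
  list(U = U, converged = conv, a_last = a_last,
       trace = data.frame(iteration = seq_along(tr_g) - 1L, gamma = tr_g,
                          grad_norm = tr_n,
                          delta = c(tr_d, rep(0, length(tr_g) - length(tr_d)))))
}

#' Resolve the signed-permutation ambiguity of an optimized factor
#'
#' Row sign flips and row permutations change neither the constraint
#' \eqn{B^* B = C^{-1}} nor the off-diagonal L1 cost, so the minimizer is
#' defined only up to a signed permutation.  This canonical form (1) solves
#' a linear assignment putting the dominant entry of each row on the
#' diagonal (maximizing \eqn{\sum_i |B_{\pi(i), i}|}), and (2) flips row
#' signs so every diagonal entry is nonnegative — appropriate because the
#' target factor is \eqn{I - G} with unit diagonal.
#'
#' @param B square factor matrix.
#' @return the canonicalized factor.
#' @export
canonicalize_factor <- function(B) {
  stopifnot(is.matrix(B), nrow(B) == ncol(B))
  n <- nrow(B)
  W <- Mod(B)
  dimnames(W) <- NULL
  K <- max(W) + 1
  ## complete bipartite rows x cols; constant offset K forces a perfect
  ## matching while preserving the argmax assignment
  g <- igraph::graph_from_biadjacency_matrix(W + K, weighted = TRUE)
  mm <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  col_of_row <- as.integer(mm$matching[seq_len(n)]) - n
  P <- matrix(0, n, n)
  P[cbind(col_of_row, seq_len(n))] <- 1     # row i moves to row position j
  Bc <- P %*% B
  dg <- diag(Bc)
  if (is.complex(B)) {
    ph <- ifelse(Mod(dg) > 0, Conj(dg) / Mod(dg), 1 + 0i)
    Bc <- Bc * ph   # length-n factor recycles down columns: scales row i
  } else {
    flip <- ifelse(dg < 0, -1, 1)
    Bc <- Bc * flip
  }
  Bc
}
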