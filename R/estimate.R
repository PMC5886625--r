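#' Standardize a multivariate time series
#'
#' Scales each node's series to mean 0 and variance 1 (population
#' convention, denominator = number of samples), the normalization applied
#' before covariance estimation.
#'
#' @param ts a [zlconn_ts()] or a nodes x time numeric matrix.
#' @return the standardized object, same type as the input.
#' @export
standardize_ts <- function(ts) {
  is_ts <- inherits(ts, "zlconn_ts")
  v <- if (is_ts) ts$values else ts
  stopifnot(is.matrix(v))
  m <- rowMeans(v)
  s2 <- rowMeans(v * v) - m * m
  bad <- which(s2 <= 0)
  if (length(bad))
    stop("node(s) with zero variance cannot be standardized: ",
         paste(bad, collapse = ", "))
  v <- (v - m) / sqrt(s2)
  if (is_ts) { ts$values <- v; ts$standardized <- TRUE; ts } else v
}

#' Zero-lag sample covariance
#'
#' \eqn{C = M^{-1} \sum_t x(t) x(t)^\top} over the \eqn{M} samples,
#' intended for standardized data (where it is the sample correlation).
#' Requires more samples than nodes so the estimate can be positive
#' definite.
#'
#' @param ts a [zlconn_ts()] or a nodes x time numeric matrix.
#' @return the symmetric N x N covariance matrix.
#' @export
sample_covariance <- function(ts) {
  v <- if (inherits(ts, "zlconn_ts")) ts$values else ts
  stopifnot(is.matrix(v))
  if (ncol(v) <= nrow(v))
    stop("need more time points than nodes for a full-rank covariance; ",
         "record a longer series")
  C <- tcrossprod(v) / ncol(v)
  (C + t(C)) / 2
}

#' Positive definite square root of the precision matrix
#'
#' The optimization over rotations needs a starting factor \eqn{B_0} with
#' \eqn{B_0^* B_0 = C^{-1}}; the unique positive definite square root
#' \eqn{B_0 = W E^{1/2} W^*} (eigenvectors \eqn{W}, eigenvalues \eqn{E} of
#' \eqn{C^{-1}}) is used.
#'
#' @param C positive definite covariance matrix (or precision matrix with
#'   `role = "precision"`).
#' @param role whether `C` is a covariance or already a precision matrix.
#' @param ridge optional nonnegative ridge: adds
#'   `ridge * mean(diag(C))` to the covariance diagonal before inversion
#'   (off by default; the estimator uses plain inversion).
#' @return the symmetric positive definite factor \eqn{B_0}.
#' @export
initial_factor <- function(C, role = c("covariance", "precision"),
                           ridge = 0) {
  role <- match.arg(role)
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (max(abs(C - ct(C))) > 1e-10 * max(1, max(abs(C))))
    stop("input matrix is not symmetric/Hermitian")
  if (ridge > 0 && role == "covariance")
    C <- C + diag(ridge * mean(Re(diag(C))), nrow(C))
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("matrix is not positive definite")
  if (max(e$values) / min(e$values) > 1e10)
    stop("matrix is numerically singular (condition number > 1e10); ",
         "consider a small ridge or longer recordings")
  half <- if (role == "covariance") 1 / sqrt(e$values) else sqrt(e$values)
  B0 <- e$vectors %*% (half * ct(e$vectors))
  if (!is.complex(B0)) B0 <- (B0 + t(B0)) / 2
  B0
}

#' Estimate directed effective connectivity from zero-lag covariance
#'
#' Fits the linear interaction model \eqn{x = Gx + v} with independent
#' unit-variance inputs, under which the precision matrix factorizes as
#' \eqn{C^{-1} = (I-G)^\top (I-G)}.  Any orthogonal rotation of a factor is
#' also a factor, so the method selects the rotation whose factor has
#' minimal off-diagonal L1 norm (the sparsest connectivity consistent with
#' the covariance), by geodesic gradient descent on the orthogonal group
#' ([unitary_minimize()]).  The optimized factor is reduced to a canonical
#' signed permutation representative ([canonicalize_factor()]) and the
#' connectivity read off as \eqn{\hat G = I - B} with the (unidentifiable)
#' diagonal set to zero.
#'
#' Time-series input is standardized and reduced to its zero-lag sample
#' covariance first; a covariance or precision matrix can also be supplied
#' directly.
#'
#' @param x a [zlconn_ts()], a nodes x time numeric matrix
#'   (`input = "timeseries"`), or a square symmetric covariance/precision
#'   matrix.
#' @param input input kind; `"auto"` treats square symmetric matrices as
#'   covariances and everything else as time series.
#' @param control optimizer settings, see [unitary_control()].
#' @param engine optimizer backend passed to [unitary_minimize()].
#' @param ridge optional ridge forwarded to [initial_factor()].
#' @return an object of class `effconn` with components `G` (estimated
#'   connectivity, zero diagonal), `B0`, `B_opt` (canonical factor), `U`,
#'   `C` (covariance used), `gamma`, `iterations`, `converged`, `trace`,
#'   `n_nodes` and `n_samples`.
#' @seealso [coef.effconn()], [threshold_network()], [performance_report()]
#' @export
#' @examples
#' G <- sample_er_network(30, 0.1, 0.7, seed = 2)
#' fit <- effconn(noise_free_precision(G), input = "precision")
#' roc_auc(coef(fit), G)
effconn <- function(x, input = c("auto", "timeseries", "covariance",
                                 "precision"),
                    control = unitary_control(), engine = "auto",
                    ridge = 0) {
  input <- match.arg(input)
  cl <- match.call()
  n_samples <- NA_integer_
  if (input == "auto") {
    input <- if (inherits(x, "zlconn_ts")) "timeseries"
    else if (is.matrix(x) && nrow(x) == ncol(x) &&
             max(abs(x - ct(x))) <= 1e-10 * max(1, max(abs(x))))
      "covariance"
    else "timeseries"
  }
  if (input == "timeseries") {
    v <- if (inherits(x, "zlconn_ts")) x$values else x
    n_samples <- ncol(v)
    C <- sample_covariance(standardize_ts(v))
  } else {
    stopifnot(is.matrix(x), nrow(x) == ncol(x))
    C <- x
  }
  B0 <- initial_factor(C, role = if (input == "precision") "precision"
                       else "covariance", ridge = ridge)
  opt <- unitary_minimize(B0, control = control, engine = engine)
  B_can <- canonicalize_factor(opt$B_opt)
  G <- diag(nrow(B_can)) - Re(B_can)
  diag(G) <- 0
  structure(list(G = G, B0 = B0, B_opt = B_can, U = opt$U,
                 C = if (input == "precision") NULL else C,
                 gamma = opt$gamma, iterations = opt$iterations,
                 converged = opt$converged, trace = opt$trace,
                 n_nodes = nrow(G), n_samples = n_samples, call = cl),
            class = "effconn")
}

#' @export
print.effconn <- function(x, ...) {
  cat("Directed effective connectivity estimate\n")
  cat(sprintf("  nodes: %d%s\n", x$n_nodes,
              if (is.na(x$n_samples)) ""
              else sprintf("   samples: %d", x$n_samples)))
  cat(sprintf("  off-diagonal L1 cost: %.4f after %d iterations (%s)\n",
              x$gamma, x$iterations, x$converged))
  invisible(x)
}

#' @export
summary.effconn <- function(object, keep_fraction = 0.1, ...) {
  Gt <- threshold_network(object$G, keep_fraction)
  k <- sum(Gt != 0)
  out <- list(n_nodes = object$n_nodes, n_samples = object$n_samples,
              gamma = object$gamma, iterations = object$iterations,
              converged = object$converged, keep_fraction = keep_fraction,
              n_edges = k, n_inhibitory = sum(Gt < 0),
              strength_range = range(abs(object$G[Gt != 0])))
  class(out) <- "summary.effconn"
  out
}

#' @export
print.summary.effconn <- function(x, ...) {
  cat("Directed effective connectivity estimate\n")
  cat(sprintf("  %d nodes, cost %.4f after %d iterations (%s)\n",
              x$n_nodes, x$gamma, x$iterations, x$converged))
  cat(sprintf("  strongest %d%% of entries: %d connections, %d inhibitory (%.0f%%)\n",
              round(100 * x$keep_fraction), x$n_edges, x$n_inhibitory,
              100 * x$n_inhibitory / max(1, x$n_edges)))
  cat(sprintf("  retained |weight| range: %.3g .. %.3g\n",
              x$strength_range[1], x$strength_range[2]))
  invisible(x)
}

#' @export
coef.effconn <- function(object, ...) object$G

#' Model-implied covariance of a fitted connectivity
#'
#' The covariance the linear model assigns to the estimated network,
#' \eqn{(I - \hat G)^{-1} (I - \hat G)^{-\top}}; comparing it with the
#' observed covariance (see [residuals.effconn()]) indicates how much
#' structure the sparse directed model absorbs.
#'
#' @param object a fitted `effconn` object.
#' @param ... unused.
#' @export
fitted.effconn <- function(object, ...) {
  ImG <- diag(object$n_nodes) - object$G
  Vi <- solve(ImG)
  Vi %*% t(Vi)
}

#' @export
residuals.effconn <- function(object, ...) {
  if (is.null(object$C))
    stop("no observed covariance stored (precision-matrix input)")
  object$C - fitted(object)
}

#' @export
plot.effconn <- function(x, keep_fraction = NULL, main = NULL, ...) {
  G <- x$G
  if (!is.null(keep_fraction)) G <- threshold_network(G, keep_fraction)
  lim <- max(abs(G)); if (lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  n <- nrow(G)
  graphics::image(seq_len(n), seq_len(n), t(G[n:1, ]),
                  zlim = c(-lim, lim), col = pal,
                  xlab = "source node", ylab = "target node",
                  main = main %||% "estimated connectivity", ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate surrogate activity from a fitted network
#'
#' Plugs the estimated connectivity into the OU surrogate model and
#' simulates; only meaningful when the estimated network is dynamically
#' stable (spectrum of \eqn{\hat G} left of 1).
#'
#' @param object a fitted `effconn` object.
#' @param nsim number of independent series.
#' @param seed optional seed.
#' @param tau,dt,T OU model parameters, see [ou_model()].
#' @param ... unused.
#' @export
simulate.effconn <- function(object, nsim = 1, seed = NULL, tau = 0.1,
                             dt = 0.1, T = 1000, ...) {
  m <- ou_model(object$G, tau = tau, dt = dt, T = T)
  simulate(m, nsim = nsim, seed = seed)
}

#' Keep only the strongest connections
#'
#' Retains the `keep_fraction` fraction of entries of largest magnitude
#' (signs preserved, counted over all \eqn{N^2} cells so a 90-node estimate
#' thresholded at 10% keeps exactly 810 connections) and zeroes the rest.
#' Ties at the cutoff are broken by first (column-major) index, making the
#' operation deterministic.
#'
#' @param G estimated connectivity matrix.
#' @param keep_fraction fraction of entries kept, in (0, 1].
#' @return the thresholded matrix.
#' @export
threshold_network <- function(G, keep_fraction = 0.1) {
  stopifnot(is.matrix(G), keep_fraction > 0, keep_fraction <= 1)
  k <- floor(keep_fraction * length(G))
  if (k >= length(G)) return(G)
  o <- order(-abs(as.vector(G)))  # radix sort: stable, first-index ties
  out <- matrix(0, nrow(G), ncol(G), dimnames = dimnames(G))
  keep <- o[seq_len(k)]
  out[keep] <- G[keep]
  out
}
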