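#' Connection strength implied by a target spectral radius
#'
#' For a sparse signed Erdos-Renyi coupling matrix with equal-magnitude
#' entries, the bulk eigenvalue spectrum has radius
#' \eqn{\rho^2 = J^2 p (1-p) N}, so the common magnitude needed to reach a
#' prescribed radius is \eqn{|J| = \rho / \sqrt{p(1-p)N}}.  The relation is
#' asymptotic in \eqn{N}; the empirical radius of a single realization
#' fluctuates around the target.
#'
#' @param n_nodes number of nodes \eqn{N \ge 2}.
#' @param connection_prob connection probability \eqn{p}, strictly inside
#'   \eqn{(0, 1)}.
#' @param spectral_radius target bulk spectral radius \eqn{\rho \ge 0}.
#' @return the common connection magnitude \eqn{|J|}.
#' @seealso [sample_er_network()]
#' @export
#' @examples
#' strength_for_radius(100, 0.1, 0.7)
strength_for_radius <- function(n_nodes, connection_prob, spectral_radius) {
  stopifnot(n_nodes >= 2, spectral_radius >= 0)
  p <- connection_prob
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("connection_prob must lie strictly between 0 and 1 ",
         "(p = 0 or 1 makes the radius formula degenerate)")
  spectral_radius / sqrt(p * (1 - p) * n_nodes)
}

#' Sample a sparse signed Erdos-Renyi coupling matrix
#'
#' Draws a directed G(N, p) network in which every ordered off-diagonal pair
#' carries a connection independently with probability `connection_prob`.
#' All connections have the same magnitude (either given via `strength` or
#' derived from `spectral_radius` through [strength_for_radius()]) and each
#' is inhibitory (negative) independently with probability
#' `inhibitory_fraction`.  Entry \eqn{(i, j)} is the influence of node
#' \eqn{j} on node \eqn{i} (row = target, column = source); the diagonal is
#' zero and carries no meaning anywhere in the package.
#'
#' @param n_nodes number of nodes.
#' @param connection_prob probability of each directed connection.
#' @param spectral_radius target bulk spectral radius; used to derive the
#'   connection magnitude when `strength` is `NULL`.
#' @param inhibitory_fraction probability that a connection is negative.
#' @param strength common connection magnitude; overrides `spectral_radius`.
#' @param exact_half if `TRUE`, exactly half of the sampled connections
#'   (rounded down) are made negative instead of i.i.d. signs.
#' @param exact_radius if `TRUE`, rescale the sampled matrix so its
#'   empirical spectral radius equals `spectral_radius` exactly (useful in
#'   sweeps where the radius must be tightly controlled).
#' @param seed optional integer seed for reproducibility.
#' @return an `n_nodes` x `n_nodes` coupling matrix with zero diagonal.
#' @export
#' @examples
#' G <- sample_er_network(50, 0.1, 0.7, seed = 1)
#' max(Mod(eigen(G, only.values = TRUE)$values))  # close to 0.7
sample_er_network <- function(n_nodes, connection_prob, spectral_radius = 0.7,
                              inhibitory_fraction = 0.5, strength = NULL,
                              exact_half = FALSE, exact_radius = FALSE,
                              seed = NULL) {
  stopifnot(n_nodes >= 2, connection_prob >= 0, connection_prob <= 1,
            inhibitory_fraction >= 0, inhibitory_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_nodes
  if (is.null(strength)) {
    strength <- if (connection_prob == 0 || spectral_radius == 0) 0
                else strength_for_radius(n, connection_prob, spectral_radius)
  }
  if (spectral_radius >= 1)
    warning("spectral radius >= 1: unstable as an OU drift ",
            "(the static noise-free model still applies)")
  G <- matrix(0, n, n)
  off <- which(row(G) != col(G))
  edges <- off[stats::runif(length(off)) < connection_prob]
  m <- length(edges)
  if (m > 0) {
    if (exact_half) {
      neg <- sample(m, floor(m * inhibitory_fraction))
      sgn <- rep(1, m); sgn[neg] <- -1
    } else {
      sgn <- ifelse(stats::runif(m) < inhibitory_fraction, -1, 1)
    }
    G[edges] <- strength * sgn
  }
  if (exact_radius && m > 0) {
    r <- max(Mod(eigen(G, only.values = TRUE)$values))
    if (r > 0) G <- G * (spectral_radius / r)
  }
  G
}

#' Superimpose a weak background network on a skeleton
#'
#' Adds an independently sampled Erdos-Renyi network of weaker connections
#' to an existing skeleton of strong connections, modelling networks whose
#' sparsity assumption holds only for the dominant links.  The background
#' magnitude is derived from `background_radius` through the radius formula.
#' Evaluation against ground truth should still use the skeleton alone.
#'
#' @param skeleton coupling matrix of strong connections.
#' @param background_prob connection probability of the background network.
#' @param background_radius spectral radius of the background network alone
#'   (the reference setting is 20% of the skeleton's radius).
#' @param seed optional seed for the background draw.
#' @return the elementwise sum of skeleton and background.
#' @export
add_background <- function(skeleton, background_prob, background_radius,
                           seed = NULL) {
  stopifnot(is.matrix(skeleton), nrow(skeleton) == ncol(skeleton))
  if (background_prob == 0 || background_radius == 0) return(skeleton)
  bg <- sample_er_network(nrow(skeleton), background_prob, background_radius,
                          seed = seed)
  skeleton + bg
}

#' Noise-free precision matrix of a linear interaction network
#'
#' Under the linear consistency model \eqn{x = Gx + v} with unit-variance
#' independent inputs, the precision (inverse covariance) of the activity is
#' \deqn{C^{-1} = (I - G)^\top (I - G) = I - G - G^\top + G^\top G.}
#' The product term encodes collider structure: entry \eqn{(i, j)} of
#' \eqn{G^\top G} is nonzero exactly when nodes \eqn{i} and \eqn{j} send
#' connections to at least one common target, which is what makes edge
#' directions identifiable from a zero-lag covariance.
#'
#' @param G coupling matrix (zero diagonal).
#' @return the \eqn{N \times N} precision matrix, symmetric positive
#'   definite whenever \eqn{I - G} is nonsingular.
#' @export
#' @examples
#' G <- matrix(0, 3, 3); G[1, 2] <- G[1, 3] <- 0.5  # collider 2 -> 1 <- 3
#' noise_free_precision(G)[2, 3]                    # 0.25, not zero
noise_free_precision <- function(G) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  ImG <- diag(nrow(G)) - G
  if (rcond(ImG) < 1e-12)
    stop("I - G is (near-)singular: network degenerate or unstable")
  crossprod(ImG)
}
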