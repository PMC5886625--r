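test_that("the L1 cost sums off-diagonal magnitudes", {
  expect_equal(l1_cost(diag(3), diag(3)), 0)

  G <- matrix(0, 2, 2); G[2, 1] <- 0.5
  B <- initial_factor(noise_free_precision(G), role = "precision")
  expect_equal(l1_cost(diag(2), B), abs(B[1, 2]) + abs(B[2, 1]))

  # diagonal exclusion applies after the rotation: permuting rows moves
  # different entries onto the excluded diagonal
  set.seed(1)
  B <- matrix(runif(9, 0.5, 1), 3)
  P <- diag(3)[c(2, 3, 1), ]
  expect_equal(l1_cost(P, B), sum(abs(P %*% B)) - sum(abs(diag(P %*% B))))
  expect_false(isTRUE(all.equal(l1_cost(P, B), l1_cost(diag(3), B))))
  expect_error(l1_cost(diag(3), diag(4)), "dimension")
})

test_that("the subgradient matches finite differences away from kinks", {
  set.seed(2)
  for (rep in 1:3) {
    B <- matrix(rnorm(25), 5)
    U <- rand_orth(5)
    UB <- U %*% B
    if (min(abs(UB[row(UB) != col(UB)])) < 1e-3) next  # keep off kinks
    d <- l1_gradient(U, B)
    h <- 1e-6
    for (i in 1:5) for (j in 1:5) {
      Up <- U; Up[i, j] <- Up[i, j] + h
      Um <- U; Um[i, j] <- Um[i, j] - h
      fd <- (l1_cost(Up, B) - l1_cost(Um, B)) / (2 * h)
      expect_lt(abs(d[i, j] - fd), 1e-5)
    }
  }
})

test_that("the subgradient takes the minimal-norm choice at zeros", {
  B <- diag(3)                 # UB = I: all off-diagonal entries exactly 0
  d <- l1_gradient(diag(3), B)
  expect_true(all(d == 0))

  # strictly positive off-diagonal factor: gradient is 1_offdiag B^T
  Bpos <- matrix(2, 3, 3)
  ones <- matrix(1, 3, 3); diag(ones) <- 0
  expect_equal(l1_gradient(diag(3), Bpos), ones %*% t(Bpos))
})

test_that("descent directions are skew and consistent with the gradient norm", {
  set.seed(3)
  U <- rand_orth(6)
  d <- matrix(rnorm(36), 6)
  a <- descent_direction(d, U)
  expect_close(a, -t(a), tol = 1e-12)
  expect_equal(norm(d - U %*% t(d) %*% U, "F"), 2 * norm(a, "F"),
               tolerance = 1e-10)
  expect_close(descent_direction(U, U), matrix(0, 6, 6), tol = 1e-12)
  # symmetric gradient at the identity admits no skew descent direction
  S <- crossprod(matrix(rnorm(36), 6))
  expect_close(descent_direction(S, diag(6)), matrix(0, 6, 6), tol = 1e-12)
})

test_that("the step size is a fixed fraction of the geodesic period", {
  rot <- function(theta) rbind(c(0, theta), c(-theta, 0))
  expect_equal(step_size(rot(2 * pi), kappa = 500), 1 / 500)
  expect_equal(step_size(rot(1), kappa = 500),
               2 * step_size(rot(1), kappa = 1000))
  # a 2x2 rotation block has eigenvalues +/- i theta, so the geodesic
  # exp(-t a) has period 2 pi / theta and the step is 1/kappa of it
  theta <- 0.37
  expect_equal(step_size(rot(theta), kappa = 100),
               (2 * pi / theta) / 100)
  expect_error(step_size(matrix(0, 2, 2)), "converged")
})

test_that("line search finds the scalar minimum along a geodesic", {
  # constant cost along the geodesic: the input point is returned
  a <- rbind(c(0, 1), c(-1, 0))
  U <- diag(2)
  expect_equal(line_search(U, a, matrix(0, 2, 2)), U)
  # cost already minimal at the start point: also returned unchanged
  expect_equal(line_search(U, a, diag(2)), U)

  # closed-form check: B = [[1,1],[0,1]], rotation angle t gives cost
  # |cos t + sin t... evaluated by brute-force grid
  B <- rbind(c(1, 1), c(0, 1))
  f <- function(t) {
    R <- rbind(c(cos(t), sin(t)), c(-sin(t), cos(t)))
    l1_cost(R, B)
  }
  ts <- seq(0, 2 * pi, length.out = 20001)
  t_star <- ts[which.min(vapply(ts, f, numeric(1)))]
  U_ls <- line_search(diag(2), a, B)
  got <- l1_cost(U_ls, B)
  expect_lt(abs(got - f(t_star)), 1e-4)

  # never increases the cost
  set.seed(4)
  for (rep in 1:5) {
    B <- matrix(rnorm(16), 4)
    U <- rand_orth(4)
    d <- l1_gradient(U, B)
    a <- descent_direction(d, U)
    expect_lte(l1_cost(line_search(U, a, B), B), l1_cost(U, B) + 1e-12)
  }
})

test_that("canonicalization undoes signed permutations", {
  expect_equal(canonicalize_factor(-diag(3)), diag(3))
  P <- diag(4)[c(3, 1, 4, 2), ]
  expect_equal(canonicalize_factor(P), diag(4))

  set.seed(5)
  for (rep in 1:5) {
    G <- sample_er_network(12, 0.15, 0.6, seed = rep)
    B <- diag(12) - G
    W <- diag(sample(c(-1, 1), 12, replace = TRUE))[sample(12), ]
    expect_close(canonicalize_factor(W %*% B), B, tol = 1e-12)
  }
})

test_that("trivial problems converge immediately", {
  res <- unitary_minimize(diag(5))
  expect_equal(res$converged, "gtol")
  expect_equal(res$gamma, 0)
  expect_equal(res$U, diag(5))
})

test_that("iterates stay unitary and conserve the factor constraint", {
  set.seed(6)
  G <- sample_er_network(15, 0.15, 0.6, seed = 7)
  B0 <- initial_factor(noise_free_precision(G), role = "precision")
  res <- unitary_minimize(B0)
  U <- res$U
  expect_lt(norm(crossprod(U) - diag(15), "F"), 1e-8)
  lhs <- crossprod(res$B_opt)
  rhs <- crossprod(B0)
  expect_lt(norm(lhs - rhs, "F") / norm(rhs, "F"), 1e-8)
})

test_that("the cost trace is non-increasing within each continuation phase", {
  set.seed(8)
  G <- sample_er_network(12, 0.15, 0.6, seed = 9)
  B0 <- initial_factor(noise_free_precision(G), role = "precision")
  res <- unitary_minimize(B0)
  for (tr in split(res$trace, res$trace$eps)) {
    expect_true(all(diff(tr$gamma) <= 1e-10))
  }
})

test_that("compiled and reference engines agree", {
  set.seed(10)
  G <- sample_er_network(8, 0.2, 0.6, seed = 11)
  B0 <- initial_factor(noise_free_precision(G), role = "precision")
  ctl <- unitary_control(max_iter = 2000)
  res_c <- unitary_minimize(B0, control = ctl, engine = "cpp")
  res_r <- unitary_minimize(B0, control = ctl, engine = "r")
  expect_equal(res_c$gamma, res_r$gamma, tolerance = 1e-4)
  expect_close(res_c$U, res_r$U, tol = 1e-2)
})

test_that("complex Hermitian input runs in the unitary group", {
  G <- collider_G(0.4)
  B0 <- initial_factor(noise_free_precision(G), role = "precision") + 0i
  res <- unitary_minimize(B0, engine = "r")
  expect_true(is.complex(res$U))
  expect_lt(sqrt(sum(Mod(Conj(t(res$U)) %*% res$U - diag(3))^2)), 1e-8)
  Bc <- canonicalize_factor(res$B_opt)
  expect_close(Re(Bc), diag(3) - G, tol = 1e-6)
  expect_lt(max(abs(Im(Bc))), 1e-6)
})

test_that("gradient descent is near-globally optimal on small instances", {
  # dense-sampling oracle over O(3): no sampled rotation may beat the
  # optimizer by more than 1e-3 on the engine's objective (the full L1
  # norm of the rotated factor)
  set.seed(12)
  n_samp <- 100000
  Qs <- matrix(0, 3 * n_samp, 3)
  for (k in seq_len(n_samp))
    Qs[(3 * k - 2):(3 * k), ] <- rand_orth(3)
  grp <- rep(seq_len(n_samp), each = 3)
  for (rep in 1:20) {
    B <- matrix(rnorm(9), 3)
    B0 <- tryCatch(initial_factor(crossprod(B) + 0.1 * diag(3),
                                  role = "precision"),
                   error = function(e) NULL)
    if (is.null(B0)) next
    res <- unitary_minimize(B0)
    oracle_full <- min(rowsum(rowSums(abs(Qs %*% B0)), grp))
    expect_gte(oracle_full, sum(abs(res$B_opt)) - 1e-3)
  }
})

test_that("ambiguous motifs have exactly degenerate costs", {
  # a source node driving two targets carries no directional information:
  # both orientations of the hub produce identical factor magnitudes
  g <- 0.5
  B1 <- diag(3) - chain_G(g)
  B2 <- diag(3) - t(chain_G(g))
  expect_equal(l1_cost(diag(3), B1), l1_cost(diag(3), B2), tolerance = 1e-9)
  # while the collider breaks the tie through the precision entry
  expect_false(isTRUE(all.equal(
    noise_free_precision(chain_G(g))[2, 3],
    noise_free_precision(collider_G(g))[2, 3])))
})
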