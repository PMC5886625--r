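# Small ground-truth motifs used across tests.
# Convention: entry (i, j) is the influence of node j on node i.

collider_G <- function(g = 0.5) {
  G <- matrix(0, 3, 3)
  G[1, 2] <- g   # 2 -> 1
  G[1, 3] <- g   # 3 -> 1
  G
}

chain_G <- function(g = 0.5) {
  G <- matrix(0, 3, 3)
  G[2, 1] <- g   # 1 -> 2
  G[3, 1] <- g   # 1 -> 3
  G
}

# all 64 directed 3-node graphs with unit weights, as a list of matrices
all_3node_graphs <- function() {
  pos <- which(row(diag(3)) != col(diag(3)))
  lapply(0:63, function(code) {
    G <- matrix(0, 3, 3)
    G[pos] <- as.integer(intToBits(code))[1:6]
    G
  })
}

rand_orth <- function(n) qr.Q(qr(matrix(rnorm(n * n), n)))

expect_close <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
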