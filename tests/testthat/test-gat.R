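random_graph <- function(m, p = 0.4) {
  A <- matrix(0, m, m)
  if (m > 1) {
    pairs <- t(combn(m, 2))
    pick <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
    A[pick] <- 1
    A[pick[, c(2, 1), drop = FALSE]] <- 1
  }
  diag(A) <- 1
  A
}

test_that("attention rows are stochastic exactly on the neighborhood support", {
  set.seed(31)
  for (rep in 1:100) {
    m <- sample(1:7, 1); d <- sample(2:4, 1)
    A <- random_graph(m)
    V <- matrix(rnorm(m * d), m, d)
    params <- gat_params(d_in = d, d_head = 3, heads = 2, seed = rep)
    for (k in 1:2) {
      alpha <- gat_attention(V, A, params, head = k)
      expect_true(all(alpha >= 0))
      expect_equal(rowSums(alpha), rep(1, m), tolerance = 1e-6)
      expect_true(all(alpha[A == 0] == 0))
    }
  }
})

test_that("attention limits: singleton support and zero attention vector", {
  set.seed(32)
  V <- matrix(rnorm(8), 4, 2)
  params <- gat_params(d_in = 2, d_head = 2, heads = 1, seed = 1)
  # isolated-but-for-self node: all mass on the self loop
  A <- diag(4)
  expect_equal(gat_attention(V, A, params), diag(4))
  # zero attention vector: uniform over each neighborhood
  params$a[[1]] <- rep(0, 4)
  A2 <- random_graph(4)
  alpha <- gat_attention(V, A2, params)
  for (i in 1:4) {
    nb <- which(A2[i, ] == 1)
    expect_equal(alpha[i, nb], rep(1 / length(nb), length(nb)))
  }
})

test_that("attention agrees with a scalar hand-oracle on a path graph", {
  set.seed(33)
  # 3-node path, d = d_h = 2, hand-set parameters
  V <- matrix(c(0.5, -1, 2, 0.3, -0.7, 1.1), 3, 2, byrow = TRUE)
  A <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3, 3)
  params <- gat_params(d_in = 2, d_head = 2, heads = 1, seed = 1)
  params$W[[1]] <- diag(2)
  params$a[[1]] <- c(1, 0, 0, 0)
  alpha <- gat_attention(V, A, params)
  expect_equal(alpha, oracle_attention(V, A, diag(2), c(1, 0, 0, 0), 0.2),
               tolerance = 1e-12)
  # and on random graphs/parameters
  for (rep in 1:20) {
    m <- sample(2:6, 1)
    V <- matrix(rnorm(2 * m), m, 2)
    A <- random_graph(m)
    params <- gat_params(d_in = 2, d_head = 3, heads = 1, seed = rep)
    expect_equal(gat_attention(V, A, params),
                 oracle_attention(V, A, params$W[[1]], params$a[[1]], 0.2),
                 tolerance = 1e-9)
  }
})

test_that("forward pass closed-form limit: zero projection, identity residual", {
  set.seed(34)
  V <- matrix(rnorm(10), 5, 2)
  params <- gat_params(d_in = 2, d_head = 2, heads = 1, seed = 1)
  params$W[[1]] <- matrix(0, 2, 2)
  H <- gat_forward(V, random_graph(5), params)
  expect_equal(H, ifelse(V > 0, V, 0.2 * V))
})

test_that("forward pass matches a per-element brute-force oracle", {
  set.seed(35)
  # 2-node clique, 2 heads, projected residual (d_in != d_head)
  V <- matrix(c(0.4, -0.2, 1.5, 0.9, -1.1, 0.6), 2, 3)
  A <- matrix(1, 2, 2)
  params <- gat_params(d_in = 3, d_head = 2, heads = 2, seed = 9)
  H <- gat_forward(V, A, params)
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  for (k in 1:2) {
    alpha <- oracle_attention(V, A, params$W[[k]], params$a[[k]], 0.2)
    P <- V %*% params$W[[k]]
    for (i in 1:2) {
      msg <- alpha[i, 1] * P[1, ] + alpha[i, 2] * P[2, ]
      gi <- lrelu(msg + drop(V[i, ] %*% params$Wr[[k]]))
      expect_equal(H[i, ((k - 1) * 2 + 1):(k * 2)], gi, tolerance = 1e-9)
    }
  }
})

test_that("permutation equivariance holds exactly", {
  set.seed(36)
  m <- 6
  V <- matrix(rnorm(m * 3), m, 3)
  A <- random_graph(m)
  params <- gat_params(d_in = 3, d_head = 4, heads = 2, seed = 2)
  H <- gat_forward(V, A, params)
  perm <- sample(m)
  H_perm <- gat_forward(V[perm, ], A[perm, perm], params)
  expect_equal(H_perm, H[perm, ])
})

test_that("output is local: non-neighbors cannot influence a node", {
  set.seed(37)
  # path graph 1-2-3: node 3 is not in node 1's first-order neighborhood
  A <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3, 3)
  V <- matrix(rnorm(9), 3, 3)
  params <- gat_params(d_in = 3, d_head = 3, heads = 2, seed = 3)
  H1 <- gat_forward(V, A, params)
  V2 <- V; V2[3, ] <- rnorm(3)
  H2 <- gat_forward(V2, A, params)
  expect_equal(H2[1, ], H1[1, ])
  expect_false(isTRUE(all.equal(H2[2, ], H1[2, ])))
})

test_that("backward pass matches central finite differences", {
  set.seed(38)
  for (cfg in list(list(d = 3, dh = 3), list(d = 3, dh = 2))) {
    m <- 4
    V <- matrix(rnorm(m * cfg$d), m, cfg$d)
    A <- random_graph(m)
    params <- gat_params(d_in = cfg$d, d_head = cfg$dh, heads = 2, seed = 4)
    R0 <- matrix(rnorm(m * 2 * cfg$dh), m, 2 * cfg$dh)
    loss_of <- function(p) sum(gat_forward(V, A, p) * R0)
    fw <- gat_forward(V, A, params, keep_cache = TRUE)
    gb <- kgner:::gat_backward(fw$cache, R0)
    expect_equal(gb$dV,
                 numeric_grad(function(v) sum(gat_forward(v, A, params) * R0), V),
                 tolerance = 1e-6)
    for (k in 1:2) {
      pW <- function(w) { p <- params; p$W[[k]] <- w; loss_of(p) }
      pa <- function(a) { p <- params; p$a[[k]] <- a; loss_of(p) }
      expect_equal(gb$dW[[k]], numeric_grad(pW, params$W[[k]]), tolerance = 1e-6)
      expect_equal(gb$da[[k]], numeric_grad(pa, params$a[[k]]), tolerance = 1e-6)
      if (!is.null(params$Wr)) {
        pr <- function(w) { p <- params; p$Wr[[k]] <- w; loss_of(p) }
        expect_equal(gb$dWr[[k]], numeric_grad(pr, params$Wr[[k]]),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("width mismatches and bad adjacencies are rejected", {
  params <- gat_params(d_in = 3, d_head = 2, heads = 1, seed = 1)
  expect_error(gat_forward(matrix(0, 2, 4), diag(2), params),
               class = "kgner_width_mismatch")
  A_bad <- matrix(c(1, 1, 0, 1), 2, 2)
  expect_error(gat_forward(matrix(0, 2, 3), A_bad, params),
               class = "kgner_bad_adjacency")
})
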