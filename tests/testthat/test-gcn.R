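test_that("the normalized adjacency handles the canonical small cases", {
  lone <- normalized_adjacency(matrix(integer(0), ncol = 2), 1)
  expect_equal(as.matrix(lone$A), matrix(1), ignore_attr = TRUE)

  pair <- normalized_adjacency(rbind(c(1L, 2L)), 2)
  expect_equal(as.matrix(pair$A), matrix(0.5, 2, 2), ignore_attr = TRUE)

  expect_error(normalized_adjacency(rbind(c(1L, 5L)), 3), "out of range")
  expect_error(normalized_adjacency(rbind(c(2L, 2L)), 3), "self-pairs")
})

test_that("sparse normalized adjacency equals the dense-matrix oracle", {
  withr::with_seed(1, {
    for (i in 1:10) {
      n <- sample(5:50, 1)
      m <- sample(0:(n * 2), 1)
      edges <- unique(t(apply(
        matrix(sample.int(n, 2 * m, replace = TRUE), ncol = 2), 1, sort)))
      edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
      op <- normalized_adjacency(edges, n)
      dense <- dense_norm_adj(edges, n)
      expect_lt(max(abs(as.matrix(op$A) - dense)), 1e-12)
      expect_lt(max(abs(as.matrix(op$A) - t(as.matrix(op$A)))), 1e-12)
      expect_true(all(Matrix::diag(op$A) > 0))
    }
  })
})

test_that("zero weights give a zero embedding", {
  stack <- gcn_init(4, hidden = 8, d_out = 3, seed = 1)
  stack$W <- lapply(stack$W, function(w) w * 0)
  op <- normalized_adjacency(rbind(c(1L, 2L)), 3)
  H <- gcn_forward(stack, matrix(rnorm(12), 3), op)
  expect_true(all(H == 0))
})

test_that("on an edgeless graph the GCN reduces to a per-node MLP", {
  withr::with_seed(2, {
    n <- 7; d <- 5
    X <- matrix(rnorm(n * d), n)
    stack <- gcn_init(d, hidden = 9, d_out = 4, seed = 3)
    op <- normalized_adjacency(matrix(integer(0), ncol = 2), n)
    H <- gcn_forward(stack, X, op)
    # independent plain feed-forward evaluation, node by node
    mlp <- t(apply(X, 1, function(x) {
      h <- x
      for (l in 1:6) h <- pmax(as.vector(h %*% stack$W[[l]]) + stack$b[[l]], 0)
      h
    }))
    expect_equal(H, mlp, tolerance = 1e-12, ignore_attr = TRUE)
  })
})

test_that("sparse propagation equals the dense-matrix forward pass", {
  withr::with_seed(4, {
    n <- 20; d <- 6
    X <- matrix(rnorm(n * d), n)
    edges <- rbind(c(1L, 2L), c(2L, 3L), c(5L, 9L), c(10L, 20L), c(4L, 5L))
    stack <- gcn_init(d, hidden = 11, d_out = 4, seed = 5)
    op <- normalized_adjacency(edges, n)
    H <- gcn_forward(stack, X, op)
    Abar <- dense_norm_adj(edges, n)
    Hd <- X
    for (l in 1:6)
      Hd <- pmax(sweep(Abar %*% Hd %*% stack$W[[l]], 2, stack$b[[l]], "+"), 0)
    expect_lt(max(abs(H - Hd)), 1e-6)
  })
})

test_that("the GCN is equivariant to node permutations", {
  withr::with_seed(6, {
    n <- 12; d <- 4
    X <- matrix(rnorm(n * d), n)
    edges <- rbind(c(1L, 4L), c(2L, 7L), c(7L, 12L), c(3L, 4L))
    stack <- gcn_init(d, hidden = 8, d_out = 3, seed = 7)
    perm <- sample(n)
    # relabel node i -> position match(i, perm)
    pedges <- cbind(match(edges[, 1], perm), match(edges[, 2], perm))
    H1 <- gcn_forward(stack, X, normalized_adjacency(edges, n))
    H2 <- gcn_forward(stack, X[perm, ], normalized_adjacency(pedges, n))
    expect_equal(H1[perm, ], H2, tolerance = 1e-12)
  })
})

test_that("layer-1 output is local: non-neighbors do not interact", {
  withr::with_seed(8, {
    n <- 6; d <- 3
    X <- matrix(rnorm(n * d), n)
    edges <- rbind(c(1L, 2L))     # node 5 is isolated from node 1
    op <- normalized_adjacency(edges, n)
    stack <- gcn_init(d, hidden = 5, d_out = 2, seed = 9)
    layer1 <- function(X) pmax(sweep(as.matrix(op$A %*% X) %*% stack$W[[1]],
                                     2, stack$b[[1]], "+"), 0)
    X2 <- X; X2[5, ] <- X2[5, ] + 10
    expect_equal(layer1(X)[1, ], layer1(X2)[1, ])
    expect_false(isTRUE(all.equal(layer1(X)[5, ], layer1(X2)[5, ])))
  })
})

test_that("analytic gradients match finite differences on a tiny instance", {
  withr::with_seed(10, {
    n <- 6; d <- 4
    X <- matrix(rnorm(n * d), n)
    y <- rep(c(0L, 1L), 3)
    op <- normalized_adjacency(rbind(c(1L, 2L), c(3L, 6L)), n)
    stack <- gcn_init(d, hidden = 5, d_out = 3, seed = 11)
    Wc <- matrix(rnorm(6), 3, 2)

    loss_of <- function(stack) {
      H <- gcn_forward(stack, X, op)
      seizgraph:::softmax_ce(H %*% Wc, y, 1:n)$loss
    }
    fw <- gcn_forward(stack, X, op, keep_cache = TRUE)
    ce <- seizgraph:::softmax_ce(fw$H6 %*% Wc, y, 1:n)
    gb <- seizgraph:::gcn_backward(stack, op, fw$cache, ce$dlogits %*% t(Wc))

    eps <- 1e-6
    for (l in c(1L, 6L)) {
      idx <- sample(length(stack$W[[l]]), 6)
      for (i in idx) {
        s1 <- stack; s1$W[[l]][i] <- s1$W[[l]][i] + eps
        s2 <- stack; s2$W[[l]][i] <- s2$W[[l]][i] - eps
        num <- (loss_of(s1) - loss_of(s2)) / (2 * eps)
        expect_equal(gb$dW[[l]][i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("the six-layer stack has the documented shapes", {
  stack <- gcn_init(38)
  expect_length(stack$W, 6)
  expect_equal(dim(stack$W[[1]]), c(38, 256))
  for (l in 2:5) expect_equal(dim(stack$W[[l]]), c(256, 256))
  expect_equal(dim(stack$W[[6]]), c(256, 16))
})
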