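test_that("modality projection matches a step-by-step hand computation", {
  set.seed(2)
  X <- matrix(rnorm(5 * 13), 5)
  W0 <- matrix(rnorm(13 * 6, sd = 0.3), 13)
  b0 <- rnorm(6); gamma <- runif(6, 0.5, 1.5); beta <- rnorm(6, sd = 0.1)
  got <- project_modality(X, W0, b0, gamma, beta)
  # independent straight-line evaluation, one row at a time
  want <- t(apply(X, 1, function(x) {
    pre <- drop(x %*% W0) + b0
    mu <- mean(pre); sd2 <- mean((pre - mu)^2)
    xhat <- (pre - mu) / sqrt(sd2 + 1e-5)
    pmax(xhat * gamma + beta, 0)
  }))
  expect_equal(got, want, tolerance = 1e-6, ignore_attr = TRUE)
  # zero weights, unit scale: constant rows normalize to zero
  expect_equal(project_modality(X, W0 * 0, b0 * 0, gamma * 0 + 1,
                                beta * 0),
               matrix(0, 5, 6), ignore_attr = TRUE)
  expect_true(all(got >= 0))
})

test_that("node fusion concatenates per-modality blocks in fixed order", {
  dims <- tiny_dims()
  params <- init_params(dims, seed = 4)
  b <- tiny_bundle(1, dims, seed = 9)
  X0 <- fuse_nodes(b, params)
  expect_equal(dim(X0), c(1, 9))
  expect_equal(X0[, 1:3],
               project_modality(b$seq_emb, params$W0_seq, params$b0_seq,
                                params$gamma_seq, params$beta_seq)[1, ],
               ignore_attr = TRUE)
  expect_equal(X0[, 7:9],
               project_modality(b$dssp_feats, params$W0_dssp,
                                params$b0_dssp, params$gamma_dssp,
                                params$beta_dssp)[1, ],
               ignore_attr = TRUE)
  # row-wise operation: permuting residues permutes rows identically
  b6 <- tiny_bundle(6, dims, seed = 10)
  perm <- c(3, 1, 6, 2, 5, 4)
  bp <- lapply(b6, function(m) m[perm, , drop = FALSE])
  expect_equal(fuse_nodes(bp, params), fuse_nodes(b6, params)[perm, ])
  # row-count mismatch is rejected
  bbad <- b6; bbad$if_emb <- bbad$if_emb[-1, , drop = FALSE]
  expect_error(fuse_nodes(bbad, params), "disagree")
})

test_that("additive attention matches the closed-form equations", {
  set.seed(6)
  X <- matrix(rnorm(6 * 4), 6)
  Wa <- matrix(rnorm(16, sd = 0.5), 4)
  Va <- rnorm(4)
  att <- additive_attention(X, Wa, Va)
  # direct evaluation: e_i = V' tanh(W x_i) (W applied as X %*% Wa)
  e <- sapply(1:6, function(i) sum(Va * tanh(drop(X[i, ] %*% Wa))))
  a <- exp(e) / sum(exp(e))
  Z <- colSums(a * X)
  expect_equal(att$weights, a, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(att$context, Z, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sum(att$weights), 1, tolerance = 1e-8)
  expect_equal(att$out[3, ], c(X[3, ], Z), ignore_attr = TRUE)

  # single node: weight 1, context is the node itself
  a1 <- additive_attention(X[1, , drop = FALSE], Wa, Va)
  expect_equal(a1$weights, 1)
  expect_equal(a1$context, X[1, ], ignore_attr = TRUE)

  # constant scores (zero map) give uniform weights and the column mean
  a2 <- additive_attention(X, Wa * 0, Va)
  expect_equal(a2$weights, rep(1 / 6, 6))
  expect_equal(a2$context, colMeans(X), ignore_attr = TRUE)
})

test_that("attention weights always normalize across random cases", {
  set.seed(8)
  for (case in 1:20) {
    n <- sample(2:30, 1); d <- sample(2:8, 1)
    att <- additive_attention(matrix(rnorm(n * d, sd = 3), n),
                              matrix(rnorm(d * d), d), rnorm(d))
    expect_equal(sum(att$weights), 1, tolerance = 1e-8)
    expect_true(all(att$weights > 0))
  }
})

test_that("the multi-scale GCN layer equals a dense per-kernel oracle", {
  set.seed(12)
  dims <- tiny_dims()
  params <- init_params(dims, seed = 3)
  n <- 12
  H <- matrix(rnorm(n * dims$d_fused), n)
  stack <- random_adj_stack(n, seed = 13)
  ahat <- lapply(stack, function(A) {
    deg <- rowSums(A)
    A / sqrt(outer(deg, deg))
  })
  got <- multiscale_gcn_layer(H, ahat, params, layer = 1)
  # independent dense computation per kernel
  Hk <- lapply(1:3, function(kk) {
    A <- stack[[kk]]
    deg <- rowSums(A)
    M <- matrix(0, n, dims$gcn_dim)
    W <- params[[paste0("Wk1_", kk)]]
    for (i in 1:n) for (j in 1:n) {
      if (A[i, j] == 1)
        M[i, ] <- M[i, ] + (1 / sqrt(deg[i] * deg[j])) *
          drop(H[j, ] %*% W)
    }
    pmax(M, 0)
  })
  want <- pmax(sweep(do.call(cbind, Hk) %*% params$Wf1, 2, params$bf1,
                     "+"), 0)
  expect_equal(got, want, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("GCN layer degenerate cases behave", {
  dims <- tiny_dims()
  params <- init_params(dims, seed = 5)
  # identical features on a vertex-transitive graph -> identical rows
  n <- 6
  A <- matrix(1, n, n)  # complete graph + loops is vertex-transitive
  ahat <- lapply(list(A, A, A), function(M) M / n)
  H <- matrix(rep(rnorm(dims$d_fused), each = n), n)
  out <- multiscale_gcn_layer(H, ahat, params, layer = 1)
  expect_equal(max(apply(out, 2, function(col) diff(range(col)))), 0)
  # size mismatches are rejected
  expect_error(multiscale_gcn_layer(H[, -1], ahat, params, 1), "width")
  expect_error(multiscale_gcn_layer(H, lapply(ahat, function(x)
    x[-1, -1]), params, 1), "adjacency")
})

test_that("residual combination is convex in its inputs", {
  H0 <- matrix(rnorm(20), 5)
  H2 <- matrix(rnorm(20), 5)
  expect_equal(residual_combine(H0, H2, 50), H0, tolerance = 1e-8)
  expect_equal(residual_combine(H0, H2, -50), H2, tolerance = 1e-8)
  expect_equal(residual_combine(H0, -H0, 0), matrix(0, 5, 4))
  mix <- residual_combine(H0, H2, 0.37)
  expect_true(all(mix <= pmax(H0, H2) + 1e-12))
  expect_true(all(mix >= pmin(H0, H2) - 1e-12))
})

test_that("the forward pass is a proper probability and equivariant", {
  dims <- tiny_dims()
  params <- init_params(dims, seed = 7)
  n <- 9
  b <- tiny_bundle(n, dims, seed = 14)
  stack <- random_adj_stack(n, seed = 15)
  ahat <- epigcn:::graph_ahat(stack)
  p <- epigcn:::epigcn_forward(b, ahat, params, dims)
  expect_true(all(p > 0 & p < 1))
  # permuting residues together with the graph permutes outputs
  perm <- sample(n)
  bp <- lapply(b, function(m) m[perm, , drop = FALSE])
  stackp <- lapply(stack, function(A) A[perm, perm])
  pp <- epigcn:::epigcn_forward(bp, epigcn:::graph_ahat(stackp), params,
                                dims)
  expect_equal(pp, p[perm], tolerance = 1e-10)
})

test_that("duplicated isolated nodes get identical probabilities", {
  dims <- tiny_dims()
  params <- init_params(dims, seed = 8)
  b1 <- tiny_bundle(1, dims, seed = 16)
  b <- lapply(b1, function(m) m[c(1, 1), , drop = FALSE])
  I2 <- diag(2)
  ahat <- epigcn:::graph_ahat(list(A1 = I2, A2 = I2, A3 = I2))
  p <- epigcn:::epigcn_forward(b, ahat, params, dims)
  expect_equal(p[1], p[2], tolerance = 1e-12)
})

test_that("analytic gradients match finite differences everywhere", {
  set.seed(42)
  dims <- tiny_dims()
  n <- 7
  b <- tiny_bundle(n, dims, seed = 17)
  stack <- random_adj_stack(n, seed = 18)
  ahat <- epigcn:::graph_ahat(stack)
  params <- init_params(dims, seed = 19)
  # jitter away from relu/zero kinks so central differences are clean
  for (nm in names(params))
    params[[nm]] <- params[[nm]] + rnorm(length(params[[nm]]), 0, 0.05)
  y <- rbinom(n, 1, 0.5)
  loss_fn <- function(pp) {
    attr(pp, "n_mlp") <- attr(params, "n_mlp")
    bce_loss(epigcn:::epigcn_forward(b, ahat, pp, dims), y)
  }
  cc <- epigcn:::epigcn_forward(b, ahat, params, dims, cache = TRUE)
  grads <- epigcn:::epigcn_backward((cc$p - y) / n, cc, ahat, params,
                                    dims)
  # every parameter tensor receives gradient (no dead branch)
  expect_true(all(vapply(grads, function(g) any(g != 0), logical(1))))
  eps <- 1e-6
  set.seed(20)
  for (nm in names(params)) {
    x <- params[[nm]]
    idx <- if (length(x) > 5) sample(length(x), 5) else seq_along(x)
    for (ii in idx) {
      pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
      lp <- loss_fn(pp)
      pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] - eps
      lm <- loss_fn(pp)
      num <- (lp - lm) / (2 * eps)
      expect_equal(grads[[nm]][ii], num, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("checkpoints restore a model that predicts identically", {
  dims <- tiny_dims()
  ds <- lapply(1:3, function(i) {
    n <- 8
    b <- tiny_bundle(n, dims, seed = 20 + i)
    list(bundle = b, graph = random_adj_stack(n, seed = 30 + i),
         labels = rbinom(n, 1, 0.4))
  })
  fit <- epigcn_fit(ds, dims = dims, epochs = 3, val_fraction = 0,
                    seed = 2)
  path <- tempfile(fileext = ".json")
  write_checkpoint(fit, path)
  fit2 <- read_checkpoint(path)
  p1 <- predict(fit, ds[[1]])
  p2 <- predict(fit2, ds[[1]])
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_error(read_checkpoint(three_res_pdb(tempfile())))
})
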