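# The dual-branch epitope network.
#
# Branch A: fused node features -> additive attention -> per-residue
#           [x_i | Z] with the pooled context Z broadcast to every node.
# Branch B: two multi-scale GCN layers over the k-hop adjacency stack,
#           then a learnable convex residual mix with a projection of
#           the fused input.
# Head:     concatenated branch outputs -> MLP -> sigmoid, one
#           probability per residue.
#
# Everything is plain dense linear algebra with hand-derived gradients;
# the analytic backward pass is checked against finite differences in
# the test suite.

LN_EPS <- 1e-5

relu <- function(x) pmax(x, 0)

softmax_vec <- function(e) {
  w <- exp(e - max(e))
  w / sum(w)
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Model dimensions and hyperparameters
#'
#' @param d_seq_emb Width of the sequence-language embedding (default
#'   2560).
#' @param d_if_emb Width of the inverse-folding embedding (default 512).
#' @param d_dssp Width of the structural feature block (13).
#' @param proj_dim Per-modality projection width (default 256); the
#'   fused node width is \code{3 * proj_dim}.
#' @param gcn_dim Hidden width of the GCN branch (default 256).
#' @param mlp_hidden Widths of the MLP head's hidden layers.
#' @param dropout Dropout rate applied inside the MLP head during
#'   training.
#' @return list of class \code{epigcn_dims}.
#' @export
model_dims <- function(d_seq_emb = 2560L, d_if_emb = 512L, d_dssp = 14L,
                       proj_dim = 256L, gcn_dim = 256L,
                       mlp_hidden = c(256L, 64L), dropout = 0.3) {
  structure(list(d_seq_emb = d_seq_emb, d_if_emb = d_if_emb,
                 d_dssp = d_dssp, proj_dim = proj_dim, gcn_dim = gcn_dim,
                 mlp_hidden = mlp_hidden, dropout = dropout,
                 d_fused = 3L * proj_dim),
            class = "epigcn_dims")
}

#' Initialize model parameters
#'
#' Weights are Glorot-uniform; layer-norm scales start at 1, shifts at 0;
#' the residual mix starts at lambda = 0.5 (theta = 0).
#'
#' @param dims A [model_dims()] object.
#' @param seed Integer seed for the weight draw.
#' @return Named list of parameter tensors (class \code{epigcn_params}).
#' @export
init_params <- function(dims, seed = 1L) {
  set.seed(seed)
  p <- dims$proj_dim; d <- dims$d_fused; g <- dims$gcn_dim
  din <- c(seq = dims$d_seq_emb, ifold = dims$d_if_emb, dssp = dims$d_dssp)
  par <- list()
  for (m in names(din)) {
    par[[paste0("W0_", m)]] <- glorot(din[[m]], p)
    par[[paste0("b0_", m)]] <- numeric(p)
    par[[paste0("gamma_", m)]] <- rep(1, p)
    par[[paste0("beta_", m)]] <- numeric(p)
  }
  par$Wa <- glorot(d, d)
  par$Va <- stats::runif(d, -sqrt(3 / d), sqrt(3 / d))
  for (l in 1:2) {
    din_l <- if (l == 1) d else g
    for (kk in 1:3) par[[paste0("Wk", l, "_", kk)]] <- glorot(din_l, g)
    par[[paste0("Wf", l)]] <- glorot(3 * g, g)
    par[[paste0("bf", l)]] <- numeric(g)
  }
  par$Wres <- glorot(d, g)
  par$theta <- 0
  widths <- c(2L * d + g, dims$mlp_hidden, 1L)
  for (l in seq_len(length(widths) - 1L)) {
    par[[paste0("Wm", l)]] <- glorot(widths[l], widths[l + 1])
    par[[paste0("bm", l)]] <- numeric(widths[l + 1])
  }
  structure(par, class = "epigcn_params", n_mlp = length(widths) - 1L)
}

#' Project one feature modality into the shared latent space
#'
#' Row-wise \code{ReLU(LayerNorm(X W + b))}: linear projection to the
#' latent width, per-row layer normalization (learnable scale/shift,
#' epsilon 1e-5), then ReLU.
#'
#' @param X N x d_in input matrix.
#' @param W0 d_in x p projection weights.
#' @param b0,gamma,beta Length-p bias, LN scale, LN shift.
#' @return N x p matrix; with \code{cache = TRUE}, a list holding
#'   intermediates for the backward pass.
#' @param cache Keep intermediates for backprop?
#' @export
project_modality <- function(X, W0, b0, gamma, beta, cache = FALSE) {
  pre <- sweep(X %*% W0, 2, b0, "+")
  mu <- rowMeans(pre)
  v <- rowMeans((pre - mu)^2)
  inv_sd <- 1 / sqrt(v + LN_EPS)
  xhat <- (pre - mu) * inv_sd
  ln <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  out <- relu(ln)
  if (!cache) return(out)
  list(out = out, X = X, xhat = xhat, inv_sd = inv_sd, ln = ln)
}

# gradient of project_modality; dOut is N x p
.project_backward <- function(dOut, cc, W0, gamma) {
  dln <- dOut * (cc$ln > 0)
  dgamma <- colSums(dln * cc$xhat)
  dbeta <- colSums(dln)
  dxhat <- sweep(dln, 2, gamma, "*")
  # standard per-row LN backward
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cc$xhat)
  dpre <- cc$inv_sd * (dxhat - m1 - cc$xhat * m2)
  dW0 <- t(cc$X) %*% dpre
  db0 <- colSums(dpre)
  dX <- dpre %*% t(W0)
  list(dW0 = dW0, db0 = db0, dgamma = dgamma, dbeta = dbeta, dX = dX)
}

#' Fuse the three modalities into node features
#'
#' Each modality is projected with its own parameters and the results
#' concatenated column-wise in the fixed order (sequence embedding |
#' inverse-folding embedding | structural features).
#'
#' @param bundle list with \code{seq_emb}, \code{if_emb}, \code{dssp_feats}
#'   matrices of equal row count.
#' @param params An \code{epigcn_params} list.
#' @param cache Keep intermediates for backprop?
#' @return N x (3 * proj_dim) matrix (or cache list).
#' @export
fuse_nodes <- function(bundle, params, cache = FALSE) {
  ns <- vapply(bundle[c("seq_emb", "if_emb", "dssp_feats")], nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("modalities disagree on residue count: ",
         paste(ns, collapse = ", "))
  mods <- c(seq = "seq_emb", ifold = "if_emb", dssp = "dssp_feats")
  caches <- list()
  blocks <- list()
  for (m in names(mods)) {
    cc <- project_modality(bundle[[mods[[m]]]],
                           params[[paste0("W0_", m)]],
                           params[[paste0("b0_", m)]],
                           params[[paste0("gamma_", m)]],
                           params[[paste0("beta_", m)]], cache = TRUE)
    caches[[m]] <- cc
    blocks[[m]] <- cc$out
  }
  X0 <- do.call(cbind, blocks)
  if (!cache) return(X0)
  list(X0 = X0, caches = caches)
}

.fuse_backward <- function(dX0, fcache, params, grads) {
  p <- ncol(fcache$caches$seq$out)
  off <- 0L
  for (m in c("seq", "ifold", "dssp")) {
    dBlock <- dX0[, off + seq_len(p), drop = FALSE]
    gb <- .project_backward(dBlock, fcache$caches[[m]],
                            params[[paste0("W0_", m)]],
                            params[[paste0("gamma_", m)]])
    grads[[paste0("W0_", m)]] <- grads[[paste0("W0_", m)]] + gb$dW0
    grads[[paste0("b0_", m)]] <- grads[[paste0("b0_", m)]] + gb$db0
    grads[[paste0("gamma_", m)]] <- grads[[paste0("gamma_", m)]] + gb$dgamma
    grads[[paste0("beta_", m)]] <- grads[[paste0("beta_", m)]] + gb$dbeta
    off <- off + p
  }
  grads
}

#' Additive attention over node features
#'
#' Scores \code{e_i = V' tanh(W x_i)}, softmax weights \code{a}, pooled
#' context \code{Z = sum_i a_i x_i}; the per-residue branch output is
#' \code{[x_i | Z]} (the global context broadcast to every residue).
#'
#' @param X N x d node feature matrix.
#' @param Wa d x d attention weight; \code{Va} length-d scoring vector.
#' @param Va Scoring vector.
#' @param cache Keep intermediates for backprop?
#' @return list with \code{weights} (length N, sums to 1),
#'   \code{context} (length d) and \code{out} (N x 2d).
#' @export
additive_attention <- function(X, Wa, Va, cache = FALSE) {
  Tn <- tanh(X %*% Wa)
  e <- drop(Tn %*% Va)
  a <- softmax_vec(e)
  Z <- drop(crossprod(X, a))
  out <- cbind(X, matrix(Z, nrow(X), length(Z), byrow = TRUE))
  r <- list(weights = a, context = Z, out = out)
  if (cache) r[c("X", "Tn", "e")] <- list(X, Tn, e)
  r
}

.attention_backward <- function(dOut, ac, Wa, Va) {
  d <- ncol(ac$X)
  dX <- dOut[, seq_len(d), drop = FALSE]
  dZ <- colSums(dOut[, d + seq_len(d), drop = FALSE])
  a <- ac$weights
  # Z = X' a
  da <- drop(ac$X %*% dZ)
  dX <- dX + outer(a, dZ)
  de <- a * (da - sum(a * da))
  dTn <- outer(de, Va)
  dVa <- drop(crossprod(ac$Tn, de))
  dpre <- dTn * (1 - ac$Tn^2)
  dWa <- crossprod(ac$X, dpre)
  dX <- dX + dpre %*% t(Wa)
  list(dX = dX, dWa = dWa, dVa = dVa)
}

#' One multi-scale GCN layer
#'
#' For each hop radius k in {1,2,3}: symmetric-normalized propagation
#' over the k-hop adjacency (degrees per scale, self-loops included),
#' linear map, ReLU.  The three scale outputs are concatenated and fused
#' by a linear layer with ReLU.
#'
#' @param H N x d_in node features.
#' @param Ahat_list list of three precomputed normalized adjacencies
#'   (\code{D^-1/2 A_k D^-1/2}).
#' @param params Model parameter list.
#' @param layer 1 or 2 (selects the layer's weights).
#' @param cache Keep intermediates for backprop?
#' @return N x gcn_dim matrix (or cache list).
#' @export
multiscale_gcn_layer <- function(H, Ahat_list, params, layer,
                                 cache = FALSE) {
  Sk <- Pk <- Hk <- vector("list", 3)
  for (kk in 1:3) {
    W <- params[[paste0("Wk", layer, "_", kk)]]
    if (nrow(W) != ncol(H))
      stop("feature width ", ncol(H), " does not match GCN weights (",
           nrow(W), ")")
    if (nrow(Ahat_list[[kk]]) != nrow(H))
      stop("adjacency size ", nrow(Ahat_list[[kk]]),
           " does not match node count ", nrow(H))
    Sk[[kk]] <- Ahat_list[[kk]] %*% H
    Pk[[kk]] <- Sk[[kk]] %*% W
    Hk[[kk]] <- relu(Pk[[kk]])
  }
  C <- do.call(cbind, Hk)
  Pf <- sweep(C %*% params[[paste0("Wf", layer)]], 2,
              params[[paste0("bf", layer)]], "+")
  out <- relu(Pf)
  if (!cache) return(out)
  list(out = out, Sk = Sk, Pk = Pk, C = C, Pf = Pf)
}

.gcn_backward <- function(dOut, gc, Ahat_list, params, layer, grads) {
  g <- ncol(gc$Pk[[1]])
  dPf <- dOut * (gc$Pf > 0)
  Wf <- params[[paste0("Wf", layer)]]
  grads[[paste0("Wf", layer)]] <- grads[[paste0("Wf", layer)]] +
    crossprod(gc$C, dPf)
  grads[[paste0("bf", layer)]] <- grads[[paste0("bf", layer)]] +
    colSums(dPf)
  dC <- dPf %*% t(Wf)
  dH <- 0
  for (kk in 1:3) {
    dHk <- dC[, (kk - 1) * g + seq_len(g), drop = FALSE]
    dPk <- dHk * (gc$Pk[[kk]] > 0)
    nm <- paste0("Wk", layer, "_", kk)
    grads[[nm]] <- grads[[nm]] + crossprod(gc$Sk[[kk]], dPk)
    # Ahat is symmetric
    dH <- dH + Ahat_list[[kk]] %*% (dPk %*% t(params[[nm]]))
  }
  list(grads = grads, dH = dH)
}

#' Convex residual combination
#'
#' \code{H = lambda * H0 + (1 - lambda) * H_deep} with
#' \code{lambda = logistic(theta)} kept strictly inside (0, 1).
#'
#' @param H0 Dimension-matched initial representation.
#' @param H_deep Output of the last GCN layer.
#' @param theta Unconstrained mixing parameter.
#' @return N x d matrix.
#' @export
residual_combine <- function(H0, H_deep, theta) {
  lam <- stats::plogis(theta)
  lam * H0 + (1 - lam) * H_deep
}

# full forward pass; bundle rows, adjacency stack, parameters.
# train = TRUE applies inverted dropout in the MLP head (masks drawn
# from the current RNG stream).
epigcn_forward <- function(bundle, Ahat_list, params, dims,
                           train = FALSE, cache = FALSE) {
  fc <- fuse_nodes(bundle, params, cache = TRUE)
  X0 <- fc$X0
  ac <- additive_attention(X0, params$Wa, params$Va, cache = TRUE)
  g1 <- multiscale_gcn_layer(X0, Ahat_list, params, 1, cache = TRUE)
  g2 <- multiscale_gcn_layer(g1$out, Ahat_list, params, 2, cache = TRUE)
  H0m <- X0 %*% params$Wres
  lam <- stats::plogis(params$theta)
  Hres <- lam * H0m + (1 - lam) * g2$out
  M <- cbind(ac$out, Hres)

  n_mlp <- attr(params, "n_mlp")
  acts <- list(M)
  pres <- list()
  masks <- list()
  keep <- 1 - dims$dropout
  for (l in seq_len(n_mlp)) {
    A <- acts[[l]]
    if (train && dims$dropout > 0 && l > 1) {
      msk <- matrix(stats::rbinom(length(A), 1, keep) / keep,
                    nrow(A), ncol(A))
      A <- A * msk
      masks[[l]] <- msk
      acts[[l]] <- A
    }
    P <- sweep(A %*% params[[paste0("Wm", l)]], 2,
               params[[paste0("bm", l)]], "+")
    pres[[l]] <- P
    acts[[l + 1]] <- if (l < n_mlp) relu(P) else P
  }
  logit <- drop(pres[[n_mlp]])
  p <- stats::plogis(logit)
  if (!cache) return(p)
  list(p = p, logit = logit, fc = fc, ac = ac, g1 = g1, g2 = g2,
       H0m = H0m, lam = lam, X0 = X0, acts = acts, pres = pres,
       masks = masks)
}

# backward pass from d(logit) (length N); returns gradient list matching
# params
epigcn_backward <- function(dlogit, cc, Ahat_list, params, dims) {
  grads <- lapply(params, function(x) x * 0)
  n_mlp <- attr(params, "n_mlp")
  dP <- matrix(dlogit, ncol = 1)
  for (l in rev(seq_len(n_mlp))) {
    A <- cc$acts[[l]]
    grads[[paste0("Wm", l)]] <- crossprod(A, dP)
    grads[[paste0("bm", l)]] <- colSums(dP)
    dA <- dP %*% t(params[[paste0("Wm", l)]])
    if (length(cc$masks) >= l && !is.null(cc$masks[[l]]))
      dA <- dA * cc$masks[[l]]
    if (l > 1) dP <- dA * (cc$pres[[l - 1]] > 0)
  }
  dM <- dA
  d <- ncol(cc$X0); g <- ncol(cc$g2$out)
  dAtt <- dM[, seq_len(2 * d), drop = FALSE]
  dHres <- dM[, 2 * d + seq_len(g), drop = FALSE]

  # residual mix
  lam <- cc$lam
  dlam <- sum(dHres * (cc$H0m - cc$g2$out))
  grads$theta <- dlam * lam * (1 - lam)
  dH0m <- lam * dHres
  grads$Wres <- crossprod(cc$X0, dH0m)
  dX0 <- dH0m %*% t(params$Wres)
  dG2 <- (1 - lam) * dHres

  gb2 <- .gcn_backward(dG2, cc$g2, Ahat_list, params, 2, grads)
  grads <- gb2$grads
  gb1 <- .gcn_backward(gb2$dH, cc$g1, Ahat_list, params, 1, grads)
  grads <- gb1$grads
  dX0 <- dX0 + gb1$dH

  ab <- .attention_backward(dAtt, cc$ac, params$Wa, params$Va)
  grads$Wa <- grads$Wa + ab$dWa
  grads$Va <- grads$Va + ab$dVa
  dX0 <- dX0 + ab$dX

  .fuse_backward(dX0, cc$fc, params, grads)
}

# normalized adjacency stack for a protein_graph (or raw multi_adj list)
graph_ahat <- function(graph) {
  adjs <- if (inherits(graph, "protein_graph")) graph$multi_adj else graph
  lapply(adjs, normalize_adjacency)
}
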