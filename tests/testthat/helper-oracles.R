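# Brute-force oracles and small shared fixtures.  Every oracle here is
# a deliberately naive re-derivation (double loops, explicit pair
# enumeration) kept independent of the package's implementation paths.

# --- graph oracles -----------------------------------------------------

oracle_sequential <- function(n, d_seq) {
  out <- NULL
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    if (i < j && abs(i - j) > 0 && abs(i - j) < d_seq)
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

oracle_radius <- function(ca, d_r, d_long) {
  n <- nrow(ca)
  out <- NULL
  for (i in 1:n) for (j in 1:n) {
    if (i < j && sqrt(sum((ca[i, ] - ca[j, ])^2)) < d_r &&
        abs(i - j) >= d_long)
      out <- rbind(out, c(i - 1, j - 1))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

oracle_knn <- function(ca, k, d_long) {
  n <- nrow(ca)
  pairs <- NULL
  for (i in 1:n) {
    cand <- setdiff(1:n, i)
    cand <- cand[abs(cand - i) >= d_long]
    if (!length(cand)) next
    dd <- sapply(cand, function(j) sqrt(sum((ca[i, ] - ca[j, ])^2)))
    ord <- cand[order(dd, cand)]
    for (j in ord[seq_len(min(k, length(ord)))])
      pairs <- rbind(pairs, c(min(i, j) - 1, max(i, j) - 1))
  }
  if (is.null(pairs)) return(matrix(integer(0), 0, 2))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  pairs[!duplicated(paste(pairs[, 1], pairs[, 2])), , drop = FALSE]
}

edge_key <- function(e) {
  if (!nrow(e)) return(character(0))
  sort(paste(e[, 1], e[, 2]))
}

# --- metric oracles ----------------------------------------------------

oracle_auc_pairs <- function(scores, labels) {
  ip <- which(labels == 1); in_ <- which(labels == 0)
  tot <- 0
  for (i in ip) for (j in in_) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(ip) * length(in_))
}

oracle_bce <- function(p, y) {
  eps <- 1e-7
  s <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], eps), 1 - eps)
    s <- s - (y[i] * log(pi) + (1 - y[i]) * log(1 - pi))
  }
  s / length(p)
}

oracle_confusion <- function(scores, labels, threshold) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(scores)) {
    call <- scores[i] >= threshold
    if (call && labels[i] == 1) tp <- tp + 1
    if (call && labels[i] == 0) fp <- fp + 1
    if (!call && labels[i] == 1) fn <- fn + 1
    if (!call && labels[i] == 0) tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_best_f1 <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- 0
  for (t in sort(cand)) {
    cm <- oracle_confusion(scores, labels, t)
    pre <- if (cm["tp"] + cm["fp"] > 0) cm["tp"] / (cm["tp"] + cm["fp"]) else 0
    rec <- if (cm["tp"] + cm["fn"] > 0) cm["tp"] / (cm["tp"] + cm["fn"]) else 0
    f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
    best <- max(best, f1)
  }
  unname(best)
}

# --- small model/data fixtures ----------------------------------------

tiny_dims <- function() {
  model_dims(d_seq_emb = 6L, d_if_emb = 5L, d_dssp = 4L, proj_dim = 3L,
             gcn_dim = 4L, mlp_hidden = c(5L, 3L), dropout = 0)
}

tiny_bundle <- function(n, dims, seed = 1) {
  set.seed(seed)
  list(seq_emb = matrix(rnorm(n * dims$d_seq_emb), n),
       if_emb = matrix(rnorm(n * dims$d_if_emb), n),
       dssp_feats = matrix(rnorm(n * dims$d_dssp), n))
}

random_adj_stack <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(rbinom(n * n, 1, p), n)
  A <- 1 * ((A + t(A)) > 0)
  diag(A) <- 0
  list(A1 = khop_adjacency(A, 1), A2 = khop_adjacency(A, 2),
       A3 = khop_adjacency(A, 3))
}

# minimal hand-written PDB text with three residues
three_res_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       3.988   2.839   0.100  1.00  0.00           C",
    "ATOM      6  C   GLY A   2       5.500   2.700   0.200  1.00  0.00           C",
    "ATOM      7  N   VAL A   3       6.100   3.900   0.250  1.00  0.00           N",
    "ATOM      8  CA  VAL A   3       7.500   4.100   0.300  1.00  0.00           C",
    "ATOM      9  C   VAL A   3       8.100   5.500   0.350  1.00  0.00           C",
    "END"), path)
  path
}

# BFS ball oracle for k-hop adjacency
oracle_khop <- function(A, k) {
  n <- nrow(A)
  out <- diag(n)
  for (s in 1:n) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) && d < k) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] == 1)) {
          if (dist[w] > d) { dist[w] <- d; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
    out[s, dist <= k] <- 1
  }
  storage.mode(out) <- "integer"
  out
}
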