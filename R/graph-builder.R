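# Typed residue-graph construction and the multi-scale adjacency stack.
#
# Three undirected edge types over residues 0..n-1 (positional indices):
#   sequential: 0 < |i-j| < d_seq
#   radius:     ||CA_i - CA_j|| < d_r  and  |i-j| >= d_long
#   knn:        j among i's k nearest CAs with |i-j| >= d_long (union
#               over directions)
# The GCN consumes the union graph through k-hop adjacencies A1, A2, A3
# (within <= k hops, self-loops included), so A1 <= A2 <= A3 entrywise.

#' Graph construction parameters
#'
#' @param d_seq Maximum sequence separation (exclusive) for sequential
#'   edges; default 3.
#' @param d_r Spatial cutoff in Angstrom (exclusive) for radius edges;
#'   default 10.
#' @param k Number of nearest neighbours for KNN edges; default 10.
#' @param d_long Minimum sequence separation (inclusive) for radius and
#'   KNN edges; default 5.  Must exceed \code{d_seq} so the two regimes
#'   do not overlap.
#' @return list of class \code{graph_params}.
#' @export
graph_params <- function(d_seq = 3L, d_r = 10, k = 10L, d_long = 5L) {
  stopifnot(d_seq >= 1, d_r > 0, k >= 1, d_long >= 1)
  if (d_long <= d_seq)
    stop("d_long (", d_long, ") must exceed d_seq (", d_seq, ")")
  structure(list(d_seq = as.integer(d_seq), d_r = d_r, k = as.integer(k),
                 d_long = as.integer(d_long)), class = "graph_params")
}

# edge sets are 2-column integer matrices of 0-based pairs with i < j
.edge_mat <- function(i, j) {
  if (!length(i)) return(matrix(integer(0), 0, 2,
                                dimnames = list(NULL, c("i", "j"))))
  cbind(i = pmin(i, j), j = pmax(i, j))
}

.edge_unique <- function(e) {
  if (!nrow(e)) return(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  e[!duplicated(paste(e[, 1], e[, 2])), , drop = FALSE]
}

#' Sequential edges
#'
#' @param n Number of residues.
#' @param d_seq Exclusive upper bound on sequence separation.
#' @return Integer matrix of 0-based undirected pairs (i < j).
#' @export
build_sequential_edges <- function(n, d_seq = 3L) {
  pairs <- list()
  for (off in seq_len(max(0L, d_seq - 1L))) {
    if (off >= n) break
    i <- 0:(n - 1L - off)
    pairs[[off]] <- .edge_mat(i, i + off)
  }
  .edge_unique(do.call(rbind, c(pairs, list(.edge_mat(integer(0),
                                                      integer(0))))))
}

#' Radius edges
#'
#' @param ca_coords N x 3 C-alpha coordinate matrix (Angstrom).
#' @param d_r Exclusive spatial cutoff.
#' @param d_long Inclusive minimum sequence separation.
#' @return Integer matrix of 0-based undirected pairs.
#' @export
build_radius_edges <- function(ca_coords, d_r = 10, d_long = 5L) {
  n <- nrow(ca_coords)
  if (n < 2) return(.edge_mat(integer(0), integer(0)))
  d <- as.matrix(stats::dist(ca_coords))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  hit <- which(upper.tri(d) & d < d_r & sep >= d_long, arr.ind = TRUE)
  .edge_unique(.edge_mat(hit[, 1] - 1L, hit[, 2] - 1L))
}

#' K-nearest-neighbour edges
#'
#' For each residue, candidate neighbours are all residues at sequence
#' separation >= \code{d_long}, ranked by C-alpha distance (ties broken
#' by lower index); directed edges to the top \code{k} are symmetrized
#' into an undirected union.
#'
#' @inheritParams build_radius_edges
#' @param k Neighbours per residue.
#' @return Integer matrix of 0-based undirected pairs.
#' @export
build_knn_edges <- function(ca_coords, k = 10L, d_long = 5L) {
  n <- nrow(ca_coords)
  if (n < 2) return(.edge_mat(integer(0), integer(0)))
  d <- as.matrix(stats::dist(ca_coords))
  out_i <- integer(0); out_j <- integer(0)
  for (i in seq_len(n)) {
    cand <- which(abs(seq_len(n) - i) >= d_long)
    if (!length(cand)) next
    ord <- cand[order(d[i, cand], cand)]
    take <- ord[seq_len(min(k, length(ord)))]
    out_i <- c(out_i, rep(i - 1L, length(take)))
    out_j <- c(out_j, take - 1L)
  }
  .edge_unique(.edge_mat(out_i, out_j))
}

#' Assemble the full typed residue graph
#'
#' @param ca_coords N x 3 C-alpha coordinate matrix.
#' @param params A [graph_params()] object.
#' @return Object of class \code{protein_graph}: \code{n_nodes}, the
#'   three typed edge sets, \code{union_adj} (binary symmetric matrix,
#'   zero diagonal) and \code{multi_adj} (list \code{A1,A2,A3} of k-hop
#'   adjacencies with self-loops).
#' @export
assemble_graph <- function(ca_coords, params = graph_params()) {
  stopifnot(inherits(params, "graph_params"))
  n <- nrow(ca_coords)
  e_seq <- build_sequential_edges(n, params$d_seq)
  e_rad <- build_radius_edges(ca_coords, params$d_r, params$d_long)
  e_knn <- build_knn_edges(ca_coords, params$k, params$d_long)
  adj <- matrix(0L, n, n)
  for (e in list(e_seq, e_rad, e_knn)) {
    if (nrow(e)) {
      adj[e + 1L] <- 1L
      adj[e[, 2:1, drop = FALSE] + 1L] <- 1L
    }
  }
  multi <- lapply(1:3, function(kk) khop_adjacency(adj, kk))
  names(multi) <- c("A1", "A2", "A3")
  structure(list(n_nodes = n, params = params,
                 edges_seq = e_seq, edges_radius = e_rad, edges_knn = e_knn,
                 union_adj = adj, multi_adj = multi),
            class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("protein_graph: ", x$n_nodes, " nodes; edges seq/radius/knn = ",
      nrow(x$edges_seq), "/", nrow(x$edges_radius), "/", nrow(x$edges_knn),
      "; union ", sum(x$union_adj) / 2, "\n", sep = "")
  invisible(x)
}

#' k-hop adjacency with self-loops
#'
#' \code{A_k[i,j] = 1} iff the shortest-path distance between i and j in
#' the (undirected) union graph is at most \code{k}; the diagonal is all
#' ones.
#'
#' @param union_adj Binary symmetric adjacency matrix (zero diagonal
#'   tolerated).
#' @param k Hop radius, a positive integer.
#' @return Binary symmetric matrix with unit diagonal.
#' @export
khop_adjacency <- function(union_adj, k) {
  stopifnot(k >= 1)
  n <- nrow(union_adj)
  reach <- diag(n) + union_adj           # <= 1 hop
  reach <- (reach > 0) * 1L
  if (k > 1) {
    step <- reach
    for (h in seq_len(k - 1L)) step <- ((step %*% reach) > 0) * 1L
    reach <- step
  }
  diag(reach) <- 1L
  storage.mode(reach) <- "integer"
  reach
}

#' Export a graph as an edge-list TSV plus JSON header
#'
#' Writes \code{<path>.tsv} with columns (i, j, type) and
#' \code{<path>.json} with the node count and construction parameters.
#'
#' @param graph A \code{protein_graph}.
#' @param path Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_graph <- function(graph, path) {
  tag <- function(e, t) if (nrow(e))
    data.frame(i = e[, 1], j = e[, 2], type = t) else NULL
  df <- rbind(tag(graph$edges_seq, "seq"),
              tag(graph$edges_radius, "radius"),
              tag(graph$edges_knn, "knn"))
  if (is.null(df)) df <- data.frame(i = integer(0), j = integer(0),
                                    type = character(0))
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_nodes = graph$n_nodes,
                            params = unclass(graph$params)),
                       js, auto_unbox = TRUE)
  invisible(c(tsv, js))
}

# symmetric GCN normalization D^{-1/2} A D^{-1/2}; A must include
# self-loops so isolated nodes have degree 1
normalize_adjacency <- function(A) {
  deg <- rowSums(A)
  deg[deg == 0] <- 1
  A / sqrt(outer(deg, deg))
}
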