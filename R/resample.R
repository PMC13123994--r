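# Hybrid class rebalancing: SMOTE-style minority oversampling plus
# random under-sampling of the majority class to a fixed 1:2
# positive:negative ratio.

#' Hybrid resampling (SMOTE + random under-sampling)
#'
#' Minority (positive) rows are augmented with synthetic samples drawn
#' by uniform interpolation between a positive row and one of its
#' \code{smote_neighbors} nearest positive rows (Euclidean distance);
#' majority rows are then randomly under-sampled so that the final
#' class distribution is exactly \code{1:ratio} (positive:negative),
#' i.e. a positive fraction of \code{1/(1+ratio)}.
#'
#' By default positives are doubled by SMOTE before the negatives are
#' under-sampled to twice the augmented positive count, yielding 33.33%
#' positives.
#'
#' @param features M x d numeric feature matrix.
#' @param labels 0/1 vector of length M.
#' @param ratio Negatives per positive in the output (default 2).
#' @param smote_multiplier Factor by which SMOTE grows the positive
#'   class (default 2: one synthetic sample per original positive).
#' @param smote_neighbors Number of nearest positive neighbours to
#'   interpolate towards (default 5).
#' @param seed RNG seed; the result is deterministic given the seed.
#' @return list with \code{features}, \code{labels}, and
#'   \code{synthetic} (logical marker for SMOTE rows).
#' @export
resample_hybrid <- function(features, labels, ratio = 2,
                            smote_multiplier = 2,
                            smote_neighbors = 5L, seed = 1L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  ip <- which(labels == 1); in_ <- which(labels == 0)
  n_pos <- length(ip)
  if (n_pos < smote_neighbors + 1L)
    stop("too few positives (", n_pos, ") for SMOTE with ",
         smote_neighbors, " neighbours; consider pure under-sampling")
  set.seed(seed)

  # grow positives by the SMOTE multiplier, but never beyond what the
  # available negatives can balance at the requested ratio; a set
  # already at (or below) the target ratio passes through unchanged
  n_pos_target <- min(round(n_pos * smote_multiplier),
                      floor(length(in_) / ratio))
  n_pos_target <- max(n_pos_target, min(n_pos, floor(length(in_) / ratio)))
  n_syn <- max(0L, n_pos_target - n_pos)
  syn <- NULL
  if (n_syn > 0) {
    P <- features[ip, , drop = FALSE]
    D <- as.matrix(stats::dist(P))
    diag(D) <- Inf
    base_idx <- rep_len(seq_len(n_pos), n_syn)
    syn <- matrix(NA_real_, n_syn, ncol(features))
    for (s in seq_len(n_syn)) {
      i <- base_idx[s]
      nb <- order(D[i, ])[seq_len(smote_neighbors)]
      j <- nb[sample.int(smote_neighbors, 1)]
      u <- stats::runif(1)
      syn[s, ] <- P[i, ] + u * (P[j, ] - P[i, ])
    }
  }
  keep_pos <- if (n_pos_target < n_pos)
    sort(ip[sample.int(n_pos, n_pos_target)])
              else ip
  pos_out <- rbind(features[keep_pos, , drop = FALSE], syn)
  n_neg_target <- min(length(in_), round(nrow(pos_out) * ratio))
  keep_neg <- if (n_neg_target < length(in_))
    in_[sample.int(length(in_), n_neg_target)]
              else in_
  out_feat <- rbind(pos_out, features[keep_neg, , drop = FALSE])
  out_lab <- c(rep(1L, nrow(pos_out)), rep(0L, n_neg_target))
  synthetic <- c(rep(FALSE, length(keep_pos)),
                 rep(TRUE, if (is.null(syn)) 0 else nrow(syn)),
                 rep(FALSE, n_neg_target))
  list(features = out_feat, labels = out_lab, synthetic = synthetic)
}
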