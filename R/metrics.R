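# Evaluation metrics and the statistical comparison stack:
# confusion-count metrics, rank-based ROC-AUC, step-wise AUPR,
# F1-maximizing threshold selection, paired DeLong AUC test, and
# stratified bootstrap confidence intervals.

#' Binary cross-entropy loss
#'
#' Mean over residues of \code{-[y log p + (1-y) log(1-p)]}, with
#' probabilities clipped to \[1e-7, 1 - 1e-7\].
#'
#' @param p Predicted probabilities.
#' @param y 0/1 labels.
#' @param w Optional nonnegative weights (renormalized to mean 1 over
#'   their support).
#' @return Scalar loss.
#' @export
bce_loss <- function(p, y, w = NULL) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  if (is.null(w)) return(mean(ll))
  sum(w * ll) / sum(w)
}

#' Threshold-based classification metrics
#'
#' Precision, recall, F1, Matthews correlation coefficient and balanced
#' accuracy from confusion counts.  Zero-division conventions: precision
#' is 0 when no positive calls are made; F1 is 0 when precision + recall
#' is 0; MCC is 0 when any denominator factor vanishes; each BACC term
#' is 0 when its class is absent.
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @return Named list: \code{pre}, \code{rec}, \code{f1}, \code{mcc},
#'   \code{bacc}.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  pre <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fn * fp) / sqrt(den) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  bacc <- (rec + spec) / 2
  list(pre = pre, rec = rec, f1 = f1, mcc = mcc, bacc = bacc)
}

.confusion_counts <- function(scores, labels, threshold) {
  call <- scores >= threshold
  list(tp = sum(call & labels == 1), fp = sum(call & labels == 0),
       fn = sum(!call & labels == 1), tn = sum(!call & labels == 0))
}

#' ROC-AUC via the rank (Mann-Whitney) formulation
#'
#' Ties between a positive and a negative score receive half credit.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels 0/1 labels (both classes must be present).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration of the precision-recall curve (no linear
#' interpolation): sum over descending score thresholds of precision
#' times the recall increment, equivalently average precision.  Tied
#' scores are handled as one block.
#'
#' @inheritParams roc_auc
#' @return AUPR in (0, 1\].
#' @export
aupr <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0) stop("AUPR needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # process tied blocks together
  blk <- cumsum(!duplicated(s))
  tp_blk <- tapply(y, blk, sum)
  n_blk <- tapply(y, blk, length)
  tp <- cumsum(tp_blk)
  np <- cumsum(n_blk)
  prec <- tp / np
  rec <- tp / n1
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' F1-maximizing decision threshold
#'
#' Scans midpoints between consecutive distinct sorted scores, plus
#' -Inf and +Inf.  Among thresholds attaining the maximal F1 the lowest
#' is returned.  If no threshold yields positive F1 (e.g. no positive
#' labels), the threshold is \code{+Inf} (predict all-negative).
#'
#' @inheritParams roc_auc
#' @return list with \code{threshold} and \code{f1}.
#' @export
select_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u, Inf)
  cand <- sort(unique(cand))
  best_f1 <- -1; best_t <- Inf
  for (t in cand) {
    cm <- .confusion_counts(scores, labels, t)
    f1 <- confusion_metrics(cm$tp, cm$fp, cm$fn, cm$tn)$f1
    if (f1 > best_f1 + 1e-12) { best_f1 <- f1; best_t <- t }
  }
  if (best_f1 <= 0) return(list(threshold = Inf, f1 = 0))
  list(threshold = best_t, f1 = best_f1)
}

#' Full evaluation report
#'
#' Confusion counts and all threshold metrics at the given (or
#' F1-optimal) threshold, plus AUC and AUPR; optional stratified
#' bootstrap CIs.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold; if \code{NULL}, selected by
#'   maximizing F1 on these data.
#' @param bootstrap Number of stratified bootstrap replicates for 95%
#'   CIs on AUC/AUPR/F1 (0 = skip).
#' @param seed Seed for the bootstrap.
#' @return list of class \code{epigcn_eval}.
#' @export
evaluate_predictions <- function(scores, labels, threshold = NULL,
                                 bootstrap = 0L, seed = 1L) {
  if (is.null(threshold)) threshold <- select_threshold(scores,
                                                        labels)$threshold
  cm <- .confusion_counts(scores, labels, threshold)
  met <- confusion_metrics(cm$tp, cm$fp, cm$fn, cm$tn)
  rep <- c(cm, threshold = threshold, met,
           list(auc = roc_auc(scores, labels),
                aupr = aupr(scores, labels)))
  if (bootstrap > 0) {
    rep$ci <- list(
      auc = stratified_bootstrap(roc_auc, scores, labels,
                                 B = bootstrap, seed = seed)$ci,
      aupr = stratified_bootstrap(aupr, scores, labels,
                                  B = bootstrap, seed = seed + 1L)$ci,
      f1 = stratified_bootstrap(function(s, y) {
        c2 <- .confusion_counts(s, y, threshold)
        confusion_metrics(c2$tp, c2$fp, c2$fn, c2$tn)$f1
      }, scores, labels, B = bootstrap, seed = seed + 2L)$ci
    )
  }
  structure(rep, class = "epigcn_eval")
}

#' @export
print.epigcn_eval <- function(x, ...) {
  cat(sprintf(
    "threshold %.4g | TP %d FP %d FN %d TN %d\n", x$threshold, x$tp,
    x$fp, x$fn, x$tn))
  cat(sprintf(
    "Pre %.4f Rec %.4f F1 %.4f MCC %.4f BACC %.4f AUC %.4f AUPR %.4f\n",
    x$pre, x$rec, x$f1, x$mcc, x$bacc, x$auc, x$aupr))
  if (!is.null(x$ci))
    for (m in names(x$ci))
      cat(sprintf("  95%% CI %s: [%.4f, %.4f]\n", m, x$ci[[m]][1],
                  x$ci[[m]][2]))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors over the same labeled
#' instances using the DeLong placement-value covariance estimate and a
#' two-sided normal reference.
#'
#' @param scores_a,scores_b Score vectors from the two models.
#' @param labels Shared 0/1 labels.
#' @return list: \code{auc_a}, \code{auc_b}, \code{delta} (a - b),
#'   \code{se}, \code{z}, \code{p}.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  pos <- labels == 1
  m <- sum(pos); n <- sum(!pos)
  if (m < 2 || n < 2) stop("DeLong test needs >= 2 of each class")
  placements <- function(s) {
    x <- s[pos]; y <- s[!pos]
    # V10[i]: fraction of negatives ranked below positive i (ties 1/2)
    v10 <- vapply(x, function(xi)
      (sum(xi > y) + 0.5 * sum(xi == y)) / n, numeric(1))
    v01 <- vapply(y, function(yj)
      (sum(x > yj) + 0.5 * sum(x == yj)) / m, numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  delta <- pa$auc - pb$auc
  var_d <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (var_d <= 0) {
    # identical (or perfectly correlated) scores: no evidence of a
    # difference
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, se = 0,
                z = 0, p = 1))
  }
  z <- delta / sqrt(var_d)
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, se = sqrt(var_d),
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Stratified bootstrap for a score-based metric
#'
#' Resamples positives and negatives separately with replacement,
#' recomputes the metric, and returns the percentile 95% CI.  If a
#' reference value is supplied, a two-sided bootstrap p-value for
#' \code{metric == reference} is computed from the centred bootstrap
#' distribution.
#'
#' @param metric_fn function(scores, labels) -> scalar.
#' @param scores,labels Data.
#' @param B Number of replicates (default 2000).
#' @param seed RNG seed.
#' @param reference Optional null value for the p-value.
#' @param conf Confidence level (default 0.95).
#' @return list: \code{point}, \code{ci} (length 2), \code{p} (or
#'   \code{NA}), \code{replicates}.
#' @export
stratified_bootstrap <- function(metric_fn, scores, labels, B = 2000L,
                                 seed = 1L, reference = NULL,
                                 conf = 0.95) {
  set.seed(seed)
  ip <- which(labels == 1); in_ <- which(labels == 0)
  point <- metric_fn(scores, labels)
  reps <- numeric(B)
  for (b in seq_len(B)) {
    idx <- c(ip[sample.int(length(ip), length(ip), replace = TRUE)],
             in_[sample.int(length(in_), length(in_), replace = TRUE)])
    reps[b] <- metric_fn(scores[idx], labels[idx])
  }
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7,
                               na.rm = TRUE))
  p <- NA_real_
  if (!is.null(reference)) {
    centred <- reps - point + reference
    p <- min(1, 2 * min(mean(centred >= point), mean(centred <= point)) +
               1 / B)
  }
  list(point = point, ci = ci, p = p, replicates = reps)
}

#' Paired comparison of two models' scores
#'
#' DeLong test on AUC plus stratified-bootstrap deltas and CIs for the
#' threshold metrics, mirroring the evaluation layout used for model
#' comparisons.
#'
#' @param scores_a,scores_b Score vectors.
#' @param labels 0/1 labels.
#' @param B Bootstrap replicates.
#' @param seed Seed.
#' @return list with \code{delong} and per-metric bootstrap summaries.
#' @export
compare_models <- function(scores_a, scores_b, labels, B = 2000L,
                           seed = 1L) {
  dl <- delong_test(scores_a, scores_b, labels)
  ta <- select_threshold(scores_a, labels)$threshold
  tb <- select_threshold(scores_b, labels)$threshold
  # paired bootstrap: resample instance indices (stratified), evaluate
  # both models on the same replicate
  set.seed(seed)
  ip <- which(labels == 1); in_ <- which(labels == 0)
  metr <- function(s, y, t) {
    cm <- .confusion_counts(s, y, t)
    m <- confusion_metrics(cm$tp, cm$fp, cm$fn, cm$tn)
    c(f1 = m$f1, mcc = m$mcc, bacc = m$bacc)
  }
  point <- metr(scores_a, labels, ta) - metr(scores_b, labels, tb)
  reps <- matrix(NA_real_, B, 3, dimnames = list(NULL, names(point)))
  for (b in seq_len(B)) {
    idx <- c(ip[sample.int(length(ip), length(ip), replace = TRUE)],
             in_[sample.int(length(in_), length(in_), replace = TRUE)])
    reps[b, ] <- metr(scores_a[idx], labels[idx], ta) -
      metr(scores_b[idx], labels[idx], tb)
  }
  out <- list(delong = dl)
  for (m in colnames(reps)) {
    r <- reps[, m]
    p <- min(1, 2 * min(mean(r >= 0), mean(r <= 0)) + 1 / B)
    out[[m]] <- list(delta = unname(point[m]),
                     ci = unname(stats::quantile(r, c(0.025, 0.975))),
                     p = p)
  }
  out
}
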