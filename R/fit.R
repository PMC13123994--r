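# Model fitting: Adam training of the dual-branch network on
# whole-protein graphs, with per-epoch class rebalancing in the loss,
# early stopping on validation AUPR, and F1-maximizing threshold
# selection.  The fitted object is a classed S3 model with the usual
# print / summary / coef / predict / plot methods.

# Adam optimizer state and update
.adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# per-epoch loss weights implementing 1:ratio rebalancing by random
# under-sampling of negative residues (positives always kept)
.loss_weights <- function(labels, ratio) {
  w <- numeric(length(labels))
  ip <- which(labels == 1); in_ <- which(labels == 0)
  if (!length(ip) || is.null(ratio) || !is.finite(ratio)) {
    w[] <- 1
    return(w)
  }
  w[ip] <- 1
  n_keep <- min(length(in_), round(length(ip) * ratio))
  if (n_keep > 0)
    w[if (n_keep < length(in_)) in_[sample.int(length(in_), n_keep)]
      else in_] <- 1
  w
}

#' Fit the dual-branch epitope model
#'
#' Trains the additive-attention + multi-scale-GCN network with binary
#' cross-entropy and Adam.  One training batch is one whole-protein
#' graph.  Class imbalance is handled per epoch by random
#' under-sampling of negative residues in the loss to a 1:ratio
#' positive:negative mix.  A protein-level validation split drives
#' early stopping (on validation AUPR) and the F1-maximizing decision
#' threshold stored in the fit.
#'
#' @param proteins list of protein entries as produced by
#'   [make_dataset()]: each with \code{bundle} (seq_emb / if_emb /
#'   dssp_feats), \code{graph} and \code{labels}.
#' @param dims A [model_dims()] object; widths must match the bundles.
#' @param epochs Maximum training epochs (default 100).
#' @param lr Adam learning rate (default 1e-3).
#' @param patience Early-stopping patience on validation AUPR (default
#'   10 epochs).
#' @param val_fraction Fraction of proteins held out for validation
#'   (default 0.2); set 0 to train on everything (no early stopping).
#' @param resample_ratio Negatives per positive in the per-epoch loss
#'   rebalancing (default 2; \code{Inf} disables rebalancing).
#' @param seed Seed controlling initialization, shuffling, dropout and
#'   under-sampling.
#' @param verbose Print per-epoch progress?
#' @return Object of class \code{epigcn}: parameters, dims, loss trace,
#'   validation metrics, decision threshold and configuration.
#' @export
epigcn_fit <- function(proteins, dims = NULL, epochs = 100L, lr = 1e-3,
                       patience = 10L, val_fraction = 0.2,
                       resample_ratio = 2, seed = 1L, verbose = FALSE) {
  stopifnot(length(proteins) >= 1)
  if (is.null(dims)) {
    b <- proteins[[1]]$bundle
    dims <- model_dims(d_seq_emb = ncol(b$seq_emb),
                       d_if_emb = ncol(b$if_emb),
                       d_dssp = ncol(b$dssp_feats))
  }
  set.seed(seed)
  params <- init_params(dims, seed = seed)
  state <- .adam_init(params)

  n <- length(proteins)
  n_val <- if (val_fraction > 0 && n >= 5) max(1L,
    round(val_fraction * n)) else 0L
  perm <- sample(n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)

  ahat <- lapply(proteins, function(e) graph_ahat(e$graph))
  loss_trace <- numeric(0)
  val_trace <- numeric(0)
  best <- list(params = params, aupr = -Inf, epoch = 0L)
  wait <- 0L

  val_scores <- function(pp) {
    s <- list(); y <- list()
    for (i in val_idx) {
      s[[length(s) + 1]] <- epigcn_forward(proteins[[i]]$bundle,
                                           ahat[[i]], pp, dims)
      y[[length(y) + 1]] <- proteins[[i]]$labels
    }
    list(scores = unlist(s), labels = unlist(y))
  }

  for (ep in seq_len(epochs)) {
    ep_loss <- 0
    for (i in tr_idx[sample.int(length(tr_idx))]) {
      e <- proteins[[i]]
      w <- .loss_weights(e$labels, resample_ratio)
      cc <- epigcn_forward(e$bundle, ahat[[i]], params, dims,
                           train = TRUE, cache = TRUE)
      ep_loss <- ep_loss + bce_loss(cc$p, e$labels, w)
      sw <- sum(w)
      dlogit <- w * (cc$p - e$labels) / sw
      grads <- epigcn_backward(dlogit, cc, ahat[[i]], params, dims)
      upd <- .adam_step(params, grads, state, lr = lr)
      params <- upd$params; state <- upd$state
    }
    loss_trace[ep] <- ep_loss / length(tr_idx)

    if (n_val > 0) {
      vs <- val_scores(params)
      v_aupr <- if (sum(vs$labels) > 0) aupr(vs$scores, vs$labels) else 0
      val_trace[ep] <- v_aupr
      if (v_aupr > best$aupr + 1e-9) {
        best <- list(params = params, aupr = v_aupr, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) {
          if (verbose) message("early stop at epoch ", ep)
          break
        }
      }
    }
    if (verbose)
      message(sprintf("epoch %d: loss %.4f%s", ep, loss_trace[ep],
                      if (n_val > 0) sprintf(" val AUPR %.4f",
                                             val_trace[ep]) else ""))
  }
  if (n_val > 0 && best$aupr > -Inf) params <- best$params

  threshold <- 0.5
  val_eval <- NULL
  if (n_val > 0) {
    vs <- val_scores(params)
    if (sum(vs$labels) > 0 && sum(vs$labels == 0) > 0) {
      threshold <- select_threshold(vs$scores, vs$labels)$threshold
      val_eval <- evaluate_predictions(vs$scores, vs$labels,
                                       threshold = threshold)
    }
  }

  structure(list(
    params = params, dims = dims, threshold = threshold,
    loss_trace = loss_trace, val_trace = val_trace,
    val_eval = val_eval, val_idx = val_idx,
    config = list(epochs = epochs, lr = lr, patience = patience,
                  val_fraction = val_fraction,
                  resample_ratio = resample_ratio, seed = seed),
    n_proteins = n), class = "epigcn")
}

#' Predict epitope probabilities for new proteins
#'
#' @param object A fitted \code{epigcn} model.
#' @param newdata One protein entry (with \code{bundle} and
#'   \code{graph}) or a list of entries.
#' @param type \code{"prob"} (default) for probabilities, \code{"class"}
#'   for 0/1 calls at the fitted threshold.
#' @param ... Unused.
#' @return Numeric vector per protein (list if several proteins were
#'   supplied).
#' @export
predict.epigcn <- function(object, newdata, type = c("prob", "class"),
                           ...) {
  type <- match.arg(type)
  single <- !is.null(newdata$bundle)
  entries <- if (single) list(newdata) else newdata
  out <- lapply(entries, function(e) {
    p <- epigcn_forward(e$bundle, graph_ahat(e$graph), object$params,
                        object$dims)
    if (type == "class") as.integer(p >= object$threshold) else p
  })
  if (single) out[[1]] else out
}

#' @export
print.epigcn <- function(x, ...) {
  cat("Dual-branch epitope model (additive attention + multi-scale GCN)\n")
  cat(sprintf("  fused width %d (proj %d x 3), GCN width %d, lambda %.3f\n",
              x$dims$d_fused, x$dims$proj_dim, x$dims$gcn_dim,
              stats::plogis(x$params$theta)))
  cat(sprintf("  trained %d epochs on %d proteins; threshold %.4g\n",
              length(x$loss_trace), x$n_proteins, x$threshold))
  if (!is.null(x$val_eval))
    cat(sprintf("  validation: AUC %.4f AUPR %.4f F1 %.4f\n",
                x$val_eval$auc, x$val_eval$aupr, x$val_eval$f1))
  invisible(x)
}

#' @export
summary.epigcn <- function(object, ...) {
  np <- sum(vapply(object$params, length, numeric(1)))
  cat(sprintf("epigcn fit: %d parameters\n", np))
  print(object)
  cat(sprintf("  final training loss %.4f (initial %.4f)\n",
              utils::tail(object$loss_trace, 1), object$loss_trace[1]))
  invisible(object)
}

#' Extract model coefficients
#'
#' @param object A fitted \code{epigcn} model.
#' @param ... Unused.
#' @return Named list of parameter tensors, plus the residual-mix
#'   \code{lambda} on the probability scale.
#' @export
coef.epigcn <- function(object, ...) {
  c(object$params, list(lambda = stats::plogis(object$params$theta)))
}

#' Plot the training trace of a fitted model
#'
#' @param x A fitted \code{epigcn} model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.epigcn <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "training BCE loss", ...)
  if (length(x$val_trace)) {
    op <- graphics::par(new = TRUE)
    on.exit(graphics::par(op))
    graphics::plot(seq_along(x$val_trace), x$val_trace, type = "l",
                   col = "firebrick", axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = "firebrick")
    graphics::mtext("validation AUPR", 4, line = -1.2,
                    col = "firebrick", cex = 0.8)
  }
  invisible(x)
}

#' Protein-level k-fold split
#'
#' Disjoint folds covering all ids, with sizes differing by at most one.
#'
#' @param protein_ids Character or integer vector of ids.
#' @param folds Number of folds (default 10).
#' @param seed Shuffling seed.
#' @return list of \code{folds} lists, each with \code{train} and
#'   \code{val} id vectors.
#' @export
kfold_split <- function(protein_ids, folds = 10L, seed = 1L) {
  stopifnot(folds >= 2, length(protein_ids) >= folds)
  set.seed(seed)
  perm <- sample(protein_ids)
  grp <- rep(seq_len(folds), length.out = length(perm))
  grp <- sort(grp)                 # sizes differ by <= 1, contiguous
  lapply(seq_len(folds), function(f)
    list(train = perm[grp != f], val = perm[grp == f]))
}

#' Cross-validated training
#'
#' Trains one model per fold and reports per-fold validation metrics.
#' Model selection: \code{"validation"} (default) picks the fold model
#' with the best fold-validation AUC (leak-free); \code{"external"}
#' picks the fold model with the highest AUC on a supplied external
#' test set, a protocol that is optimistic because the test set then
#' participates in model selection.
#'
#' @param proteins Protein entries (see [epigcn_fit()]).
#' @param folds Number of folds (default 10).
#' @param selection \code{"validation"} or \code{"external"}.
#' @param test_proteins External test entries (required for
#'   \code{"external"} selection).
#' @param seed Seed (fold assignment and per-fold training).
#' @param ... Passed to [epigcn_fit()].
#' @return list of class \code{epigcn_cv}: \code{fold_metrics}
#'   (data.frame), \code{best_fold}, \code{model} (the selected fit),
#'   \code{selection}.
#' @export
epigcn_cv <- function(proteins, folds = 10L,
                      selection = c("validation", "external"),
                      test_proteins = NULL, seed = 1L, ...) {
  selection <- match.arg(selection)
  if (selection == "external" && is.null(test_proteins))
    stop("external selection needs test_proteins")
  splits <- kfold_split(seq_along(proteins), folds = folds, seed = seed)
  fits <- vector("list", folds)
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- proteins[splits[[f]]$train]
    va <- proteins[splits[[f]]$val]
    fit <- epigcn_fit(tr, seed = seed + f, val_fraction = 0.2, ...)
    sc <- unlist(predict(fit, va))
    yy <- unlist(lapply(va, `[[`, "labels"))
    ev <- evaluate_predictions(sc, yy, threshold = fit$threshold)
    crit <- if (selection == "external") {
      st <- unlist(predict(fit, test_proteins))
      yt <- unlist(lapply(test_proteins, `[[`, "labels"))
      roc_auc(st, yt)
    } else ev$auc
    fits[[f]] <- fit
    rows[[f]] <- data.frame(fold = f, auc = ev$auc, aupr = ev$aupr,
                            f1 = ev$f1, mcc = ev$mcc, bacc = ev$bacc,
                            selection_auc = crit)
  }
  fm <- do.call(rbind, rows)
  best <- which.max(fm$selection_auc)
  structure(list(fold_metrics = fm, best_fold = best,
                 model = fits[[best]], selection = selection),
            class = "epigcn_cv")
}

#' @export
print.epigcn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s selection); best fold %d\n",
              nrow(x$fold_metrics), x$selection, x$best_fold))
  print(round(colMeans(x$fold_metrics[, c("auc", "aupr", "f1", "mcc",
                                          "bacc")]), 4))
  invisible(x)
}
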