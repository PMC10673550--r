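#' Area under the ROC curve from classifier scores
#'
#' Rank-based (Wilcoxon) AUC, equivalent to the trapezoidal rule on the
#' empirical ROC curve with tie handling by average ranks. Invariant to
#' monotone transforms of the scores.
#'
#' @param scores numeric classifier scores (higher = more positive-like).
#' @param labels class labels aligned with `scores`.
#' @param positive the positive class (default `"TUMOR"` when present).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels,
                      positive = if ("TUMOR" %in% labels) "TUMOR"
                                 else sort(unique(labels))[2]) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Train one backend and score a held-out set. Backends:
#   RF    - randomForest, 500 trees, positive-class probability
#   SVM   - e1071 linear kernel, default cost, decision values
#   PLSDA - 2-component NIPALS PLS1 on +/-1 response, predicted score
.fit_and_score <- function(Xtr, ytr, Xte, method, positive) {
  yf <- factor(ytr, levels = sort(unique(ytr)))
  if (method == "RF") {
    fit <- randomForest::randomForest(Xtr, yf, ntree = 500)
    unname(stats::predict(fit, Xte, type = "prob")[, positive])
  } else if (method == "SVM") {
    fit <- e1071::svm(Xtr, yf, kernel = "linear", scale = FALSE)
    dv <- attr(stats::predict(fit, Xte, decision.values = TRUE),
               "decision.values")
    cls <- strsplit(colnames(dv), "/")[[1]]
    if (cls[1] == positive) drop(dv) else -drop(dv)
  } else if (method == "PLSDA") {
    y <- ifelse(ytr == positive, 1, -1)
    mu <- colMeans(Xtr); my <- mean(y)
    Xc <- sweep(Xtr, 2, mu); yc <- y - my
    Xte_c <- sweep(Xte, 2, mu)
    score <- rep(my, nrow(Xte))
    for (a in 1:2) {
      w <- drop(crossprod(Xc, yc)); nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      t_ <- drop(Xc %*% w)
      p <- drop(crossprod(Xc, t_)) / drop(crossprod(t_))
      cc <- drop(crossprod(yc, t_)) / drop(crossprod(t_))
      t_new <- drop(Xte_c %*% w)
      score <- score + t_new * cc
      Xc <- Xc - tcrossprod(t_, p)
      Xte_c <- Xte_c - tcrossprod(t_new, p)
      yc <- yc - t_ * cc
    }
    score
  } else {
    stop("unknown method: ", method)
  }
}

#' Monte-Carlo cross-validated multivariate ROC
#'
#' Repeated stratified random splits (train fraction per class, default
#' 2/3); the held-out samples of each repeat are scored by the chosen
#' backend and summarized as one AUC per repeat (trapezoidal/rank rule).
#' The reported AUC is the mean over repeats with a percentile interval
#' from the repeat distribution.
#'
#' @param z z-scored matrix, analytes x samples.
#' @param labels two-class sample labels.
#' @param method `"RF"`, `"SVM"` or `"PLSDA"`.
#' @param features optional subset of analyte ids to use (default all).
#' @param n_repeats Monte-Carlo repeats (default 50).
#' @param train_fraction per-class training fraction (default 2/3).
#' @param seed RNG seed (splits are identical across methods at a fixed
#'   seed).
#' @param positive positive class label.
#' @return A `roc_result`: `auc` (mean), `auc_ci` (2.5/97.5 percentiles),
#'   `repeats` (per-repeat AUCs), `method`, `features`, `seed`.
#' @export
mccv_auc <- function(z, labels, method = c("RF", "SVM", "PLSDA"),
                     features = NULL, n_repeats = 50, train_fraction = 2 / 3,
                     seed = 1,
                     positive = if ("TUMOR" %in% labels) "TUMOR"
                                else sort(unique(labels))[2]) {
  method <- match.arg(method)
  labels <- as.character(labels)
  if (length(unique(labels)) != 2) stop("labels must have two classes")
  if (!is.null(features)) {
    missing_f <- setdiff(features, rownames(z))
    if (length(missing_f) > 0) stop("unknown features: ",
                                    paste(missing_f, collapse = ", "))
    z <- z[features, , drop = FALSE]
  }
  if (nrow(z) < 1) stop("need >= 1 feature")
  X <- t(z)
  aucs <- numeric(n_repeats)
  local_seed(seed, {
    for (r in seq_len(n_repeats)) {
      repeat {
        # stratified draw; redrawn (and it would be logged) if a split ever
        # came out single-class, which stratification rules out
        tr <- logical(length(labels))
        for (g in unique(labels)) {
          idx <- which(labels == g)
          ntr <- min(length(idx) - 1L, max(1L, round(train_fraction * length(idx))))
          tr[sample(idx, ntr)] <- TRUE
        }
        if (length(unique(labels[tr])) == 2 &&
            length(unique(labels[!tr])) == 2) break
        message("single-class split redrawn")
      }
      sc <- .fit_and_score(X[tr, , drop = FALSE], labels[tr],
                           X[!tr, , drop = FALSE], method, positive)
      aucs[r] <- auc_score(sc, labels[!tr], positive)
    }
  })
  structure(
    list(method = method, auc = mean(aucs),
         auc_ci = unname(stats::quantile(aucs, c(0.025, 0.975))),
         repeats = aucs, n_repeats = n_repeats,
         features = if (is.null(features)) rownames(z) else features,
         train_fraction = train_fraction, seed = seed),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("%s MCCV ROC: AUC = %.3f [%.3f, %.3f] over %d repeats (%d features)\n",
              x$method, x$auc, x$auc_ci[1], x$auc_ci[2], x$n_repeats,
              length(x$features)))
  invisible(x)
}

#' Feature-subset multivariate ROC models
#'
#' Builds one MCCV ROC model per requested panel size. By default the
#' feature ranking is nested: within every repeat, features are ranked on
#' the training samples only (by univariate |AUC - 0.5|) and the top `k`
#' are used, avoiding selection leakage into the held-out AUC. With
#' `nested = FALSE` a fixed ranking (given or computed globally) is used —
#' the optimistic variant.
#'
#' @inheritParams mccv_auc
#' @param sizes integer vector of panel sizes (all >= 1, <= n features).
#' @param ranked_features optional fixed ranking (feature ids, best first);
#'   implies the global ranking when `nested = FALSE`.
#' @param nested rank within training folds (default TRUE).
#' @return A list of `roc_result`, one per size, named by size.
#' @export
feature_subset_models <- function(z, labels, sizes, method = "RF",
                                  ranked_features = NULL, nested = TRUE,
                                  n_repeats = 50, train_fraction = 2 / 3,
                                  seed = 1,
                                  positive = if ("TUMOR" %in% labels) "TUMOR"
                                             else sort(unique(labels))[2]) {
  labels <- as.character(labels)
  if (any(sizes < 1)) stop("sizes must be >= 1")
  if (any(sizes > nrow(z))) stop("size exceeds available features")
  rank_features <- function(zz, ll) {
    sep <- apply(zz, 1, function(x) abs(auc_score(x, ll, positive) - 0.5))
    rownames(zz)[order(sep, decreasing = TRUE)]
  }
  if (!nested) {
    if (is.null(ranked_features)) ranked_features <- rank_features(z, labels)
    out <- lapply(sizes, function(k) {
      mccv_auc(z, labels, method, features = ranked_features[seq_len(k)],
               n_repeats = n_repeats, train_fraction = train_fraction,
               seed = seed, positive = positive)
    })
    names(out) <- sizes
    return(out)
  }
  X <- t(z)
  results <- lapply(sizes, function(k) numeric(n_repeats))
  local_seed(seed, {
    for (r in seq_len(n_repeats)) {
      tr <- logical(length(labels))
      for (g in unique(labels)) {
        idx <- which(labels == g)
        ntr <- min(length(idx) - 1L, max(1L, round(train_fraction * length(idx))))
        tr[sample(idx, ntr)] <- TRUE
      }
      ranking <- rank_features(z[, tr, drop = FALSE], labels[tr])
      for (si in seq_along(sizes)) {
        feats <- ranking[seq_len(sizes[si])]
        sc <- .fit_and_score(X[tr, feats, drop = FALSE], labels[tr],
                             X[!tr, feats, drop = FALSE], method, positive)
        results[[si]][r] <- auc_score(sc, labels[!tr], positive)
      }
    }
  })
  out <- lapply(seq_along(sizes), function(si) {
    aucs <- results[[si]]
    structure(
      list(method = method, auc = mean(aucs),
           auc_ci = unname(stats::quantile(aucs, c(0.025, 0.975))),
           repeats = aucs, n_repeats = n_repeats,
           features = paste0("top-", sizes[si], " (nested)"),
           train_fraction = train_fraction, seed = seed),
      class = "roc_result"
    )
  })
  names(out) <- sizes
  out
}
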