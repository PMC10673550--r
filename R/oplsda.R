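# NIPALS-style OPLS-DA for a two-class response.
#
# The response is coded +1 (positive class) / -1, centered. Orthogonal
# components remove Y-uncorrelated X variation before a single predictive
# component is extracted (Trygg-Wold O-PLS):
#   w  = X'y / y'y (normalized), t = Xw, p = X't / t't
#   wo = p - (w'p) w (normalized), to = X wo, po = X'to / to'to
#   X <- X - to po'
# After filtering, the predictive component gives scores t, loading p and
# regression coefficient c = y't / t't; R2Y = 1 - ||y - tc||^2 / ||y||^2.

.opls_core <- function(X, y, n_orthogonal) {
  W_o <- NULL; P_o <- NULL; T_o <- NULL; ss_o <- numeric(0)
  for (k in seq_len(n_orthogonal)) {
    w <- drop(crossprod(X, y)) / drop(crossprod(y))
    w <- w / sqrt(sum(w^2))
    t_ <- drop(X %*% w)
    p <- drop(crossprod(X, t_)) / drop(crossprod(t_))
    w_o <- p - drop(crossprod(w, p)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break
    w_o <- w_o / nw
    t_o <- drop(X %*% w_o)
    p_o <- drop(crossprod(X, t_o)) / drop(crossprod(t_o))
    X <- X - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
    c_o <- drop(crossprod(y, t_o)) / drop(crossprod(t_o))
    ss_o <- c(ss_o, c_o^2 * sum(t_o^2))  # Y variation carried by t_o (~0)
  }
  w <- drop(crossprod(X, y)) / drop(crossprod(y))
  w <- w / sqrt(sum(w^2))
  t_ <- drop(X %*% w)
  p <- drop(crossprod(X, t_)) / drop(crossprod(t_))
  c_ <- drop(crossprod(y, t_)) / drop(crossprod(t_))
  list(w = w, p = p, c = c_, t = t_, W_o = W_o, P_o = P_o, T_o = T_o,
       ss_o = ss_o, ss_pred_y = c_^2 * sum(t_^2))
}

.opls_predict_scores <- function(core, Xnew) {
  if (!is.null(core$W_o)) {
    for (k in seq_len(ncol(core$W_o))) {
      t_o <- drop(Xnew %*% core$W_o[, k])
      Xnew <- Xnew - tcrossprod(t_o, core$P_o[, k])
    }
  }
  drop(Xnew %*% core$w) * core$c
}

# Stratified fold assignment, deterministic given seed.
.stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  local_seed(seed, {
    for (g in unique(labels)) {
      idx <- which(labels == g)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Fit an OPLS-DA model with VIP scores
#'
#' Orthogonal partial least squares discriminant analysis on a z-scored
#' analyte-by-sample matrix, with one predictive component plus
#' `n_orthogonal` orthogonal components (default 1) and Q2 estimated by
#' stratified 7-fold cross-validation. The fit is deterministic given the
#' input and `seed` (used only for the CV fold assignment).
#'
#' VIP is computed over the predictive plus orthogonal components:
#' `VIP_j = sqrt( p * sum_a SS_a w_aj^2 / sum_a SS_a )` with each
#' component weighted by the Y variation its scores explain (orthogonal
#' components are included but carry near-zero Y variation by
#' construction, so discriminant-relevant weights dominate). Weight
#' vectors are unit-norm, hence `mean(VIP^2) = 1` exactly.
#'
#' @param z z-scored matrix, analytes in rows, samples in columns (no
#'   constant analytes).
#' @param labels two-class sample labels aligned with columns.
#' @param n_orthogonal number of orthogonal components (default 1).
#' @param cv logical; estimate Q2 by cross-validation (default TRUE).
#' @param cv_folds folds (default 7).
#' @param seed fold-assignment seed.
#' @param positive label treated as +1 (default `"TUMOR"` when present).
#' @return An `opls_model`: scores (`t`, `t_ortho`), loadings, weights,
#'   `r2y`, `q2`, `vip` (named by analyte), and fit metadata.
#' @export
fit_oplsda <- function(z, labels, n_orthogonal = 1, cv = TRUE, cv_folds = 7,
                       seed = 1,
                       positive = if ("TUMOR" %in% labels) "TUMOR"
                                  else sort(unique(labels))[2]) {
  stopifnot(is.matrix(z))
  labels <- as.character(labels)
  if (length(unique(labels)) != 2) stop("labels must have exactly two classes")
  if (min(table(labels)) < 2) stop("need >= 2 samples per class")
  if (any(is.na(z))) stop("z matrix must be complete (impute or drop first)")
  rs <- apply(z, 1, stats::sd)
  if (any(rs == 0)) stop("constant analytes must be excluded before OPLS-DA")
  X <- t(z)                              # samples x analytes
  y <- ifelse(labels == positive, 1, -1)
  y <- y - mean(y)
  core <- .opls_core(X, y, n_orthogonal)
  y_hat <- core$t * core$c
  r2y <- 1 - sum((y - y_hat)^2) / sum(y^2)
  q2 <- NA_real_
  if (cv) {
    folds <- .stratified_folds(labels, cv_folds, seed)
    press <- 0
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      mu <- colMeans(Xtr); my <- mean(ytr)
      core_f <- .opls_core(sweep(Xtr, 2, mu), ytr - my, n_orthogonal)
      pred <- .opls_predict_scores(core_f, sweep(X[!tr, , drop = FALSE], 2, mu)) + my
      press <- press + sum((y[!tr] - pred)^2)
    }
    q2 <- 1 - press / sum(y^2)
  }
  # VIP over predictive + orthogonal variation
  W <- cbind(core$w, core$W_o)
  ss <- c(core$ss_pred_y, core$ss_o)
  vip <- sqrt(nrow(z) * drop(W^2 %*% ss) / sum(ss))
  names(vip) <- rownames(z)
  structure(
    list(
      scores = core$t, ortho_scores = core$T_o,
      weights = core$w, loadings = core$p, c = core$c,
      ortho_weights = core$W_o, ortho_loadings = core$P_o,
      r2y = r2y, q2 = q2, vip = vip,
      n_orthogonal = n_orthogonal, positive = positive,
      labels = labels, cv_folds = cv_folds, seed = seed
    ),
    class = "opls_model"
  )
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("OPLS-DA: 1 predictive + %d orthogonal component(s); R2Y = %.3f, Q2 = %s\n",
              x$n_orthogonal, x$r2y,
              ifelse(is.na(x$q2), "not computed", sprintf("%.3f", x$q2))))
  invisible(x)
}

#' Predict OPLS-DA class scores for new samples
#'
#' @param object an `opls_model`.
#' @param newdata z matrix, analytes x samples, same analytes as the fit.
#' @param ... unused.
#' @return Numeric class scores (positive values lean to the positive class).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  core <- list(w = object$weights, c = object$c,
               W_o = object$ortho_weights, P_o = object$ortho_loadings)
  .opls_predict_scores(core, t(newdata))
}

#' Permutation test of an OPLS-DA model
#'
#' Refits the model under `n_perm` random label permutations and records
#' the permuted R2Y and Q2. The model passes when every permuted R2Y and
#' every permuted Q2 lie below the original values (no-overfit check).
#'
#' @param model the fitted `opls_model`.
#' @param z the z matrix the model was fitted on.
#' @param labels the original labels.
#' @param n_perm permutations (default 200).
#' @param seed RNG seed for the permutations.
#' @return A list: `pass`, `r2y_perm`, `q2_perm`, `r2y`, `q2`, `n_perm`.
#' @export
permutation_test <- function(model, z, labels, n_perm = 200, seed = 1) {
  stopifnot(inherits(model, "opls_model"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  labels <- as.character(labels)
  r2y_perm <- numeric(n_perm); q2_perm <- numeric(n_perm)
  local_seed(seed, {
    for (i in seq_len(n_perm)) {
      perm <- sample(labels)
      m <- fit_oplsda(z, perm, n_orthogonal = model$n_orthogonal,
                      cv = !is.na(model$q2), cv_folds = model$cv_folds,
                      seed = model$seed, positive = model$positive)
      r2y_perm[i] <- m$r2y
      q2_perm[i] <- m$q2
    }
  })
  pass <- all(r2y_perm < model$r2y) &&
    (is.na(model$q2) || all(q2_perm < model$q2))
  list(pass = pass, r2y_perm = r2y_perm, q2_perm = q2_perm,
       r2y = model$r2y, q2 = model$q2, n_perm = n_perm)
}
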