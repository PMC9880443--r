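#' Named feature sets for the prediction study
#'
#' The six input feature sets compared in the overfitting analysis, from the
#' minimum dose alone (A) to the full dosimetric + geometric + patient-label
#' set (F).
#'
#' @param name one of "A".."F".
#' @return character vector of feature column names.
#' @export
feature_set <- function(name = c("A", "B", "C", "D", "E", "F")) {
  name <- match.arg(name)
  switch(name,
    A = "d_min",
    B = c("d_min", "scalar_pdmin_mm"),
    C = c("d_min", "scalar_pdmin_mm", "d_pdmin_global"),
    D = c("d_min", "patient_id"),
    E = c("d_min", "patient_id", "hdd_mm"),
    F = c("d_min", "scalar_pdmin_mm", "d_pdmin_global", "hdd_mm",
          "dl_hdpworst_mm", "patient_id"))
}

# design matrix: numeric features as-is, patient_id one-hot encoded over the
# full table's levels (a held-out patient's indicator columns are then all
# zero in its training folds — the unseen-category convention)
build_design <- function(table, features) {
  num <- setdiff(features, "patient_id")
  stopifnot(all(num %in% names(table)))
  X <- as.data.frame(table[, num, drop = FALSE])
  if ("patient_id" %in% features) {
    pids <- sort(unique(table$patient_id))
    for (p in pids) X[[paste0("pid_", p)]] <- as.numeric(table$patient_id == p)
  }
  X
}

new_cv_result <- function(pred, importance = NULL, folds = NULL) {
  pc <- pearson_with_fisher_ci(pred$y, pred$y_hat)
  structure(list(predictions = pred, pearson_r = pc$r,
                 fisher_ci = c(lo = pc$lo, hi = pc$hi),
                 ve_cv = ve_cv(pred$y, pred$y_hat),
                 importance = importance, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d held-out predictions, R = %.3f (95%% CI %.3f-%.3f), VE_cv = %.3f>\n",
              nrow(x$predictions), x$pearson_r, x$fisher_ci["lo"],
              x$fisher_ci["hi"], x$ve_cv))
  if (!is.null(x$importance)) {
    cat("importance (OOB permutation, fold average):\n")
    print(round(sort(x$importance, decreasing = TRUE), 4))
  }
  invisible(x)
}

#' Leave-one-patient-out random-forest regression of gEUD
#'
#' For every patient, a weighted random forest is trained on all other
#' patients' fractions and scores the held-out patient, so each fraction is
#' predicted exactly once by a model that never saw its patient. Variable
#' importance is the out-of-bag permutation importance (mean-squared-error
#' loss reduction), averaged over folds. Optionally the first
#' `augment_fractions` fractions of the held-out patient are added to its
#' training set and only fractions beyond `score_from` are scored (the
#' early-fraction augmentation protocol).
#'
#' @param table feature table (needs `patient_id`, `fraction`, the target and
#'   feature columns).
#' @param features feature column names (see [feature_set()]).
#' @param target target column (default `"geud"`, normalized gEUD).
#' @param weights per-row sample weights; default from [make_weights()] on
#'   the target.
#' @param seed integer seed (forest growth is seeded per fold).
#' @param num_trees,min_node_size forest size and leaf size.
#' @param augment_fractions number of early held-out-patient fractions added
#'   to training (0 = none).
#' @param score_from first fraction scored when augmenting (default 6, so
#'   augmentation fractions 1-5 are never scored).
#' @return a `cv_result`: held-out predictions, Pearson R with Fisher CI,
#'   VE_cv and averaged importance.
#' @export
lopo_random_forest <- function(table, features = feature_set("A"),
                               target = "geud", weights = NULL, seed = 1L,
                               num_trees = 500, min_node_size = 5,
                               augment_fractions = 0, score_from = 6) {
  pats <- unique(table$patient_id)
  if (length(pats) < 3) stop("need at least three patients")
  if (sd(table[[target]]) == 0) stop("constant target")
  if (is.null(weights)) weights <- make_weights(table[[target]])
  X <- build_design(table, features)
  y <- table[[target]]
  mtry <- max(1L, ceiling(sqrt(ncol(X))))
  preds <- list(); imps <- list(); folds <- list()
  for (fi in seq_along(pats)) {
    p <- pats[fi]
    test_idx <- which(table$patient_id == p)
    if (augment_fractions > 0) {
      aug <- test_idx[table$fraction[test_idx] <= augment_fractions]
      test_idx <- test_idx[table$fraction[test_idx] >= score_from]
      train_idx <- c(which(table$patient_id != p), aug)
    } else {
      train_idx <- which(table$patient_id != p)
    }
    if (length(test_idx) == 0) next
    if (sd(y[train_idx]) == 0)
      stop(sprintf("constant target in training fold for patient %s", p))
    dtr <- cbind(X[train_idx, , drop = FALSE], .y = y[train_idx])
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = dtr,
      num.trees = num_trees, mtry = mtry, min.node.size = min_node_size,
      case.weights = weights[train_idx], importance = "permutation",
      seed = seed + fi, num.threads = 1)
    y_hat <- predict(fit, X[test_idx, , drop = FALSE],
                     num.threads = 1)$predictions
    preds[[fi]] <- data.frame(patient_id = table$patient_id[test_idx],
                              fraction = table$fraction[test_idx],
                              y = y[test_idx], y_hat = y_hat)
    imps[[fi]] <- fit$variable.importance
    folds[[fi]] <- list(patient = p, n_train = length(train_idx),
                        n_test = length(test_idx),
                        train_patients = setdiff(pats, p))
  }
  pred <- do.call(rbind, preds)
  imp_mat <- do.call(rbind, imps)
  imp <- colMeans(imp_mat)
  # collapse one-hot patient indicators into a single patient_id importance
  if ("patient_id" %in% features) {
    pid_cols <- grep("^pid_", names(imp))
    imp <- c(imp[-pid_cols], patient_id = sum(imp[pid_cols]))
  }
  new_cv_result(pred, importance = imp, folds = folds)
}

# train one weighted single-hidden-layer MLP on standardized data
fit_mlp <- function(X, y, w, hidden, decay, maxit, seed) {
  set.seed(seed)
  nnet::nnet(x = as.matrix(X), y = y, weights = w, size = hidden,
             linout = TRUE, decay = decay, maxit = maxit, trace = FALSE)
}

#' Nested leave-one-patient-out MLP regression of gEUD
#'
#' Outer loop: leave one patient out. Inner loop: the outer-training patients
#' are repeatedly split into an inner training set (two-thirds of them, six
#' of nine in the reference cohort size) used to fit a candidate
#' single-hidden-layer perceptron and the remainder used as the inner
#' validation set for early model selection; the candidate with the best
#' Pearson correlation between predicted and true target over the full
#' outer-training set is selected and scores the held-out patient, which is
#' never seen during model building. Inputs and target are standardized with
#' outer-training statistics; candidates that fail to produce finite
#' predictions are refit with a new initialization (capped).
#'
#' @inheritParams lopo_random_forest
#' @param hidden hidden-layer size.
#' @param n_candidates inner-loop candidates (random splits) per outer fold.
#' @param decay weight decay of the perceptron.
#' @param maxit optimizer iteration cap.
#' @return a `cv_result`.
#' @export
nested_lopo_mlp <- function(table, features = feature_set("A"),
                            target = "geud", weights = NULL, seed = 1L,
                            hidden = 8, n_candidates = 12, decay = 1e-2,
                            maxit = 400) {
  pats <- unique(table$patient_id)
  if (length(pats) < 3) stop("need at least three patients")
  if (sd(table[[target]]) == 0) stop("constant target")
  if (is.null(weights)) weights <- make_weights(table[[target]])
  X <- build_design(table, features)
  y <- table[[target]]
  preds <- list(); folds <- list()
  for (fi in seq_along(pats)) {
    p <- pats[fi]
    test_idx <- which(table$patient_id == p)
    train_idx <- which(table$patient_id != p)
    tr_pats <- setdiff(pats, p)
    # standardize with outer-training statistics
    mu <- colMeans(X[train_idx, , drop = FALSE])
    sg <- pmax(apply(X[train_idx, , drop = FALSE], 2, sd), 1e-8)
    Xs <- sweep(sweep(as.matrix(X), 2, mu), 2, sg, "/")
    ymu <- mean(y[train_idx]); ysg <- max(sd(y[train_idx]), 1e-8)
    ys <- (y - ymu) / ysg
    n_inner <- max(1L, round(length(tr_pats) * 2 / 3))
    best <- NULL; best_r <- -Inf
    for (ci in seq_len(n_candidates)) {
      cand_seed <- seed * 10000L + fi * 100L + ci
      set.seed(cand_seed)
      inner_tr_pats <- sample(tr_pats, n_inner)
      itr <- which(table$patient_id %in% inner_tr_pats)
      fit <- NULL
      for (retry in 0:2) {
        fit <- fit_mlp(Xs[itr, , drop = FALSE], ys[itr], weights[itr],
                       hidden, decay, maxit, cand_seed + retry * 7919L)
        sel_hat <- as.numeric(predict(fit, Xs[train_idx, , drop = FALSE]))
        if (all(is.finite(sel_hat))) break
      }
      if (!all(is.finite(sel_hat)) || sd(sel_hat) == 0) next
      r_sel <- cor(ys[train_idx], sel_hat)
      if (is.finite(r_sel) && r_sel > best_r) { best_r <- r_sel; best <- fit }
    }
    if (is.null(best)) stop(sprintf("no usable MLP candidate for patient %s", p))
    y_hat <- as.numeric(predict(best, Xs[test_idx, , drop = FALSE])) * ysg + ymu
    preds[[fi]] <- data.frame(patient_id = table$patient_id[test_idx],
                              fraction = table$fraction[test_idx],
                              y = y[test_idx], y_hat = y_hat)
    folds[[fi]] <- list(patient = p, inner_candidates = n_candidates,
                        inner_train_size = n_inner, selection_r = best_r,
                        train_patients = tr_pats)
  }
  pred <- do.call(rbind, preds)
  new_cv_result(pred, folds = folds)
}
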