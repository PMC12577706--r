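# Gradient-boosted outcome submodels with imbalance-aware resampling,
# repeated stratified k-fold cross-validation, min-max score normalization
# and permutation feature importance.

# ---- metrics -------------------------------------------------------------

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with average ranks for ties.
#'
#' @param scores Numeric predictions.
#' @param labels Logical or 0/1 vector (TRUE/1 = positive class).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision over descending score thresholds, with tied
#' scores collapsed into a single threshold.
#'
#' @inheritParams auroc
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels)
  if (np == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[grp_end]
  n_pred <- grp_end
  prec <- tp / n_pred
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' F1 score at a decision threshold
#' @inheritParams auroc
#' @param threshold Decision threshold (default 0.5).
#' @return F1 in [0, 1] (0 when precision+recall is 0).
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels)
  if (tp == 0) return(0)
  prec <- tp / sum(pred)
  rec <- tp / sum(labels)
  2 * prec * rec / (prec + rec)
}

# ---- resampling ----------------------------------------------------------

#' Class-imbalance resampling plan
#'
#' @param undersample_fraction Majority class is randomly reduced to this
#'   fraction of its original size (one of 0.1, 0.2, 0.5, 1 in the tuning
#'   grid; any value in (0, 1] accepted).
#' @param oversampler `"none"`, `"random"`, `"smote"` or `"adasyn"`; when
#'   not `"none"` the minority class is oversampled to a 1:1 ratio with the
#'   (reduced) majority class.
#' @param k_neighbors Neighbourhood size for SMOTE/ADASYN (default 5).
#' @return A `resampling_plan` list.
#' @export
resampling_plan <- function(undersample_fraction = 1,
                            oversampler = c("none", "random", "smote",
                                            "adasyn"),
                            k_neighbors = 5L) {
  oversampler <- match.arg(oversampler)
  structure(list(undersample_fraction = undersample_fraction,
                 oversampler = oversampler,
                 k_neighbors = as.integer(k_neighbors)),
            class = "resampling_plan")
}

# k nearest neighbours (Euclidean) of each row of `x` among rows of `pool`,
# excluding self-matches by index when `self` is given.
knn_index <- function(x, pool, k, self = NULL) {
  d2 <- outer(rowSums(x^2), rowSums(pool^2), "+") - 2 * x %*% t(pool)
  t(vapply(seq_len(nrow(x)), function(i) {
    di <- d2[i, ]
    if (!is.null(self)) di[self[i]] <- Inf
    order(di)[seq_len(k)]
  }, integer(k)))
}

smote_points <- function(xmin, n_new, k, weights = NULL) {
  k <- min(k, nrow(xmin) - 1L)
  nb <- knn_index(xmin, xmin, k, self = seq_len(nrow(xmin)))
  base_idx <- if (is.null(weights)) {
    sample(nrow(xmin), n_new, replace = TRUE)
  } else {
    sample(nrow(xmin), n_new, replace = TRUE, prob = weights)
  }
  out <- matrix(0, n_new, ncol(xmin), dimnames = list(NULL, colnames(xmin)))
  for (t in seq_len(n_new)) {
    i <- base_idx[t]
    j <- nb[i, sample(k, 1L)]
    u <- runif(1)
    out[t, ] <- xmin[i, ] + u * (xmin[j, ] - xmin[i, ])
  }
  out
}

#' Resample a training split to a balanced class ratio
#'
#' Random undersampling of the majority class to
#' `plan$undersample_fraction` of its original size, optionally followed by
#' oversampling of the minority class to parity: random duplication, SMOTE
#' (synthetic points on segments between minority neighbours) or ADASYN
#' (SMOTE weighted towards minority points with many majority neighbours).
#' Validation data must never pass through this function.
#'
#' @param x Numeric feature matrix.
#' @param y Logical labels (TRUE = positive/minority by convention; the
#'   majority class is determined from the data).
#' @param plan A [resampling_plan()].
#' @param seed RNG seed.
#' @return list(x=, y=) of the balanced split.
#' @export
resample_training <- function(x, y, plan, seed = 1L) {
  x <- as.matrix(x)
  y <- as.logical(y)
  with_seed(seed, {
    maj <- names(which.max(table(y)))
    is_maj <- y == as.logical(maj)
    maj_idx <- which(is_maj)
    min_idx <- which(!is_maj)
    n_keep <- max(1L, round(plan$undersample_fraction * length(maj_idx)))
    maj_keep <- sample(maj_idx, n_keep)
    xmin <- x[min_idx, , drop = FALSE]
    if (plan$oversampler == "none") {
      idx <- c(maj_keep, min_idx)
      return(list(x = x[idx, , drop = FALSE], y = y[idx]))
    }
    n_new <- n_keep - length(min_idx)
    if (n_new <= 0) {
      idx <- c(maj_keep, min_idx)
      return(list(x = x[idx, , drop = FALSE], y = y[idx]))
    }
    extra <- switch(plan$oversampler,
      random = xmin[sample(length(min_idx), n_new, replace = TRUE), ,
                    drop = FALSE],
      smote = {
        if (length(min_idx) < 2L) stop("SMOTE requires >= 2 minority samples")
        smote_points(xmin, n_new, plan$k_neighbors)
      },
      adasyn = {
        if (length(min_idx) < 2L) stop("ADASYN requires >= 2 minority samples")
        k <- min(plan$k_neighbors, nrow(x) - 1L)
        nb <- knn_index(xmin, x, k, self = min_idx)
        r <- vapply(seq_len(nrow(xmin)), function(i) {
          mean(is_maj[nb[i, ]])
        }, numeric(1))
        wts <- if (sum(r) == 0) rep(1, length(r)) else r / sum(r)
        smote_points(xmin, n_new, plan$k_neighbors, weights = wts)
      })
    xb <- rbind(x[maj_keep, , drop = FALSE], xmin, extra)
    yb <- c(y[maj_keep], y[min_idx], rep(y[min_idx][1], n_new))
    list(x = xb, y = yb)
  })
}

# ---- training ------------------------------------------------------------

#' Train a gradient-boosted outcome scorer
#'
#' Fits an xgboost binary classifier on the (resampled) training split.
#'
#' @param x Numeric feature matrix (rows = sites).
#' @param y Logical labels (TRUE = the undesired outcome class).
#' @param plan A [resampling_plan()] applied to the training data.
#' @param hyperparams list(n_trees=, learning_rate=, interaction_depth=).
#' @param seed RNG seed (resampling and booster).
#' @return Object of class `trained_scorer` holding the booster, feature
#'   manifest, hyperparameters and (once calibrated) score min/max.
#' @export
train_scorer <- function(x, y, plan = resampling_plan(),
                         hyperparams = list(n_trees = 150L,
                                            learning_rate = 0.1,
                                            interaction_depth = 3L),
                         seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("feature/label length mismatch")
  bal <- resample_training(x, y, plan, seed = seed)
  dtrain <- xgboost::xgb.DMatrix(bal$x, label = as.numeric(bal$y))
  booster <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eta = hyperparams$learning_rate,
                  max_depth = hyperparams$interaction_depth,
                  nthread = 1L, seed = seed),
    data = dtrain, nrounds = hyperparams$n_trees, verbose = 0))
  structure(list(booster = booster, manifest = colnames(x),
                 hyperparams = hyperparams, plan = plan, seed = seed,
                 score_min = NA_real_, score_max = NA_real_),
            class = "trained_scorer")
}

#' Raw model outputs for a feature matrix
#' @param scorer A `trained_scorer`.
#' @param x Feature matrix with the scorer's column manifest.
#' @return Numeric vector of raw probabilities.
#' @export
predict_raw <- function(scorer, x) {
  x <- as.matrix(x)
  if (!identical(colnames(x), scorer$manifest))
    stop("feature manifest mismatch")
  predict(scorer$booster, xgboost::xgb.DMatrix(x))
}

#' Store the score range observed on a reference site set
#'
#' The min and max raw outputs over the reference set define the min-max
#' normalization applied by [predict_normalized()].
#'
#' @param scorer A `trained_scorer`.
#' @param reference_x Feature matrix of the reference (e.g. genome-wide)
#'   site set.
#' @return The calibrated scorer.
#' @export
calibrate_scorer <- function(scorer, reference_x) {
  raw <- predict_raw(scorer, reference_x)
  scorer$score_min <- min(raw)
  scorer$score_max <- max(raw)
  scorer
}

#' Min-max-normalized predictions in [0, 1]
#'
#' `(raw - min) / (max - min)` with the stored reference range; outputs for
#' out-of-range inputs are clipped to [0, 1]. Normalization is an
#' order-preserving affine map.
#'
#' @inheritParams predict_raw
#' @return Numeric scores in [0, 1].
#' @export
predict_normalized <- function(scorer, x) {
  if (is.na(scorer$score_min)) stop("scorer is not calibrated")
  raw <- predict_raw(scorer, x)
  rng <- scorer$score_max - scorer$score_min
  if (rng == 0) return(rep(0, length(raw)))
  pmin(1, pmax(0, (raw - scorer$score_min) / rng))
}

# Stratified fold assignment: a seeded shuffle within each class.
stratified_folds <- function(y, k, seed) {
  y <- as.logical(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Resampling is applied inside each training fold only; validation folds
#' are left untouched. The report aggregates repeats x k fold-instances.
#'
#' @inheritParams train_scorer
#' @param repeats Number of repeats (default 5).
#' @param k Folds per repeat (default 3).
#' @return Object of class `cv_report`: data.frame `folds` (repeat, fold,
#'   auroc, auprc, f1) and list `summary` (means and sds).
#' @export
repeated_kfold_cv <- function(x, y, plan = resampling_plan(),
                              hyperparams = list(n_trees = 150L,
                                                 learning_rate = 0.1,
                                                 interaction_depth = 3L),
                              repeats = 5L, k = 3L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.logical(y)
  if (min(table(y)) < k) stop("a class has fewer members than k")
  rows <- list()
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, k, seed = seed * 1000L + r)
    for (f in seq_len(k)) {
      tr <- fold != f
      scorer <- train_scorer(x[tr, , drop = FALSE], y[tr], plan,
                             hyperparams, seed = seed * 100L + r * 10L + f)
      p <- predict_raw(scorer, x[!tr, , drop = FALSE])
      yv <- y[!tr]
      rows[[length(rows) + 1L]] <-
        data.frame(rep = r, fold = f, auroc = auroc(p, yv),
                   auprc = auprc(p, yv), f1 = f1_score(p, yv))
    }
  }
  folds <- do.call(rbind, rows)
  structure(list(
    folds = folds,
    summary = list(auroc_mean = mean(folds$auroc), auroc_sd = sd(folds$auroc),
                   auprc_mean = mean(folds$auprc), auprc_sd = sd(folds$auprc),
                   f1_mean = mean(folds$f1), f1_sd = sd(folds$f1))),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("cv_report: %d fold-instances | AUROC %.3f (sd %.3f) | AUPRC %.3f (sd %.3f) | F1 %.3f\n",
              nrow(x$folds), s$auroc_mean, s$auroc_sd, s$auprc_mean,
              s$auprc_sd, s$f1_mean))
  invisible(x)
}

#' Exhaustive grid search over hyperparameters and resampling plans
#'
#' Every (hyperparameter, resampling) combination is evaluated by
#' [repeated_kfold_cv()]; the best configuration is the one with the highest
#' mean AUROC, ties broken by mean AUPRC.
#'
#' @inheritParams repeated_kfold_cv
#' @param hyper_grid List of hyperparameter lists.
#' @param resampling_grid List of [resampling_plan()]s.
#' @return list(best = list(hyperparams, plan, report), results = data.frame
#'   with one row per configuration).
#' @export
grid_search <- function(x, y, hyper_grid, resampling_grid,
                        repeats = 5L, k = 3L, seed = 1L) {
  if (length(hyper_grid) == 0 || length(resampling_grid) == 0)
    stop("empty grid")
  rows <- list()
  best <- NULL
  for (hi in seq_along(hyper_grid)) {
    for (ri in seq_along(resampling_grid)) {
      rep_ <- repeated_kfold_cv(x, y, plan = resampling_grid[[ri]],
                                hyperparams = hyper_grid[[hi]],
                                repeats = repeats, k = k, seed = seed)
      s <- rep_$summary
      rows[[length(rows) + 1L]] <- data.frame(
        hyper = hi, resampling = ri,
        n_trees = hyper_grid[[hi]]$n_trees,
        learning_rate = hyper_grid[[hi]]$learning_rate,
        interaction_depth = hyper_grid[[hi]]$interaction_depth,
        undersample_fraction = resampling_grid[[ri]]$undersample_fraction,
        oversampler = resampling_grid[[ri]]$oversampler,
        auroc = s$auroc_mean, auprc = s$auprc_mean, f1 = s$f1_mean)
      better <- is.null(best) || s$auroc_mean > best$auroc ||
        (s$auroc_mean == best$auroc && s$auprc_mean > best$auprc)
      if (better) {
        best <- list(hyperparams = hyper_grid[[hi]],
                     plan = resampling_grid[[ri]], report = rep_,
                     auroc = s$auroc_mean, auprc = s$auprc_mean)
      }
    }
  }
  list(best = best, results = do.call(rbind, rows))
}

#' Permutation importance of feature groups
#'
#' For each group, the group's columns are jointly shuffled across samples
#' `n_perm` times; the drop in AUROC relative to the intact data measures
#' the group's contribution. The 90% confidence interval is the 5th-95th
#' percentile range of the permuted deltas.
#'
#' @param scorer A `trained_scorer`.
#' @param x,y Evaluation feature matrix and labels.
#' @param feature_groups Named list of column-name vectors.
#' @param n_perm Permutations per group (default 1000).
#' @param seed RNG seed.
#' @return data.frame(group, delta_auroc, ci_lo, ci_hi), sorted by mean
#'   delta (descending).
#' @export
permutation_importance <- function(scorer, x, y, feature_groups,
                                   n_perm = 1000L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.logical(y)
  base <- auroc(predict_raw(scorer, x), y)
  rows <- with_seed(seed, lapply(names(feature_groups), function(g) {
    cols <- feature_groups[[g]]
    if (!all(cols %in% colnames(x))) stop("unknown feature group: ", g)
    deltas <- vapply(seq_len(n_perm), function(p) {
      xp <- x
      perm <- sample(nrow(x))
      xp[, cols] <- xp[perm, cols, drop = FALSE]
      base - auroc(predict_raw(scorer, xp), y)
    }, numeric(1))
    data.frame(group = g, delta_auroc = mean(deltas),
               ci_lo = unname(quantile(deltas, 0.05)),
               ci_hi = unname(quantile(deltas, 0.95)))
  }))
  out <- do.call(rbind, rows)
  out <- out[order(-out$delta_auroc), ]
  rownames(out) <- NULL
  out
}
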