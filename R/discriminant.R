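as_feature_matrix <- function(X) {
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (any(!is.finite(X))) stop("features must be finite")
  X
}

as_binary_factor <- function(y, n) {
  y <- factor(y)
  if (nlevels(y) != 2L) stop("exactly two classes are required")
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (any(table(y) < 2L)) stop("at least 2 samples per class are required")
  y
}

# within-class (pooled) and between-class scatter matrices
scatter_matrices <- function(X, y) {
  mu <- colMeans(X)
  lev <- levels(y)
  SW <- matrix(0, ncol(X), ncol(X))
  SB <- matrix(0, ncol(X), ncol(X))
  means <- matrix(NA_real_, length(lev), ncol(X),
                  dimnames = list(lev, colnames(X)))
  for (l in lev) {
    Xl <- X[y == l, , drop = FALSE]
    ml <- colMeans(Xl)
    means[l, ] <- ml
    C <- sweep(Xl, 2L, ml)
    SW <- SW + crossprod(C)
    SB <- SB + nrow(Xl) * tcrossprod(ml - mu)
  }
  list(SW = SW, SB = SB, means = means)
}

#' Fisher linear discriminant for two classes
#'
#' Finds the projection direction w maximizing the Fisher criterion
#' J(w) = (w' S_B w) / (w' S_W w), i.e. the ratio of between-class to
#' within-class scatter along the projection. For two classes the solution
#' of the generalized eigenproblem S_B w = lambda S_W w has the closed form
#' w proportional to S_W^-1 (mu_1 - mu_0), which is what is computed (and
#' returned normalized to unit length). The decision threshold on the
#' projection is placed where the two pooled-covariance Gaussian class
#' posteriors with training priors are equal.
#'
#' If S_W is (numerically) singular, a ridge term
#' \code{eps = 1e-8 * trace(S_W)/d} is added and recorded in the model.
#'
#' @param X Feature matrix or data frame (rows = samples).
#' @param y Two-level class labels.
#' @return Object of class \code{"flim_lda"}: \code{w} (unit direction),
#'   \code{threshold}, \code{class_means}, \code{SW}, \code{SB},
#'   \code{priors}, \code{classes}, \code{features}, \code{ridge}.
#' @seealso [stepwise_select()], [loo_validate()], [holdout_validate()]
#' @export
fit_lda <- function(X, y) {
  X <- as_feature_matrix(X)
  y <- as_binary_factor(y, nrow(X))
  sc <- scatter_matrices(X, y)
  d <- ncol(X); n <- nrow(X)
  SW <- sc$SW
  ridge <- 0
  ok <- FALSE
  sol <- tryCatch(solve(SW, sc$means[2L, ] - sc$means[1L, ]),
                  error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) {
    ridge <- 1e-8 * sum(diag(SW)) / d
    if (ridge == 0) ridge <- 1e-8
    sol <- solve(SW + diag(ridge, d), sc$means[2L, ] - sc$means[1L, ])
  }
  if (sum(sol^2) == 0) sol <- c(1, rep(0, d - 1L))  # coincident class means
  w <- sol / sqrt(sum(sol^2))
  priors <- as.vector(table(y)) / n
  m0 <- sum(w * sc$means[1L, ]); m1 <- sum(w * sc$means[2L, ])
  sigma2 <- drop(t(w) %*% (SW / (n - 2L)) %*% w)
  threshold <- (m0 + m1) / 2
  if (m1 != m0 && sigma2 > 0)
    threshold <- threshold + sigma2 * log(priors[1L] / priors[2L]) / (m1 - m0)
  structure(list(w = w, threshold = threshold, class_means = sc$means,
                 SW = SW, SB = sc$SB, priors = stats::setNames(priors, levels(y)),
                 classes = levels(y), features = colnames(X), ridge = ridge),
            class = "flim_lda")
}

#' @export
print.flim_lda <- function(x, ...) {
  cat("Fisher LDA:", paste(x$classes, collapse = " vs "), "\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat("  w:", paste(sprintf("%.4f", x$w), collapse = ", "),
      " threshold:", sprintf("%.4f", x$threshold), "\n")
  invisible(x)
}

#' Fisher criterion value for a direction
#'
#' @param model A [fit_lda()] model.
#' @param w Direction vector (any nonzero scale).
#' @return J(w) = (w' S_B w)/(w' S_W w).
#' @export
fisher_criterion <- function(model, w = model$w) {
  drop((t(w) %*% model$SB %*% w) / (t(w) %*% model$SW %*% w))
}

#' Predict method for Fisher LDA
#'
#' @param object A [fit_lda()] model.
#' @param newdata Feature matrix/data frame containing the model's features.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.flim_lda <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  proj <- drop(X %*% object$w)
  m0 <- sum(object$w * object$class_means[1L, ])
  m1 <- sum(object$w * object$class_means[2L, ])
  hi <- if (m1 >= m0) object$classes[2L] else object$classes[1L]
  lo <- setdiff(object$classes, hi)
  factor(ifelse(proj > object$threshold, hi, lo), levels = object$classes)
}

# Wilks' lambda of a feature subset: det(W)/det(T)
wilks_lambda <- function(X, y, subset) {
  if (length(subset) == 0L) return(1)
  Xs <- X[, subset, drop = FALSE]
  sc <- scatter_matrices(Xs, y)
  TT <- sc$SW + sc$SB
  dW <- det(sc$SW); dT <- det(TT)
  if (!is.finite(dW) || !is.finite(dT) || dT <= 0) return(NA_real_)
  max(dW / dT, 0)
}

# partial F for adding `cand` to `base` (g = 2 groups)
partial_f <- function(X, y, base, cand, n) {
  p <- length(base)
  l0 <- wilks_lambda(X, y, base)
  l1 <- wilks_lambda(X, y, c(base, cand))
  if (!is.finite(l0) || !is.finite(l1) || l1 <= 0) return(NA_real_)
  (n - 2L - p) * (l0 / l1 - 1)
}

# pooled within-class tolerance of cand given base (1 - R^2); guards collinearity
wc_tolerance <- function(X, y, base, cand) {
  if (length(base) == 0L) return(1)
  sc <- scatter_matrices(X[, c(base, cand), drop = FALSE], y)
  W <- sc$SW
  k <- length(base) + 1L
  wcc <- W[k, k]
  if (wcc <= 0) return(0)
  beta <- tryCatch(solve(W[-k, -k, drop = FALSE], W[-k, k]),
                   error = function(e) NULL)
  if (is.null(beta)) return(0)
  max(1 - drop(W[k, -k, drop = FALSE] %*% beta) / wcc, 0)
}

#' Stepwise discriminant feature selection
#'
#' Classic stepwise discriminant analysis: features are entered one at a
#' time by largest partial Wilks'-lambda F statistic exceeding
#' \code{f_enter}, and after each entry any included feature whose partial
#' F-to-remove falls below \code{f_remove} is dropped. A pooled
#' within-class tolerance check (1 - R^2 of the candidate on the selected
#' set) excludes collinear candidates. The defaults F-to-enter = 3.84 and
#' F-to-remove = 2.71 are the conventional thresholds of classical
#' statistics packages.
#'
#' @param X Feature matrix or data frame.
#' @param y Two-level class labels.
#' @param f_enter,f_remove Entry/removal thresholds (\code{f_enter >
#'   f_remove}).
#' @param tol Minimum tolerance for a candidate (default 1e-6).
#' @param max_steps Safety cap on iterations.
#' @return List of class \code{"flim_stepwise"}: \code{selected} (ordered
#'   names; empty if nothing passes entry, flagged by \code{chance_level}),
#'   \code{model} (refit [fit_lda()] on the selection, or NULL),
#'   \code{history} (data frame of enter/remove events).
#' @export
stepwise_select <- function(X, y, f_enter = 3.84, f_remove = 2.71,
                            tol = 1e-6, max_steps = 50L) {
  X <- as_feature_matrix(X)
  y <- as_binary_factor(y, nrow(X))
  if (f_enter <= f_remove) stop("f_enter must exceed f_remove")
  n <- nrow(X)
  candidates <- colnames(X)
  selected <- character(0)
  history <- list()
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    # forward entry
    pool <- setdiff(candidates, selected)
    pool <- pool[vapply(pool, function(f)
      wc_tolerance(X, y, selected, f) > tol, logical(1L))]
    if (length(pool)) {
      fs <- vapply(pool, function(f) partial_f(X, y, selected, f, n), numeric(1L))
      fs[!is.finite(fs)] <- -Inf
      if (max(fs) > f_enter) {
        enter <- pool[which.max(fs)]
        selected <- c(selected, enter)
        history[[length(history) + 1L]] <-
          data.frame(step = step, action = "enter", feature = enter,
                     partial_F = max(fs))
        changed <- TRUE
      }
    }
    # backward removal
    repeat {
      if (length(selected) < 2L) break
      fr <- vapply(selected, function(f)
        partial_f(X, y, setdiff(selected, f), f, n), numeric(1L))
      fr[!is.finite(fr)] <- Inf
      if (min(fr) < f_remove) {
        drop_f <- selected[which.min(fr)]
        selected <- setdiff(selected, drop_f)
        history[[length(history) + 1L]] <-
          data.frame(step = step, action = "remove", feature = drop_f,
                     partial_F = min(fr))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  model <- if (length(selected))
    fit_lda(X[, selected, drop = FALSE], y) else NULL
  structure(list(selected = selected, model = model,
                 chance_level = length(selected) == 0L,
                 history = if (length(history)) do.call(rbind, history)
                           else data.frame()),
            class = "flim_stepwise")
}

#' @export
print.flim_stepwise <- function(x, ...) {
  if (x$chance_level)
    cat("Stepwise LDA: no feature passed F-to-enter (chance-level model)\n")
  else
    cat("Stepwise LDA selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

confusion_table <- function(truth, pred, classes) {
  table(factor(truth, levels = classes), factor(pred, levels = classes),
        dnn = c("truth", "predicted"))
}

#' Macro F-score from a 2x2 confusion table
#'
#' Per-class F is the harmonic mean of precision and recall (0 when a class
#' has no predicted or no true members); \code{"macro"} averages the two
#' classes unweighted.
#'
#' @param confusion 2x2 table/matrix, rows = truth, columns = predicted.
#' @param averaging \code{"macro"} (default) or \code{"per_class"}.
#' @return Macro F (scalar) or the per-class F vector.
#' @export
f_score <- function(confusion, averaging = c("macro", "per_class")) {
  averaging <- match.arg(averaging)
  cm <- as.matrix(confusion)
  if (any(cm < 0)) stop("confusion counts must be nonnegative")
  f <- numeric(nrow(cm))
  for (k in seq_len(nrow(cm))) {
    tp <- cm[k, k]
    prec <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
    rec  <- if (sum(cm[k, ]) > 0) tp / sum(cm[k, ]) else 0
    f[k] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  names(f) <- rownames(cm)
  if (averaging == "macro") mean(f) else f
}

refit_and_predict <- function(Xtr, ytr, Xte, stepwise, features, sw_args) {
  if (stepwise) {
    sel <- do.call(stepwise_select, c(list(X = Xtr, y = ytr), sw_args))
    if (sel$chance_level) {
      maj <- names(which.max(table(ytr)))
      return(list(pred = factor(rep(maj, nrow(Xte)), levels = levels(ytr)),
                  selected = character(0)))
    }
    model <- sel$model
    list(pred = predict(model, Xte), selected = sel$selected)
  } else {
    feats <- if (is.null(features)) colnames(Xtr) else features
    model <- fit_lda(Xtr[, feats, drop = FALSE], ytr)
    list(pred = predict(model, Xte), selected = feats)
  }
}

#' Leave-one-out validation
#'
#' Each validation unit (a cell, or a whole patient when \code{unit_ids}
#' groups cells by patient) is held out in turn; the model -- including
#' stepwise selection when requested -- is refit on the remaining units and
#' the held-out unit is predicted. Folds whose training data collapse to a
#' single class are skipped and reported.
#'
#' @param X Feature matrix or data frame.
#' @param y Two-level labels.
#' @param unit_ids Optional vector grouping rows into validation units
#'   (default: one unit per row).
#' @param stepwise Run [stepwise_select()] inside every fold.
#' @param features Fixed feature subset when \code{stepwise = FALSE}.
#' @param sw_args List of extra arguments for [stepwise_select()].
#' @return Object of class \code{"flim_validation"} with resubstitution
#'   \code{accuracy}, \code{accuracy_loo}, \code{confusion} (LOO),
#'   \code{selected_features} (full-data fit), \code{skipped_folds}.
#' @export
loo_validate <- function(X, y, unit_ids = NULL, stepwise = FALSE,
                         features = NULL, sw_args = list()) {
  X <- as_feature_matrix(X)
  y <- as_binary_factor(y, nrow(X))
  if (is.null(unit_ids)) unit_ids <- seq_len(nrow(X))
  if (length(unit_ids) != nrow(X)) stop("unit_ids must match rows of X")
  units <- unique(unit_ids)
  if (length(units) < 3L) stop("need at least 3 validation units")

  full <- refit_and_predict(X, y, X, stepwise, features, sw_args)
  resub_acc <- mean(full$pred == y)

  pred <- factor(rep(NA_character_, nrow(X)), levels = levels(y))
  skipped <- character(0)
  for (u in units) {
    test <- unit_ids == u
    ytr <- y[!test]
    if (length(unique(ytr)) < 2L || any(table(ytr) < 2L)) {
      skipped <- c(skipped, as.character(u)); next
    }
    r <- refit_and_predict(X[!test, , drop = FALSE], droplevels(ytr),
                           X[test, , drop = FALSE], stepwise, features, sw_args)
    pred[test] <- r$pred
  }
  eval_rows <- !is.na(pred)
  structure(list(level = if (is.null(unit_ids)) "cell" else "unit",
                 accuracy = resub_acc,
                 accuracy_loo = mean(pred[eval_rows] == y[eval_rows]),
                 confusion = confusion_table(y[eval_rows], pred[eval_rows],
                                             levels(y)),
                 selected_features = full$selected,
                 skipped_folds = skipped,
                 n_units = length(units)),
            class = "flim_validation")
}

#' Repeated stratified 50/50 hold-out validation
#'
#' Splits the data into equal-size training and test halves (stratified by
#' class), fits the discriminant on the training half and scores the test
#' half; repeated \code{repeats} times. Reports per-repeat accuracy and
#' macro F-score with their mean and SD, mirroring the conventional
#' machine-learning evaluation of a linear discriminant classifier.
#'
#' @inheritParams loo_validate
#' @param train_fraction Fraction of each class used for training
#'   (default 0.5).
#' @param repeats Number of random splits (default 10).
#' @param seed Integer seed making the splits reproducible.
#' @return Object of class \code{"flim_validation"} with
#'   \code{per_repeat_accuracy}, \code{accuracy} (mean),
#'   \code{accuracy_sd}, \code{f_score_mean}, \code{f_score_sd},
#'   pooled \code{confusion}.
#' @export
holdout_validate <- function(X, y, train_fraction = 0.5, repeats = 10L,
                             seed = 1L, stepwise = FALSE, features = NULL,
                             sw_args = list()) {
  X <- as_feature_matrix(X)
  y <- as_binary_factor(y, nrow(X))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  acc <- fsc <- numeric(repeats)
  pooled <- matrix(0, 2L, 2L, dimnames = list(levels(y), levels(y)))
  for (r in seq_len(repeats)) {
    train <- logical(nrow(X))
    for (l in levels(y)) {
      idx <- which(y == l)
      ntr <- round(length(idx) * train_fraction)
      if (ntr < 2L || length(idx) - ntr < 1L) stop("degenerate split")
      train[sample(idx, ntr)] <- TRUE
    }
    res <- refit_and_predict(X[train, , drop = FALSE], droplevels(y[train]),
                             X[!train, , drop = FALSE], stepwise, features,
                             sw_args)
    cm <- confusion_table(y[!train], res$pred, levels(y))
    acc[r] <- sum(diag(cm)) / sum(cm)
    fsc[r] <- f_score(cm)
    pooled <- pooled + cm
  }
  structure(list(level = "cell", per_repeat_accuracy = acc,
                 accuracy = mean(acc), accuracy_sd = stats::sd(acc),
                 f_score_mean = mean(fsc), f_score_sd = stats::sd(fsc),
                 confusion = pooled, repeats = repeats, seed = seed),
            class = "flim_validation")
}

#' @export
print.flim_validation <- function(x, ...) {
  cat("Validation report\n")
  if (!is.null(x$accuracy_loo))
    cat(sprintf("  accuracy %.3f (resubstitution), %.3f (leave-one-out over %d units)\n",
                x$accuracy, x$accuracy_loo, x$n_units))
  else
    cat(sprintf("  accuracy %.3f +/- %.3f, macro F %.3f +/- %.3f (%d repeats)\n",
                x$accuracy, x$accuracy_sd, x$f_score_mean, x$f_score_sd,
                x$repeats))
  if (length(x$skipped_folds)) cat("  skipped folds:",
                                   paste(x$skipped_folds, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate cell-level features to patient level
#'
#' One row per patient; every feature column becomes the arithmetic mean of
#' that patient's cells (the patient-level representation of the analysis),
#' with the contributing cell count recorded.
#'
#' @param cell_features Data frame with a \code{cell_id} column and numeric
#'   feature columns.
#' @param manifest Manifest data frame mapping \code{cell_id} to
#'   \code{patient_id} and \code{group}.
#' @return Data frame with \code{patient_id}, \code{group}, \code{n_cells}
#'   and the averaged feature columns.
#' @export
aggregate_per_patient <- function(cell_features, manifest) {
  if (!"cell_id" %in% names(cell_features)) stop("cell_features needs cell_id")
  idx <- match(cell_features$cell_id, manifest$cell_id)
  if (anyNA(idx))
    stop("orphan cells without a manifest entry: ",
         paste(utils::head(cell_features$cell_id[is.na(idx)], 3L), collapse = ", "))
  pid <- manifest$patient_id[idx]
  grp <- manifest$group[idx]
  num_cols <- names(cell_features)[vapply(cell_features, is.numeric, logical(1L))]
  agg <- stats::aggregate(cell_features[num_cols], by = list(patient_id = pid),
                          FUN = mean)
  agg <- agg[order(agg$patient_id), , drop = FALSE]
  grp_map <- tapply(grp, pid, function(g) g[1L])
  n_map <- tapply(pid, pid, length)
  data.frame(patient_id = agg$patient_id,
             group = as.vector(grp_map[agg$patient_id]),
             n_cells = as.vector(n_map[agg$patient_id]),
             agg[num_cols], stringsAsFactors = FALSE, row.names = NULL)
}
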