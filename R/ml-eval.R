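# Small-sample ML validation harness: tree-ensemble fitting, cross-validation
# designs (stratified k-fold, leave-one-out, balanced leave-P-out), greedy
# forward selection, recursive feature elimination and classification reports.
#
# All stochastic steps are seeded and run single-threaded so that every
# report is bit-reproducible.

as_label_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  stopifnot(all(labels %in% c("high", "low")))
  factor(labels, levels = c("low", "high"))
}

as_feature_df <- function(features) {
  if (inherits(features, "feature_matrix")) features <- unclass(features)
  if (is.matrix(features)) {
    features <- as.data.frame(features, check.names = FALSE)
  }
  stopifnot(is.data.frame(features))
  if (is.null(names(features)) || any(!nzchar(names(features)))) {
    names(features) <- paste0("f", seq_along(features))
  }
  features
}

#' Tree-ensemble model specification
#'
#' Captures the ensemble variant and hyperparameters used throughout the
#' evaluation harness: an extremely randomised trees classifier (default, as
#' used for in-loop rule validation) or a random forest (used for the
#' descriptor benchmark protocol). Defaults: 100 trees, unlimited depth.
#'
#' @param kind `"extratrees"` or `"random_forest"`.
#' @param num_trees number of trees (default 100).
#' @param mtry variables tried per split; `NULL` for the ranger default.
#' @param seed base random seed recorded with every report.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(kind = c("extratrees", "random_forest"),
                       num_trees = 100L, mtry = NULL, seed = 0L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, num_trees = as.integer(num_trees), mtry = mtry,
                 seed = as.integer(seed)),
            class = "model_spec")
}

fit_model <- function(spec, x, y, seed = spec$seed) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as_feature_df(x)
  y <- as_label_factor(y)
  if (nlevels(droplevels(y)) < 2) {
    stop("labels contain a single class; cannot fit a classifier",
         call. = FALSE)
  }
  ranger::ranger(
    x = x, y = y,
    num.trees = spec$num_trees,
    mtry = spec$mtry,
    splitrule = if (spec$kind == "extratrees") "extratrees" else "gini",
    replace = spec$kind != "extratrees",
    sample.fraction = if (spec$kind == "extratrees") 1 else 0.632,
    probability = TRUE,
    seed = seed,
    num.threads = 1
  )
}

# Probability of the positive class ("high"); ties at 0.5 resolve to "low"
# (deterministic negative-class preference).
predict_model <- function(fit, x) {
  x <- as_feature_df(x)
  pr <- stats::predict(fit, data = x, num.threads = 1)$predictions
  p_high <- pr[, "high"]
  list(class = factor(ifelse(p_high > 0.5, "high", "low"),
                      levels = c("low", "high")),
       p_high = as.numeric(p_high))
}

new_eval_report <- function(per_split, per_seed, seeds, design, model,
                            y_true = NULL, y_pred = NULL, y_score = NULL,
                            importances = NULL) {
  acc_seed <- vapply(per_seed, mean, numeric(1))
  rep <- list(
    accuracy_mean = mean(acc_seed),
    accuracy_sd = if (length(acc_seed) > 1) stats::sd(acc_seed) else 0,
    accuracy_sd_splits = stats::sd(unlist(per_split)),
    per_split = unlist(per_split),
    per_seed = acc_seed,
    seeds = seeds,
    design = design,
    model = model,
    importances = importances,
    importance_backend = if (!is.null(importances)) "permutation" else NULL
  )
  if (!is.null(y_true)) {
    cm <- classification_report(y_true, y_pred, y_score)
    rep[c("recall", "precision", "f1", "roc_auc")] <-
      cm[c("recall", "precision", "f1", "roc_auc")]
  }
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s evaluation (%s, %d trees)\n", x$design, x$model$kind,
              x$model$num_trees))
  cat(sprintf("  accuracy: %.3f +/- %.3f (sd over %d seed%s)\n",
              x$accuracy_mean, x$accuracy_sd, length(x$seeds),
              if (length(x$seeds) > 1) "s" else ""))
  if (!is.null(x$roc_auc)) {
    cat(sprintf("  recall %.3f, precision %.3f, F1 %.3f, ROC-AUC %s\n",
                x$recall, x$precision, x$f1,
                if (is.na(x$roc_auc)) "undefined" else sprintf("%.3f", x$roc_auc)))
  }
  invisible(x)
}

# Stratified fold assignment: within each class, shuffle and deal round-robin.
stratified_folds <- function(y, k, seed) {
  y <- as_label_factor(y)
  fold <- integer(length(y))
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' @param features feature matrix or data.frame (samples x features).
#' @param labels `"high"`/`"low"` vector.
#' @param spec a [model_spec()].
#' @param k number of folds (default 5).
#' @param seed seed controlling fold assignment and tree growth.
#' @return an `eval_report` with per-fold accuracies and pooled
#'   classification metrics.
#' @export
kfold_cv <- function(features, labels, spec = model_spec(), k = 5L,
                     seed = spec$seed) {
  x <- as_feature_df(features)
  y <- as_label_factor(labels)
  stopifnot(nrow(x) >= k)
  if (nlevels(droplevels(y)) < 2) {
    stop("labels contain a single class", call. = FALSE)
  }
  fold <- stratified_folds(y, k, seed)
  accs <- numeric(k)
  y_pred <- factor(rep("low", length(y)), levels = c("low", "high"))
  y_score <- numeric(length(y))
  for (f in seq_len(k)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    fit <- fit_model(spec, x[tr, , drop = FALSE], y[tr], seed = seed + f)
    pr <- predict_model(fit, x[te, , drop = FALSE])
    accs[f] <- mean(pr$class == y[te])
    y_pred[te] <- pr$class
    y_score[te] <- pr$p_high
  }
  new_eval_report(list(accs), list(accs), seeds = seed, design = "kfold",
                  model = spec, y_true = y, y_pred = y_pred, y_score = y_score)
}

# LOO accuracy of one model on one feature set (single seed); the workhorse
# behind loo_eval and forward_select.
loo_accuracy <- function(x, y, spec, seed) {
  x <- as_feature_df(x)
  y <- as_label_factor(y)
  n <- nrow(x)
  correct <- logical(n)
  p_high <- numeric(n)
  if (ncol(x) == 0) {
    # no features: majority vote of the training labels, ties -> "low"
    for (i in seq_len(n)) {
      maj <- if (mean(y[-i] == "high") > 0.5) "high" else "low"
      correct[i] <- maj == as.character(y[i])
      p_high[i] <- mean(y[-i] == "high")
    }
    return(list(acc = mean(correct), correct = correct, p_high = p_high))
  }
  for (i in seq_len(n)) {
    fit <- fit_model(spec, x[-i, , drop = FALSE], y[-i], seed = seed + i)
    pr <- predict_model(fit, x[i, , drop = FALSE])
    correct[i] <- pr$class == y[i]
    p_high[i] <- pr$p_high
  }
  list(acc = mean(correct), correct = correct, p_high = p_high)
}

#' Leave-one-out evaluation over multiple seeds
#'
#' Each of the n samples is held out in turn (n train-test splits per seed);
#' accuracy is the fraction of held-out samples predicted correctly, reported
#' as mean +/- sd across seeds (the sd across splits is also exposed).
#'
#' @inheritParams kfold_cv
#' @param seeds integer vector of seeds (e.g. nine seeds for a
#'   protocol-grade report).
#' @return an `eval_report`; `per_split` has length `n * length(seeds)`.
#' @export
loo_eval <- function(features, labels, spec = model_spec(),
                     seeds = spec$seed) {
  x <- as_feature_df(features)
  y <- as_label_factor(labels)
  stopifnot(nrow(x) >= 3)
  if (nlevels(droplevels(y)) < 2) {
    stop("labels contain a single class", call. = FALSE)
  }
  per_seed <- list()
  per_split <- list()
  y_pred <- list(); y_score <- list(); y_true <- list()
  for (s in seeds) {
    res <- loo_accuracy(x, y, spec, seed = s)
    per_seed[[length(per_seed) + 1L]] <- res$acc
    per_split[[length(per_split) + 1L]] <- as.numeric(res$correct)
    y_true[[length(y_true) + 1L]] <- y
    y_pred[[length(y_pred) + 1L]] <-
      factor(ifelse(res$p_high > 0.5, "high", "low"), levels = c("low", "high"))
    y_score[[length(y_score) + 1L]] <- res$p_high
  }
  imp <- feature_importance(spec, x, y, seed = seeds[1])
  new_eval_report(per_split, per_seed, seeds = seeds, design = "loo",
                  model = spec,
                  y_true = unlist(lapply(y_true, as.character)),
                  y_pred = unlist(lapply(y_pred, as.character)),
                  y_score = unlist(y_score),
                  importances = imp)
}

#' Balanced leave-P-out split plans
#'
#' Samples `n_splits` distinct test sets of size `p`, each containing exactly
#' `p/2` high and `p/2` low samples, uniformly without replacement from the
#' pool of all such balanced sets.
#'
#' @param labels `"high"`/`"low"` vector.
#' @param p test-set size (even; default 4, i.e. 2 high + 2 low).
#' @param n_splits number of distinct splits (default 50).
#' @param seed sampling seed.
#' @return list of `n_splits` elements, each `list(train = , test = )` with
#'   integer indices; train and test partition the samples.
#' @export
lpo_balanced_splits <- function(labels, p = 4L, n_splits = 50L, seed = 0L) {
  y <- as_label_factor(labels)
  stopifnot(p >= 2, p %% 2 == 0)
  half <- p / 2
  hi <- which(y == "high"); lo <- which(y == "low")
  if (length(hi) < half || length(lo) < half) {
    stop("need at least ", half, " samples per class", call. = FALSE)
  }
  hi_sets <- utils::combn(hi, half)
  lo_sets <- utils::combn(lo, half)
  total <- ncol(hi_sets) * ncol(lo_sets)
  if (n_splits > total) {
    stop("requested ", n_splits, " splits but only ", total,
         " balanced test sets exist", call. = FALSE)
  }
  set.seed(seed)
  pick <- sample.int(total, n_splits)
  all_idx <- seq_along(y)
  lapply(pick, function(k) {
    i <- ((k - 1) %% ncol(hi_sets)) + 1
    j <- ((k - 1) %/% ncol(hi_sets)) + 1
    test <- c(hi_sets[, i], lo_sets[, j])
    list(train = setdiff(all_idx, test), test = test)
  })
}

#' Greedy forward feature selection by leave-one-out accuracy
#'
#' Starting from the empty set (whose baseline is the LOO majority-class
#' accuracy), repeatedly adds the feature that maximises LOO accuracy on the
#' training data; stops when no strict improvement is possible or `cap`
#' features are selected. Ties are broken by column order.
#'
#' @inheritParams kfold_cv
#' @param cap maximum number of selected features (default 5).
#' @return `list(selected = character ids in selection order,
#'   trace = accuracy after each addition, baseline = empty-set accuracy)`.
#' @export
forward_select <- function(features, labels, spec = model_spec(), cap = 5L,
                           seed = spec$seed) {
  x <- as_feature_df(features)
  y <- as_label_factor(labels)
  stopifnot(ncol(x) >= 1)
  selected <- character(0)
  trace <- numeric(0)
  best <- loo_accuracy(x[, selected, drop = FALSE], y, spec, seed)$acc
  baseline <- best
  remaining <- names(x)
  while (length(selected) < cap && length(remaining)) {
    accs <- vapply(remaining, function(f) {
      loo_accuracy(x[, c(selected, f), drop = FALSE], y, spec, seed)$acc
    }, numeric(1))
    k <- which.max(accs)  # which.max takes the first maximum: column order
    if (accs[k] <= best) break
    best <- accs[k]
    selected <- c(selected, remaining[k])
    trace <- c(trace, best)
    remaining <- remaining[-k]
  }
  list(selected = selected, trace = trace, baseline = baseline)
}

#' Frequency of features among the top positions of selections
#'
#' @param selections list of character vectors (ordered selected feature ids,
#'   one per train-test split).
#' @param top_k how many leading positions count (default 3).
#' @return named integer vector: for every feature appearing anywhere, the
#'   number of splits where it ranks within the first `top_k` selections.
#' @export
top_feature_frequency <- function(selections, top_k = 3L) {
  all_feats <- unique(unlist(selections))
  counts <- stats::setNames(integer(length(all_feats)), all_feats)
  for (sel in selections) {
    top <- utils::head(sel, top_k)
    counts[top] <- counts[top] + 1L
  }
  counts
}

#' Recursive feature elimination with cross-validation
#'
#' Starting from all features, repeatedly drops the least important feature
#' (seeded permutation importance of a fit on the current subset, step size
#' 1), recording stratified 5-fold CV accuracy of every subset; returns the
#' subset maximising CV accuracy (ties resolve to the smaller subset).
#'
#' @inheritParams kfold_cv
#' @return `list(selected = character ids, trace = data.frame(size,
#'   accuracy))`.
#' @export
rfecv_select <- function(features, labels, spec = model_spec(),
                         seed = spec$seed, k = 5L) {
  x <- as_feature_df(features)
  y <- as_label_factor(labels)
  stopifnot(ncol(x) >= 2)
  if (nlevels(droplevels(y)) < 2) {
    stop("labels contain a single class", call. = FALSE)
  }
  current <- names(x)
  subsets <- list()
  accs <- numeric(0)
  while (length(current) >= 1) {
    cv <- kfold_cv(x[, current, drop = FALSE], y, spec, k = k, seed = seed)
    subsets[[length(subsets) + 1L]] <- current
    accs <- c(accs, cv$accuracy_mean)
    if (length(current) == 1) break
    imp <- feature_importance(spec, x[, current, drop = FALSE], y, seed = seed)
    drop_feat <- names(imp)[which.min(imp)]
    current <- setdiff(current, drop_feat)
  }
  # best accuracy; among ties prefer the smallest subset (latest recorded)
  best_idx <- max(which(accs == max(accs)))
  list(selected = subsets[[best_idx]],
       trace = data.frame(size = lengths(subsets), accuracy = accs))
}

#' Per-feature attribution by seeded permutation importance
#'
#' Attribution backend for fitted tree ensembles: ranger's permutation
#' importance (mean decrease in out-of-bag accuracy when a feature is
#' permuted), seeded for reproducibility. The backend name is recorded in
#' the attribute `backend`.
#'
#' @inheritParams kfold_cv
#' @return named numeric vector of importances (attribute
#'   `backend = "permutation"`).
#' @export
feature_importance <- function(spec, features, labels, seed = spec$seed) {
  x <- as_feature_df(features)
  y <- as_label_factor(labels)
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = spec$num_trees, mtry = spec$mtry,
    splitrule = if (spec$kind == "extratrees") "extratrees" else "gini",
    importance = "permutation",
    seed = seed, num.threads = 1
  )
  imp <- fit$variable.importance
  attr(imp, "backend") <- "permutation"
  imp
}

#' Binary classification metrics with "high" as the positive class
#'
#' @param y_true,y_pred `"high"`/`"low"` vectors of equal length.
#' @param y_score optional numeric score for the positive class (needed for
#'   ROC-AUC).
#' @return one-row data.frame: `accuracy`, `recall`, `precision`, `f1`,
#'   `roc_auc` (NA with `auc_undefined = TRUE` when the truth is
#'   single-class or no score is given).
#' @export
classification_report <- function(y_true, y_pred, y_score = NULL) {
  y_true <- as_label_factor(y_true)
  y_pred <- as_label_factor(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_pred == "high" & y_true == "high")
  fp <- sum(y_pred == "high" & y_true == "low")
  fn <- sum(y_pred == "low" & y_true == "high")
  accuracy <- mean(y_pred == y_true)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (!is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  auc_undefined <- is.null(y_score) || nlevels(droplevels(y_true)) < 2
  roc_auc <- if (auc_undefined) NA_real_ else {
    as.numeric(pROC::auc(pROC::roc(y_true, y_score, quiet = TRUE,
                                   levels = c("low", "high"),
                                   direction = "<")))
  }
  data.frame(accuracy = accuracy, recall = recall, precision = precision,
             f1 = f1, roc_auc = roc_auc, auc_undefined = auc_undefined)
}
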