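# The package's central fit: score a rule set against a labelled modifier
# dataset and validate it with a small-sample ML protocol, returning a
# classed object with the usual accessor methods.

#' Fit and validate a substructure rule set on a modifier dataset
#'
#' Compiles the rules into a ternary feature matrix, scores each rule with
#' association statistics, evaluates the matrix (optionally alongside
#' experimental features such as Fe-loading) with a cross-validated tree
#' ensemble, and fits a final model on all samples for prediction.
#'
#' @param rules a `rule_set` (or single `rule_spec`).
#' @param data a `modifier_dataset`; labelled by the median split if the
#'   `label` column is absent.
#' @param extra_features experimental feature columns appended to the rule
#'   matrix (default `"fe_loading"`); use `character(0)` for rules only.
#' @param model a [model_spec()] (default extra-trees, 100 trees).
#' @param design `"loo"` (leave-one-out, default) or `"kfold"`.
#' @param seeds seeds for the evaluation (default 0).
#' @return an object of class `rulefit` with components `rules`, `data`,
#'   `matrix`, `metrics`, `report`, `fitted`, `features`.
#' @seealso [para_ewg_rule()], [example_modifier_dataset()]
#' @examples
#' \donttest{
#' fit <- rulefit(para_ewg_rule(), example_modifier_dataset())
#' summary(fit)
#' predict(fit, "OC(=O)c1ccc(Cl)cc1")
#' }
#' @export
rulefit <- function(rules, data, extra_features = "fe_loading",
                    model = model_spec(), design = c("loo", "kfold"),
                    seeds = model$seed) {
  design <- match.arg(design)
  if (inherits(rules, "rule_spec")) rules <- rule_set(list(rules))
  stopifnot(inherits(rules, "rule_set"), inherits(data, "modifier_dataset"))
  if (!"label" %in% names(data) || anyNA(data$label)) {
    data <- binarize_by_median(data)
  }
  stopifnot(all(extra_features %in% names(data)))
  fm <- build_feature_matrix(rules, data)
  metrics <- metrics_report(fm, data)
  feats <- as_feature_df(fm)
  for (col in extra_features) feats[[col]] <- data[[col]]
  report <- if (design == "loo") {
    loo_eval(feats, data$label, model, seeds = seeds)
  } else {
    kfold_cv(feats, data$label, model, seed = seeds[1])
  }
  fitted <- fit_model(model, feats, data$label, seed = model$seed)
  structure(list(rules = rules, data = data, matrix = fm, metrics = metrics,
                 report = report, fitted = fitted, features = feats,
                 extra_features = extra_features, model = model,
                 design = design, call = match.call()),
            class = "rulefit")
}

#' @export
print.rulefit <- function(x, ...) {
  cat("rulefit:", length(x$rules$rules), "rule(s) on", nrow(x$data),
      "molecules\n")
  cat(sprintf("  %s accuracy %.3f +/- %.3f\n", x$report$design,
              x$report$accuracy_mean, x$report$accuracy_sd))
  invisible(x)
}

#' @export
summary.rulefit <- function(object, ...) {
  structure(list(fit = object), class = "summary.rulefit")
}

#' @export
print.summary.rulefit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nAssociation metrics per rule:\n")
  print(fit$metrics, row.names = FALSE, digits = 3)
  if (!is.null(fit$report$importances)) {
    cat("\nFeature importances (", fit$report$importance_backend, "):\n",
        sep = "")
    print(round(sort(fit$report$importances, decreasing = TRUE), 4))
  }
  invisible(x)
}

#' @export
coef.rulefit <- function(object, ...) {
  imp <- object$report$importances
  if (is.null(imp)) {
    imp <- feature_importance(object$model, object$features,
                              object$data$label)
  }
  imp
}

#' Predict activity class for new molecules
#'
#' @param object a `rulefit`.
#' @param newdata character vector of SMILES, or a `modifier_dataset`
#'   carrying the fit's experimental feature columns. When plain SMILES are
#'   given and the fit uses experimental features, those are imputed at
#'   their training means (rule-only information).
#' @param type `"class"` (default), `"prob"` (probability of high) or
#'   `"matrix"` (the compiled rule features).
#' @param ... unused.
#' @return factor, numeric vector, or `feature_matrix` according to `type`.
#' @export
predict.rulefit <- function(object, newdata,
                            type = c("class", "prob", "matrix"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "modifier_dataset")) {
    smiles <- stats::setNames(newdata$smiles, newdata$id)
    extra <- newdata[, object$extra_features, drop = FALSE]
  } else {
    smiles <- as.character(newdata)
    extra <- as.data.frame(lapply(object$extra_features, function(col) {
      rep(mean(object$data[[col]]), length(smiles))
    }))
    names(extra) <- object$extra_features
  }
  fm <- build_feature_matrix(object$rules, smiles)
  if (type == "matrix") return(fm)
  feats <- as_feature_df(fm)
  for (col in object$extra_features) feats[[col]] <- extra[[col]]
  pr <- predict_model(object$fitted, feats)
  if (type == "prob") pr$p_high else pr$class
}

#' Plot rule metrics and feature importances
#'
#' Two base-graphics panels: per-rule lift (with the independence line at 1)
#' and the fitted model's feature importances.
#'
#' @param x a `rulefit`.
#' @param ... passed to `barplot`.
#' @export
plot.rulefit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  lift <- ifelse(is.na(x$metrics$lift), 0, x$metrics$lift)
  graphics::barplot(lift, names.arg = x$metrics$rule_id, las = 2,
                    ylab = "lift", main = "rule lift", ...)
  graphics::abline(h = 1, lty = 2)
  imp <- coef(x)
  graphics::barplot(sort(imp, decreasing = TRUE), las = 2,
                    ylab = "permutation importance",
                    main = "feature importance", ...)
  invisible(x)
}
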