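# Association statistics for rule columns against binary activity labels.
#
# For a rule column c in {-1,0,1}^n and labels in {high, low}:
#   applied set A  = { i : c[i] != 0 }
#   correct(i)     = (c[i] = +1 and label[i] = high) or
#                    (c[i] = -1 and label[i] = low)
#   support        = |A| / n
#   confidence     = #correct / |A|
#   baseline       = mean over i in A of the empirical rate of the class the
#                    rule predicts for i (full-dataset class rates)
#   lift           = confidence / baseline
#   leverage       = mean of the two one-sided association-rule leverages,
#                    lev(c) = P(pred = c & label = c) - P(pred = c) P(label = c)
#                    for c in {high, low}, probabilities over all n samples
# These are the standard association-rule definitions adapted to signed,
# direction-aware predictions; lift ~ 1 and leverage ~ 0 under independence,
# and leverage is bounded in [-0.25, 0.25].

#' Score one rule column against labels
#'
#' @param column integer vector with values in `{-1, 0, 1}`.
#' @param labels factor or character vector with values `"high"` / `"low"`.
#' @return a one-row data.frame with `support`, `confidence`, `lift`,
#'   `leverage`, `n_applied` and a logical `undefined` flag (set when the
#'   rule applies to no sample, in which case confidence/lift/leverage are
#'   `NA` by design rather than silently dropped).
#' @examples
#' score_rule(c(1, 1, -1, 0), c("high", "low", "low", "high"))
#' @export
score_rule <- function(column, labels) {
  stopifnot(length(column) == length(labels), length(column) >= 1)
  if (!all(column %in% c(-1, 0, 1))) {
    stop("rule column entries must be in {-1, 0, 1}", call. = FALSE)
  }
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("high", "low")))
  n <- length(column)
  rate_high <- mean(labels == "high")
  rate_low <- 1 - rate_high
  applied <- column != 0
  n_applied <- sum(applied)
  support <- n_applied / n
  if (n_applied == 0) {
    return(data.frame(support = 0, confidence = NA_real_, lift = NA_real_,
                      leverage = NA_real_, n_applied = 0L, undefined = TRUE))
  }
  predicted <- ifelse(column[applied] == 1, "high", "low")
  correct <- predicted == labels[applied]
  confidence <- mean(correct)
  baseline <- mean(ifelse(predicted == "high", rate_high, rate_low))
  undefined <- baseline == 0
  lift <- if (undefined) NA_real_ else confidence / baseline
  p_pred_high <- sum(column == 1) / n
  p_pred_low <- sum(column == -1) / n
  lev_high <- sum(column == 1 & labels == "high") / n - p_pred_high * rate_high
  lev_low <- sum(column == -1 & labels == "low") / n - p_pred_low * rate_low
  leverage <- (lev_high + lev_low) / 2
  data.frame(support = support, confidence = confidence, lift = lift,
             leverage = leverage, n_applied = n_applied, undefined = undefined)
}

#' Score every rule column of a feature matrix
#'
#' @param fm a `feature_matrix` (samples x rules).
#' @param labels `"high"`/`"low"` vector aligned with the matrix rows, or a
#'   labelled `modifier_dataset`.
#' @return data.frame with one row per rule, `rule_id` first, columns as in
#'   [score_rule()], in matrix column order.
#' @export
metrics_report <- function(fm, labels) {
  if (inherits(labels, "modifier_dataset")) {
    stopifnot(identical(rownames(fm), labels$id))
    labels <- labels$label
  }
  stopifnot(nrow(fm) == length(labels))
  rows <- lapply(seq_len(ncol(fm)), function(j) {
    cbind(data.frame(rule_id = colnames(fm)[j]), score_rule(fm[, j], labels))
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(rule_id = character(), support = numeric(),
               confidence = numeric(), lift = numeric(), leverage = numeric(),
               n_applied = integer(), undefined = logical())
}
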