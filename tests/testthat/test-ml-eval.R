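make_xy <- function(n = 36, seed = 1, p_noise = 2) {
  set.seed(seed)
  y <- factor(rep(c("low", "high"), length.out = n), levels = c("low", "high"))
  x <- data.frame(signal = as.integer(y == "high"))
  for (j in seq_len(p_noise)) x[[paste0("noise", j)]] <- rnorm(n)
  list(x = x, y = y)
}

test_that("k-fold CV is perfect on a separating feature and deterministic", {
  d <- make_xy()
  r <- kfold_cv(d$x["signal"], d$y, model_spec(seed = 3), k = 5)
  expect_equal(r$accuracy_mean, 1.0)
  r2 <- kfold_cv(d$x, d$y, model_spec(seed = 3), k = 5)
  r3 <- kfold_cv(d$x, d$y, model_spec(seed = 3), k = 5)
  expect_identical(r2$per_split, r3$per_split)
  expect_error(kfold_cv(d$x, factor(rep("high", 36), c("low", "high")),
                        model_spec()), "single class")
})

test_that("pure-noise features give chance-level k-fold accuracy", {
  accs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    x <- data.frame(a = rnorm(36), b = rnorm(36))
    y <- factor(rep(c("low", "high"), 18), levels = c("low", "high"))
    kfold_cv(x, y, model_spec(seed = s), k = 5, seed = s)$accuracy_mean
  }, numeric(1))
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
})

test_that("LOO produces n splits per seed and exposes all seeds", {
  d <- make_xy(n = 36)
  seeds <- 1:9
  r <- loo_eval(d$x["signal"], d$y, model_spec(), seeds = seeds)
  expect_equal(length(r$per_split), 36 * 9)
  expect_equal(r$seeds, seeds)
  expect_equal(length(r$per_seed), 9)
  expect_equal(r$accuracy_mean, 1.0)
  expect_equal(r$accuracy_sd, 0)
})

test_that("balanced leave-P-out sampling is exact, seeded and guarded", {
  y <- rep(c("high", "low"), each = 9)
  sp <- lpo_balanced_splits(y, p = 4, n_splits = 50, seed = 1)
  expect_length(sp, 50)
  keys <- vapply(sp, function(s) paste(sort(s$test), collapse = ","),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
  for (s in sp) {
    expect_length(s$test, 4)
    expect_equal(sum(y[s$test] == "high"), 2)
    expect_equal(sum(y[s$test] == "low"), 2)
    expect_equal(sort(c(s$train, s$test)), 1:18)
    expect_length(intersect(s$train, s$test), 0)
  }
  # the pool is C(9,2)^2 = 1296; asking for more than that errors
  expect_error(lpo_balanced_splits(y, p = 4, n_splits = 1297, seed = 1),
               "1296")
  expect_error(lpo_balanced_splits(c("high", rep("low", 9)), p = 4),
               "per class")
  expect_identical(lpo_balanced_splits(y, seed = 9),
                   lpo_balanced_splits(y, seed = 9))
})

test_that("forward selection prefers the dominant feature and never regresses", {
  d <- make_xy(n = 24, seed = 2)
  sel <- forward_select(d$x, d$y, model_spec(seed = 1))
  expect_equal(sel$selected[1], "signal")
  expect_true(all(diff(c(sel$baseline, sel$trace)) > 0))

  # degenerate: all-constant candidates -> nothing selected, no crash
  const <- data.frame(c1 = rep(1, 24), c2 = rep(0, 24))
  sel0 <- forward_select(const, d$y, model_spec(seed = 1))
  expect_length(sel0$selected, 0)

  # accuracy trace non-decreasing on random fixtures
  set.seed(33)
  for (rep in 1:3) {
    x <- data.frame(matrix(rnorm(20 * 4), 20, 4))
    y <- factor(rep(c("low", "high"), 10), levels = c("low", "high"))
    s <- forward_select(x, y, model_spec(seed = rep))
    expect_true(all(diff(c(s$baseline, s$trace)) > 0))
  }
})

test_that("top-feature frequency counts leading positions only", {
  sels <- c(rep(list(c("a", "b", "c", "d")), 30),
            rep(list(c("b", "c", "e", "a")), 20))
  counts <- top_feature_frequency(sels, top_k = 3)
  expect_equal(counts[["a"]], 30)   # 4th in the other 20 splits
  expect_equal(counts[["b"]], 50)
  expect_equal(counts[["d"]], 0)
  expect_lte(sum(counts), 50 * 3)
})

test_that("RFECV retains an informative feature among noise", {
  hits <- vapply(1:20, function(s) {
    set.seed(200 + s)
    y <- factor(rep(c("low", "high"), 18), levels = c("low", "high"))
    x <- data.frame(signal = as.integer(y == "high") + rnorm(36, 0, 0.1),
                    n1 = rnorm(36), n2 = rnorm(36), n3 = rnorm(36))
    sel <- rfecv_select(x, y, model_spec(seed = s), seed = s)
    "signal" %in% sel$selected
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  set.seed(9)
  x <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  y <- factor(rep(c("low", "high"), 15), levels = c("low", "high"))
  expect_identical(rfecv_select(x, y, model_spec(seed = 4), seed = 4)$selected,
                   rfecv_select(x, y, model_spec(seed = 4), seed = 4)$selected)
})

test_that("permutation importance ranks a separating feature first", {
  d <- make_xy(n = 36, seed = 5)
  imp <- feature_importance(model_spec(seed = 2), d$x, d$y)
  expect_equal(names(which.max(abs(imp))), "signal")
  expect_equal(attr(imp, "backend"), "permutation")
  # zero-variance feature gets zero importance
  x2 <- cbind(d$x, flat = 1)
  imp2 <- feature_importance(model_spec(seed = 2), x2, d$y)
  expect_equal(unname(imp2["flat"]), 0)
})

test_that("classification metrics match a 2x2 confusion-table oracle", {
  perfect <- classification_report(c("high", "low"), c("high", "low"),
                                   c(0.9, 0.1))
  expect_equal(perfect$accuracy, 1); expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1); expect_equal(perfect$f1, 1)
  expect_equal(perfect$roc_auc, 1)

  allneg <- classification_report(rep(c("high", "low"), 5), rep("low", 10))
  expect_equal(allneg$recall, 0)
  expect_equal(allneg$accuracy, 0.5)
  expect_true(allneg$auc_undefined)

  set.seed(77)
  for (rep in 1:5) {
    y <- sample(c("high", "low"), 30, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(y)) < 2) next
    p <- sample(c("high", "low"), 30, replace = TRUE)
    tp <- sum(p == "high" & y == "high"); fp <- sum(p == "high" & y == "low")
    fn <- sum(p == "low" & y == "high")
    r <- classification_report(y, p)
    expect_equal(r$accuracy, mean(p == y))
    expect_equal(r$recall, tp / (tp + fn))
    if (tp + fp > 0) expect_equal(r$precision, tp / (tp + fp))
    if (r$precision + r$recall > 0) {
      expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall))
    }
  }
})

test_that("adding the true rule column never hurts an Fe-loading-only model", {
  # qualitative headline property on synthetic ground truth
  spec <- synthetic_spec()
  wins <- vapply(0:4, function(s) {
    lib <- generate_library(spec, seed = s)
    sim <- assign_yields(lib, spec, seed = s)
    ds <- sim$dataset
    rulecol <- as.integer(sim$truth$indicators[, "r2"])
    fe_only <- loo_eval(data.frame(fe = ds$fe_loading), ds$label,
                        model_spec(seed = s), seeds = s)$accuracy_mean
    both <- loo_eval(data.frame(fe = ds$fe_loading, r2 = rulecol), ds$label,
                     model_spec(seed = s), seeds = s)$accuracy_mean
    both >= fe_only
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
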