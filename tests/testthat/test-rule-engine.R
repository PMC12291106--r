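test_that("predicate matching follows SMARTS and Boolean semantics", {
  expect_true(match_predicate(pred_smarts("[NX3;H2,H1]"), "Nc1ccc(C(=O)O)cc1"))
  expect_false(match_predicate(pred_smarts("[NX3](=O)=O"), "Cc1ccc(C(=O)O)cc1"))
  comb <- pred_and(pred_smarts("c1ccccc1"), pred_not(pred_smarts("[OX2H]")))
  expect_false(match_predicate(comb, "c1ccccc1O"))
  expect_true(match_predicate(comb, "c1ccccc1C"))
  expect_true(match_predicate(pred_or(pred_smarts("[F]"), pred_smarts("[Cl]")),
                              "OC(=O)c1ccc(Cl)cc1"))
  # count_ge uses unique (deduplicated) matches
  expect_true(match_predicate(pred_count_ge("[OX2H]", 2), "OCCO"))
  expect_false(match_predicate(pred_count_ge("[OX2H]", 2), "OCC"))
  expect_error(pred_smarts("[[["), "invalid SMARTS")
})

test_that("compiled rules honour scope and first-match clause precedence", {
  ev <- compile_rule(para_ewg_rule())
  ex <- para_benzoic_examples()
  expect_equal(ev(ex$smiles), ex$expected)
  expect_equal(ev("CC(=O)O"), 0L)          # scope fails: not an aryl acid
  expect_equal(ev("Cc1cccc(C(=O)O)c1"), 0L) # meta, not para
  expect_equal(ev("OC(=O)c1ccccc1C"), 0L)   # ortho, not para

  # overlapping clauses: authored order decides
  overlap_a <- rule_spec("a", "amine beats aryl", list(
    clause(pred_smarts("[NX3;H2,H1]"), +1L),
    clause(pred_smarts("c1ccccc1"), -1L)))
  overlap_b <- rule_spec("b", "aryl beats amine", list(
    clause(pred_smarts("c1ccccc1"), -1L),
    clause(pred_smarts("[NX3;H2,H1]"), +1L)))
  m <- "Nc1ccc(C(=O)O)cc1"
  expect_equal(compile_rule(overlap_a)(m), 1L)
  expect_equal(compile_rule(overlap_b)(m), -1L)

  # non-overlapping clauses commute
  disj_a <- rule_spec("a", "", list(clause(pred_smarts("[F]"), +1L),
                                    clause(pred_smarts("[#16]"), -1L)))
  disj_b <- rule_spec("b", "", list(clause(pred_smarts("[#16]"), -1L),
                                    clause(pred_smarts("[F]"), +1L)))
  mols <- c("OC(=O)c1ccc(F)cc1", "OC(=O)c1ccc(S)cc1", "CC(=O)O")
  expect_equal(compile_rule(disj_a)(mols), compile_rule(disj_b)(mols))
})

test_that("feature matrices are ternary, deterministic and shaped n x rules", {
  ds <- example_modifier_dataset()
  rs <- rule_set(c(list(para_ewg_rule()), decoy_rules()))
  fm <- build_feature_matrix(rs, ds)
  expect_equal(dim(fm), c(12, 6))
  expect_true(all(fm %in% c(-1L, 0L, 1L)))
  expect_identical(rownames(fm), ds$id)
  expect_identical(unclass(fm), unclass(build_feature_matrix(rs, ds)))
  # rule column of the worked example
  expect_equal(unname(fm[c("aba", "mba", "aa"), "r2"]), c(1L, -1L, 0L))
  # duplicate molecules give identical rows (purity)
  fm2 <- build_feature_matrix(rs, c(x = ds$smiles[1], y = ds$smiles[1]))
  expect_equal(unname(fm2[1, ]), unname(fm2[2, ]))
  # degenerate: empty rule list
  fm0 <- build_feature_matrix(list(), ds)
  expect_equal(dim(fm0), c(12, 0))
})

test_that("rule matcher agrees cell-for-cell with the RDKit enumeration oracle", {
  smiles <- oracle_fixture_smiles()
  expect_gte(length(smiles), 20)
  rs <- oracle_fixture_rules()
  expect_gte(length(rs$rules), 5)
  fm <- build_feature_matrix(rs, stats::setNames(smiles, paste0("m", seq_along(smiles))))

  pats <- vapply(rs$rules, function(r) r$clauses[[1]]$predicate$smarts,
                 character(1))
  dirs <- vapply(rs$rules, function(r) r$clauses[[1]]$direction, integer(1))
  counts <- rdkit_match_counts(smiles, pats)
  oracle <- sapply(seq_along(pats), function(j) {
    ifelse(counts[, j] >= 1, dirs[j], 0L)
  })
  expect_equal(unname(unclass(fm)), unname(oracle))

  # unique-match counts agree too (count_ge ground truth)
  for (j in seq_along(pats)) {
    expect_equal(smarts_count(smiles, pats[j]), unname(counts[, j]),
                 info = pats[j])
  }
})

test_that("check_matrix flags zero, single and constant coverage", {
  fm <- structure(cbind(r_zero = c(0L, 0L, 0L, 0L),
                        r_one = c(1L, 0L, 0L, 0L),
                        r_const = c(1L, 1L, 1L, 1L),
                        r_ok = c(1L, -1L, 0L, 1L)),
                  class = c("feature_matrix", "matrix", "array"))
  rownames(fm) <- paste0("m", 1:4)
  diag <- check_matrix(fm)
  expect_true(any(diag$rule_id == "r_zero" & diag$problem == "zero-coverage"))
  expect_true(any(diag$rule_id == "r_one" & diag$problem == "coverage<2"))
  expect_true(any(diag$rule_id == "r_const" & diag$problem == "constant column"))
  expect_false("r_ok" %in% diag$rule_id)
  expect_equal(nrow(check_matrix(fm[, "r_ok", drop = FALSE])), 0)
})

test_that("matrix agreement equals the brute-force cell count", {
  mk <- function(vals, nr, nc) {
    m <- matrix(as.integer(vals), nr, nc,
                dimnames = list(paste0("s", 1:nr), paste0("r", 1:nc)))
    structure(m, class = c("feature_matrix", class(m)))
  }
  a <- mk(sample(c(-1, 0, 1), 100, replace = TRUE), 10, 10)
  expect_equal(matrix_agreement(a, a), 1.0)

  b <- mk(rep(0, 10), 5, 2); d <- b; d[3, 2] <- 1L
  expect_equal(matrix_agreement(b, d), 0.9)

  set.seed(7)
  for (rep in 1:5) {
    x <- mk(sample(c(-1, 0, 1), 360, replace = TRUE), 36, 10)
    y <- mk(sample(c(-1, 0, 1), 360, replace = TRUE), 36, 10)
    manual <- sum(vapply(seq_len(360), function(i) x[[i]] == y[[i]],
                         logical(1))) / 360
    expect_equal(matrix_agreement(x, y), manual)
    expect_equal(matrix_agreement(x, y), matrix_agreement(y, x))
  }
  e <- mk(rep(0, 8), 4, 2)
  expect_error(matrix_agreement(b, e), "shape")
})

test_that("rule sets serialise to JSON and back losslessly", {
  rs <- rule_set(c(list(para_ewg_rule()), decoy_rules()))
  path <- tempfile(fileext = ".json")
  write_rules(rs, path)
  rs2 <- read_rules(path)
  ds <- example_modifier_dataset()
  expect_identical(unclass(build_feature_matrix(rs2, ds)),
                   unclass(build_feature_matrix(rs, ds)))
  expect_equal(vapply(rs2$rules, `[[`, character(1), "text"),
               vapply(rs$rules, `[[`, character(1), "text"))

  # matrix CSV round-trip
  fm <- build_feature_matrix(rs, ds)
  mpath <- tempfile(fileext = ".csv")
  write_matrix(fm, mpath)
  expect_identical(unclass(read_matrix(mpath)), unclass(fm))
})

test_that("rule set size and id constraints are enforced", {
  r <- para_ewg_rule()
  many <- lapply(1:16, function(i) {
    rule_spec(paste0("r", i), "x", list(clause(pred_smarts("[F]"), 1L)))
  })
  expect_error(rule_set(many), "maximum")
  expect_error(rule_set(list(r, r)), "duplicated")
  expect_error(build_feature_matrix(rule_set(list(r)),
                                    c(bad = "C1CC")), "bad")
})
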