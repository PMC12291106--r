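# Declarative substructure rules and their compilation to ternary features.
#
# A rule is a natural-language structure-activity statement plus an ordered
# list of clauses (substructure predicate -> direction +1/-1) and an optional
# scope predicate. Compiled against a molecule it yields:
#   +1  rule applies and predicts high activity
#   -1  rule applies and predicts low activity
#    0  rule is irrelevant to the molecule (scope fails or no clause matches)
# Clause order is precedence: the first matching clause wins, mirroring the
# if/else-if structure of executable rule encodings.

# ---- predicates -------------------------------------------------------------

new_predicate <- function(kind, smarts = NULL, children = NULL, threshold = NULL) {
  p <- list(kind = kind, smarts = smarts, children = children,
            threshold = threshold)
  class(p) <- "rule_predicate"
  p
}

#' Substructure predicates for rule clauses
#'
#' Predicates are small declarative trees: a SMARTS leaf, Boolean combinators
#' (`and`, `or`, `not`) and a match-count threshold (`count_ge`, true iff the
#' number of unique substructure matches is at least `threshold`).
#'
#' @param smarts a SMARTS pattern.
#' @param ... child predicates (for `pred_and` / `pred_or`).
#' @param p a single child predicate (for `pred_not`).
#' @param threshold minimum number of unique matches (integer >= 1).
#' @return a `rule_predicate` object.
#' @examples
#' pred_and(pred_smarts("c1ccccc1"), pred_not(pred_smarts("[OX2H]")))
#' @export
pred_smarts <- function(smarts) {
  assert_valid_smarts(smarts)
  new_predicate("smarts", smarts = smarts)
}

#' @rdname pred_smarts
#' @export
pred_and <- function(...) {
  ch <- list(...)
  stopifnot(length(ch) >= 1, all(vapply(ch, inherits, logical(1), "rule_predicate")))
  new_predicate("and", children = ch)
}

#' @rdname pred_smarts
#' @export
pred_or <- function(...) {
  ch <- list(...)
  stopifnot(length(ch) >= 1, all(vapply(ch, inherits, logical(1), "rule_predicate")))
  new_predicate("or", children = ch)
}

#' @rdname pred_smarts
#' @export
pred_not <- function(p) {
  stopifnot(inherits(p, "rule_predicate"))
  new_predicate("not", children = list(p))
}

#' @rdname pred_smarts
#' @export
pred_count_ge <- function(smarts, threshold) {
  assert_valid_smarts(smarts)
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 1)
  new_predicate("count_ge", smarts = smarts, threshold = as.integer(threshold))
}

#' Evaluate a predicate against molecules
#'
#' @param pred a `rule_predicate`.
#' @param smiles character vector of valid SMILES.
#' @return logical vector, one entry per molecule.
#' @export
match_predicate <- function(pred, smiles) {
  stopifnot(inherits(pred, "rule_predicate"))
  switch(pred$kind,
    smarts = smarts_match(smiles, pred$smarts),
    count_ge = smarts_count(smiles, pred$smarts) >= pred$threshold,
    and = Reduce(`&`, lapply(pred$children, match_predicate, smiles = smiles)),
    or  = Reduce(`|`, lapply(pred$children, match_predicate, smiles = smiles)),
    not = !match_predicate(pred$children[[1]], smiles),
    stop("unknown predicate kind: ", pred$kind, call. = FALSE)
  )
}

# ---- rules ------------------------------------------------------------------

#' Rule clauses, rule specifications and rule sets
#'
#' `clause()` pairs a predicate with a predicted direction; `rule_spec()`
#' bundles an identifier, the human-readable rule text, ordered clauses and an
#' optional scope predicate (outside the scope the rule evaluates to 0);
#' `rule_set()` is an ordered collection of rules.
#'
#' @param predicate a `rule_predicate`.
#' @param direction `+1` (predicts high) or `-1` (predicts low).
#' @param rule_id short unique identifier.
#' @param text the natural-language statement of the rule.
#' @param clauses list of `rule_clause` objects (at least one).
#' @param scope optional `rule_predicate` gating applicability.
#' @param ... `rule_spec` objects.
#' @param max_rules upper bound on the number of rules (default 15).
#' @return objects of class `rule_clause`, `rule_spec` and `rule_set`.
#' @export
clause <- function(predicate, direction) {
  stopifnot(inherits(predicate, "rule_predicate"), direction %in% c(-1L, 1L))
  structure(list(predicate = predicate, direction = as.integer(direction)),
            class = "rule_clause")
}

#' @rdname clause
#' @export
rule_spec <- function(rule_id, text, clauses, scope = NULL) {
  stopifnot(is.character(rule_id), nzchar(rule_id),
            is.character(text),
            is.list(clauses), length(clauses) >= 1,
            all(vapply(clauses, inherits, logical(1), "rule_clause")))
  if (!is.null(scope)) stopifnot(inherits(scope, "rule_predicate"))
  structure(list(rule_id = rule_id, text = text, clauses = clauses,
                 scope = scope),
            class = "rule_spec")
}

#' @rdname clause
#' @export
rule_set <- function(..., max_rules = 15L) {
  rules <- list(...)
  if (length(rules) == 1 && is.list(rules[[1]]) &&
      !inherits(rules[[1]], "rule_spec")) {
    rules <- rules[[1]]
  }
  stopifnot(length(rules) >= 1,
            all(vapply(rules, inherits, logical(1), "rule_spec")))
  if (length(rules) > max_rules) {
    stop("rule set has ", length(rules), " rules; maximum is ", max_rules,
         call. = FALSE)
  }
  ids <- vapply(rules, `[[`, character(1), "rule_id")
  if (anyDuplicated(ids)) stop("duplicated rule_id(s)", call. = FALSE)
  structure(list(rules = rules), class = "rule_set")
}

rule_ids <- function(rs) vapply(rs$rules, `[[`, character(1), "rule_id")

#' @export
print.rule_set <- function(x, ...) {
  cat("rule set with", length(x$rules), "rule(s)\n")
  for (r in x$rules) {
    cat(sprintf("  [%s] %s (%d clause%s%s)\n", r$rule_id, r$text,
                length(r$clauses), if (length(r$clauses) > 1) "s" else "",
                if (is.null(r$scope)) "" else ", scoped"))
  }
  invisible(x)
}

#' Compile a rule into a molecule evaluator
#'
#' The returned function is pure and deterministic: for each molecule it
#' returns 0 when the scope predicate (if any) fails, otherwise the direction
#' of the first clause whose predicate matches, otherwise 0.
#'
#' @param spec a `rule_spec`.
#' @return a function mapping a character vector of SMILES to an integer
#'   vector with values in `{-1, 0, 1}`.
#' @export
compile_rule <- function(spec) {
  stopifnot(inherits(spec, "rule_spec"))
  force(spec)
  function(smiles) {
    out <- integer(length(smiles))
    live <- rep(TRUE, length(smiles))
    if (!is.null(spec$scope)) live <- match_predicate(spec$scope, smiles)
    undecided <- live
    for (cl in spec$clauses) {
      if (!any(undecided)) break
      idx <- which(undecided)
      hit <- match_predicate(cl$predicate, smiles[idx])
      out[idx[hit]] <- cl$direction
      undecided[idx[hit]] <- FALSE
    }
    out
  }
}

# ---- feature matrix ---------------------------------------------------------

#' Compile a rule set into a ternary feature matrix
#'
#' @param rs a `rule_set` (or a bare list of `rule_spec`s); an empty list
#'   yields an n x 0 matrix.
#' @param ds a `modifier_dataset`, or a character vector of SMILES (ids taken
#'   from names or generated).
#' @return an integer matrix of class `feature_matrix`, samples x rules, with
#'   entries in `{-1, 0, 1}`, row names = sample ids, column names = rule ids.
#' @export
build_feature_matrix <- function(rs, ds) {
  if (inherits(ds, "modifier_dataset")) {
    smiles <- ds$smiles; ids <- ds$id
  } else {
    smiles <- as.character(ds)
    ids <- if (!is.null(names(ds))) names(ds) else paste0("m", seq_along(smiles))
  }
  bad <- !is_valid_smiles(smiles)
  if (any(bad)) {
    stop("invalid SMILES for id(s): ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  }
  rules <- if (inherits(rs, "rule_set")) rs$rules else rs
  fm <- matrix(0L, nrow = length(smiles), ncol = length(rules),
               dimnames = list(ids, vapply(rules, `[[`, character(1), "rule_id")))
  for (j in seq_along(rules)) {
    col <- tryCatch(compile_rule(rules[[j]])(smiles), error = function(e) {
      stop("rule '", rules[[j]]$rule_id, "': ", conditionMessage(e),
           call. = FALSE)
    })
    fm[, j] <- col
  }
  class(fm) <- c("feature_matrix", class(fm))
  fm
}

#' Diagnose structural problems in a feature matrix
#'
#' Flags all-zero columns (zero coverage), columns with fewer than two
#' nonzero entries (a rule must be supported by at least two data points) and
#' constant columns.
#'
#' @param fm a `feature_matrix`.
#' @param rs optional `rule_set` for id cross-checking.
#' @return data.frame with columns `rule_id`, `problem`; zero rows iff clean.
#' @export
check_matrix <- function(fm, rs = NULL) {
  if (!is.null(rs)) {
    stopifnot(identical(colnames(fm), rule_ids(rs)))
  }
  diags <- list()
  for (j in seq_len(ncol(fm))) {
    col <- fm[, j]
    nz <- sum(col != 0L)
    if (nz == 0L) {
      diags[[length(diags) + 1L]] <- data.frame(
        rule_id = colnames(fm)[j], problem = "zero-coverage")
    } else if (nz < 2L) {
      diags[[length(diags) + 1L]] <- data.frame(
        rule_id = colnames(fm)[j], problem = "coverage<2")
    }
    if (nrow(fm) > 1 && length(unique(col)) == 1L && col[1] != 0L) {
      diags[[length(diags) + 1L]] <- data.frame(
        rule_id = colnames(fm)[j], problem = "constant column")
    }
  }
  if (length(diags)) do.call(rbind, diags) else
    data.frame(rule_id = character(), problem = character())
}

#' Cell-wise agreement between two feature matrices
#'
#' @param generated,reference `feature_matrix` objects with identical shape
#'   and row/column ids.
#' @return fraction of cells with equal entries, in `[0, 1]`.
#' @export
matrix_agreement <- function(generated, reference) {
  if (!identical(dim(generated), dim(reference))) {
    stop("matrices differ in shape", call. = FALSE)
  }
  if (!identical(dimnames(generated), dimnames(reference))) {
    stop("matrices differ in row/column ids", call. = FALSE)
  }
  if (length(generated) == 0) return(1)
  mean(generated == reference)
}

# ---- serialisation ----------------------------------------------------------

predicate_to_list <- function(p) {
  switch(p$kind,
    smarts = list(kind = "smarts", smarts = p$smarts),
    count_ge = list(kind = "count_ge", smarts = p$smarts,
                    threshold = p$threshold),
    not = list(kind = "not", children = list(predicate_to_list(p$children[[1]]))),
    list(kind = p$kind, children = lapply(p$children, predicate_to_list))
  )
}

predicate_from_list <- function(x) {
  switch(x$kind,
    smarts = pred_smarts(x$smarts),
    count_ge = pred_count_ge(x$smarts, x$threshold),
    and = do.call(pred_and, lapply(x$children, predicate_from_list)),
    or  = do.call(pred_or, lapply(x$children, predicate_from_list)),
    not = pred_not(predicate_from_list(x$children[[1]])),
    stop("unknown predicate kind: ", x$kind, call. = FALSE)
  )
}

ruleset_to_list <- function(rs) {
  lapply(rs$rules, function(r) {
    out <- list(rule_id = r$rule_id, text = r$text,
                clauses = lapply(r$clauses, function(cl) {
                  list(predicate = predicate_to_list(cl$predicate),
                       direction = cl$direction)
                }))
    if (!is.null(r$scope)) out$scope <- predicate_to_list(r$scope)
    out
  })
}

ruleset_from_list <- function(x) {
  rules <- lapply(x, function(r) {
    rule_spec(
      rule_id = r$rule_id, text = r$text,
      clauses = lapply(r$clauses, function(cl) {
        clause(predicate_from_list(cl$predicate), cl$direction)
      }),
      scope = if (!is.null(r$scope)) predicate_from_list(r$scope)
    )
  })
  rule_set(rules)
}

#' Read and write rule sets as JSON
#'
#' The on-disk format is a JSON array of rule objects
#' `{rule_id, text, scope?, clauses: [{predicate, direction}]}` with nested
#' predicate objects `{kind, smarts?, threshold?, children?}`.
#'
#' @param path JSON file path.
#' @param rs a `rule_set`.
#' @return `read_rules` returns a `rule_set`; `write_rules` returns `path`
#'   invisibly.
#' @export
read_rules <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  ruleset_from_list(x)
}

#' @rdname read_rules
#' @export
write_rules <- function(rs, path) {
  jsonlite::write_json(ruleset_to_list(rs), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read and write feature matrices as CSV
#'
#' Row ids in the first column (`id`), rule ids as the remaining headers.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV file path.
#' @return `read_matrix` returns a `feature_matrix`; `write_matrix` returns
#'   `path` invisibly.
#' @export
write_matrix <- function(fm, path) {
  df <- data.frame(id = rownames(fm), unclass(fm), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  if (length(m) && !all(m %in% c(-1L, 0L, 1L))) {
    stop("feature matrix entries must be in {-1, 0, 1}", call. = FALSE)
  }
  class(m) <- c("feature_matrix", class(m))
  m
}
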