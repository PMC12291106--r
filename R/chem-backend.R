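# Substructure-matching backend (OpenBabel via ChemmineR/ChemmineOB).
#
# All SMARTS evaluation in the package funnels through smarts_count() so that
# results can be memoised: the rule engine, the refinement loop and the
# synthetic-data recovery experiments repeatedly query the same small set of
# molecules against the same patterns.

.molrules <- new.env(parent = emptyenv())
.molrules$match_cache <- new.env(parent = emptyenv())

.cache_key <- function(smiles, smarts) paste(smiles, smarts, sep = "\x01")

#' Check whether SMILES strings parse to valid molecules
#'
#' @param smiles character vector of SMILES strings.
#' @return logical vector, `TRUE` where the string parses to a molecule.
#' @examples
#' is_valid_smiles(c("CC(=O)O", "C1CC"))
#' @export
is_valid_smiles <- function(smiles) {
  if (is.null(.molrules$valid_cache)) {
    .molrules$valid_cache <- new.env(parent = emptyenv())
  }
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    key <- paste0("v\x01", s)
    if (exists(key, envir = .molrules$valid_cache)) {
      return(get(key, envir = .molrules$valid_cache))
    }
    ok <- TRUE
    suppressWarnings(
      tryCatch(ChemmineR::smiles2sdf(stats::setNames(s, "m")),
               error = function(e) ok <<- FALSE)
    )
    assign(key, ok, envir = .molrules$valid_cache)
    ok
  }, logical(1), USE.NAMES = FALSE)
}

# Parse a character vector of SMILES into an SDFset, with a clear error
# naming the offending entries. `ids` label error messages only.
parse_smiles <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(ids)) ids <- paste0("m", seq_along(smiles))
  bad <- !is_valid_smiles(smiles)
  if (any(bad)) {
    stop("invalid SMILES for id(s): ",
         paste(ids[bad], collapse = ", "),
         " [", paste(smiles[bad], collapse = ", "), "]", call. = FALSE)
  }
  suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, make.unique(ids))))
}

# Validate a SMARTS pattern; error names the pattern.
assert_valid_smarts <- function(smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1)
  ok <- tryCatch({
    smarts_count("CCO", smarts)  # multi-atom probe; single-atom SDFs
    TRUE                         # trip an upstream indexing bug
  }, error = function(e) FALSE)
  if (!ok) stop("invalid SMARTS pattern: ", smarts, call. = FALSE)
  invisible(TRUE)
}

#' Count unique SMARTS substructure matches
#'
#' Evaluates one SMARTS pattern against a vector of molecules and returns the
#' number of unique (deduplicated) substructure matches per molecule. Results
#' are memoised per (SMILES, SMARTS) pair for the lifetime of the R session.
#'
#' @param smiles character vector of valid SMILES.
#' @param smarts a single SMARTS pattern.
#' @return integer vector of unique match counts, one per input molecule.
#' @examples
#' smarts_count(c("Nc1ccc(C(=O)O)cc1", "CC(=O)O"), "[NX3;H2,H1]")
#' @export
smarts_count <- function(smiles, smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1)
  keys <- .cache_key(smiles, smarts)
  out <- rep(NA_integer_, length(smiles))
  cached <- vapply(keys, exists, logical(1), envir = .molrules$match_cache)
  if (any(cached)) {
    out[cached] <- vapply(keys[cached], get, integer(1),
                          envir = .molrules$match_cache)
  }
  todo <- which(!cached)
  if (length(todo)) {
    uniq <- unique(smiles[todo])
    sdf <- tryCatch(parse_smiles(uniq),
                    error = function(e) stop(conditionMessage(e), call. = FALSE))
    counts <- tryCatch(
      suppressWarnings(ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE)),
      error = function(e) stop("invalid SMARTS pattern: ", smarts, call. = FALSE)
    )
    counts <- as.integer(counts)
    names(counts) <- uniq
    for (i in todo) {
      v <- counts[[smiles[i]]]
      out[i] <- v
      assign(keys[i], v, envir = .molrules$match_cache)
    }
  }
  out
}

# Boolean convenience wrapper.
smarts_match <- function(smiles, smarts) smarts_count(smiles, smarts) >= 1L

# Path to the bundled python helper used by the fragment-descriptor module
# and by nothing else.
python_helper_path <- function() {
  p <- system.file("python", "fragment_descriptors.py", package = "molrules")
  if (!nzchar(p)) stop("bundled python helper not found", call. = FALSE)
  p
}
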