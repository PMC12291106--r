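# Dataset representation and label construction.
#
# A modifier dataset is a plain data.frame (class "modifier_dataset") with one
# row per molecule. Required columns: id, smiles, yield_percent, fe_loading,
# modifier_sbu, fe_hf. Optional: name, ton, label.

DATASET_REQUIRED <- c("id", "smiles", "yield_percent", "fe_loading",
                      "modifier_sbu", "fe_hf")
DATASET_NUMERIC  <- c("yield_percent", "fe_loading", "modifier_sbu", "fe_hf")

#' Construct a modifier dataset
#'
#' @param df data.frame with at least the columns `id`, `smiles`,
#'   `yield_percent`, `fe_loading`, `modifier_sbu`, `fe_hf`; optionally
#'   `name`, `ton` and `label`.
#' @param check if `TRUE` (default), every SMILES must parse and ids must be
#'   unique; violations raise an error.
#' @return the data.frame with class `modifier_dataset` prepended.
#' @export
modifier_dataset <- function(df, check = TRUE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(DATASET_REQUIRED, names(df))
  if (length(missing_cols)) {
    stop("dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$id <- as.character(df$id)
  df$smiles <- as.character(df$smiles)
  for (col in intersect(c(DATASET_NUMERIC, "ton"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (check) {
    if (anyDuplicated(df$id)) {
      stop("duplicated id(s): ",
           paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
           call. = FALSE)
    }
    bad <- !is_valid_smiles(df$smiles)
    if (any(bad)) {
      stop("invalid SMILES for id(s): ",
           paste(df$id[bad], collapse = ", "), call. = FALSE)
    }
  }
  class(df) <- unique(c("modifier_dataset", class(df)))
  df
}

#' Read a modifier dataset from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row and dot-decimal
#' numerics. Row order is preserved.
#'
#' @param path path to a CSV file with columns `id`, `smiles`,
#'   `yield_percent`, `fe_loading`, `modifier_sbu`, `fe_hf` and optionally
#'   `name`, `ton`, `label`.
#' @param check validate SMILES and id uniqueness (default `TRUE`).
#' @return a `modifier_dataset`.
#' @export
read_dataset <- function(path, check = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  modifier_dataset(df, check = check)
}

#' Write a modifier dataset to CSV
#'
#' @param ds a `modifier_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign high/low labels by the median yield
#'
#' A molecule is labelled `"high"` iff its yield is strictly greater than the
#' median yield of the dataset (standard order-statistic median); ties with
#' the median are labelled `"low"`. With this convention the class split is
#' always within one sample of balance when yields are distinct.
#'
#' @param ds a `modifier_dataset` with all `yield_percent` present.
#' @return the dataset with a `label` factor column (`low` < `high`).
#' @export
binarize_by_median <- function(ds) {
  stopifnot(inherits(ds, "modifier_dataset"))
  if (nrow(ds) == 0) stop("cannot label an empty dataset", call. = FALSE)
  y <- ds$yield_percent
  if (anyNA(y)) stop("yield_percent contains missing values", call. = FALSE)
  med <- stats::median(y)
  ds$label <- factor(ifelse(y > med, "high", "low"), levels = c("low", "high"))
  ds
}

#' Diagnose common dataset problems
#'
#' Returns (rather than raises) diagnostics for duplicated ids, non-finite
#' numeric fields and unparsable SMILES.
#'
#' @param ds a `modifier_dataset` (construct with `check = FALSE` to diagnose
#'   dirty data).
#' @return a data.frame with columns `id`, `field`, `problem`; zero rows iff
#'   the dataset is clean.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "modifier_dataset"))
  diags <- list()
  dup <- unique(ds$id[duplicated(ds$id)])
  for (d in dup) {
    diags[[length(diags) + 1L]] <- data.frame(
      id = d, field = "id", problem = "duplicated id")
  }
  for (col in intersect(DATASET_NUMERIC, names(ds))) {
    bad <- which(!is.finite(ds[[col]]))
    for (i in bad) {
      diags[[length(diags) + 1L]] <- data.frame(
        id = ds$id[i], field = col, problem = "non-finite value")
    }
  }
  bad_smiles <- which(!is_valid_smiles(ds$smiles))
  for (i in bad_smiles) {
    diags[[length(diags) + 1L]] <- data.frame(
      id = ds$id[i], field = "smiles", problem = "unparsable SMILES")
  }
  if (length(diags)) do.call(rbind, diags) else
    data.frame(id = character(), field = character(), problem = character())
}

#' @export
print.modifier_dataset <- function(x, ...) {
  cat("modifier dataset:", nrow(x), "molecules\n")
  if ("label" %in% names(x) && !anyNA(x$label)) {
    tb <- table(x$label)
    cat("labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}
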