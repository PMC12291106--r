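# Fragment-pooled physicochemical descriptors.
#
# A modifier is anchored to the catalyst through its carboxylate, so fragment
# levels are defined as bond-radius shells around the carboxyl carbon
# (default radii 2, 4, 6 bonds; level 1 is a subset of level 2 is a subset of
# level 3). Within each level, five per-atom properties (Gasteiger PEOE
# partial charge, Wildman-Crippen LogP and MR contributions, Labute
# approximate surface area, TPSA contributions) are averaged, giving 15
# descriptors per molecule. The per-atom contributions come from a bundled
# python helper (RDKit), invoked once per batch of molecules.

FRAG_PROPS <- c("PEOE_charge", "LogP", "MR", "LabuteASA", "TPSA")

frag_cache_key <- function(smiles, radii) {
  paste(smiles, paste(radii, collapse = ","), sep = "\x01")
}

# One batched helper invocation; memoised per (smiles, radii).
run_fragment_helper <- function(smiles, radii = c(2, 4, 6)) {
  if (is.null(.molrules$frag_cache)) {
    .molrules$frag_cache <- new.env(parent = emptyenv())
  }
  keys <- frag_cache_key(smiles, radii)
  todo <- which(!vapply(keys, exists, logical(1), envir = .molrules$frag_cache))
  if (length(todo)) {
    uniq <- unique(smiles[todo])
    req <- jsonlite::toJSON(list(smiles = uniq, radii = radii),
                            auto_unbox = FALSE)
    out <- suppressWarnings(
      system2("python", shQuote(python_helper_path()), input = as.character(req),
              stdout = TRUE, stderr = FALSE)
    )
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) {
      stop("descriptor backend failed (python exit status ", status, ")",
           call. = FALSE)
    }
    res <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
    for (i in seq_along(uniq)) {
      assign(frag_cache_key(uniq[i], radii), res[[i]],
             envir = .molrules$frag_cache)
    }
  }
  lapply(keys, get, envir = .molrules$frag_cache)
}

#' Fragment levels around the carboxylate anchor
#'
#' Level k contains every atom within `radii[k]` bonds (topological distance)
#' of the carboxyl carbon; levels are nested by construction. If a molecule
#' carries more than one carboxyl group, the first by canonical atom order is
#' used and a warning is emitted.
#'
#' @param smiles character vector of valid SMILES, each containing a
#'   carboxylic acid / carboxylate group.
#' @param radii increasing integer bond radii, one per level (default
#'   `c(2, 4, 6)`).
#' @return a list (one element per molecule) of lists of integer vectors:
#'   1-based atom indices per level.
#' @export
fragment_from_anchor <- function(smiles, radii = c(2, 4, 6)) {
  stopifnot(all(diff(radii) > 0))
  res <- run_fragment_helper(smiles, radii)
  out <- vector("list", length(smiles))
  for (i in seq_along(res)) {
    r <- res[[i]]
    if (!isTRUE(r$valid)) {
      stop("invalid SMILES: ", smiles[i], call. = FALSE)
    }
    if (identical(r$n_anchors, 0L) || identical(r$n_anchors, 0)) {
      stop("no carboxyl anchor in molecule: ", smiles[i], call. = FALSE)
    }
    if (r$n_anchors > 1) {
      warning("molecule ", smiles[i], " has ", r$n_anchors,
              " carboxyl groups; using the first by canonical atom order",
              call. = FALSE)
    }
    out[[i]] <- lapply(r$levels, function(lv) vapply(lv, as.integer, 1L) + 1L)
  }
  out
}

#' Fragment-pooled descriptor row for one molecule
#'
#' @param smiles a single valid SMILES with a carboxyl anchor.
#' @param levels optional list of 1-based atom-index vectors (one per level),
#'   e.g. from [fragment_from_anchor()]; overrides `radii` when given.
#' @param radii bond radii defining the fragment levels.
#' @return named numeric vector of `5 properties x n_levels` pooled
#'   (mean per-atom) values, named `<property>_L<level>`.
#' @export
pooled_descriptors <- function(smiles, levels = NULL, radii = c(2, 4, 6)) {
  stopifnot(length(smiles) == 1)
  r <- run_fragment_helper(smiles, radii)[[1]]
  if (!isTRUE(r$valid)) stop("invalid SMILES: ", smiles, call. = FALSE)
  if (is.null(levels) && !r$n_anchors) {
    stop("no carboxyl anchor in molecule: ", smiles, call. = FALSE)
  }
  if (is.null(levels)) {
    levels <- lapply(r$levels, function(lv) vapply(lv, as.integer, 1L) + 1L)
  }
  out <- numeric(0)
  for (lev in seq_along(levels)) {
    atoms <- as.integer(levels[[lev]])
    stopifnot(all(atoms >= 1), all(atoms <= r$n_atoms))
    for (p in FRAG_PROPS) {
      vals <- vapply(r$props[[p]], as.numeric, 1)[atoms]
      if (any(!is.finite(vals))) {
        stop("non-finite ", p, " contribution for molecule ", smiles,
             call. = FALSE)
      }
      out[sprintf("%s_L%d", p, lev)] <- mean(vals)
    }
  }
  out
}

#' Fragment-pooled descriptor table for a dataset
#'
#' @param ds a `modifier_dataset` (or character vector of SMILES).
#' @param radii bond radii defining the fragment levels.
#' @return data.frame with `id` plus one column per pooled descriptor.
#' @export
fragment_descriptor_table <- function(ds, radii = c(2, 4, 6)) {
  if (inherits(ds, "modifier_dataset")) {
    smiles <- ds$smiles; ids <- ds$id
  } else {
    smiles <- as.character(ds); ids <- paste0("m", seq_along(smiles))
  }
  run_fragment_helper(smiles, radii)  # one batched backend call
  rows <- lapply(smiles, pooled_descriptors, radii = radii)
  tab <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(id = ids), tab)
}

#' Greedy removal of highly correlated features
#'
#' Scans column pairs in order; whenever `|Pearson r| > threshold`, the
#' later column is dropped. Zero-variance columns are dropped first with a
#' diagnostic. The procedure is deterministic in column order.
#'
#' @param feature_table data.frame or matrix of numeric features (an `id`
#'   column, if present, is ignored).
#' @param threshold absolute correlation above which the later feature is
#'   removed (default 0.95).
#' @return character vector of retained feature names, in input order, with
#'   attribute `dropped` (data.frame of dropped features and reasons).
#' @export
prune_correlated <- function(feature_table, threshold = 0.95) {
  ft <- as.data.frame(feature_table)
  ft$id <- NULL
  stopifnot(ncol(ft) >= 2, nrow(ft) >= 3)
  dropped <- data.frame(feature = character(), reason = character())
  keep <- character(0)
  for (nm in names(ft)) {
    v <- ft[[nm]]
    if (stats::sd(v) == 0) {
      dropped <- rbind(dropped, data.frame(feature = nm,
                                           reason = "zero variance"))
      next
    }
    redundant <- FALSE
    for (prev in keep) {
      if (abs(stats::cor(v, ft[[prev]])) > threshold) {
        dropped <- rbind(dropped, data.frame(
          feature = nm, reason = paste0("|r| > ", threshold, " with ", prev)))
        redundant <- TRUE
        break
      }
    }
    if (!redundant) keep <- c(keep, nm)
  }
  attr(keep, "dropped") <- dropped
  keep
}
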