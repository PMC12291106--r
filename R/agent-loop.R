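# Iterative multi-role rule refinement loop.
#
# One round runs the full cycle
#   rule_generator -> rule_commenter -> rule_advisor -> matrix_generator
#   -> (compile matrix, check) -> matrix_checker -> metrics
#   -> metric_commenter -> ML eval -> ml_commenter -> project_manager
# against a pluggable chat backend. Conversational roles exchange messages
# whose payloads are JSON blocks; the computational stages (matrix
# compilation in "code mode", association metrics, cross-validated ML
# accuracy) are executed in-process by the rule engine and never delegated
# to the backend. A scripted backend replays a transcript fixture verbatim,
# making the whole loop deterministic and offline.

LOOP_ROLES <- data.frame(
  name = c("rule_generator", "rule_commenter", "rule_advisor",
           "matrix_generator", "matrix_checker", "metric_calculator",
           "metric_commenter", "ml_calculator", "ml_commenter",
           "project_manager"),
  memory_scope = c("current_round", "current_round", "full_history",
                   "current_round", "current_round", "current_round",
                   "full_history", "current_round", "full_history",
                   "full_history"),
  backed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

#' Loop configuration
#'
#' @param max_iterations hard cap on refinement rounds (default 10).
#' @param epsilon minimum round-to-round accuracy improvement counted as
#'   progress (default 0.01).
#' @param revision_threshold a rule revised more than this many times with
#'   sub-epsilon improvement triggers the stop rule (default 3).
#' @param model a [model_spec()] for the in-loop ML evaluation.
#' @param k folds for the in-loop cross-validation (default 5).
#' @param min_rules,max_rules guideline bounds on the rule-set size.
#' @return a list of class `loop_config`.
#' @export
loop_config <- function(max_iterations = 10L, epsilon = 0.01,
                        revision_threshold = 3L,
                        model = model_spec(seed = 0L), k = 5L,
                        min_rules = 5L, max_rules = 15L) {
  structure(list(max_iterations = as.integer(max_iterations),
                 epsilon = epsilon,
                 revision_threshold = as.integer(revision_threshold),
                 model = model, k = as.integer(k),
                 min_rules = as.integer(min_rules),
                 max_rules = as.integer(max_rules)),
            class = "loop_config")
}

#' Fresh loop state
#'
#' @return a list of class `loop_state` tracking iteration count, rule-text
#'   versions, compiled rule sets, transcripts, metric/ML reports, per-rule
#'   revision counts and the stop decision.
#' @export
loop_state <- function() {
  structure(list(iteration = 0L,
                 rule_texts = list(),       # per round: named character
                 ruleset_versions = list(), # per round: rule_set
                 matrices = list(),
                 metric_reports = list(),
                 ml_reports = list(),
                 accuracy_history = numeric(0),
                 revision_counts = integer(0),
                 transcripts = list(),
                 protocol_violations = 0L,
                 stopped = FALSE,
                 stop_reason = NA_character_),
            class = "loop_state")
}

agent_message <- function(role, iteration, direction, content, payload = NULL) {
  list(role = role, iteration = iteration, direction = direction,
       content = content, payload = payload)
}

append_message <- function(state, ...) {
  state$transcripts[[length(state$transcripts) + 1L]] <- agent_message(...)
  state
}

# ---- payload parsing --------------------------------------------------------

# A response must contain exactly one JSON payload: either a single fenced
# ```json block (surrounding prose is tolerated) or the whole content being
# valid JSON.
parse_payload <- function(content) {
  pat <- "(?s)```json\\s*\\n.*?```"
  hits <- regmatches(content, gregexpr(pat, content, perl = TRUE))[[1]]
  if (length(hits) > 1) {
    stop("response contains ", length(hits),
         " JSON blocks; exactly one is required", call. = FALSE)
  }
  txt <- if (length(hits) == 1) {
    sub("```$", "", sub("^```json\\s*\\n", "", hits))
  } else {
    content
  }
  jsonlite::fromJSON(txt, simplifyVector = FALSE)
}

protocol_violation <- function(role, message) {
  structure(class = c("protocol_violation", "error", "condition"),
            list(message = paste0("[", role, "] ", message), call = NULL))
}

# Ask the backend for a role's response and parse/validate its payload.
# One retry (with the error echoed back) is allowed before a protocol
# violation is signalled.
ask_role <- function(backend, role, iteration, request, validate = NULL) {
  attempt <- function(req) {
    content <- backend$ask(role, req)
    payload <- parse_payload(content)
    if (!is.null(validate)) validate(payload)
    list(content = content, payload = payload)
  }
  res <- tryCatch(attempt(request), error = function(e) e)
  if (inherits(res, "error")) {
    retry_req <- paste0(request, "\n[protocol error, please fix and resend: ",
                        conditionMessage(res), "]")
    res <- tryCatch(attempt(retry_req), error = function(e) e)
    if (inherits(res, "error")) {
      stop(protocol_violation(role, conditionMessage(res)))
    }
  }
  res
}

# ---- backends ---------------------------------------------------------------

#' Scripted chat backend
#'
#' Replays a transcript fixture: responses are returned verbatim in order,
#' each keyed by the role expected to speak next. Requests are checked
#' against that order; a role mismatch or an exhausted script raises an
#' error. Fixtures are JSONL files (one `{"role": ..., "content": ...}`
#' object per line) or equivalent in-memory lists.
#'
#' @param fixture path to a JSONL transcript, or a list of
#'   `list(role =, content =)` messages.
#' @return a backend object with an `ask(role, request)` function.
#' @export
scripted_backend <- function(fixture) {
  msgs <- if (is.character(fixture)) {
    lines <- readLines(fixture, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  } else {
    fixture
  }
  env <- new.env(parent = emptyenv())
  env$cursor <- 0L
  structure(list(
    kind = "scripted",
    n_messages = length(msgs),
    ask = function(role, request) {
      env$cursor <- env$cursor + 1L
      if (env$cursor > length(msgs)) {
        stop("scripted backend exhausted after ", length(msgs),
             " messages (next role requested: ", role, ")", call. = FALSE)
      }
      msg <- msgs[[env$cursor]]
      if (!identical(msg$role, role)) {
        stop("scripted backend out of sequence: expected role '", msg$role,
             "' but '", role, "' was requested", call. = FALSE)
      }
      msg$content
    },
    rewind = function() env$cursor <- 0L
  ), class = "chat_backend")
}

#' Live HTTP chat backend stub
#'
#' Contract for a chat-completion-style backend (role-tagged messages over
#' HTTP). The core package never calls the network; this constructor only
#' records the endpoint configuration and fails loudly when asked, so that
#' offline use is explicit. Supply a custom `ask` function to integrate a
#' real service.
#'
#' @param url endpoint URL.
#' @param model model name sent with each request.
#' @param temperature sampling temperature.
#' @param ask optional function `(role, request) -> character` implementing
#'   the transport.
#' @return a backend object with an `ask(role, request)` function.
#' @export
http_backend <- function(url, model = "", temperature = 0, ask = NULL) {
  if (is.null(ask)) {
    ask <- function(role, request) {
      stop("http_backend has no transport configured; supply ask=",
           call. = FALSE)
    }
  }
  structure(list(kind = "http", url = url, model = model,
                 temperature = temperature, ask = ask),
            class = "chat_backend")
}

# ---- guideline checking -----------------------------------------------------

#' Check a rule set and its matrix against the authoring guidelines
#'
#' Flags rule-set sizes outside the configured range, rules supported by
#' fewer than two data points, and (optionally) rules whose nonzero entries
#' all share one direction when direction variety was requested.
#'
#' @param rs a `rule_set`.
#' @param fm the `feature_matrix` built from `rs`.
#' @param min_rules,max_rules inclusive bounds on the rule count.
#' @param require_direction_variety flag single-direction rules (default
#'   `FALSE`).
#' @return data.frame with columns `rule_id` (`"*"` for set-level findings)
#'   and `problem`; zero rows iff all guidelines are met.
#' @export
guideline_check <- function(rs, fm, min_rules = 5L, max_rules = 15L,
                            require_direction_variety = FALSE) {
  stopifnot(inherits(rs, "rule_set"))
  diags <- list()
  n_rules <- length(rs$rules)
  if (n_rules < min_rules) {
    diags[[length(diags) + 1L]] <- data.frame(
      rule_id = "*", problem = paste0("count below ", min_rules))
  }
  if (n_rules > max_rules) {
    diags[[length(diags) + 1L]] <- data.frame(
      rule_id = "*", problem = paste0("count above ", max_rules))
  }
  cm <- check_matrix(fm, rs)
  cov <- cm[cm$problem %in% c("zero-coverage", "coverage<2"), , drop = FALSE]
  if (nrow(cov)) diags[[length(diags) + 1L]] <- cov
  if (require_direction_variety) {
    for (j in seq_len(ncol(fm))) {
      nz <- fm[fm[, j] != 0, j]
      if (length(nz) && length(unique(nz)) == 1L) {
        diags[[length(diags) + 1L]] <- data.frame(
          rule_id = colnames(fm)[j], problem = "no direction variety")
      }
    }
  }
  if (length(diags)) do.call(rbind, diags) else
    data.frame(rule_id = character(), problem = character())
}

# ---- stopping rule ----------------------------------------------------------

#' Decide whether the refinement loop should stop
#'
#' Stops when (a) any rule has been revised more than `revision_threshold`
#' times while the last round improved accuracy by less than `epsilon`,
#' (b) the project manager signalled acceptance, or (c) the iteration cap is
#' reached.
#'
#' @param state a `loop_state`.
#' @param config a [loop_config()].
#' @return `list(stop = logical, reason = character)`.
#' @export
stopping_rule <- function(state, config = loop_config()) {
  if (isTRUE(state$manager_accepted)) {
    return(list(stop = TRUE, reason = "manager acceptance"))
  }
  deltas <- diff(state$accuracy_history)
  last_delta <- if (length(deltas)) deltas[length(deltas)] else Inf
  if (length(state$revision_counts) &&
      any(state$revision_counts > config$revision_threshold) &&
      last_delta < config$epsilon) {
    return(list(stop = TRUE, reason = "revision threshold"))
  }
  if (state$iteration >= config$max_iterations) {
    return(list(stop = TRUE, reason = "max iterations"))
  }
  list(stop = FALSE, reason = "continue")
}

# ---- the round --------------------------------------------------------------

validate_rule_texts <- function(payload) {
  if (length(payload) == 0) stop("empty rule set", call. = FALSE)
  for (r in payload) {
    if (is.null(r$rule_id) || is.null(r$text)) {
      stop("each rule needs rule_id and text", call. = FALSE)
    }
  }
  invisible(TRUE)
}

validate_encoded_rules <- function(payload) {
  if (length(payload) == 0) stop("empty rule set", call. = FALSE)
  ruleset_from_list(payload)  # errors on malformed predicates
  invisible(TRUE)
}

#' Run one refinement round
#'
#' Executes a full generate / comment / advise / encode / compile / check /
#' score / evaluate / decide cycle. All exchanged messages are appended to
#' the state's transcript; a backend protocol violation (after one retry
#' with the error echoed back) is recorded and leaves the iteration counter
#' unchanged.
#'
#' @param state a `loop_state` (not yet stopped).
#' @param backend a chat backend (e.g. [scripted_backend()]).
#' @param ds a labelled `modifier_dataset`.
#' @param config a [loop_config()].
#' @return the updated `loop_state`.
#' @export
run_round <- function(state, backend, ds, config = loop_config()) {
  stopifnot(inherits(state, "loop_state"), !state$stopped,
            inherits(ds, "modifier_dataset"), "label" %in% names(ds))
  it <- state$iteration + 1L

  res <- tryCatch({
    out <- state

    # -- rule generation ------------------------------------------------------
    req <- sprintf(paste0(
      "Round %d. Propose or revise structure-activity rules for %d ",
      "molecules (labels: %s). Reply with one JSON block: a list of ",
      "{rule_id, text}."), it, nrow(ds),
      paste(levels(ds$label), table(ds$label), sep = "=", collapse = ", "))
    out <- append_message(out, "rule_generator", it, "request", req)
    gen <- ask_role(backend, "rule_generator", it, req, validate_rule_texts)
    out <- append_message(out, "rule_generator", it, "response",
                          gen$content, gen$payload)
    texts <- stats::setNames(
      vapply(gen$payload, function(r) r$text, character(1)),
      vapply(gen$payload, function(r) r$rule_id, character(1)))
    prev <- if (length(out$rule_texts)) {
      out$rule_texts[[length(out$rule_texts)]]
    } else stats::setNames(character(0), character(0))
    for (id in names(texts)) {
      if (!(id %in% names(out$revision_counts))) {
        out$revision_counts[id] <- 0L
      }
      if (id %in% names(prev) && !identical(prev[[id]], texts[[id]])) {
        out$revision_counts[id] <- out$revision_counts[id] + 1L
      }
    }
    out$rule_texts[[it]] <- texts

    # -- commentary and advice ------------------------------------------------
    req <- paste0("Assess clarity, property insight, complexity, coverage ",
                  "and balance of the current rules. One JSON block.")
    out <- append_message(out, "rule_commenter", it, "request", req)
    com <- ask_role(backend, "rule_commenter", it, req)
    out <- append_message(out, "rule_commenter", it, "response",
                          com$content, com$payload)

    req <- paste0("Given the comments and the full discussion history, ",
                  "advise the rule generator. One JSON block.")
    out <- append_message(out, "rule_advisor", it, "request", req)
    adv <- ask_role(backend, "rule_advisor", it, req)
    out <- append_message(out, "rule_advisor", it, "response",
                          adv$content, adv$payload)

    # -- declarative encoding + code-mode compilation -------------------------
    req <- paste0("Encode the current rules as declarative SMARTS clauses ",
                  "(JSON rule objects with predicate trees and directions).")
    out <- append_message(out, "matrix_generator", it, "request", req)
    enc <- ask_role(backend, "matrix_generator", it, req,
                    validate_encoded_rules)
    out <- append_message(out, "matrix_generator", it, "response",
                          enc$content, enc$payload)
    rs <- ruleset_from_list(enc$payload)
    fm <- build_feature_matrix(rs, ds)
    checks <- rbind(check_matrix(fm, rs),
                    guideline_check(rs, fm, config$min_rules,
                                    config$max_rules))

    req <- sprintf(paste0(
      "Compiled %d x %d matrix; %d structural finding(s): %s. ",
      "Confirm or flag. One JSON block."), nrow(fm), ncol(fm), nrow(checks),
      if (nrow(checks)) paste(checks$rule_id, checks$problem, sep = ":",
                              collapse = "; ") else "none")
    out <- append_message(out, "matrix_checker", it, "request", req)
    chk <- ask_role(backend, "matrix_checker", it, req)
    out <- append_message(out, "matrix_checker", it, "response",
                          chk$content, chk$payload)

    # -- metrics (computed) ---------------------------------------------------
    met <- metrics_report(fm, ds)
    out <- append_message(out, "metric_calculator", it, "response",
                          "support/confidence/lift/leverage computed", met)
    req <- paste0("Comment on the rule metrics across iterations. ",
                  "One JSON block.")
    out <- append_message(out, "metric_commenter", it, "request", req)
    mc <- ask_role(backend, "metric_commenter", it, req)
    out <- append_message(out, "metric_commenter", it, "response",
                          mc$content, mc$payload)

    # -- ML evaluation (computed) ---------------------------------------------
    ml <- kfold_cv(fm, ds$label, config$model, k = config$k,
                   seed = config$model$seed)
    out <- append_message(out, "ml_calculator", it, "response",
                          sprintf("%d-fold CV accuracy %.3f", config$k,
                                  ml$accuracy_mean),
                          list(accuracy = ml$accuracy_mean))
    req <- sprintf(paste0("CV accuracy is %.3f. Diagnose over/underfitting ",
                          "and rule effectiveness. One JSON block."),
                   ml$accuracy_mean)
    out <- append_message(out, "ml_commenter", it, "request", req)
    mlc <- ask_role(backend, "ml_commenter", it, req)
    out <- append_message(out, "ml_commenter", it, "response",
                          mlc$content, mlc$payload)

    # -- manager decision -----------------------------------------------------
    req <- paste0("Review this round. Reply with one JSON block ",
                  '{"decision": "accept"|"continue", "reason": ...}.')
    out <- append_message(out, "project_manager", it, "request", req)
    pm <- ask_role(backend, "project_manager", it, req, function(p) {
      if (is.null(p$decision) || !p$decision %in% c("accept", "continue")) {
        stop("decision must be 'accept' or 'continue'", call. = FALSE)
      }
    })
    out <- append_message(out, "project_manager", it, "response",
                          pm$content, pm$payload)

    out$iteration <- it
    out$ruleset_versions[[it]] <- rs
    out$matrices[[it]] <- fm
    out$metric_reports[[it]] <- met
    out$ml_reports[[it]] <- ml
    out$accuracy_history <- c(out$accuracy_history, ml$accuracy_mean)
    out$manager_accepted <- identical(pm$payload$decision, "accept")
    dec <- stopping_rule(out, config)
    out$stopped <- dec$stop
    out$stop_reason <- if (dec$stop) dec$reason else NA_character_
    out
  }, protocol_violation = function(e) {
    st <- state
    st$protocol_violations <- st$protocol_violations + 1L
    st <- append_message(st, "project_manager", it, "response",
                         paste0("protocol violation: ", conditionMessage(e)))
    st
  })
  res
}

#' Run the refinement loop to completion
#'
#' @inheritParams run_round
#' @param final_loo run a leave-one-out evaluation of the final matrix once
#'   the loop stops (default `TRUE`).
#' @return the final `loop_state`, with `final_report` (an `eval_report`)
#'   when `final_loo` is set and at least one round completed.
#' @export
run_loop <- function(ds, backend, config = loop_config(), final_loo = TRUE) {
  state <- loop_state()
  while (!state$stopped) {
    before <- state$iteration
    state <- run_round(state, backend, ds, config)
    if (state$iteration == before && !state$stopped) {
      # protocol violation without progress: give up rather than spin
      state$stopped <- TRUE
      state$stop_reason <- "protocol failure"
    }
  }
  if (final_loo && length(state$matrices)) {
    fm <- state$matrices[[length(state$matrices)]]
    state$final_report <- loo_eval(fm, ds$label, config$model,
                                   seeds = config$model$seed)
  }
  state
}

#' @export
print.loop_state <- function(x, ...) {
  cat("refinement loop state: iteration", x$iteration,
      if (x$stopped) paste0("(stopped: ", x$stop_reason, ")") else "(running)",
      "\n")
  if (length(x$accuracy_history)) {
    cat("  accuracy history:",
        paste(sprintf("%.3f", x$accuracy_history), collapse = " -> "), "\n")
  }
  if (length(x$revision_counts)) {
    cat("  revisions:", paste(names(x$revision_counts), x$revision_counts,
                              sep = "=", collapse = ", "), "\n")
  }
  cat("  transcript:", length(x$transcripts), "messages;",
      x$protocol_violations, "protocol violation(s)\n")
  invisible(x)
}

# ---- transcript serialisation ----------------------------------------------

#' Write and read loop transcripts as JSONL
#'
#' One agent message per line: `{role, iteration, direction, content,
#' payload}`. Round-trips losslessly.
#'
#' @param transcripts list of agent messages (e.g. `state$transcripts`).
#' @param path JSONL file path.
#' @return `write_transcript` returns `path` invisibly; `read_transcript`
#'   returns the list of messages.
#' @export
write_transcript <- function(transcripts, path) {
  lines <- vapply(transcripts, function(m) {
    as.character(jsonlite::toJSON(m, auto_unbox = TRUE, null = "null",
                                  digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transcript
#' @export
read_transcript <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines[nzchar(lines)], jsonlite::fromJSON, simplifyVector = FALSE)
}
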