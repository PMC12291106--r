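test_that("scripted replay refines the rule to its final wording and stops", {
  ds <- example_modifier_dataset()
  cfg <- loop_config(model = model_spec(seed = 1))
  st <- run_loop(ds, scripted_backend(replay_messages()), cfg)

  expect_true(st$stopped)
  expect_equal(st$stop_reason, "manager acceptance")
  expect_equal(st$iteration, 4)
  expect_equal(st$protocol_violations, 0)
  expect_equal(
    unname(st$rule_texts[[4]][["r2"]]),
    paste("para-substituted benzoic acids with electron-withdrawing,",
          "metal-coordinating groups yield high; electron-donating",
          "or noncoordinating groups yield low"))
  expect_equal(unname(st$revision_counts[["r2"]]), 3)

  # the final round's matrix classifies the six reference molecules exactly
  fm <- st$matrices[[4]]
  ex <- para_benzoic_examples()
  expect_equal(unname(fm[ex$id, "r2"]), ex$expected)

  # no stale artifacts: every completed round carries matrix+metrics+ML
  expect_length(st$matrices, 4)
  expect_length(st$metric_reports, 4)
  expect_length(st$ml_reports, 4)
  expect_s3_class(st$final_report, "eval_report")

  # deterministic across repeats
  st2 <- run_loop(ds, scripted_backend(replay_messages()), cfg)
  expect_identical(st$accuracy_history, st2$accuracy_history)
  expect_identical(lapply(st$matrices, unclass), lapply(st2$matrices, unclass))
  expect_identical(st$transcripts, st2$transcripts)
})

test_that("each replay round speaks for every conversational role", {
  ds <- example_modifier_dataset()
  st <- run_loop(ds, scripted_backend(replay_messages()),
                 loop_config(model = model_spec(seed = 1)), final_loo = FALSE)
  resp <- Filter(function(m) m$direction == "response", st$transcripts)
  for (it in 1:4) {
    roles <- vapply(Filter(function(m) m$iteration == it, resp),
                    `[[`, character(1), "role")
    expect_true(all(c("rule_generator", "rule_commenter", "rule_advisor",
                      "matrix_generator", "matrix_checker",
                      "metric_calculator", "metric_commenter",
                      "ml_calculator", "ml_commenter", "project_manager")
                    %in% roles))
  }
})

test_that("an empty ruleset is a protocol violation that freezes the state", {
  ds <- example_modifier_dataset()
  empty <- "```json\n[]\n```"
  be <- scripted_backend(list(
    list(role = "rule_generator", content = empty),
    list(role = "rule_generator", content = empty)  # the retry
  ))
  st <- run_round(loop_state(), be, ds)
  expect_equal(st$iteration, 0)
  expect_equal(st$protocol_violations, 1)
  expect_false(st$stopped)
})

test_that("scripted backend enforces order and detects exhaustion", {
  be <- scripted_backend(list())
  expect_error(be$ask("rule_generator", "go"), "exhausted")
  be2 <- scripted_backend(list(list(role = "rule_commenter", content = "{}")))
  expect_error(be2$ask("rule_generator", "go"), "rule_commenter")
})

test_that("payload parsing requires exactly one JSON block", {
  one <- "prose before\n```json\n{\"a\": 1}\n```\nprose after"
  expect_equal(molrules:::parse_payload(one)$a, 1)
  expect_equal(molrules:::parse_payload('{"b": 2}')$b, 2)
  two <- paste0(one, "\n```json\n{}\n```")
  expect_error(molrules:::parse_payload(two), "exactly one")
  expect_error(molrules:::parse_payload("no json here"))
})

test_that("the stop rule covers threshold, acceptance and iteration cap", {
  cfg <- loop_config(epsilon = 0.01, max_iterations = 10)
  fresh <- loop_state()
  expect_false(stopping_rule(fresh, cfg)$stop)

  st <- loop_state()
  st$revision_counts <- c(r2 = 4L)
  st$accuracy_history <- c(0.6, 0.605)  # sub-epsilon improvement
  dec <- stopping_rule(st, cfg)
  expect_true(dec$stop)
  expect_equal(dec$reason, "revision threshold")

  # a clearly improving rule is not cut off by the revision count
  st$accuracy_history <- c(0.6, 0.75)
  expect_false(stopping_rule(st, cfg)$stop)

  st2 <- loop_state()
  st2$iteration <- 10L
  dec2 <- stopping_rule(st2, cfg)
  expect_true(dec2$stop)
  expect_equal(dec2$reason, "max iterations")

  st3 <- loop_state()
  st3$manager_accepted <- TRUE
  expect_equal(stopping_rule(st3, cfg)$reason, "manager acceptance")
})

test_that("guideline check flags size, coverage and direction problems", {
  ds <- example_modifier_dataset()
  rs3 <- rule_set(decoy_rules()[1:3])
  fm3 <- build_feature_matrix(rs3, ds)
  g <- guideline_check(rs3, fm3)
  expect_true(any(grepl("count below 5", g$problem)))

  rs <- rule_set(c(list(para_ewg_rule()), decoy_rules()))
  fm <- build_feature_matrix(rs, ds)
  g2 <- guideline_check(rs, fm)
  # the ether decoy applies to a single molecule here -> coverage finding
  expect_true(any(g2$rule_id == "ether_low"))
  expect_false("r2" %in% g2$rule_id)

  g3 <- guideline_check(rs, fm, require_direction_variety = TRUE)
  expect_true(any(g3$problem == "no direction variety"))
})

test_that("transcripts round-trip through JSONL", {
  ds <- example_modifier_dataset()
  st <- run_loop(ds, scripted_backend(replay_messages()),
                 loop_config(model = model_spec(seed = 1)), final_loo = FALSE)
  path <- tempfile(fileext = ".jsonl")
  write_transcript(st$transcripts, path)
  back <- read_transcript(path)
  expect_length(back, length(st$transcripts))
  for (k in seq_along(back)) {
    expect_equal(back[[k]]$role, st$transcripts[[k]]$role)
    expect_equal(back[[k]]$iteration, st$transcripts[[k]]$iteration)
    expect_equal(back[[k]]$content, st$transcripts[[k]]$content)
  }
})
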