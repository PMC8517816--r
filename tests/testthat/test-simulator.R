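# In silico patient protocol: answer patterns, trajectory reproducibility,
# extreme profiles, convergence measurement and review exports.

model <- load_model(default_model_path())

test_that("answer sequences follow the scenario patterns", {
  qids <- model$dimensions$anxiety$question_ids
  imm <- generate_answer_sequence(
    model, scenario_spec("immediate_worsening", "anxiety"))
  expect_length(imm, 15L)
  for (t in 1:9) expect_equal(unname(imm[[t]]$indices[qids]), rep(0L, 3))
  for (t in 10:15) expect_equal(unname(imm[[t]]$indices[qids]), rep(3L, 3))

  const <- generate_answer_sequence(
    model, scenario_spec("constant_lowest", "anxiety"))
  for (t in 1:15) expect_equal(unname(const[[t]]$indices[qids]), rep(0L, 3))

  prog <- generate_answer_sequence(
    model, scenario_spec("progressive_worsening", "anxiety"))
  lv <- vapply(prog, function(a) max(a$indices), integer(1))
  expect_equal(lv[1:9], rep(0L, 9))
  expect_true(all(diff(lv[10:15]) >= 0))     # non-decreasing ramp
  expect_equal(lv[15], 3L)                   # reaches the highest level

  # non-target handling: unanswered by default, lowest on request
  expect_setequal(names(imm[[1]]$indices), qids)
  low <- generate_answer_sequence(
    model, scenario_spec("immediate_worsening", "anxiety",
                         nontarget = "lowest"))
  expect_setequal(names(low[[1]]$indices), names(model$questions))
  expect_equal(unname(low[[3]]$indices[["sleep_quality"]]), 0L)

  # sampled mode is deterministic given the seed
  sc <- scenario_spec("immediate_worsening", "anxiety",
                      answer_mode = "sampled", seed = 99L)
  expect_identical(generate_answer_sequence(model, sc),
                   generate_answer_sequence(model, sc))
  sc2 <- scenario_spec("immediate_worsening", "anxiety",
                       answer_mode = "sampled", seed = 100L)
  expect_false(identical(generate_answer_sequence(model, sc),
                         generate_answer_sequence(model, sc2)))
})

test_that("scenario runs are reproducible and leave non-target advice flat", {
  sc <- scenario_spec("immediate_worsening", "anxiety", seed = 5L)
  tr <- run_scenario(model, sc)
  expect_length(tr$steps, 15L)
  expect_equal(vapply(tr$steps, function(s) s$state$step, integer(1)), 1:15)
  expect_identical(run_scenario(model, sc), tr)

  score <- function(t, id, col) {
    a <- tr$steps[[t]]$state$advice
    a[[col]][a$id == id]
  }
  # emergency-type advice rises after the worsening onset
  for (id in c("call_emergency", "call_friends", "call_psychiatrist")) {
    expect_gt(score(15, id, "absolute"), score(9, id, "absolute"))
  }
  # advice without the anxiety parent: constant absolute, falling normalized
  for (id in c("sleep_hygiene", "physical_activity", "social_rhythm")) {
    abs_scores <- vapply(1:15, score, numeric(1), id = id, col = "absolute")
    expect_equal(max(abs_scores) - min(abs_scores), 0, tolerance = 1e-9)
    expect_lt(score(15, id, "normalized"), score(9, id, "normalized"))
  }
})

test_that("severity mass accumulates after onset, with path-independent endpoint", {
  mass <- function(tr, t) {
    sum(tr$steps[[t]]$state$dimensions$anxiety$cs[c("medium", "high")])
  }
  imm <- run_scenario(model, scenario_spec("immediate_worsening", "anxiety"))
  prog <- run_scenario(model, scenario_spec("progressive_worsening", "anxiety"))
  for (tr in list(imm, prog)) {
    m10_15 <- vapply(10:15, mass, numeric(1), tr = tr)
    expect_true(all(diff(m10_15) >= -1e-12))
  }
  expect_equal(mass(imm, 15), mass(prog, 15), tolerance = 0.05)

  # the constant scenario keeps the target's severity mode at absent/low
  const <- run_scenario(model, scenario_spec("constant_lowest", "anxiety"))
  cs15 <- const$steps[[15]]$state$dimensions$anxiety$cs
  expect_true(names(which.max(cs15)) %in% c("absent", "low"))
})

test_that("extreme profiles bracket the prior in stochastic order", {
  ep <- extreme_profiles(model, "anxiety", "man_over_18")
  expect_equal(unname(ep$a_priori), c(0.3, 0.4, 0.15, 0.15))
  expect_equal(names(which.max(ep$p_minus)), "absent")
  expect_equal(names(which.max(ep$p_plus)), "high")
  expect_gt(ep$p_plus[["high"]], ep$a_priori[["high"]])

  for (d in names(model$dimensions)) {
    for (ctx in context_profiles) {
      ep <- extreme_profiles(model, d, ctx)
      expect_true(stochastically_leq(ep$p_minus, ep$a_priori))
      expect_true(stochastically_leq(ep$a_priori, ep$p_plus))
    }
  }
})

test_that("ranking convergence is measured from the trajectory tail", {
  tr <- run_scenario(model, scenario_spec("constant_lowest", "anxiety"))
  s <- convergence_steps(tr)
  expect_lte(s, 3L)
  # definition: all rankings from s on equal the final ranking, s minimal
  rankings <- lapply(tr$steps, function(x) advice_ranking(x$state))
  final <- rankings[[15]]
  expect_true(all(vapply(s:15, function(t) identical(rankings[[t]], final),
                         logical(1))))
  if (s > 1) expect_false(identical(rankings[[s - 1]], final))

  one <- run_scenario(model, scenario_spec("constant_lowest", "anxiety",
                                           n_steps = 1L, onset_step = 1L))
  expect_equal(convergence_steps(one), 1L)
  expect_error(convergence_steps(structure(list(steps = list()),
                                           class = "emibayes_trajectory")),
               class = "emibayes_input_error")
})

test_that("review exports are complete, normalised and byte-stable", {
  tr <- run_scenario(model, scenario_spec("immediate_worsening", "anxiety"))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  files <- export_review_tables(tr, out1)
  export_review_tables(tr, out2)

  states <- utils::read.csv(file.path(out1, "state_table.csv"))
  expect_equal(nrow(states), 15L)
  expect_true(all(paste0(names(model$dimensions), "_if") %in% names(states)))
  # sign convention: immediate values positive, severities negated
  expect_true(all(states$anxiety_if >= 0))
  expect_true(all(states$anxiety_cs <= 0))

  advice <- utils::read.csv(file.path(out1, "advice_table.csv"))
  expect_equal(nrow(advice), 15L)
  norm_cols <- grep("_normalized$", names(advice))
  expect_equal(unname(rowSums(advice[, norm_cols])), rep(1, 15),
               tolerance = 1e-9)

  for (f in basename(files)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("sampled patients average to the deterministic trajectory when answers are nearly deterministic", {
  # one-dimension model with a near-degenerate answer likelihood
  lik <- matrix(0.01, 4, 4); diag(lik) <- 0.97
  q <- question_spec("q1", "d1", likelihood = lik)
  cpt <- model$dimensions$anxiety$severity_cpt
  d <- dimension_spec("d1", prior = stats::setNames(
    rep(list(c(0.3, 0.4, 0.15, 0.15)), 4), context_profiles),
    question_ids = "q1", severity_cpt = cpt)
  a <- advice_spec("a1", activation = list(d1 = c(0, 0.3, 0.6, 0.9)))
  m1 <- bn_model(list(d), list(q), list(a), alpha = 0.5)

  det <- run_scenario(m1, scenario_spec("immediate_worsening", "d1"))
  sampled <- lapply(1:500, function(s) {
    run_scenario(m1, scenario_spec("immediate_worsening", "d1",
                                   answer_mode = "sampled", seed = s))
  })
  for (t in c(5, 15)) {
    avg <- Reduce(`+`, lapply(sampled, function(tr) {
      tr$steps[[t]]$state$dimensions$d1$if_posterior
    })) / length(sampled)
    expect_equal(unname(avg),
                 unname(det$steps[[t]]$state$dimensions$d1$if_posterior),
                 tolerance = 0.05)
  }
})
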