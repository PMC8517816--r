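# One inference cycle: naive-Bayes IF posterior, forgetting update, severity
# inference, noisy-OR scoring, normalisation, and the composed step.

model <- load_model(default_model_path())

test_that("initial belief reproduces the context priors and CF = IF", {
  b <- init_belief(model, "man_over_18")
  expect_equal(b$step, 0L)
  expect_equal(unname(b$dimensions$anxiety$if_posterior),
               c(0.3, 0.4, 0.15, 0.15))
  b2 <- init_belief(model, context_profile("woman", "under_18"))
  expect_equal(unname(b2$dimensions$anxiety$if_posterior),
               c(0.2, 0.2, 0.3, 0.3))
  for (d in names(model$dimensions)) {
    expect_identical(b$dimensions[[d]]$cf, b$dimensions[[d]]$if_posterior)
  }
  expect_error(init_belief(model, "child_over_40"),
               class = "emibayes_context_error")
})

test_that("IF posterior follows Bayes' rule on the elicited anxiety tables", {
  uniform <- rep(0.25, 4)
  post <- if_posterior(model, "anxiety", uniform,
                       answer_set(indices = c(anxiety_level = 3L)))
  # prior x (0, 0, 0.05, 0.80), renormalised
  expect_equal(unname(post), c(0, 0, 1 / 17, 16 / 17), tolerance = 1e-12)

  post2 <- if_posterior(model, "anxiety", c(0.3, 0.4, 0.15, 0.15),
                        answer_set(indices = c(anxiety_level = 0L)))
  expect_equal(unname(post2), c(0.9375, 0.0625, 0, 0), tolerance = 1e-12)

  # no answers: the empty product leaves the prior untouched
  prior <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(unname(if_posterior(model, "anxiety", prior, answer_set())),
               prior)

  # answers to other dimensions' questions contribute no factor
  post3 <- if_posterior(model, "anxiety", prior,
                        answer_set(indices = c(sleep_quality = 3L)))
  expect_equal(unname(post3), prior)
})

test_that("IF posterior is invariant to question order and matches VAS binning", {
  a1 <- answer_set(indices = c(anxiety_level = 2L, anxiety_coping = 1L,
                               anxiety_duration = 3L))
  a2 <- answer_set(indices = c(anxiety_duration = 3L, anxiety_level = 2L,
                               anxiety_coping = 1L))
  prior <- c(0.3, 0.4, 0.15, 0.15)
  expect_equal(if_posterior(model, "anxiety", prior, a1),
               if_posterior(model, "anxiety", prior, a2))

  # a VAS score of 87 falls in the top bin under the default 25/50/75 cuts
  expect_equal(vas_to_index(c(0, 24.9, 25, 60, 87, 100)), c(0, 0, 1, 2, 3, 3))
  via_vas <- if_posterior(model, "anxiety", prior,
                          answer_set(vas = c(anxiety_level = 87)))
  via_idx <- if_posterior(model, "anxiety", prior,
                          answer_set(indices = c(anxiety_level = 3L)))
  expect_equal(via_vas, via_idx)
})

test_that("contradictory evidence raises a typed error instead of renormalising", {
  # a point-mass prior at absent is annihilated by a highest-severity answer
  expect_error(
    if_posterior(model, "anxiety", point_mass("absent"),
                 answer_set(indices = c(anxiety_level = 3L))),
    class = "emibayes_inconsistent_evidence_error")
})

test_that("the forgetting update is a convex combination with exact limits", {
  cf <- c(1, 0, 0, 0)
  ifd <- c(0, 0, 0, 1)
  expect_equal(unname(cf_update(cf, ifd, 1)), cf)     # no update
  expect_equal(unname(cf_update(cf, ifd, 0)), ifd)    # no aggregation
  expect_equal(unname(cf_update(cf, ifd, 0.5)), c(0.5, 0, 0, 0.5))
  expect_error(cf_update(cf, ifd, 1.2), class = "emibayes_parameter_error")

  # contraction identity: ||cf_new - if||_1 = alpha * ||cf_old - if||_1
  set.seed(7)
  for (i in 1:25) {
    cf_old <- rand_dist(); if_new <- rand_dist(); alpha <- stats::runif(1)
    cf_new <- cf_update(cf_old, if_new, alpha)
    expect_distribution(cf_new)
    expect_equal(sum(abs(cf_new - if_new)), alpha * sum(abs(cf_old - if_new)),
                 tolerance = 1e-12)
  }
})

test_that("severity inference reproduces the elicited table and is bilinear", {
  anx <- model$dimensions$anxiety
  cs <- cs_infer(anx, point_mass("high"), point_mass("high"))
  expect_equal(unname(cs), c(0, 0, 0.01, 0.99))
  cs2 <- cs_infer(anx, point_mass("low"), point_mass("high"))
  expect_equal(cs2[["high"]], 0.9)
  expect_equal(cs2[["medium"]], 0.1)

  # a mixed immediate distribution averages the table rows
  mixed <- c(0, 0.5, 0, 0.5)
  cs3 <- cs_infer(anx, mixed, point_mass("high"))
  manual <- 0.5 * anx$severity_cpt["high", "low", ] +
            0.5 * anx$severity_cpt["high", "high", ]
  expect_equal(unname(cs3), unname(manual))

  # brute-force sum over all 16 (cf, if) pairs on random inputs
  set.seed(11)
  for (i in 1:10) {
    ifd <- rand_dist(); cfd <- rand_dist()
    manual <- numeric(4)
    for (cf in 1:4) for (ifl in 1:4) {
      manual <- manual + cfd[cf] * ifd[ifl] * anx$severity_cpt[cf, ifl, ]
    }
    expect_equal(unname(cs_infer(anx, ifd, cfd)), unname(manual),
                 tolerance = 1e-12)
    expect_distribution(cs_infer(anx, ifd, cfd))
  }
})

test_that("noisy-OR scoring matches closed form, enumeration, and monotonicity", {
  cf_advice <- model$advice$call_friends
  expect_equal(advice_score(cf_advice, list(anxiety = point_mass("high"))), 0.99)
  expect_equal(advice_score(cf_advice, list(anxiety = point_mass("absent"))), 0)

  two <- advice_spec(id = "two", activation = list(
    d1 = c(0, 0.5, 0.5, 0.5), d2 = c(0, 0.5, 0.5, 0.5)))
  expect_equal(advice_score(two, list(d1 = point_mass("low"),
                                      d2 = point_mass("medium"))), 0.75)
  expect_error(advice_score(two, list(d1 = point_mass("low"))),
               class = "emibayes_model_error")

  # graded severity distributions: exhaustive enumeration over 4^p configs
  set.seed(13)
  for (i in 1:10) {
    p <- sample(1:3, 1)
    act <- stats::setNames(lapply(seq_len(p), function(j) c(0, sort(stats::runif(3)))),
                           paste0("d", seq_len(p)))
    adv <- advice_spec(id = "a", activation = act, leak = stats::runif(1, 0, 0.3))
    cs <- stats::setNames(lapply(seq_len(p), function(j) rand_dist()),
                          paste0("d", seq_len(p)))
    configs <- expand.grid(rep(list(1:4), p))
    brute <- 0
    for (r in seq_len(nrow(configs))) {
      cfg <- as.integer(configs[r, ])
      w <- prod(vapply(seq_len(p), function(j) cs[[j]][cfg[j]], numeric(1)))
      yes <- 1 - (1 - adv$leak) *
        prod(vapply(seq_len(p), function(j) 1 - act[[j]][cfg[j]], numeric(1)))
      brute <- brute + w * yes
    }
    expect_equal(advice_score(adv, cs), brute, tolerance = 1e-12)
  }

  # raising a parent's severity in stochastic order never lowers the score
  set.seed(17)
  for (i in 1:10) {
    lower <- rand_dist()
    shift <- stats::runif(1, 0, lower[1])
    higher <- lower + c(-shift, 0, 0, shift)
    expect_gte(advice_score(cf_advice, list(anxiety = higher)),
               advice_score(cf_advice, list(anxiety = lower)))
  }
})

test_that("advice normalisation sums to one and flags the all-zero state", {
  expect_equal(unname(normalize_advice(c(a = 0.2, b = 0.2, c = 0.6))),
               c(0.2, 0.2, 0.6))
  expect_equal(unname(normalize_advice(c(a = 0.99, b = 0.99))), c(0.5, 0.5))
  z <- normalize_advice(c(a = 0, b = 0, c = 0, d = 0))
  expect_equal(as.vector(z), rep(0.25, 4))
  expect_true(isTRUE(attr(z, "degenerate")))
})

test_that("a full step chains posterior, forgetting and severity correctly", {
  b0 <- init_belief(model, "man_over_18")

  # no answers with alpha = 1: everything but the counter is a fixed point
  frozen <- model
  frozen$alpha <- 1
  b1 <- step_belief(frozen, b0, answer_set())
  expect_equal(b1$step, 1L)
  expect_equal(b1$dimensions, b0$dimensions, tolerance = 1e-12)
  expect_equal(b1$advice, b0$advice, tolerance = 1e-12)

  # one scoring with one answer reproduces the chained hand computation
  ans <- answer_set(indices = c(anxiety_level = 0L))
  b2 <- step_belief(model, b0, ans)
  post <- if_posterior(model, "anxiety", b0$dimensions$anxiety$cf, ans)
  expect_equal(unname(post), c(0.9375, 0.0625, 0, 0), tolerance = 1e-12)
  cf <- cf_update(b0$dimensions$anxiety$cf, post, model$alpha)
  expect_equal(b2$dimensions$anxiety$if_posterior, post)
  expect_equal(b2$dimensions$anxiety$cf, cf)
  expect_equal(b2$dimensions$anxiety$cs,
               cs_infer(model$dimensions$anxiety, post, cf))
  scores <- stats::setNames(b2$advice$absolute, b2$advice$id)
  expect_equal(scores[["call_friends"]],
               advice_score(model$advice$call_friends,
                            list(anxiety = b2$dimensions$anxiety$cs)))
  # the input state is untouched
  expect_equal(unname(b0$dimensions$anxiety$if_posterior),
               c(0.3, 0.4, 0.15, 0.15))

  # every emitted distribution is valid
  for (d in b2$dimensions) {
    expect_distribution(d$if_posterior)
    expect_distribution(d$cf)
    expect_distribution(d$cs)
  }
  expect_equal(sum(b2$advice$normalized), 1, tolerance = 1e-12)
})

test_that("constant lowest answers leave the advice ranking stable at the tail", {
  state <- init_belief(model, "man_over_18")
  ans <- answer_set(indices = stats::setNames(
    rep(0L, 3), model$dimensions$anxiety$question_ids))
  states <- list()
  for (t in 1:15) {
    state <- step_belief(model, state, ans)
    states[[t]] <- state
  }
  expect_identical(advice_ranking(states[[14]]), advice_ranking(states[[15]]))
})

test_that("belief snapshots serialise to JSON and back", {
  b <- init_belief(model, "woman_over_18")
  j <- belief_to_json(b)
  parsed <- jsonlite::fromJSON(j)
  expect_equal(parsed$step, 0)
  expect_equal(parsed$context, "woman_over_18")
  expect_equal(parsed$dimensions$anxiety$if_posterior,
               unname(b$dimensions$anxiety$if_posterior))
  expect_equal(sum(parsed$advice$normalized), 1, tolerance = 1e-9)
})
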