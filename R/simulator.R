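# In silico patient simulation: the preclinical validation protocol.
# Extreme profiles probe one dimension's posterior under all-highest /
# all-lowest answers; worsening scenarios feed 15 successive scorings
# (9 lowest, then an immediate jump or a progressive ramp to the highest
# severity) through the engine and log everything.

#' Describe an in silico patient scenario
#'
#' @param pattern One of `"constant_lowest"`, `"immediate_worsening"`,
#'   `"progressive_worsening"`.
#' @param target_dimension Dimension whose answers follow the pattern.
#' @param context A [context_profile()] key.
#' @param n_steps Number of scorings (default 15).
#' @param onset_step First scoring of the worsening phase (default 10).
#' @param answer_mode `"deterministic_extreme"` (answers equal the true
#'   level) or `"sampled"` (answers drawn from P(answer | IF = true level)).
#' @param nontarget `"unanswered"` (default): other dimensions' questions are
#'   left out, so their beliefs stay exactly at the context prior and
#'   cross-dimension advice effects are isolated. `"lowest"`: other
#'   dimensions' questions get the least severe answer at every scoring.
#' @param seed Integer seed driving sampled-mode randomness.
#' @return An object of class `emibayes_scenario`.
#' @export
scenario_spec <- function(pattern = c("constant_lowest", "immediate_worsening",
                                      "progressive_worsening"),
                          target_dimension, context = "man_over_18",
                          n_steps = 15L, onset_step = 10L,
                          answer_mode = c("deterministic_extreme", "sampled"),
                          nontarget = c("unanswered", "lowest"),
                          seed = 1L) {
  pattern <- match.arg(pattern)
  answer_mode <- match.arg(answer_mode)
  nontarget <- match.arg(nontarget)
  n_steps <- as.integer(n_steps)
  onset_step <- as.integer(onset_step)
  if (n_steps < 1) abort_emibayes("parameter", "n_steps must be >= 1")
  if (onset_step < 1 || onset_step > n_steps) {
    abort_emibayes("parameter", "onset_step must lie in 1..n_steps")
  }
  structure(list(pattern = pattern,
                 target_dimension = as.character(target_dimension),
                 context = context_profile(context),
                 n_steps = n_steps, onset_step = onset_step,
                 answer_mode = answer_mode, nontarget = nontarget,
                 seed = as.integer(seed)),
            class = "emibayes_scenario")
}

check_scenario <- function(model, scenario) {
  if (!inherits(scenario, "emibayes_scenario")) {
    abort_emibayes("input", "expected a scenario_spec()")
  }
  if (!scenario$target_dimension %in% names(model$dimensions)) {
    abort_emibayes("model", sprintf("target dimension '%s' not in model",
                                    scenario$target_dimension))
  }
  invisible(scenario)
}

# True severity level (0-based) of the target dimension at scoring t.
scenario_true_level <- function(scenario, t) {
  if (scenario$pattern == "constant_lowest" || t < scenario$onset_step) {
    return(0L)
  }
  if (scenario$pattern == "immediate_worsening") return(3L)
  # progressive: linear ramp in level index from onset to the final scoring,
  # rounded upward so the highest level is held long enough for the cumulated
  # value to approach the immediate pattern's terminal state
  span <- scenario$n_steps - scenario$onset_step
  if (span == 0) return(3L)
  as.integer(ceiling(3 * (t - scenario$onset_step) / span))
}

#' Generate the answer sequence of a scenario
#'
#' Deterministic-extreme mode answers every target-dimension question at the
#' pattern's true level; sampled mode draws each answer from
#' P(answer | IF = true level) using the scenario seed (repeated calls give
#' the identical sequence).
#'
#' @param model An `emibayes_model`.
#' @param scenario A [scenario_spec()].
#' @return List of `n_steps` [answer_set()]s.
#' @export
generate_answer_sequence <- function(model, scenario) {
  check_scenario(model, scenario)
  target_qids <- model$dimensions[[scenario$target_dimension]]$question_ids
  other_qids <- setdiff(names(model$questions), target_qids)

  sample_answer <- function(qid, level) {
    probs <- model$questions[[qid]]$likelihood[, level + 1L]
    sample.int(4L, 1L, prob = probs) - 1L
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(scenario$seed)

  lapply(seq_len(scenario$n_steps), function(t) {
    level <- scenario_true_level(scenario, t)
    target_ans <- if (scenario$answer_mode == "sampled") {
      vapply(target_qids, sample_answer, integer(1), level = level)
    } else {
      stats::setNames(rep(level, length(target_qids)), target_qids)
    }
    idx <- target_ans
    if (scenario$nontarget == "lowest") {
      idx <- c(idx, stats::setNames(rep(0L, length(other_qids)), other_qids))
    }
    answer_set(indices = idx, step = t)
  })
}

#' Run a scenario through the engine
#'
#' Initialises the belief from the scenario context, generates the answer
#' sequence, applies [step_belief()] per scoring, and logs everything.
#' Rerunning with the same seed reproduces the record exactly.
#'
#' @param model An `emibayes_model`.
#' @param scenario A [scenario_spec()].
#' @return An `emibayes_trajectory`: the scenario, the initial state, and one
#'   `(answers, state)` pair per scoring.
#' @export
run_scenario <- function(model, scenario) {
  check_scenario(model, scenario)
  answers <- generate_answer_sequence(model, scenario)
  state <- init_belief(model, scenario$context)
  steps <- vector("list", scenario$n_steps)
  for (t in seq_len(scenario$n_steps)) {
    state <- step_belief(model, state, answers[[t]])
    steps[[t]] <- list(answers = answers[[t]], state = state)
  }
  structure(list(scenario = scenario,
                 model_metadata = model$metadata,
                 alpha = model$alpha,
                 initial_state = init_belief(model, scenario$context),
                 steps = steps),
            class = "emibayes_trajectory")
}

#' @export
print.emibayes_trajectory <- function(x, ...) {
  cat(sprintf("<emibayes_trajectory> %s on '%s', %d scorings (onset %d), context %s\n",
              x$scenario$pattern, x$scenario$target_dimension,
              x$scenario$n_steps, x$scenario$onset_step, x$scenario$context))
  cat("final top advice:", advice_ranking(x$steps[[length(x$steps)]]$state)[1:3],
      "\n")
  invisible(x)
}

#' Extreme-profile distributions of a dimension
#'
#' The three distributions used in the first validation step: the context
#' prior, P(++) — the posterior when every question of the dimension is
#' answered at the highest severity — and P(--), the same with the lowest.
#'
#' @param model An `emibayes_model`.
#' @param dimension_id Dimension to probe.
#' @param context A [context_profile()] key.
#' @return List with elements `a_priori`, `p_plus`, `p_minus`.
#' @export
extreme_profiles <- function(model, dimension_id, context) {
  context <- context_profile(context)
  d <- model$dimensions[[dimension_id]]
  if (is.null(d)) {
    abort_emibayes("model", sprintf("unknown dimension '%s'", dimension_id))
  }
  prior <- level_distribution(d$prior[[context]])
  ans_at <- function(level) {
    answer_set(indices = stats::setNames(rep(level, length(d$question_ids)),
                                         d$question_ids))
  }
  list(a_priori = prior,
       p_plus = if_posterior(model, dimension_id, prior, ans_at(3L)),
       p_minus = if_posterior(model, dimension_id, prior, ans_at(0L)))
}

#' Scoring at which the advice ranking has converged
#'
#' The smallest step `s` such that the full advice ranking at every step
#' `>= s` equals the ranking at the final step.
#'
#' @param trajectory An `emibayes_trajectory`.
#' @export
convergence_steps <- function(trajectory) {
  if (!inherits(trajectory, "emibayes_trajectory") ||
      length(trajectory$steps) == 0) {
    abort_emibayes("input", "expected a non-empty trajectory")
  }
  rankings <- lapply(trajectory$steps, function(s) advice_ranking(s$state))
  final <- rankings[[length(rankings)]]
  s <- length(rankings)
  while (s > 1 && identical(rankings[[s - 1]], final)) s <- s - 1
  s
}

#' Export review tables for expert inspection
#'
#' Writes three files into `path`:
#' \describe{
#'   \item{state_table.csv}{one row per scoring; per dimension the expected
#'     severity score ([severity_score()]) of the immediate value (positive)
#'     and of the contextual severity (negated), matching the review plots'
#'     sign convention.}
#'   \item{advice_table.csv}{one row per scoring; absolute and normalized
#'     score per advice.}
#'   \item{trajectory.json}{the full belief log (distributions included).}
#' }
#' Re-exporting the same trajectory yields byte-identical files.
#'
#' @param trajectory An `emibayes_trajectory`.
#' @param path Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
export_review_tables <- function(trajectory, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  states <- lapply(trajectory$steps, `[[`, "state")
  dim_ids <- names(states[[1]]$dimensions)
  adv_ids <- states[[1]]$advice$id

  state_tab <- data.frame(step = vapply(states, `[[`, integer(1), "step"))
  for (id in dim_ids) {
    state_tab[[paste0(id, "_if")]] <- vapply(states, function(s) {
      severity_score(s$dimensions[[id]]$if_posterior)
    }, numeric(1))
    state_tab[[paste0(id, "_cs")]] <- vapply(states, function(s) {
      -severity_score(s$dimensions[[id]]$cs)
    }, numeric(1))
  }
  advice_tab <- data.frame(step = state_tab$step)
  for (id in adv_ids) {
    advice_tab[[paste0(id, "_absolute")]] <- vapply(states, function(s) {
      s$advice$absolute[s$advice$id == id]
    }, numeric(1))
    advice_tab[[paste0(id, "_normalized")]] <- vapply(states, function(s) {
      s$advice$normalized[s$advice$id == id]
    }, numeric(1))
  }

  files <- file.path(path, c("state_table.csv", "advice_table.csv",
                             "trajectory.json"))
  utils::write.csv(state_tab, files[1], row.names = FALSE)
  utils::write.csv(advice_tab, files[2], row.names = FALSE)

  bundle <- list(
    scenario = unclass(trajectory$scenario),
    alpha = trajectory$alpha,
    model_metadata = trajectory$model_metadata,
    initial_state = belief_to_json(trajectory$initial_state, json = FALSE),
    steps = lapply(trajectory$steps, function(s) {
      list(answers = list(indices = as.list(s$answers$indices),
                          vas = as.list(s$answers$vas),
                          step = s$answers$step),
           state = belief_to_json(s$state, json = FALSE))
    })
  )
  writeLines(jsonlite::toJSON(bundle, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), files[3])
  invisible(files)
}
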