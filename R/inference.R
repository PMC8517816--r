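# One full update cycle per scoring:
#   IF posterior (naive Bayes over the dimension's answered questions)
#   -> CF forgetting update -> CS inference -> noisy-OR advice scoring.
# The prior fed to scoring t's IF posterior is the current CF distribution;
# the static context prior enters only at initialisation.

#' Naive-Bayes posterior of a dimension's immediate value
#'
#' Given the value of the immediate factor, answers to its questions are
#' conditionally independent; the posterior is the prior times one likelihood
#' factor per answered question, renormalised. Unanswered questions
#' contribute no factor. Products are accumulated in log space; zero
#' likelihood cells stay exactly zero (no smoothing), and evidence that
#' annihilates every level raises a typed inconsistent-evidence error.
#'
#' @param model An `emibayes_model`.
#' @param dimension_id Dimension to update.
#' @param prior Level distribution used as prior (usually the current CF).
#' @param answers An [answer_set()]; answers to other dimensions' questions
#'   are ignored.
#' @return The posterior level distribution.
#' @export
if_posterior <- function(model, dimension_id, prior, answers) {
  d <- model$dimensions[[dimension_id]]
  if (is.null(d)) {
    abort_emibayes("model", sprintf("unknown dimension '%s'", dimension_id))
  }
  prior <- level_distribution(prior)
  idx <- resolve_answers(model, answers)
  idx <- idx[names(idx) %in% d$question_ids]

  logp <- log(prior)
  for (qid in names(idx)) {
    lik <- model$questions[[qid]]$likelihood[idx[[qid]] + 1L, ]
    logp <- logp + log(lik)
  }
  if (all(logp == -Inf)) {
    abort_emibayes("inconsistent_evidence", sprintf(
      "dimension '%s': the answers have zero probability under every level",
      dimension_id))
  }
  w <- exp(logp - max(logp[is.finite(logp)]))
  level_distribution(w / sum(w))
}

#' Forgetting-factor update of the cumulated value
#'
#' `CF_new = (1 - alpha) * IF + alpha * CF_old`, applied elementwise to the
#' two level distributions. `alpha = 0` discards history (CF = IF);
#' `alpha = 1` freezes the cumulated value.
#'
#' @param cf_old,if_new Level distributions.
#' @param alpha Forgetting factor in \[0, 1\].
#' @export
cf_update <- function(cf_old, if_new, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    abort_emibayes("parameter", "alpha must be a number in [0, 1]")
  }
  cf_old <- level_distribution(cf_old)
  if_new <- level_distribution(if_new)
  level_distribution((1 - alpha) * if_new + alpha * cf_old)
}

#' Contextual severity of a dimension
#'
#' Marginalises the elicited P(CS | IF, CF) table over the current immediate
#' and cumulated distributions, treated as independent at this step (their
#' temporal coupling lives in the [cf_update()] recurrence):
#' `cs(s) = sum_{c,i} cf(c) * if(i) * CPT[c, i, s]`.
#'
#' @param dimension A [dimension_spec()] entry.
#' @param if_dist,cf_dist Level distributions.
#' @export
cs_infer <- function(dimension, if_dist, cf_dist) {
  if_dist <- level_distribution(if_dist)
  cf_dist <- level_distribution(cf_dist)
  w <- outer(cf_dist, if_dist)           # [cf, if]
  cs <- vapply(1:4, function(s) sum(w * dimension$severity_cpt[, , s]),
               numeric(1))
  level_distribution(cs)
}

#' Noisy-OR advice score
#'
#' Exact marginal probability that the advice is relevant under the noisy-OR
#' model, with each parent's contextual severity drawn independently from its
#' current distribution:
#' `1 - (1 - leak) * prod_p E[1 - activation(p, CS_p)]`.
#'
#' @param advice An [advice_spec()] entry.
#' @param cs_dists Named list of level distributions covering all parents.
#' @return Probability in \[0, 1\].
#' @export
advice_score <- function(advice, cs_dists) {
  missing <- setdiff(advice$parents, names(cs_dists))
  if (length(missing)) {
    abort_emibayes("model", sprintf(
      "advice '%s': missing CS distribution for parent(s): %s",
      advice$id, paste(missing, collapse = ", ")))
  }
  survive <- vapply(advice$parents, function(p) {
    sum(level_distribution(cs_dists[[p]]) * (1 - advice$activation[[p]]))
  }, numeric(1))
  1 - (1 - advice$leak) * prod(survive)
}

#' Normalise advice scores to relative scores
#'
#' Divides each absolute score by their sum. If every absolute score is zero
#' the uniform distribution is returned with attribute `degenerate = TRUE`.
#'
#' @param absolute_scores Named numeric vector of probabilities.
#' @export
normalize_advice <- function(absolute_scores) {
  total <- sum(absolute_scores)
  if (total <= 0) {
    out <- rep(1 / length(absolute_scores), length(absolute_scores))
    names(out) <- names(absolute_scores)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  absolute_scores / total
}

# Compute the advice block of a belief state from the per-dimension CS list.
compute_advice_scores <- function(model, cs_list) {
  absolute <- vapply(model$advice, advice_score, numeric(1), cs_dists = cs_list)
  normalized <- normalize_advice(absolute)
  data.frame(id = names(model$advice),
             name = vapply(model$advice, `[[`, "", "name"),
             absolute = as.numeric(absolute),
             normalized = as.numeric(normalized),
             row.names = NULL, stringsAsFactors = FALSE)
}

new_belief <- function(model, step, dims, context) {
  cs_list <- lapply(dims, `[[`, "cs")
  structure(list(step = as.integer(step), context = context,
                 dimensions = dims,
                 advice = compute_advice_scores(model, cs_list)),
            class = "emibayes_belief")
}

#' Initial belief state for a patient context
#'
#' For every dimension the immediate and cumulated distributions are both
#' initialised to the context prior P(IF | age, gender); contextual severity
#' and advice scores are computed from them. Step counter starts at 0.
#'
#' @param model An `emibayes_model`.
#' @param context A [context_profile()] key, e.g. `"man_over_18"`.
#' @return An object of class `emibayes_belief`.
#' @export
init_belief <- function(model, context) {
  context <- context_profile(context)
  dims <- lapply(model$dimensions, function(d) {
    prior <- level_distribution(d$prior[[context]])
    list(if_posterior = prior, cf = prior,
         cs = cs_infer(d, prior, prior))
  })
  new_belief(model, 0L, dims, context)
}

#' Advance a belief state by one scoring
#'
#' For each dimension: the IF posterior is computed from this scoring's
#' answers with the current CF as prior, the CF is updated by the forgetting
#' recurrence, and the contextual severity re-inferred; advice scores are
#' then recomputed. The input state is not modified.
#'
#' @param model An `emibayes_model`.
#' @param state Current `emibayes_belief`.
#' @param answers An [answer_set()] for this scoring.
#' @return A new `emibayes_belief` with `step + 1`.
#' @export
step_belief <- function(model, state, answers) {
  dims <- lapply(names(model$dimensions), function(id) {
    cur <- state$dimensions[[id]]
    post <- if_posterior(model, id, cur$cf, answers)
    cf <- cf_update(cur$cf, post, model$alpha)
    list(if_posterior = post, cf = cf,
         cs = cs_infer(model$dimensions[[id]], post, cf))
  })
  names(dims) <- names(model$dimensions)
  new_belief(model, state$step + 1L, dims, state$context)
}

#' Advice ranking of a belief state
#'
#' Advice ids ordered by descending absolute score; ties broken by model
#' specification order (stable).
#'
#' @param state An `emibayes_belief`.
#' @export
advice_ranking <- function(state) {
  a <- state$advice
  a$id[order(-a$absolute, seq_len(nrow(a)))]
}

#' @export
print.emibayes_belief <- function(x, n = 3, ...) {
  cat(sprintf("<emibayes_belief> step %d, context %s\n", x$step, x$context))
  for (id in names(x$dimensions)) {
    d <- x$dimensions[[id]]
    cat(sprintf("  %-22s IF (%s)  CS (%s)\n", id,
                paste(sprintf("%.3f", d$if_posterior), collapse = " "),
                paste(sprintf("%.3f", d$cs), collapse = " ")))
  }
  top <- utils::head(x$advice[order(-x$advice$absolute), ], n)
  cat("top advice:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-20s absolute %.4f  normalized %.4f\n",
                top$id[i], top$absolute[i], top$normalized[i]))
  }
  invisible(x)
}

#' Serialise a belief state to a JSON-ready list / JSON string
#'
#' @param state An `emibayes_belief`.
#' @param json Return a JSON string (default) or the bare list.
#' @export
belief_to_json <- function(state, json = TRUE) {
  x <- list(
    step = state$step,
    context = state$context,
    dimensions = lapply(state$dimensions, function(d) {
      list(if_posterior = as.numeric(d$if_posterior),
           cf = as.numeric(d$cf),
           cs = as.numeric(d$cs))
    }),
    advice = state$advice
  )
  if (!json) return(x)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}
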