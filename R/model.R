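# Knowledge-base containers. A model is the pair [G, Theta]: the graph is
# implied by the dimension/question/advice parent lists, the parameters are
# the elicited tables. Constructors are permissive (so that broken models can
# be built and handed to the validator); inference functions assume a model
# that passes validate_model().

#' Build a question specification
#'
#' @param id Unique token.
#' @param dimension Id of the clinical dimension the question probes.
#' @param text Question wording.
#' @param answers Four answer labels ordered from least to most severe.
#' @param likelihood 4x4 matrix, `likelihood[j, k] = P(answer = j | IF = k)`;
#'   rows index answers (least..most severe), columns index the IF level
#'   (absent..high). Every column sums to 1.
#' @param counts Optional per-100 elicitation table of the same shape;
#'   auto-converted column-wise via [counts_to_distribution()] when
#'   `likelihood` is missing.
#' @param vas_thresholds Three increasing cut points in (0, 100) binning a
#'   visual-analog score into the four answers.
#' @export
question_spec <- function(id, dimension, text = id,
                          answers = c("none", "low", "medium", "high"),
                          likelihood = NULL, counts = NULL,
                          vas_thresholds = c(25, 50, 75)) {
  if (is.null(likelihood)) {
    if (is.null(counts)) {
      abort_emibayes("model", sprintf(
        "question '%s': provide either a likelihood matrix or a counts table", id))
    }
    counts <- as.matrix(counts)
    likelihood <- apply(counts, 2, function(col) as.numeric(counts_to_distribution(col)))
  }
  likelihood <- as.matrix(likelihood)
  dimnames(likelihood) <- list(answer = severity_levels, if_level = severity_levels)
  list(id = as.character(id), dimension = as.character(dimension),
       text = as.character(text), answers = as.character(answers),
       likelihood = likelihood,
       vas_thresholds = as.numeric(vas_thresholds))
}

#' Build a dimension specification
#'
#' @param id,name Identifier and display name.
#' @param prior Named list mapping each of [context_profiles] to a level
#'   distribution: the a-priori P(IF | age, gender).
#' @param question_ids Questions probing this dimension.
#' @param severity_cpt 4x4x4 array `severity_cpt[cf, if, ]` giving
#'   P(CS | IF, CF), each row a level distribution over CS. First index is the
#'   cumulated level, second the immediate level, third the severity —
#'   all in absent..high order.
#' @export
dimension_spec <- function(id, name = id, prior, question_ids, severity_cpt) {
  severity_cpt <- array(as.numeric(severity_cpt), dim = c(4, 4, 4),
                        dimnames = list(cf = severity_levels,
                                        if_level = severity_levels,
                                        cs = severity_levels))
  list(id = as.character(id), name = as.character(name),
       prior = lapply(prior, as.numeric),
       question_ids = as.character(question_ids),
       severity_cpt = severity_cpt)
}

#' Build an advice specification (noisy-OR parameters)
#'
#' Each parent dimension, at each contextual-severity level, independently
#' makes the advice relevant with its activation probability; the leak is the
#' baseline probability with all parents absent. Stored free parameters are
#' 3 per parent (absent is pinned to 0 unless overridden) plus the leak —
#' linear in the number of parents instead of the 4^p rows of a full table.
#'
#' @param id,name Identifier and display name.
#' @param activation Named list mapping each parent dimension id to a numeric
#'   vector of four activation probabilities in absent..high order (a length-3
#'   vector is taken as low/medium/high with absent = 0).
#' @param leak Leak probability, default 0.
#' @export
advice_spec <- function(id, name = id, activation, leak = 0) {
  activation <- lapply(activation, function(a) {
    a <- as.numeric(a)
    if (length(a) == 3L) a <- c(0, a)
    names(a) <- severity_levels[seq_along(a)]
    a
  })
  list(id = as.character(id), name = as.character(name),
       parents = names(activation), activation = activation,
       leak = as.numeric(leak))
}

#' Assemble a model from its parts
#'
#' @param dimensions,questions,advice Lists of [dimension_spec()],
#'   [question_spec()] and [advice_spec()] entries.
#' @param alpha Forgetting factor in \[0, 1\]: weight kept by the old
#'   cumulated value at each update, `CF_new = (1 - alpha) * IF + alpha * CF_old`.
#' @param metadata Free-form list (version, provenance notes).
#' @param validate Run [validate_model()] and fail on any violation.
#' @return An object of class `emibayes_model`.
#' @export
bn_model <- function(dimensions, questions, advice, alpha = 0.5,
                     metadata = list(), validate = TRUE) {
  name_by_id <- function(entries) {
    stats::setNames(entries, vapply(entries, `[[`, "", "id"))
  }
  model <- structure(
    list(format = "ema-bn/1",
         metadata = metadata,
         alpha = as.numeric(alpha),
         dimensions = name_by_id(dimensions),
         questions = name_by_id(questions),
         advice = name_by_id(advice)),
    class = "emibayes_model")
  if (validate) {
    report <- validate_model(model)
    if (nrow(report) > 0) {
      abort_emibayes("validation", paste0(
        "invalid model (", nrow(report), " violation(s)):\n",
        paste0("  - [", report$path, "] ", report$rule, ": ",
               report$message, collapse = "\n")),
        report = report)
    }
  }
  model
}

#' @export
print.emibayes_model <- function(x, ...) {
  cat(sprintf("<emibayes_model> %d dimensions, %d questions, %d advice; alpha = %g\n",
              length(x$dimensions), length(x$questions), length(x$advice),
              x$alpha))
  cat("dimensions:", paste(names(x$dimensions), collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Validation

violation <- function(path, rule, message) {
  data.frame(path = path, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a model against the knowledge-base invariants
#'
#' Checks normalisation of every stored distribution (priors, question
#' likelihood columns, severity rows), cross-reference integrity, uniqueness
#' of ids, VAS threshold ordering, the monotone-activation constraint on
#' noisy-OR parameters, and the forgetting-factor range. Violations are
#' reported, never silently repaired.
#'
#' @param model An `emibayes_model`.
#' @return Data frame with columns `path`, `rule`, `message`; zero rows iff
#'   the model is valid.
#' @export
validate_model <- function(model) {
  out <- list()
  add <- function(v) out[[length(out) + 1L]] <<- v
  check_dist <- function(p, path) {
    if (!is_level_distribution(p)) {
      add(violation(path, "distribution",
                    sprintf("entries [%s] do not form a probability distribution",
                            paste(signif(as.numeric(p), 6), collapse = ", "))))
    }
  }

  ids <- c(names(model$dimensions), names(model$questions), names(model$advice))
  if (anyDuplicated(ids)) {
    add(violation("model", "unique_ids",
                  paste("duplicated id(s):",
                        paste(unique(ids[duplicated(ids)]), collapse = ", "))))
  }
  if (!is.numeric(model$alpha) || length(model$alpha) != 1 ||
      is.na(model$alpha) || model$alpha < 0 || model$alpha > 1) {
    add(violation("alpha", "range", "forgetting factor must lie in [0, 1]"))
  }

  for (d in model$dimensions) {
    base <- paste0("dimensions/", d$id)
    missing_ctx <- setdiff(context_profiles, names(d$prior))
    if (length(missing_ctx)) {
      add(violation(paste0(base, "/prior"), "context_coverage",
                    paste("missing context profile(s):",
                          paste(missing_ctx, collapse = ", "))))
    }
    for (ctx in intersect(context_profiles, names(d$prior))) {
      check_dist(d$prior[[ctx]], paste0(base, "/prior/", ctx))
    }
    if (length(d$question_ids) == 0) {
      add(violation(base, "questions_nonempty", "dimension has no questions"))
    }
    for (q in d$question_ids) {
      if (!q %in% names(model$questions)) {
        add(violation(paste0(base, "/question_ids"), "dangling_reference",
                      sprintf("question '%s' not defined", q)))
      } else if (model$questions[[q]]$dimension != d$id) {
        add(violation(paste0(base, "/question_ids"), "cross_reference",
                      sprintf("question '%s' belongs to dimension '%s'",
                              q, model$questions[[q]]$dimension)))
      }
    }
    for (cf in 1:4) for (ifl in 1:4) {
      check_dist(d$severity_cpt[cf, ifl, ],
                 sprintf("%s/severity_cpt/cf=%s/if=%s", base,
                         severity_levels[cf], severity_levels[ifl]))
    }
  }

  for (q in model$questions) {
    base <- paste0("questions/", q$id)
    if (!q$dimension %in% names(model$dimensions)) {
      add(violation(base, "dangling_reference",
                    sprintf("dimension '%s' not defined", q$dimension)))
    } else if (!q$id %in% model$dimensions[[q$dimension]]$question_ids) {
      add(violation(base, "cross_reference",
                    sprintf("not listed by dimension '%s'", q$dimension)))
    }
    if (length(q$answers) != 4) {
      add(violation(base, "answer_labels", "need exactly 4 answer labels"))
    }
    for (k in 1:4) {
      check_dist(q$likelihood[, k],
                 sprintf("%s/likelihood/if=%s", base, severity_levels[k]))
    }
    vt <- q$vas_thresholds
    if (length(vt) != 3 || any(diff(vt) <= 0) || vt[1] <= 0 || vt[3] >= 100) {
      add(violation(paste0(base, "/vas_thresholds"), "vas_thresholds",
                    "need 3 strictly increasing cut points inside (0, 100)"))
    }
  }

  for (a in model$advice) {
    base <- paste0("advice/", a$id)
    if (length(a$parents) == 0) {
      add(violation(base, "parents_nonempty", "advice has no parent dimensions"))
    }
    for (p in a$parents) {
      if (!p %in% names(model$dimensions)) {
        add(violation(base, "dangling_reference",
                      sprintf("parent dimension '%s' not defined", p)))
        next
      }
      act <- a$activation[[p]]
      if (length(act) != 4 || any(!is.finite(act)) ||
          any(act < 0) || any(act > 1)) {
        add(violation(paste0(base, "/activation/", p), "activation_range",
                      "activation needs 4 probabilities in [0, 1]"))
      } else if (any(diff(act) < -DIST_TOL)) {
        add(violation(paste0(base, "/activation/", p), "activation_monotone",
                      sprintf("activation must be non-decreasing in severity, got [%s]",
                              paste(act, collapse = ", "))))
      }
    }
    if (!is.numeric(a$leak) || a$leak < 0 || a$leak > 1) {
      add(violation(paste0(base, "/leak"), "leak_range",
                    "leak must lie in [0, 1]"))
    }
  }

  if (length(out) == 0) {
    return(data.frame(path = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write a validation report as JSON lines
#'
#' One JSON record per violation, with fields `path`, `rule`, `message`.
#'
#' @param report Result of [validate_model()].
#' @param path Output file (or connection).
#' @export
write_validation_report <- function(report, path) {
  lines <- vapply(seq_len(nrow(report)), function(i) {
    jsonlite::toJSON(as.list(report[i, , drop = FALSE]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
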