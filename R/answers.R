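#' A set of answers for one scoring
#'
#' Answers are either 0-based indices into a question's four answer bins
#' (0 = least severe .. 3 = most severe) or raw visual-analog scores in
#' \[0, 100\], binned through the question's `vas_thresholds` at inference
#' time. Questions left out contribute no evidence.
#'
#' @param indices Named integer vector, question id -> answer index 0..3.
#' @param vas Named numeric vector, question id -> VAS score in \[0, 100\].
#' @param step Scoring number (integer >= 1), informational.
#' @return An object of class `emibayes_answers`.
#' @export
answer_set <- function(indices = integer(), vas = numeric(), step = NA_integer_) {
  if (length(indices)) {
    if (is.null(names(indices)) || any(!nzchar(names(indices)))) {
      abort_emibayes("input", "answer indices must be named by question id")
    }
    if (any(!indices %in% 0:3)) {
      abort_emibayes("input", "answer indices must lie in 0..3")
    }
  }
  if (length(vas)) {
    if (is.null(names(vas)) || any(!nzchar(names(vas)))) {
      abort_emibayes("input", "VAS scores must be named by question id")
    }
    if (any(!is.finite(vas)) || any(vas < 0) || any(vas > 100)) {
      abort_emibayes("input", "VAS scores must lie in [0, 100]")
    }
  }
  structure(list(indices = indices, vas = vas, step = as.integer(step)),
            class = "emibayes_answers")
}

#' @export
print.emibayes_answers <- function(x, ...) {
  cat(sprintf("<emibayes_answers> step %s: %d indexed, %d VAS\n",
              x$step, length(x$indices), length(x$vas)))
  invisible(x)
}

#' Bin a visual-analog score into a 0-based answer index
#'
#' Scores below the first threshold map to bin 0, then upward; a score at or
#' above the last threshold maps to bin 3.
#'
#' @param score VAS score(s) in \[0, 100\].
#' @param thresholds Three increasing cut points.
#' @export
vas_to_index <- function(score, thresholds = c(25, 50, 75)) {
  findInterval(score, thresholds)
}

# Flatten an answer set to a named 0-based index vector over question ids,
# converting VAS scores with each question's own thresholds. Unknown question
# ids and duplicate answers are model errors.
resolve_answers <- function(model, answers) {
  if (!inherits(answers, "emibayes_answers")) {
    abort_emibayes("input", "expected an answer_set()")
  }
  ids <- c(names(answers$indices), names(answers$vas))
  unknown <- setdiff(ids, names(model$questions))
  if (length(unknown)) {
    abort_emibayes("model", sprintf("answers reference unknown question(s): %s",
                                    paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(ids)) {
    abort_emibayes("input", sprintf("question(s) answered twice: %s",
                                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  out <- integer(0)
  if (length(answers$indices)) out <- c(out, as.integer(answers$indices))
  if (length(answers$vas)) {
    binned <- vapply(names(answers$vas), function(qid) {
      vas_to_index(answers$vas[[qid]], model$questions[[qid]]$vas_thresholds)
    }, numeric(1))
    out <- c(out, as.integer(binned))
  }
  names(out) <- ids
  out
}

#' Read an answer stream from JSON lines
#'
#' One JSON object per line, e.g.
#' `{"step": 1, "answers": {"anxiety_level": 3}, "vas": {"anxiety_coping": 80}}`.
#'
#' @param path File path, or a character vector of JSON lines.
#' @return List of [answer_set()] objects.
#' @export
read_answer_stream <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) {
      abort_emibayes("io", sprintf("malformed JSON on line %d: %s",
                                   i, conditionMessage(e)))
    })
    answer_set(
      indices = if (length(rec$answers)) unlist(rec$answers) else integer(),
      vas = if (length(rec$vas)) unlist(rec$vas) else numeric(),
      step = if (is.null(rec$step)) i else rec$step
    )
  })
}
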