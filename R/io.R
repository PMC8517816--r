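# Model file dialect: a single YAML document, format "ema-bn/1".
# Level order is explicit and fixed: [absent, low, medium, high]; every
# stored vector follows it. Question likelihoods may be given either as
# probabilities ("likelihood") or as per-100 counts ("counts"); counts are
# converted on load. Severity tables are keyed cf-level first, then if-level.

MODEL_FORMAT <- "ema-bn/1"

#' Load a model specification file
#'
#' Reads, converts (per-100 count tables to probabilities) and fully
#' validates a YAML model document. Loading, saving with [save_model()] and
#' loading again yields an equivalent model.
#'
#' @param path Path to a YAML model file.
#' @return A validated `emibayes_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort_emibayes("io", sprintf("model file '%s' does not exist", path))
  }
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort_emibayes("format", sprintf("cannot parse '%s' as YAML: %s",
                                     path, conditionMessage(e)))
  })
  if (!identical(doc$format, MODEL_FORMAT)) {
    abort_emibayes("format", sprintf(
      "'%s': key 'format' must be \"%s\" (got %s)", path, MODEL_FORMAT,
      if (is.null(doc$format)) "nothing" else paste0('"', doc$format, '"')))
  }
  need <- function(x, key, where) {
    if (is.null(x[[key]])) {
      abort_emibayes("format", sprintf("'%s': missing key '%s' in %s",
                                       path, key, where))
    }
    x[[key]]
  }

  questions <- lapply(need(doc, "questions", "document"), function(q) {
    id <- need(q, "id", "questions entry")
    to_matrix <- function(tab, what) {
      if (!all(severity_levels %in% names(tab))) {
        abort_emibayes("format", sprintf(
          "'%s': question '%s' %s must have one entry per level absent..high",
          path, id, what))
      }
      sapply(severity_levels, function(l) as.numeric(tab[[l]]))
    }
    question_spec(
      id = id,
      dimension = need(q, "dimension", paste0("question '", id, "'")),
      text = if (is.null(q$text)) id else q$text,
      answers = unlist(need(q, "answers", paste0("question '", id, "'"))),
      likelihood = if (!is.null(q$likelihood)) to_matrix(q$likelihood, "likelihood"),
      counts = if (is.null(q$likelihood)) to_matrix(need(q, "counts",
        paste0("question '", id, "'")), "counts"),
      vas_thresholds = if (is.null(q$vas_thresholds)) c(25, 50, 75)
                       else unlist(q$vas_thresholds)
    )
  })

  dimensions <- lapply(need(doc, "dimensions", "document"), function(d) {
    id <- need(d, "id", "dimensions entry")
    cpt_doc <- need(d, "severity_cpt", paste0("dimension '", id, "'"))
    cpt <- array(NA_real_, dim = c(4, 4, 4))
    for (cf in 1:4) for (ifl in 1:4) {
      row <- cpt_doc[[severity_levels[cf]]][[severity_levels[ifl]]]
      if (is.null(row)) {
        abort_emibayes("format", sprintf(
          "'%s': dimension '%s' severity_cpt missing row cf=%s/if=%s",
          path, id, severity_levels[cf], severity_levels[ifl]))
      }
      cpt[cf, ifl, ] <- as.numeric(unlist(row))
    }
    dimension_spec(
      id = id,
      name = if (is.null(d$name)) id else d$name,
      prior = lapply(need(d, "prior", paste0("dimension '", id, "'")),
                     function(p) as.numeric(unlist(p))),
      question_ids = unlist(need(d, "questions", paste0("dimension '", id, "'"))),
      severity_cpt = cpt
    )
  })

  advice <- lapply(need(doc, "advice", "document"), function(a) {
    id <- need(a, "id", "advice entry")
    act <- lapply(need(a, "activation", paste0("advice '", id, "'")),
                  function(v) {
                    if (!is.null(names(v))) {
                      full <- stats::setNames(numeric(4), severity_levels)
                      full[names(v)] <- as.numeric(unlist(v))
                      full
                    } else as.numeric(unlist(v))
                  })
    advice_spec(id = id, name = if (is.null(a$name)) id else a$name,
                activation = act,
                leak = if (is.null(a$leak)) 0 else a$leak)
  })

  bn_model(dimensions = dimensions, questions = questions, advice = advice,
           alpha = need(doc, "alpha", "document"),
           metadata = if (is.null(doc$metadata)) list() else doc$metadata,
           validate = TRUE)
}

#' Save a model specification file
#'
#' Writes the documented YAML dialect (all tables as probabilities).
#'
#' @param model An `emibayes_model`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  num <- function(x) lapply(as.numeric(x), identity)
  doc <- list(
    format = MODEL_FORMAT,
    metadata = model$metadata,
    alpha = model$alpha,
    levels = as.list(severity_levels),
    dimensions = unname(lapply(model$dimensions, function(d) {
      cpt <- stats::setNames(lapply(1:4, function(cf) {
        stats::setNames(lapply(1:4, function(ifl) num(d$severity_cpt[cf, ifl, ])),
                        severity_levels)
      }), severity_levels)
      list(id = d$id, name = d$name,
           prior = lapply(d$prior, num),
           questions = as.list(d$question_ids),
           severity_cpt = cpt)
    })),
    questions = unname(lapply(model$questions, function(q) {
      list(id = q$id, dimension = q$dimension, text = q$text,
           answers = as.list(q$answers),
           likelihood = stats::setNames(
             lapply(1:4, function(k) num(q$likelihood[, k])), severity_levels),
           vas_thresholds = as.list(q$vas_thresholds))
    })),
    advice = unname(lapply(model$advice, function(a) {
      list(id = a$id, name = a$name,
           activation = lapply(a$activation, num),
           leak = a$leak)
    }))
  )
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

#' Path to the default model shipped with the package
#'
#' @export
default_model_path <- function() {
  system.file("extdata", "default_model.yaml", package = "emibayes",
              mustWork = TRUE)
}

#' Load the default model
#'
#' The shipped knowledge base: 9 clinical dimensions, 23 questions, 10 pieces
#' of advice. The anxiety tables are the expert-elicited ones; the remaining
#' dimensions carry structurally valid placeholder tables (see the package
#' vignette and [build_default_model()]).
#'
#' @export
default_model <- function() {
  load_model(default_model_path())
}
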