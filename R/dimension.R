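# Model complexity: the number of independent parameters needed to describe
# all conditional distributions, sum over nodes of (r_i - 1) * q_i, where r_i
# is the node cardinality and q_i the number of parent configurations
# (q_i = 1 for a root node).

#' Number of independent parameters of a network structure
#'
#' For an abstract structure, supply a list of nodes, each a list with
#' `name`, `cardinality` and `parents` (character vector of node names).
#' For a model, the derived structure contains the two binary context nodes
#' (gender, age group), per dimension an immediate-value, cumulated-value
#' (both with the context as parents) and severity node (parents IF and CF),
#' one node per question (parent: its dimension's IF), and one binary node
#' per advice (parents: the severity nodes of its parent dimensions).
#'
#' Note the full-table count for an advice node is exponential in its number
#' of parents; the noisy-OR parameterisation actually stored needs only
#' [advice_parameter_count()] free parameters.
#'
#' @param x An `emibayes_model` or a list of node descriptions.
#' @return List with `total` (the parameter count) and `nodes`, a data frame
#'   with per-node cardinality `r`, parent-configuration count `q` and
#'   parameter contribution.
#' @export
model_dimension <- function(x) UseMethod("model_dimension")

#' @export
model_dimension.list <- function(x) {
  names(x) <- vapply(x, `[[`, "", "name")
  card <- vapply(x, function(n) as.integer(n$cardinality), integer(1))

  # Cycle check: repeatedly peel nodes whose parents are all peeled.
  remaining <- names(x)
  done <- character()
  repeat {
    ready <- remaining[vapply(remaining, function(n) {
      parents <- x[[n]]$parents
      if (length(parents) && !all(parents %in% names(x))) {
        abort_emibayes("structure", sprintf(
          "node '%s' has unknown parent(s): %s", n,
          paste(setdiff(parents, names(x)), collapse = ", ")))
      }
      all(x[[n]]$parents %in% done)
    }, logical(1))]
    if (length(ready) == 0) break
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining)) {
    abort_emibayes("structure", sprintf(
      "cycle detected involving node(s): %s", paste(remaining, collapse = ", ")))
  }

  q <- vapply(x, function(n) {
    if (length(n$parents) == 0) 1 else prod(card[n$parents])
  }, numeric(1))
  nodes <- data.frame(name = names(x), r = card, q = q,
                      parameters = (card - 1) * q,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(total = sum(nodes$parameters), nodes = nodes)
}

#' @export
model_dimension.emibayes_model <- function(x) {
  model_dimension(model_structure_nodes(x))
}

# Derive the abstract node list of a model's graph.
model_structure_nodes <- function(model) {
  nodes <- list(
    list(name = "gender", cardinality = 2L, parents = character()),
    list(name = "age_group", cardinality = 2L, parents = character())
  )
  for (d in model$dimensions) {
    nodes <- c(nodes, list(
      list(name = paste0("IF_", d$id), cardinality = 4L,
           parents = c("gender", "age_group")),
      list(name = paste0("CF_", d$id), cardinality = 4L,
           parents = c("gender", "age_group")),
      list(name = paste0("CS_", d$id), cardinality = 4L,
           parents = paste0(c("IF_", "CF_"), d$id))
    ))
  }
  for (q in model$questions) {
    nodes <- c(nodes, list(
      list(name = paste0("Q_", q$id), cardinality = 4L,
           parents = paste0("IF_", q$dimension))))
  }
  for (a in model$advice) {
    nodes <- c(nodes, list(
      list(name = paste0("advice_", a$id), cardinality = 2L,
           parents = paste0("CS_", a$parents))))
  }
  nodes
}

#' Free parameters stored by an advice's noisy-OR model
#'
#' Three non-absent activation levels per parent plus the leak: `3p + 1`,
#' linear in the number of parents (a full table would need `4^p` rows).
#'
#' @param advice An [advice_spec()] entry.
#' @export
advice_parameter_count <- function(advice) {
  3L * length(advice$parents) + 1L
}
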