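# Brute-force exact inference by exhaustive summation of the factorised
# joint. Test-only companion to the engine: it must stay independent of the
# closed-form paths it checks, so it enumerates every configuration.

#' Describe a node for the enumeration oracle
#'
#' @param name Node name.
#' @param values Character vector of the node's states.
#' @param parents Character vector of parent node names (order matters: it is
#'   the order of the CPT dimensions after the first).
#' @param cpt Array of `P(node | parents)`: first dimension indexes the
#'   node's own states, remaining dimensions the parents' states in order.
#'   A root node takes a plain probability vector.
#' @export
bn_node <- function(name, values, parents = character(), cpt) {
  cpt <- as.array(cpt)
  list(name = name, values = values, parents = parents, cpt = cpt)
}

#' Exact posterior by exhaustive enumeration
#'
#' Sums the factorised joint distribution over every configuration of the
#' relevant part of the network, conditions on the evidence, and marginalises
#' the query node. Barren nodes — nodes that are neither the query, nor
#' evidence, nor an ancestor of either — integrate out to one and are
#' dropped before enumeration; evidence nodes are clamped to their observed
#' state. Both reductions leave the posterior unchanged while keeping the
#' summation exhaustive over the remaining joint. Intended for testing on
#' small networks only; refuses reduced state spaces above one million
#' configurations.
#'
#' @param nodes List of [bn_node()] descriptions (any order; parents must be
#'   among the nodes).
#' @param evidence Named list, node name -> observed state (a value from that
#'   node's `values`).
#' @param query Name of the node whose posterior is requested.
#' @return Named probability vector over the query node's states.
#' @export
enumeration_oracle <- function(nodes, evidence = list(), query) {
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  if (!query %in% names(nodes)) {
    abort_emibayes("model", sprintf("unknown query node '%s'", query))
  }
  for (n in nodes) {
    if (length(n$parents) && !all(n$parents %in% names(nodes))) {
      abort_emibayes("structure", sprintf(
        "node '%s' has unknown parent(s)", n$name))
    }
  }
  for (ev in names(evidence)) {
    if (!ev %in% names(nodes)) {
      abort_emibayes("model", sprintf("evidence on unknown node '%s'", ev))
    }
  }

  # Keep the query, the evidence and all their ancestors.
  relevant <- character()
  frontier <- c(query, names(evidence))
  while (length(frontier)) {
    n <- frontier[[1]]
    frontier <- frontier[-1]
    if (n %in% relevant) next
    relevant <- c(relevant, n)
    frontier <- c(frontier, nodes[[n]]$parents)
  }
  nodes <- nodes[names(nodes) %in% relevant]

  domains <- lapply(nodes, function(n) {
    if (n$name %in% names(evidence)) {
      v <- match(evidence[[n$name]], n$values)
      if (is.na(v)) {
        abort_emibayes("model", sprintf(
          "evidence value '%s' not a state of node '%s'",
          evidence[[n$name]], n$name))
      }
      v
    } else {
      seq_along(n$values)
    }
  })
  if (prod(lengths(domains)) > 1e6) {
    abort_emibayes("oracle_scope", sprintf(
      "joint state space has %g configurations (limit 1e6)",
      prod(lengths(domains))))
  }

  grid <- expand.grid(domains, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(nodes)

  prob <- rep(1, nrow(grid))
  for (n in nodes) {
    idx <- as.matrix(grid[, c(n$name, n$parents), drop = FALSE])
    prob <- prob * n$cpt[idx]
  }

  total <- sum(prob)
  if (total <= 0) {
    abort_emibayes("inconsistent_evidence",
                   "evidence has probability zero under the joint")
  }
  states <- grid[[query]]
  post <- vapply(seq_along(nodes[[query]]$values),
                 function(v) sum(prob[states == v]), numeric(1)) / total
  names(post) <- nodes[[query]]$values
  post
}

#' Expand noisy-OR parameters to a full conditional probability table
#'
#' Builds the explicit `2 x 4^p` table P(advice | CS_1..CS_p) implied by the
#' noisy-OR parameters, for use by the enumeration oracle. First dimension is
#' c("no", "yes"); remaining dimensions are the parents' severity levels.
#'
#' @param advice An [advice_spec()] entry.
#' @export
noisy_or_cpt <- function(advice) {
  p <- length(advice$parents)
  dims <- c(2L, rep(4L, p))
  cpt <- array(NA_real_, dim = dims)
  configs <- expand.grid(rep(list(1:4), p), KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(configs))) {
    cfg <- as.integer(configs[r, ])
    survive <- prod(vapply(seq_len(p), function(j) {
      1 - advice$activation[[advice$parents[j]]][cfg[j]]
    }, numeric(1)))
    yes <- 1 - (1 - advice$leak) * survive
    cpt[matrix(c(1L, cfg), nrow = 1)] <- 1 - yes
    cpt[matrix(c(2L, cfg), nrow = 1)] <- yes
  }
  cpt
}

#' Build the oracle network for one scoring of a model
#'
#' One root node per dimension for the immediate value (prior: the context
#' prior unless `cf` overrides it), one root per dimension for the cumulated
#' value (prior: `cf`, defaulting to the context prior), the severity node
#' with parents (IF, CF), one node per question with parent IF, and one
#' binary node per advice whose CPT is the expanded noisy-OR table.
#'
#' @param model An `emibayes_model`.
#' @param context A [context_profile()] key.
#' @param cf Optional named list of cumulated-value distributions per
#'   dimension (also used as the IF prior, matching the engine's use of CF
#'   as the scoring-time prior); defaults to the context priors.
#' @return List of [bn_node()]s, ready for [enumeration_oracle()].
#' @export
bn_from_model <- function(model, context, cf = NULL) {
  context <- context_profile(context)
  nodes <- list()
  for (d in model$dimensions) {
    prior <- if (!is.null(cf[[d$id]])) as.numeric(cf[[d$id]])
             else as.numeric(d$prior[[context]])
    # CS CPT as [cs, if, cf]
    cs_cpt <- aperm(d$severity_cpt, c(3, 2, 1))
    nodes <- c(nodes, list(
      bn_node(paste0("IF_", d$id), severity_levels, cpt = prior),
      bn_node(paste0("CF_", d$id), severity_levels, cpt = prior),
      bn_node(paste0("CS_", d$id), severity_levels,
              parents = paste0(c("IF_", "CF_"), d$id), cpt = cs_cpt)
    ))
  }
  for (q in model$questions) {
    nodes <- c(nodes, list(
      bn_node(paste0("Q_", q$id), q$answers,
              parents = paste0("IF_", q$dimension), cpt = q$likelihood)))
  }
  for (a in model$advice) {
    nodes <- c(nodes, list(
      bn_node(paste0("advice_", a$id), c("no", "yes"),
              parents = paste0("CS_", a$parents), cpt = noisy_or_cpt(a))))
  }
  nodes
}
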