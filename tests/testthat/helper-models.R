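# Fixtures built in code: random small models for property tests and an
# independent brute-force parameter counter.

rand_dist <- function(n = 4) {
  x <- stats::runif(n) + 0.05
  x / sum(x)
}

# Random valid model: n_dims dimensions, n_questions per dimension, n_advice
# advice entries with 1..2 parents each. Deterministic given the seed.
random_model <- function(n_dims = 2, n_questions = 1, n_advice = 1, seed = 1,
                         alpha = stats::runif(1)) {
  set.seed(seed)
  force(alpha)
  dim_ids <- paste0("d", seq_len(n_dims))
  questions <- list()
  dimensions <- lapply(dim_ids, function(id) {
    qids <- paste0(id, "_q", seq_len(n_questions))
    for (q in qids) {
      questions[[q]] <<- question_spec(
        id = q, dimension = id,
        likelihood = sapply(1:4, function(k) rand_dist()))
    }
    cpt <- array(0, c(4, 4, 4))
    for (cf in 1:4) for (ifl in 1:4) cpt[cf, ifl, ] <- rand_dist()
    dimension_spec(
      id = id,
      prior = stats::setNames(lapply(1:4, function(i) rand_dist()),
                              context_profiles),
      question_ids = qids, severity_cpt = cpt)
  })
  advice <- lapply(seq_len(n_advice), function(i) {
    parents <- sample(dim_ids, sample(1:min(2, n_dims), 1))
    act <- lapply(parents, function(p) c(0, sort(stats::runif(3))))
    names(act) <- parents
    advice_spec(id = paste0("a", i), activation = act,
                leak = stats::runif(1, 0, 0.2))
  })
  bn_model(dimensions = dimensions, questions = unname(questions),
           advice = advice, alpha = alpha)
}

# Independent parameter counter: explicitly enumerates every
# (node, parent configuration) pair instead of multiplying cardinalities.
brute_force_dimension <- function(nodes) {
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  total <- 0L
  for (n in nodes) {
    configs <- if (length(n$parents) == 0) {
      1L
    } else {
      nrow(expand.grid(lapply(n$parents, function(p) {
        seq_len(nodes[[p]]$cardinality)
      })))
    }
    total <- total + (n$cardinality - 1L) * configs
  }
  total
}

expect_distribution <- function(p) {
  expect_length(p, 4L)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-9)
}
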