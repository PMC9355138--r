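# shared fixtures, built in code

# config with all three fidelities set to a common level
fid_config <- function(n, fidelity, seed, ...) {
  cohort_config(n_respondents = n, vmls_rank1_fidelity = fidelity,
                ibase_best_fidelity = fidelity,
                ibase_least_affinity = fidelity, seed = seed, ...)
}

# null world: outcomes carry no crowd signal at all
null_config <- function(n, seed) {
  crowds <- peer_crowds()
  cohort_config(
    n_respondents = n, seed = seed,
    behavior_crowd_logodds = matrix(
      0, 5, 7,
      dimnames = list(crowds, c("cigarettes", "lcc", "smokeless", "vape",
                                "alcohol", "marijuana", "sad_hopeless"))),
    trait_means = list(brs = stats::setNames(rep(3, 5), crowds),
                       spi = stats::setNames(rep(3.4, 5), crowds),
                       bsss = stats::setNames(rep(3.3, 5), crowds)),
    ace_prob = matrix(0.3, 5, 9, dimnames = list(crowds, paste0("ace_", 1:9)))
  )
}

scored_cohort <- function(config) {
  score_cohort(generate_cohort(config), config$grid_spec)
}

# independent scoring oracle: walks every selection and tallies points,
# a literal re-derivation of the published point rule
oracle_vmls <- function(rank1, rank2) {
  tally <- stats::setNames(rep(0, 5), peer_crowds())
  half_point <- c("Alternative", "Mainstream")
  for (q in seq_along(rank1)) {
    tally[rank1[q]] <- tally[rank1[q]] + 2
    w <- if (rank2[q] %in% half_point) 0.5 else 1
    tally[rank2[q]] <- tally[rank2[q]] + w
  }
  tally
}

# direct likelihood maximization for logistic regression (Nelder-Mead on the
# hand-written log-likelihood), independent of the IRLS route
oracle_logistic <- function(y, X) {
  nll <- function(beta) {
    eta <- as.vector(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  opt$par
}

# exhaustive 2-question pattern grid (ordered rank1 != rank2 pairs)
two_question_patterns <- function() {
  crowds <- peer_crowds()
  pairs <- expand.grid(r1 = crowds, r2 = crowds, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$r1 != pairs$r2, ]
  expand.grid(q1 = seq_len(nrow(pairs)), q2 = seq_len(nrow(pairs)))
}
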