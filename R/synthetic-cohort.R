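#' Generate a synthetic respondent cohort
#'
#' Draws a full cohort from the generative model described by a
#' [cohort_config()]: a latent crowd per respondent, ranked-choice mindset
#' responses and photo-grid selections whose fidelity to the latent crowd is
#' tunable, adversity/resilience/trait items, past-30-day substance use, and
#' demographics. The latent crowd column is the generator's oracle and is
#' withheld from all analysis stages (it is written to CSV flagged as
#' oracle-only).
#'
#' The generator is fully deterministic given the config: the seed is part of
#' the config and the RNG is re-seeded on entry.
#'
#' @param config A validated [cohort_config()].
#' @return A data frame with one row per respondent: `respondent_id`,
#'   `latent_crowd`, 14 mindset-response columns (`vmls_q{1..7}_rank{1,2}`),
#'   12 photo-pick columns per pair of grids (`ibase_g{g}_best{1..3}`,
#'   `ibase_g{g}_least{1..3}`), item responses (`ace_1..9`, `brs_1..6`,
#'   `spi_1..8`, `bsss_1..8`), `use_days_*` for six substances,
#'   `sad_hopeless`, and demographics.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_respondents = 50, seed = 7))
#' table(cohort$latent_crowd)
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_respondents
  crowds <- peer_crowds()
  latent <- sample(crowds, n, replace = TRUE, prob = config$crowd_prevalences)
  vmls <- sample_vmls_response(latent, config)
  ibase <- sample_ibase_response(latent, config)
  outcomes <- sample_outcomes(latent, config)
  cbind(
    data.frame(respondent_id = sprintf("R%06d", seq_len(n)),
               latent_crowd = latent, stringsAsFactors = FALSE),
    vmls, ibase, outcomes
  )
}

#' Simulate ranked-choice mindset responses
#'
#' For each of the seven questions, the rank-1 option matches the latent
#' crowd with probability `vmls_rank1_fidelity` and is otherwise uniform over
#' the other four crowds; the rank-2 option is drawn from the latent crowd's
#' affinity row restricted to crowds other than the rank-1 pick.
#'
#' @param latent_crowd Character vector of latent crowd labels (one per
#'   respondent); all draws use the current RNG state.
#' @param config A [cohort_config()].
#' @return Data frame with columns `vmls_q{q}_rank1` / `vmls_q{q}_rank2`.
#' @export
sample_vmls_response <- function(latent_crowd, config) {
  crowds <- peer_crowds()
  idx <- match(latent_crowd, crowds)
  if (anyNA(idx)) stop("latent_crowd must be one of the five crowds", call. = FALSE)
  n <- length(idx)
  out <- vector("list", 14)
  nm <- character(14)
  for (q in 1:7) {
    faithful <- stats::runif(n) < config$vmls_rank1_fidelity
    offset <- sample.int(4, n, replace = TRUE)
    r1 <- ifelse(faithful, idx, ((idx - 1 + offset) %% 5) + 1)
    # rank-2: affinity row of the latent crowd, zeroed at the rank-1 crowd
    p <- config$vmls_affinity[idx, , drop = FALSE]
    p[cbind(seq_len(n), r1)] <- 0
    rs <- rowSums(p)
    # a degenerate row (all mass on the rank-1 crowd) falls back to uniform
    deg <- rs <= 0
    if (any(deg)) {
      p[deg, ] <- 1
      p[cbind(which(deg), r1[deg])] <- 0
      rs[deg] <- 4
    }
    cp <- p / rs
    for (j in 2:5) cp[, j] <- cp[, j] + cp[, j - 1]
    u <- stats::runif(n)
    r2 <- rowSums(u > cp) + 1L
    out[[2 * q - 1]] <- crowds[r1]
    out[[2 * q]] <- crowds[r2]
    nm[2 * q - 1] <- sprintf("vmls_q%d_rank1", q)
    nm[2 * q] <- sprintf("vmls_q%d_rank2", q)
  }
  stats::setNames(as.data.frame(out, stringsAsFactors = FALSE), nm)
}

#' Simulate photo-grid selections
#'
#' Within each grid the respondent picks three best-fit and three least-fit
#' photos without replacement. Each best pick targets a remaining own-crowd
#' photo with probability `ibase_best_fidelity` (uniform over the remaining
#' other-crowd photos otherwise); each least pick deliberately avoids
#' own-crowd photos with probability `ibase_least_affinity` and is uniform
#' over all remaining photos otherwise. Best and least sets are disjoint by
#' construction.
#'
#' @inheritParams sample_vmls_response
#' @return Data frame with columns `ibase_g{g}_best{1..3}` and
#'   `ibase_g{g}_least{1..3}` holding photo ids.
#' @export
sample_ibase_response <- function(latent_crowd, config) {
  crowds <- peer_crowds()
  gs <- config$grid_spec
  idx <- match(latent_crowd, crowds)
  if (anyNA(idx)) stop("latent_crowd must be one of the five crowds", call. = FALSE)
  n <- length(idx)
  f <- config$ibase_best_fidelity
  a <- config$ibase_least_affinity
  grids <- sort(unique(gs$grid))
  cols <- list()
  for (g in grids) {
    sub <- gs[gs$grid == g, ]
    best <- matrix(NA_character_, n, 3)
    least <- matrix(NA_character_, n, 3)
    for (ci in seq_along(crowds)) {
      rows <- which(idx == ci)
      if (!length(rows)) next
      own_ids <- sub$photo_id[sub$crowd == crowds[ci]]
      oth_ids <- sub$photo_id[sub$crowd != crowds[ci]]
      m <- length(own_ids); M <- length(oth_ids); nr <- length(rows)
      # best picks: count of own-crowd photos taken, capped by availability
      k <- pmin(stats::rbinom(nr, 3, f), m, 3)
      # least picks: sequential own-pick probability given remaining pools
      r_own <- m - k
      r_oth <- M - (3 - k)
      j <- integer(nr)
      for (step in 1:3) {
        p_own <- ifelse(r_own == 0, 0,
                        ifelse(r_oth == 0, 1,
                               (1 - a) * r_own / (r_own + r_oth)))
        pick_own <- stats::runif(nr) < p_own
        j <- j + pick_own
        r_own <- r_own - pick_own
        r_oth <- r_oth - !pick_own
      }
      # identities: uniform random orderings of each pool, consumed in order
      perm_own <- random_orderings(nr, m)
      perm_oth <- random_orderings(nr, M)
      for (cpos in 1:3) {
        use_own <- cpos <= k
        bcol <- character(nr)
        bcol[use_own] <- own_ids[perm_own[cbind(which(use_own), cpos)]]
        if (any(!use_own)) {
          w <- which(!use_own)
          bcol[w] <- oth_ids[perm_oth[cbind(w, cpos - k[w])]]
        }
        best[rows, cpos] <- bcol
        use_own_l <- cpos <= j
        lcol <- character(nr)
        if (any(use_own_l)) {
          w <- which(use_own_l)
          lcol[w] <- own_ids[perm_own[cbind(w, k[w] + cpos)]]
        }
        if (any(!use_own_l)) {
          w <- which(!use_own_l)
          lcol[w] <- oth_ids[perm_oth[cbind(w, (3 - k[w]) + (cpos - j[w]))]]
        }
        least[rows, cpos] <- lcol
      }
    }
    for (cpos in 1:3) cols[[sprintf("ibase_g%d_best%d", g, cpos)]] <- best[, cpos]
    for (cpos in 1:3) cols[[sprintf("ibase_g%d_least%d", g, cpos)]] <- least[, cpos]
  }
  as.data.frame(cols, stringsAsFactors = FALSE)
}

# n independent uniform random orderings of 1..k, as an n x k integer matrix
random_orderings <- function(n, k) {
  if (k == 0) return(matrix(integer(0), n, 0))
  if (k == 1) return(matrix(1L, n, 1))
  u <- matrix(stats::runif(n * k), n, k)
  matrix(t(apply(u, 1, order)), nrow = n, ncol = k)
}

#' Simulate scale items, behaviors, and demographics
#'
#' Dichotomous outcomes are Bernoulli on the logistic scale
#' (`base + crowd effect`); a positive substance indicator draws its
#' past-30-day frequency uniformly from 1-30 (only the dichotomy is analyzed
#' downstream). Trait items are a per-respondent latent level (normal with
#' the crowd's mean/SD) plus item noise, rounded and clamped to the response
#' range. Adversity items are independent Bernoulli draws with per-crowd
#' probabilities. Demographics are sampled from the configured marginals,
#' independently of crowd.
#'
#' @inheritParams sample_vmls_response
#' @return Data frame with item, behavior, and demographic columns.
#' @export
sample_outcomes <- function(latent_crowd, config) {
  crowds <- peer_crowds()
  idx <- match(latent_crowd, crowds)
  if (anyNA(idx)) stop("latent_crowd must be one of the five crowds", call. = FALSE)
  n <- length(idx)
  out <- list()

  for (item in 1:9) {
    out[[paste0("ace_", item)]] <-
      stats::rbinom(n, 1, config$ace_prob[idx, item])
  }

  trait_items <- function(trait, k, lo, hi, to_item = identity) {
    latent <- stats::rnorm(n, config$trait_means[[trait]][idx],
                           config$trait_sds[[trait]][idx])
    vals <- vapply(seq_len(k), function(i) {
      v <- round(to_item(latent) + stats::rnorm(n, 0, 0.7))
      pmin(hi, pmax(lo, v))
    }, numeric(n))
    matrix(vals, nrow = n, ncol = k)
  }
  brs <- trait_items("brs", 6, 1, 5)
  # items 2, 4, 6 are stored reverse-coded so that scoring (which reverses
  # them back) recovers the latent resilience level
  for (i in c(2, 4, 6)) brs[, i] <- 6 - brs[, i]
  for (i in 1:6) out[[paste0("brs_", i)]] <- brs[, i]

  rng <- config$spi_item_range
  # map the 0-10 score scale onto the item response range
  spi <- trait_items("spi", 8, rng[1], rng[2],
                     to_item = function(t) rng[1] + t / 10 * (rng[2] - rng[1]))
  for (i in 1:8) out[[paste0("spi_", i)]] <- spi[, i]

  bsss <- trait_items("bsss", 8, 1, 5)
  for (i in 1:8) out[[paste0("bsss_", i)]] <- bsss[, i]

  for (b in seq_along(binary_outcomes())) {
    name <- binary_outcomes()[b]
    p <- stats::plogis(config$behavior_base_logodds[[name]] +
                         config$behavior_crowd_logodds[idx, b])
    ind <- stats::rbinom(n, 1, p)
    if (name == "sad_hopeless") {
      out$sad_hopeless <- ind
    } else {
      days <- integer(n)
      pos <- ind == 1
      days[pos] <- sample.int(30, sum(pos), replace = TRUE)
      out[[paste0("use_days_", name)]] <- days
    }
  }

  dm <- config$demographic_marginals
  out$age <- as.integer(sample(names(dm$age), n, TRUE, dm$age))
  out$gender <- sample(names(dm$gender), n, TRUE, dm$gender)
  out$race_ethnicity <- sample(names(dm$race_ethnicity), n, TRUE,
                               dm$race_ethnicity)
  out$region <- sample(names(dm$region), n, TRUE, dm$region)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Write a cohort and its configuration to disk
#'
#' Writes the respondent table as CSV (the `latent_crowd` column is
#' oracle-only ground truth and is documented as such) together with the
#' generating configuration, as a human-readable YAML-style text file and a
#' machine-readable JSON copy.
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param path Output CSV path; the config files take the same stem with
#'   `_config.yml` / `_config.json` suffixes.
#' @param config Optional [cohort_config()] to write alongside.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, config = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE)
  if (!is.null(config)) {
    stem <- sub("\\.csv$", "", path)
    writeLines(config_as_yaml(config), paste0(stem, "_config.yml"))
    jsonlite::write_json(config_as_list(config), paste0(stem, "_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

config_as_list <- function(config) {
  x <- unclass(config)
  x$grid_spec <- as.list(x$grid_spec)
  x$behavior_crowd_logodds <- as.data.frame(x$behavior_crowd_logodds)
  x$vmls_affinity <- as.data.frame(x$vmls_affinity)
  x$ace_prob <- as.data.frame(x$ace_prob)
  x
}

# flat YAML-style rendering for humans; JSON is the machine copy
config_as_yaml <- function(config) {
  fmt <- function(v) paste(format(v, trim = TRUE), collapse = ", ")
  c(
    paste0("n_respondents: ", config$n_respondents),
    paste0("seed: ", config$seed),
    paste0("crowd_prevalences: [", fmt(config$crowd_prevalences), "]"),
    paste0("vmls_rank1_fidelity: ", config$vmls_rank1_fidelity),
    paste0("ibase_best_fidelity: ", config$ibase_best_fidelity),
    paste0("ibase_least_affinity: ", config$ibase_least_affinity),
    paste0("ibase_points: ", config$ibase_points),
    paste0("behavior_base_logodds: [", fmt(config$behavior_base_logodds), "]"),
    paste0("spi_item_range: [", fmt(config$spi_item_range), "]"),
    "# full matrices (affinity, crowd log-odds, ace probabilities, grid map)",
    "# are in the JSON copy written alongside this file"
  )
}
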