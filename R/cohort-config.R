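#' Photo-grid layout for the photo-based instrument
#'
#' Builds the photo-to-crowd map used both to simulate photo selections and to
#' score them. Real deployments use proprietary photo sets; the package
#' operates on the crowd mapping only, which is all the scoring rule needs.
#'
#' @param n_grids Number of photo grids shown (default 2).
#' @param photos_per_crowd Photos representing each crowd within one grid
#'   (default 2, i.e. 10 photos per grid).
#' @return A data frame with columns `photo_id`, `grid`, `crowd`.
#' @export
#' @examples
#' head(default_grid_spec())
default_grid_spec <- function(n_grids = 2, photos_per_crowd = 2) {
  stopifnot(n_grids >= 1, photos_per_crowd >= 1)
  rows <- expand.grid(
    slot = seq_len(photos_per_crowd),
    crowd = peer_crowds(),
    grid = seq_len(n_grids),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  data.frame(
    photo_id = sprintf("g%d_%s_%d", rows$grid, tolower(rows$crowd), rows$slot),
    grid = rows$grid,
    crowd = rows$crowd,
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic respondent cohort
#'
#' Collects every generative parameter of the synthetic world: latent crowd
#' prevalences, instrument fidelities (how strongly responses track the
#' latent crowd), crowd-specific behavior log-odds, per-crowd trait
#' distributions, and demographic marginals. Defaults reproduce the published
#' sample's marginal structure: crowd prevalences from the validation study's
#' descriptive table (renormalized over the five non-tied categories),
#' behavior base rates from the reported prevalences, and crowd effects whose
#' signs follow the reported risk profiles (e.g. elevated vaping/marijuana
#' for Hip Hop, protective Mainstream effects across substances).
#'
#' Instrument fidelities have no published estimate; the defaults (0.55) are
#' chosen once to place cross-instrument convergent correlations in the
#' 0.2-0.6 band the validation study reports, and are documented as
#' illustrative rather than estimated.
#'
#' @param n_respondents Cohort size.
#' @param crowd_prevalences Named probability vector over [peer_crowds()];
#'   must sum to 1.
#' @param vmls_rank1_fidelity Probability a rank-1 mindset choice matches the
#'   latent crowd; otherwise uniform over the other four options.
#' @param vmls_affinity 5x5 row-stochastic matrix: distribution of the rank-2
#'   crowd given the latent crowd; diagonal must be 0 (the own-crowd option
#'   is the modal rank-1 pick, never the planned second choice).
#' @param ibase_best_fidelity Probability each best-fit photo pick targets a
#'   remaining own-crowd photo.
#' @param ibase_least_affinity Probability each least-fit pick deliberately
#'   avoids own-crowd photos.
#' @param grid_spec Photo map from [default_grid_spec()].
#' @param ibase_points Points per photo selection (+ for best, - for least).
#' @param behavior_base_logodds Named 7-vector of intercepts for the
#'   dichotomous outcomes (six substances + sad/hopeless).
#' @param behavior_crowd_logodds 5x7 matrix of crowd effects on the log-odds
#'   scale (rows = crowds, columns = outcomes).
#' @param trait_means,trait_sds Lists with per-crowd 5-vectors for `brs`
#'   (1-5), `spi` (0-10 score scale), `bsss` (1-5).
#' @param ace_prob 5x9 matrix of per-crowd Bernoulli probabilities for the
#'   nine adversity items.
#' @param demographic_marginals List of named probability vectors: `age`
#'   (13-18), `gender`, `race_ethnicity`, `region`.
#' @param spi_item_range Response range of the social-prioritization items
#'   before rescaling to the 0-10 score (default 1-5).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return A validated list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_respondents = 1113,
                          crowd_prevalences = default_crowd_prevalences(),
                          vmls_rank1_fidelity = 0.55,
                          vmls_affinity = default_vmls_affinity(),
                          ibase_best_fidelity = 0.55,
                          ibase_least_affinity = 0.55,
                          grid_spec = default_grid_spec(),
                          ibase_points = 2,
                          behavior_base_logodds = default_behavior_base_logodds(),
                          behavior_crowd_logodds = default_behavior_crowd_logodds(),
                          trait_means = default_trait_means(),
                          trait_sds = default_trait_sds(),
                          ace_prob = default_ace_prob(),
                          demographic_marginals = default_demographic_marginals(),
                          spi_item_range = c(1, 5),
                          seed = 1L) {
  config <- structure(
    list(
      n_respondents = n_respondents,
      crowd_prevalences = crowd_prevalences,
      vmls_rank1_fidelity = vmls_rank1_fidelity,
      vmls_affinity = vmls_affinity,
      ibase_best_fidelity = ibase_best_fidelity,
      ibase_least_affinity = ibase_least_affinity,
      grid_spec = grid_spec,
      ibase_points = ibase_points,
      behavior_base_logodds = behavior_base_logodds,
      behavior_crowd_logodds = behavior_crowd_logodds,
      trait_means = trait_means,
      trait_sds = trait_sds,
      ace_prob = ace_prob,
      demographic_marginals = demographic_marginals,
      spi_item_range = spi_item_range,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(config)
  config
}

#' @rdname cohort_config
#' @export
default_crowd_prevalences <- function() {
  # published single-crowd assignment shares, renormalized over non-tied
  p <- c(Alternative = 0.304, Country = 0.106, HipHop = 0.146,
         Mainstream = 0.186, Popular = 0.189)
  p / sum(p)
}

#' @rdname cohort_config
#' @export
default_vmls_affinity <- function() {
  crowds <- peer_crowds()
  a <- matrix(0.25, 5, 5, dimnames = list(crowds, crowds))
  diag(a) <- 0
  a
}

#' @rdname cohort_config
#' @export
default_behavior_base_logodds <- function() {
  # intercepts matched to published behavior prevalences
  stats::qlogis(c(cigarettes = 0.078, lcc = 0.049, smokeless = 0.024,
                  vape = 0.186, alcohol = 0.290, marijuana = 0.200,
                  sad_hopeless = 0.574))
}

#' @rdname cohort_config
#' @export
default_behavior_crowd_logodds <- function() {
  m <- rbind(
    Alternative = c( 0.0,  0.0, -0.6,  0.0,  0.0,  0.5,  0.7),
    Country     = c( 0.6,  0.5,  1.0,  0.0,  0.0, -0.2, -0.5),
    HipHop      = c( 0.3,  0.7,  0.0,  0.7,  0.4,  0.6,  0.0),
    Mainstream  = c(-0.8, -0.8, -0.8, -0.8, -0.5, -0.8,  0.0),
    Popular     = c( 0.0,  0.0, -0.5,  0.4,  0.5,  0.0, -0.3)
  )
  colnames(m) <- binary_outcomes()
  m
}

#' @rdname cohort_config
#' @export
default_trait_means <- function() {
  crowds <- peer_crowds()
  list(
    brs  = stats::setNames(c(2.80, 3.05, 3.05, 3.10, 3.10), crowds),
    spi  = stats::setNames(c(3.00, 3.40, 3.70, 2.80, 4.30), crowds),
    bsss = stats::setNames(c(3.50, 3.10, 3.40, 3.10, 3.50), crowds)
  )
}

#' @rdname cohort_config
#' @export
default_trait_sds <- function() {
  crowds <- peer_crowds()
  list(
    brs  = stats::setNames(rep(0.80, 5), crowds),
    spi  = stats::setNames(rep(2.20, 5), crowds),
    bsss = stats::setNames(rep(0.75, 5), crowds)
  )
}

#' @rdname cohort_config
#' @export
default_ace_prob <- function() {
  per_crowd <- c(Alternative = 0.40, Country = 0.30, HipHop = 0.40,
                 Mainstream = 0.22, Popular = 0.26)
  matrix(rep(per_crowd, 9), nrow = 5,
         dimnames = list(peer_crowds(), paste0("ace_", 1:9)))
}

#' @rdname cohort_config
#' @export
default_demographic_marginals <- function() {
  list(
    age = stats::setNames(c(0.064, 0.064, 0.064, 0.2693, 0.2693, 0.2694),
                          13:18),
    gender = stats::setNames(c(0.573, 0.353, 0.074), gender_levels()),
    race_ethnicity = stats::setNames(c(0.544, 0.112, 0.162, 0.083, 0.099),
                                     race_levels()),
    region = stats::setNames(c(0.321, 0.270, 0.212, 0.197), region_levels())
  )
}

#' Validate a cohort configuration
#'
#' Checks every structural invariant of the generative model and raises a
#' configuration error naming the first offending field.
#'
#' @param config A [cohort_config()] object.
#' @return The config, invisibly, if valid.
#' @export
validate_cohort_config <- function(config) {
  crowds <- peer_crowds()
  check_prob <- function(x, field) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
      stop_config(field, "must contain probabilities in [0, 1]")
    }
  }
  if (!is.numeric(config$n_respondents) || length(config$n_respondents) != 1 ||
      config$n_respondents < 1 || config$n_respondents != round(config$n_respondents)) {
    stop_config("n_respondents", "must be a positive integer count")
  }
  p <- config$crowd_prevalences
  check_prob(p, "crowd_prevalences")
  if (length(p) != 5 || !setequal(names(p), crowds)) {
    stop_config("crowd_prevalences", "must be named over the five crowds")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop_config("crowd_prevalences", "must sum to 1 (tolerance 1e-9)")
  }
  check_prob(config$vmls_rank1_fidelity, "vmls_rank1_fidelity")
  a <- config$vmls_affinity
  if (!is.matrix(a) || !all(dim(a) == c(5, 5))) {
    stop_config("vmls_affinity", "must be a 5x5 matrix")
  }
  check_prob(a, "vmls_affinity")
  if (any(abs(rowSums(a) - 1) > 1e-9)) {
    stop_config("vmls_affinity", "rows must sum to 1")
  }
  if (any(diag(a) != 0)) {
    stop_config("vmls_affinity", "must have a zero diagonal")
  }
  check_prob(config$ibase_best_fidelity, "ibase_best_fidelity")
  check_prob(config$ibase_least_affinity, "ibase_least_affinity")
  gs <- config$grid_spec
  if (!is.data.frame(gs) ||
      !all(c("photo_id", "grid", "crowd") %in% names(gs))) {
    stop_config("grid_spec", "must have columns photo_id, grid, crowd")
  }
  if (anyDuplicated(gs$photo_id)) {
    stop_config("grid_spec", "photo ids must be unique")
  }
  for (g in unique(gs$grid)) {
    sub <- gs[gs$grid == g, ]
    if (nrow(sub) < 6) {
      stop_config("grid_spec", sprintf("grid %s has fewer than 6 photos", g))
    }
    if (!all(crowds %in% sub$crowd)) {
      stop_config("grid_spec",
                  sprintf("grid %s must include at least one photo per crowd", g))
    }
  }
  b <- config$behavior_base_logodds
  if (length(b) != 7 || !setequal(names(b), binary_outcomes())) {
    stop_config("behavior_base_logodds",
                "must be named over the seven dichotomous outcomes")
  }
  m <- config$behavior_crowd_logodds
  if (!is.matrix(m) || !all(dim(m) == c(5, 7))) {
    stop_config("behavior_crowd_logodds", "must be a 5x7 matrix")
  }
  for (tr in c("brs", "spi", "bsss")) {
    if (length(config$trait_means[[tr]]) != 5) {
      stop_config("trait_means", sprintf("must give 5 per-crowd means for %s", tr))
    }
    if (length(config$trait_sds[[tr]]) != 5 || any(config$trait_sds[[tr]] < 0)) {
      stop_config("trait_sds", sprintf("must give 5 non-negative SDs for %s", tr))
    }
  }
  if (!is.matrix(config$ace_prob) || !all(dim(config$ace_prob) == c(5, 9))) {
    stop_config("ace_prob", "must be a 5x9 matrix")
  }
  check_prob(config$ace_prob, "ace_prob")
  dm <- config$demographic_marginals
  for (field in c("age", "gender", "race_ethnicity", "region")) {
    v <- dm[[field]]
    if (is.null(v)) stop_config("demographic_marginals", paste("missing", field))
    check_prob(v, paste0("demographic_marginals$", field))
    if (abs(sum(v) - 1) > 1e-6) {
      stop_config(paste0("demographic_marginals$", field), "must sum to 1")
    }
  }
  if (length(config$spi_item_range) != 2 ||
      diff(config$spi_item_range) <= 0) {
    stop_config("spi_item_range", "must be an increasing (min, max) pair")
  }
  invisible(config)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  n_respondents:", x$n_respondents, " seed:", x$seed, "\n")
  cat("  prevalences:",
      paste(sprintf("%s=%.3f", names(x$crowd_prevalences), x$crowd_prevalences),
            collapse = " "), "\n")
  cat("  fidelities: vmls_rank1=", x$vmls_rank1_fidelity,
      " ibase_best=", x$ibase_best_fidelity,
      " ibase_least=", x$ibase_least_affinity, "\n", sep = "")
  cat("  grid:", length(unique(x$grid_spec$grid)), "grids x",
      nrow(x$grid_spec) / length(unique(x$grid_spec$grid)), "photos\n")
  invisible(x)
}
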