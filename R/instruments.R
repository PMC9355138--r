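#' Score the ranked-choice mindset instrument
#'
#' Each of the seven questions offers five crowd-mapped options; the
#' respondent ranks a first and second choice. A crowd earns 2 points per
#' rank-1 selection and its rank-2 weight (1 point, or 0.5 for Alternative
#' and Mainstream) per rank-2 selection, giving a 0-14 score per crowd.
#'
#' @param rank1,rank2 Character vectors of length 7: the crowd of the rank-1
#'   and rank-2 option per question. `rank1[q] != rank2[q]` is required.
#' @param rank2_weights Named per-crowd rank-2 weights
#'   (default [vmls_rank2_weights()]).
#' @return Named numeric vector of five crowd scores (a crowd score set),
#'   with attribute `instrument = "vmls"`.
#' @export
#' @examples
#' score_vmls(rep("HipHop", 7), rep("Country", 7))
score_vmls <- function(rank1, rank2, rank2_weights = vmls_rank2_weights()) {
  crowds <- peer_crowds()
  if (length(rank1) != 7 || length(rank2) != 7 ||
      anyNA(rank1) || anyNA(rank2)) {
    stop("exactly 7 ranked pairs are required, with no missing choices",
         call. = FALSE)
  }
  bad <- which(!(rank1 %in% crowds) | !(rank2 %in% crowds))
  if (length(bad)) {
    stop(sprintf("question %d: unknown crowd label", bad[1]), call. = FALSE)
  }
  dup <- which(rank1 == rank2)
  if (length(dup)) {
    stop(sprintf("question %d: rank-1 and rank-2 must differ", dup[1]),
         call. = FALSE)
  }
  scores <- vapply(crowds, function(cr) {
    2 * sum(rank1 == cr) + rank2_weights[[cr]] * sum(rank2 == cr)
  }, numeric(1))
  structure(scores, instrument = "vmls")
}

#' Score the photo-grid instrument
#'
#' Respondents pick, in each grid, the three photos that best and the three
#' that least fit their friend group. A crowd earns `+points` per best-fit
#' photo and `-points` per least-fit photo mapped to it; with two grids and
#' the default 2 points per selection the score spans -12 to 12.
#'
#' @param best,least Character vectors of photo ids (3 per grid, so 6 with
#'   the default two grids). Best and least sets must be disjoint within a
#'   grid.
#' @param grid_spec Photo map data frame (see [default_grid_spec()]).
#' @param points Points per selection (design choice; default 2 reproduces
#'   the published -12..12 range).
#' @return Named numeric vector of five crowd scores, with attribute
#'   `instrument = "ibase"`.
#' @export
score_ibase <- function(best, least, grid_spec = default_grid_spec(),
                        points = 2) {
  map <- stats::setNames(grid_spec$crowd, grid_spec$photo_id)
  gmap <- stats::setNames(grid_spec$grid, grid_spec$photo_id)
  unknown <- setdiff(c(best, least), names(map))
  if (length(unknown)) {
    stop(sprintf("unknown photo id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (g in unique(grid_spec$grid)) {
    b <- best[gmap[best] == g]
    l <- least[gmap[least] == g]
    if (length(b) != 3 || length(l) != 3) {
      stop(sprintf("grid %s must contribute exactly 3 best and 3 least picks", g),
           call. = FALSE)
    }
    if (length(intersect(b, l))) {
      stop(sprintf("grid %s: best and least sets overlap", g), call. = FALSE)
    }
  }
  if (anyDuplicated(best) || anyDuplicated(least)) {
    stop("photo ids may not be selected twice", call. = FALSE)
  }
  crowds <- peer_crowds()
  scores <- vapply(crowds, function(cr) {
    points * sum(map[best] == cr) - points * sum(map[least] == cr)
  }, numeric(1))
  structure(scores, instrument = "ibase")
}

#' Assign a single primary crowd from a score set
#'
#' The respondent's crowd is the unique argmax of the five scores; any tie at
#' the maximum (including all scores equal) yields `"Tied"`.
#'
#' @param scores Named numeric vector of five crowd scores.
#' @return A single crowd label or `"Tied"`.
#' @export
#' @examples
#' assign_primary_crowd(c(Alternative = 14, Country = 0, HipHop = 0,
#'                        Mainstream = 0, Popular = 0))
assign_primary_crowd <- function(scores) {
  if (length(scores) != 5 || anyNA(scores)) {
    stop("a score set holds exactly 5 non-missing crowd scores", call. = FALSE)
  }
  mx <- max(scores)
  top <- names(scores)[scores == mx]
  if (length(top) == 1) top else "Tied"
}

# shared item validation + row-wise reduction for the auxiliary scales
scale_reduce <- function(items, k, lo, hi, reducer, label) {
  x <- if (is.matrix(items) || is.data.frame(items)) {
    as.matrix(items)
  } else {
    matrix(items, nrow = 1)
  }
  if (ncol(x) != k) {
    stop(sprintf("%s requires exactly %d items", label, k), call. = FALSE)
  }
  if (anyNA(x)) stop(sprintf("%s has missing items", label), call. = FALSE)
  if (any(x < lo | x > hi)) {
    stop(sprintf("%s items must lie in [%s, %s]", label, lo, hi), call. = FALSE)
  }
  out <- reducer(x)
  if (nrow(x) == 1) out[[1]] else out
}

#' Score the adverse childhood experiences count
#'
#' Nine binary adversity items; the score is the number experienced (0-9).
#'
#' @param items Length-9 binary vector, or an n x 9 matrix for many
#'   respondents.
#' @return Integer count(s) in 0-9.
#' @export
score_ace <- function(items) {
  scale_reduce(items, 9, 0, 1, rowSums, "ACE")
}

#' Score the brief resilience scale
#'
#' Six items on 1-5; items 2, 4, 6 are negatively worded and reverse-coded
#' before averaging (published scale convention). The score is the item mean,
#' 1-5, higher = more resilient.
#'
#' @param items Length-6 vector in 1-5, or an n x 6 matrix.
#' @param reverse Indices of reverse-coded items (configurable; default 2, 4, 6).
#' @return Numeric score(s) in 1-5.
#' @export
score_brs <- function(items, reverse = c(2, 4, 6)) {
  scale_reduce(items, 6, 1, 5, function(x) {
    x[, reverse] <- 6 - x[, reverse]
    rowMeans(x)
  }, "BRS")
}

#' Score the social prioritization index
#'
#' Eight items on a configurable response range, linearly rescaled so the
#' score spans 0-10 (higher = socializing matters more). The published report
#' states only the 0-10 score range; the linear rescaling is this package's
#' documented choice.
#'
#' @param items Length-8 vector, or an n x 8 matrix.
#' @param item_range `(min, max)` of the item response range (default 1-5).
#' @return Numeric score(s) in 0-10.
#' @export
score_spi <- function(items, item_range = c(1, 5)) {
  lo <- item_range[1]; hi <- item_range[2]
  scale_reduce(items, 8, lo, hi, function(x) {
    (rowMeans(x) - lo) / (hi - lo) * 10
  }, "SPI")
}

#' Score the brief sensation seeking scale
#'
#' Eight items on 1-5; the score is the item mean (higher = greater
#' sensation seeking).
#'
#' @param items Length-8 vector in 1-5, or an n x 8 matrix.
#' @return Numeric score(s) in 1-5.
#' @export
score_bsss <- function(items) {
  scale_reduce(items, 8, 1, 5, rowMeans, "BSSS")
}

#' Dichotomize past-30-day use frequency
#'
#' Any use in the past 30 days counts as current use.
#'
#' @param use_days Integer vector of day counts in 0-30.
#' @return Binary vector: 1 iff `use_days >= 1`.
#' @export
dichotomize_behavior <- function(use_days) {
  if (anyNA(use_days) || any(use_days < 0) || any(use_days > 30)) {
    stop("use_days must lie in [0, 30] with no missing values", call. = FALSE)
  }
  as.integer(use_days >= 1)
}

# vectorized cohort-level scorers ------------------------------------------

vmls_choice_matrix <- function(cohort, rank) {
  cols <- sprintf("vmls_q%d_rank%d", 1:7, rank)
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    stop("cohort lacks mindset-response columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as.matrix(cohort[cols])
}

ibase_pick_matrix <- function(cohort, grid_spec, kind) {
  grids <- sort(unique(grid_spec$grid))
  cols <- as.vector(vapply(grids, function(g) {
    sprintf("ibase_g%d_%s%d", g, kind, 1:3)
  }, character(3)))
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    stop("cohort lacks photo-pick columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as.matrix(cohort[cols])
}

#' Score a full cohort
#'
#' Applies both crowd instruments and all auxiliary scales to a respondent
#' table (synthetic or user-supplied), appending ten crowd-score columns,
#' two primary-crowd assignments, the four scale scores, and the seven
#' dichotomized behaviors. Inputs must be complete: a row with any missing
#' instrument item invalidates that instrument's score, so such rows are
#' rejected at load time (see [load_respondents_csv()]) rather than scored.
#'
#' @param cohort Respondent table as produced by [generate_cohort()] or
#'   [load_respondents_csv()].
#' @param grid_spec Photo map used for the photo-grid instrument.
#' @param ibase_points Points per photo selection.
#' @param rank2_weights Rank-2 weights for the mindset instrument.
#' @param spi_item_range Response range of the social-prioritization items.
#' @return The cohort with scoring columns appended: `vmls_*`, `ibase_*`
#'   (five each), `vmls_assignment`, `ibase_assignment`, `ace`, `brs`,
#'   `spi`, `bsss`, `use_*` binaries.
#' @export
score_cohort <- function(cohort, grid_spec = default_grid_spec(),
                         ibase_points = 2,
                         rank2_weights = vmls_rank2_weights(),
                         spi_item_range = c(1, 5)) {
  crowds <- peer_crowds()
  n <- nrow(cohort)
  r1 <- vmls_choice_matrix(cohort, 1)
  r2 <- vmls_choice_matrix(cohort, 2)
  dup <- which(rowSums(r1 == r2) > 0)
  if (length(dup)) {
    stop(sprintf("row %d: rank-1 and rank-2 coincide within a question",
                 dup[1]), call. = FALSE)
  }
  vmls <- vapply(crowds, function(cr) {
    2 * rowSums(r1 == cr) + rank2_weights[[cr]] * rowSums(r2 == cr)
  }, numeric(n))
  vmls <- matrix(vmls, nrow = n,
                 dimnames = list(NULL, score_columns("vmls")))

  map <- stats::setNames(grid_spec$crowd, grid_spec$photo_id)
  best <- ibase_pick_matrix(cohort, grid_spec, "best")
  least <- ibase_pick_matrix(cohort, grid_spec, "least")
  unknown <- setdiff(c(best, least), names(map))
  if (length(unknown)) {
    stop("unknown photo id(s): ", paste(utils::head(unknown, 3), collapse = ", "),
         call. = FALSE)
  }
  bc <- matrix(map[best], nrow = n)
  lc <- matrix(map[least], nrow = n)
  ibase <- vapply(crowds, function(cr) {
    ibase_points * (rowSums(bc == cr) - rowSums(lc == cr))
  }, numeric(n))
  ibase <- matrix(ibase, nrow = n,
                  dimnames = list(NULL, score_columns("ibase")))

  assign_all <- function(m) apply(m, 1, function(s) {
    assign_primary_crowd(stats::setNames(s, crowds))
  })

  item_block <- function(prefix, k) as.matrix(cohort[paste0(prefix, seq_len(k))])
  scored <- cbind(
    cohort,
    as.data.frame(vmls),
    as.data.frame(ibase),
    data.frame(
      vmls_assignment = assign_all(vmls),
      ibase_assignment = assign_all(ibase),
      ace = score_ace(item_block("ace_", 9)),
      brs = score_brs(item_block("brs_", 6)),
      spi = score_spi(item_block("spi_", 8), item_range = spi_item_range),
      bsss = score_bsss(item_block("bsss_", 8)),
      stringsAsFactors = FALSE
    )
  )
  for (s in substances()) {
    scored[[paste0("use_", s)]] <-
      dichotomize_behavior(cohort[[paste0("use_days_", s)]])
  }
  scored
}
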