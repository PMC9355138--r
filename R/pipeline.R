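required_cohort_columns <- function(grid_spec = default_grid_spec()) {
  grids <- sort(unique(grid_spec$grid))
  c(
    sprintf("vmls_q%d_rank%d", rep(1:7, each = 2), 1:2),
    as.vector(vapply(grids, function(g) {
      c(sprintf("ibase_g%d_best%d", g, 1:3), sprintf("ibase_g%d_least%d", g, 1:3))
    }, character(6))),
    paste0("ace_", 1:9), paste0("brs_", 1:6), paste0("spi_", 1:8),
    paste0("bsss_", 1:8),
    paste0("use_days_", substances()),
    "sad_hopeless", "age", "gender", "race_ethnicity", "region"
  )
}

#' Load a respondent table from CSV
#'
#' Reads a cohort CSV (synthetic or user-supplied) against the documented
#' column dictionary. The header must contain every required column (schema
#' error otherwise). Rows violating record-level invariants — duplicate
#' ranks within a question, overlapping or unknown photo picks, out-of-range
#' items, use-day counts outside 0-30 — are rejected individually; valid
#' rows proceed. Rejections are reported via a warning and attached as the
#' `rejected` attribute (a data frame of file line numbers and reasons).
#'
#' @param path CSV file path.
#' @param grid_spec Photo map the photo-pick columns are validated against.
#' @return Data frame of valid respondent records, with attribute
#'   `rejected`.
#' @export
load_respondents_csv <- function(path, grid_spec = default_grid_spec()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- required_cohort_columns(grid_spec)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("schema error: missing column(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("schema error: no data rows", call. = FALSE)

  reasons <- rep(NA_character_, nrow(df))
  flag <- function(bad, reason) {
    fresh <- bad & is.na(reasons)
    reasons[fresh] <<- reason
  }

  r1 <- as.matrix(df[sprintf("vmls_q%d_rank1", 1:7)])
  r2 <- as.matrix(df[sprintf("vmls_q%d_rank2", 1:7)])
  flag(rowSums(!matrix(r1 %in% peer_crowds(), nrow(df))) > 0 |
         rowSums(!matrix(r2 %in% peer_crowds(), nrow(df))) > 0,
       "unknown crowd label in ranked choices")
  flag(rowSums(r1 == r2) > 0, "rank-1 equals rank-2 within a question")

  best <- ibase_pick_matrix(df, grid_spec, "best")
  least <- ibase_pick_matrix(df, grid_spec, "least")
  known <- stats::setNames(grid_spec$grid, grid_spec$photo_id)
  flag(rowSums(!matrix(best %in% names(known), nrow(df))) > 0 |
         rowSums(!matrix(least %in% names(known), nrow(df))) > 0,
       "unknown photo id")
  overlap <- vapply(seq_len(nrow(df)), function(i) {
    any(best[i, ] %in% least[i, ]) || anyDuplicated(best[i, ]) > 0 ||
      anyDuplicated(least[i, ]) > 0
  }, logical(1))
  flag(overlap, "best/least photo sets overlap or repeat")

  range_bad <- function(cols, lo, hi) {
    m <- as.matrix(df[cols])
    rowSums(is.na(m) | m < lo | m > hi) > 0
  }
  flag(range_bad(paste0("ace_", 1:9), 0, 1), "ACE item out of range")
  flag(range_bad(paste0("brs_", 1:6), 1, 5), "BRS item out of range")
  flag(range_bad(paste0("spi_", 1:8), 1, 5), "SPI item out of range")
  flag(range_bad(paste0("bsss_", 1:8), 1, 5), "BSSS item out of range")
  flag(range_bad(paste0("use_days_", substances()), 0, 30),
       "use_days outside [0, 30]")
  flag(is.na(df$sad_hopeless) | !(df$sad_hopeless %in% c(0, 1)),
       "sad_hopeless not binary")
  flag(is.na(df$age) | df$age < 13 | df$age > 18, "age outside 13-18")

  bad <- !is.na(reasons)
  rejected <- data.frame(line = which(bad) + 1L, reason = reasons[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    warning(sprintf("%d invalid row(s) rejected (see attr(., 'rejected'))",
                    nrow(rejected)), call. = FALSE)
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Descriptive summary of a scored cohort
#'
#' Frequencies and means in the layout of the published participant table:
#' demographics, primary crowd assignments for both instruments (including
#' the tied category), behavior prevalences, and trait means/SDs.
#'
#' @param scored Scored table from [score_cohort()].
#' @return Long data frame: `section`, `level`, `n`, `percent`, `mean`, `sd`.
#' @export
describe_cohort <- function(scored) {
  n <- nrow(scored)
  freq_block <- function(section, values, levels) {
    tab <- table(factor(values, levels = levels))
    data.frame(section = section, level = names(tab), n = as.integer(tab),
               percent = round(100 * as.integer(tab) / n, 1),
               mean = NA_real_, sd = NA_real_, stringsAsFactors = FALSE)
  }
  mean_block <- function(section, level, x) {
    data.frame(section = section, level = level, n = sum(!is.na(x)),
               percent = NA_real_, mean = round(mean(x, na.rm = TRUE), 2),
               sd = round(stats::sd(x, na.rm = TRUE), 2),
               stringsAsFactors = FALSE)
  }
  assignment_levels <- c(peer_crowds(), "Tied")
  rbind(
    freq_block("gender", scored$gender, gender_levels()),
    freq_block("race_ethnicity", scored$race_ethnicity, race_levels()),
    freq_block("region", scored$region, region_levels()),
    freq_block("age_group", ifelse(scored$age <= 15, "13-15", "16-18"),
               c("13-15", "16-18")),
    freq_block("ibase_crowd", scored$ibase_assignment, assignment_levels),
    freq_block("vmls_crowd", scored$vmls_assignment, assignment_levels),
    do.call(rbind, lapply(substances(), function(s) {
      freq_block(paste0("current_", s), scored[[paste0("use_", s)]], c(0, 1))
    })),
    freq_block("sad_hopeless", scored$sad_hopeless, c(0, 1)),
    mean_block("experiences", "ace", scored$ace),
    mean_block("experiences", "brs", scored$brs),
    mean_block("traits", "spi", scored$spi),
    mean_block("traits", "bsss", scored$bsss)
  )
}

stage <- function(name, log_level, expr) {
  t0 <- proc.time()[["elapsed"]]
  if (log_level != "quiet") message(sprintf("[%s] starting", name))
  result <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (log_level != "quiet") {
    message(sprintf("[%s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  result
}

#' Run the full validation pipeline
#'
#' Orchestrates generate (or load) -> score -> descriptives -> reliability ->
#' MTMM -> validity -> prediction battery as one reproducible run. All
#' outputs are written under `out_dir` and returned as a bundle; identical
#' config and seed yield byte-identical outputs. With `mtmm_only = TRUE`,
#' only the packaged published matrix is evaluated (no cohort is generated).
#'
#' @param config A [cohort_config()] describing the synthetic cohort, or
#'   `NULL` when `csv` is given.
#' @param csv Optional path to a respondent CSV (exactly one of `config` or
#'   `csv` supplies the cohort).
#' @param out_dir Output directory (created if needed).
#' @param alpha Significance level for validity decisions, in (0, 1).
#' @param omega_method Estimator for [fit_one_factor()].
#' @param battery_mode Passed to [run_prediction_battery()].
#' @param mtmm_only Evaluate the packaged published matrix only.
#' @param log_level `"info"` (stage timers on stderr) or `"quiet"`.
#' @return Invisibly, a bundle list: `scored`, `descriptives`,
#'   `reliability`, `mtmm`, `validity`, `battery`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config = cohort_config(), csv = NULL,
                         out_dir = tempfile("peercrowds_run_"),
                         alpha = 0.05, omega_method = "uls",
                         battery_mode = "separate", mtmm_only = FALSE,
                         log_level = "info") {
  stopifnot(alpha > 0, alpha < 1)
  if (!is.null(config) && !is.null(csv)) {
    stop("supply exactly one cohort source: config or csv", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (mtmm_only) {
    mtmm <- stage("mtmm-fixture", log_level, mtmm_table3_fixture())
    validity <- stage("validity", log_level, evaluate_validity(mtmm, alpha))
    write_mtmm_csv(mtmm, file.path(out_dir, "mtmm.csv"))
    write_validity_json(validity, file.path(out_dir, "validity.json"))
    bundle <- list(mtmm = mtmm, validity = validity,
                   manifest = pipeline_manifest(NULL, alpha, mtmm_only = TRUE),
                   out_dir = out_dir)
    jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_report(bundle, file.path(out_dir, "report.txt"))
    return(invisible(bundle))
  }

  grid_spec <- if (!is.null(config)) config$grid_spec else default_grid_spec()
  cohort <- if (!is.null(csv)) {
    stage("load", log_level, load_respondents_csv(csv, grid_spec))
  } else {
    stage("generate", log_level, generate_cohort(config))
  }
  if (is.null(csv)) {
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"), config)
  }
  scored <- stage("score", log_level, {
    if (!is.null(config)) {
      score_cohort(cohort, grid_spec, ibase_points = config$ibase_points,
                   spi_item_range = config$spi_item_range)
    } else {
      score_cohort(cohort, grid_spec)
    }
  })
  descriptives <- stage("descriptives", log_level, describe_cohort(scored))
  reliability <- stage("reliability", log_level,
                       reliability_table(cohort, grid_spec,
                                         method = omega_method))
  mtmm <- stage("mtmm", log_level, build_mtmm(scored, reliability))
  validity <- stage("validity", log_level, evaluate_validity(mtmm, alpha))
  battery <- stage("battery", log_level,
                   run_prediction_battery(scored, mode = battery_mode))

  utils::write.csv(scored, file.path(out_dir, "scored.csv"), row.names = FALSE)
  utils::write.csv(descriptives, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(reliability, file.path(out_dir, "reliability.csv"),
                   row.names = FALSE)
  write_mtmm_csv(mtmm, file.path(out_dir, "mtmm.csv"))
  write_validity_json(validity, file.path(out_dir, "validity.json"))
  utils::write.csv(battery, file.path(out_dir, "battery_long.csv"),
                   row.names = FALSE)
  utils::write.csv(format_battery_table(battery),
                   file.path(out_dir, "battery_table.csv"), row.names = FALSE)

  manifest <- pipeline_manifest(config, alpha, battery_mode = battery_mode,
                                omega_method = omega_method, csv = csv)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  bundle <- list(scored = scored, descriptives = descriptives,
                 reliability = reliability, mtmm = mtmm, validity = validity,
                 battery = battery, manifest = manifest, out_dir = out_dir)
  write_report(bundle, file.path(out_dir, "report.txt"))
  invisible(bundle)
}

write_validity_json <- function(validity, path) {
  jsonlite::write_json(
    list(alpha = validity$alpha,
         n_convergent_pass = validity$n_convergent_pass,
         n_violations = validity$n_violations,
         convergent = validity$convergent,
         violations = validity$violations),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
}

pipeline_manifest <- function(config, alpha, battery_mode = NA,
                              omega_method = NA, csv = NULL,
                              mtmm_only = FALSE) {
  hash <- if (!is.null(config)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(config_as_list(config), tmp, auto_unbox = TRUE,
                         digits = NA)
    unname(tools::md5sum(tmp))
  } else NA_character_
  list(
    package = "peercrowds",
    version = as.character(utils::packageVersion("peercrowds")),
    r_version = R.version.string,
    seed = if (!is.null(config)) config$seed else NA_integer_,
    config_hash = hash,
    cohort_source = if (!is.null(csv)) csv else if (mtmm_only) "fixture" else "synthetic",
    alpha = alpha,
    battery_mode = battery_mode,
    omega_method = omega_method
  )
}

#' Render a human-readable run report
#'
#' Writes a plain-text summary: the reliability diagonal, the MTMM in the
#' published 10x10 layout, the validity decisions, and the battery in the
#' published outcomes-by-crowd layout (failed cells flagged, not blank).
#'
#' @param bundle Bundle list from [run_pipeline()].
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path) {
  lines <- c("peercrowds pipeline report",
             strrep("=", 60))
  if (!is.null(bundle$descriptives)) {
    lines <- c(lines, "", "Sample descriptives (first rows):",
               utils::capture.output(print(utils::head(bundle$descriptives, 12),
                                           row.names = FALSE)))
  }
  if (!is.null(bundle$reliability)) {
    lines <- c(lines, "", "Reliability (McDonald's omega):",
               utils::capture.output(print(bundle$reliability, row.names = FALSE)))
  }
  if (!is.null(bundle$mtmm)) {
    lines <- c(lines, "", "Multi-trait multi-method matrix:",
               utils::capture.output(print(bundle$mtmm)))
  }
  if (!is.null(bundle$validity)) {
    lines <- c(lines, "", utils::capture.output(print(bundle$validity)))
  }
  if (!is.null(bundle$battery)) {
    lines <- c(lines, "", "Prediction battery (AOR for behaviors, B for scores):",
               utils::capture.output(print(format_battery_table(bundle$battery),
                                           row.names = FALSE)))
  }
  writeLines(lines, path)
  invisible(path)
}
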