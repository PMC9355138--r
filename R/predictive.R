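battery_covariates <- function() c("age", "gender", "race_ethnicity")

# design-matrix prep shared by both fits: fixed reference levels
prepare_model_frame <- function(scored, outcome, predictors, covariates) {
  need <- c(outcome, predictors, intersect(covariates, names(scored)))
  missing <- setdiff(c(outcome, predictors, covariates), names(scored))
  if (length(missing)) {
    stop("scored table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- scored[c(outcome, predictors, covariates)]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if ("gender" %in% covariates) {
    df$gender <- factor(df$gender, levels = gender_levels())
  }
  if ("race_ethnicity" %in% covariates) {
    df$race_ethnicity <- factor(df$race_ethnicity, levels = race_levels())
  }
  df
}

estimate_row <- function(outcome, instrument, crowd, coef, se, p, n, family) {
  data.frame(
    outcome = outcome, instrument = instrument, crowd = crowd,
    family = family, coefficient = coef, se = se, p = p,
    aor = if (family == "binary") exp(coef) else NA_real_,
    n = n, failed = FALSE, error = NA_character_,
    stringsAsFactors = FALSE
  )
}

extract_predictor <- function(fit, predictor, outcome) {
  sm <- summary(fit)$coefficients
  if (!predictor %in% rownames(sm)) {
    stop(sprintf("predictor %s dropped from the %s model (rank deficiency)",
                 predictor, outcome), call. = FALSE)
  }
  sm[predictor, ]
}

#' Logistic regression of one behavior on one crowd score
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()]) of a dichotomous outcome on a crowd score, adjusting for
#' age (continuous years), gender (reference: Female), and race/ethnicity
#' (reference: NH white). Reports the coefficient per score point, its Wald
#' standard error and p-value, and the adjusted odds ratio
#' `AOR = exp(coefficient)`.
#'
#' @param scored Scored respondent table from [score_cohort()].
#' @param outcome Name of a binary column (e.g. `"use_vape"`,
#'   `"sad_hopeless"`).
#' @param predictor Name of a crowd score column (e.g. `"vmls_hiphop"`), or
#'   several (joint entry).
#' @param covariates Adjustment set (default age, gender, race/ethnicity).
#' @return One-row data frame: `outcome`, `instrument`, `crowd`, `family`,
#'   `coefficient`, `se`, `p`, `aor`, `n`. With multiple predictors, one row
#'   per predictor.
#' @export
fit_logistic <- function(scored, outcome, predictor,
                         covariates = battery_covariates()) {
  df <- prepare_model_frame(scored, outcome, predictor, covariates)
  y <- df[[outcome]]
  if (!all(y %in% c(0, 1))) {
    stop(sprintf("outcome %s is not binary", outcome), call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop(sprintf("degenerate outcome %s: only one class present", outcome),
         call. = FALSE)
  }
  form <- stats::reformulate(c(predictor, covariates), response = outcome)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged || separation) {
    stop(sprintf("logistic fit failed for %s ~ %s: %s", outcome,
                 paste(predictor, collapse = "+"),
                 if (separation) "quasi-complete separation" else "non-convergence"),
         call. = FALSE)
  }
  do.call(rbind, lapply(predictor, function(pr) {
    est <- extract_predictor(fit, pr, outcome)
    estimate_row(outcome, predictor_instrument(pr), predictor_crowd(pr),
                 est[1], est[2], est[4], nrow(df), "binary")
  }))
}

#' Linear regression of one trait score on one crowd score
#'
#' Ordinary least squares fit of a continuous outcome on a crowd score with
#' the same adjustment set as [fit_logistic()]. Reports the slope `B` per
#' score point, its standard error and two-sided p-value.
#'
#' @inheritParams fit_logistic
#' @param outcome Name of a continuous column (`"ace"`, `"brs"`, `"spi"`,
#'   `"bsss"`).
#' @return One-row data frame (same schema as [fit_logistic()], `aor = NA`).
#' @export
fit_linear <- function(scored, outcome, predictor,
                       covariates = battery_covariates()) {
  df <- prepare_model_frame(scored, outcome, predictor, covariates)
  form <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- stats::lm(form, data = df)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  do.call(rbind, lapply(predictor, function(pr) {
    est <- extract_predictor(fit, pr, outcome)
    estimate_row(outcome, predictor_instrument(pr), predictor_crowd(pr),
                 est[1], est[2], est[4], nrow(df), "continuous")
  }))
}

predictor_instrument <- function(predictor) {
  ifelse(startsWith(predictor, "vmls_"), "vmls",
         ifelse(startsWith(predictor, "ibase_"), "ibase", NA_character_))
}

predictor_crowd <- function(predictor) {
  crowds <- peer_crowds()
  crowds[match(sub("^(vmls|ibase)_", "", predictor), tolower(crowds))]
}

#' Run the full prediction battery
#'
#' One regression per instrument x crowd x outcome: logistic for the seven
#' dichotomous outcomes (six current-use behaviors and sad/hopeless), linear
#' for the four experience/trait scores — 110 models under the default
#' separate-entry mode. Crowd scores within an instrument are negatively
#' correlated by construction (shared forced choices), which makes joint
#' entry unstable, so each score is entered in its own model by default;
#' `mode = "joint"` enters all five crowd scores of an instrument together.
#' Per-cell estimation failures are flagged in the output rather than
#' aborting the battery.
#'
#' @param scored Scored respondent table from [score_cohort()].
#' @param mode `"separate"` (default) or `"joint"`.
#' @param covariates Adjustment set for every model.
#' @return Long data frame with one row per (instrument, crowd, outcome):
#'   `coefficient`, `se`, `p`, `aor` (binary outcomes only), `n`, `failed`,
#'   `error`.
#' @export
run_prediction_battery <- function(scored, mode = c("separate", "joint"),
                                   covariates = battery_covariates()) {
  mode <- match.arg(mode)
  outcomes <- data.frame(
    name = c(paste0("use_", substances()), "sad_hopeless", trait_outcomes()),
    family = c(rep("binary", 7), rep("continuous", 4)),
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (instrument in c("ibase", "vmls")) {
    preds <- score_columns(instrument)
    for (oi in seq_len(nrow(outcomes))) {
      fitter <- if (outcomes$family[oi] == "binary") fit_logistic else fit_linear
      run_one <- function(predictor) {
        tryCatch(fitter(scored, outcomes$name[oi], predictor, covariates),
                 error = function(e) {
                   do.call(rbind, lapply(predictor, function(pr) {
                     out <- estimate_row(outcomes$name[oi], instrument,
                                         predictor_crowd(pr), NA_real_,
                                         NA_real_, NA_real_, NA_integer_,
                                         outcomes$family[oi])
                     out$failed <- TRUE
                     out$error <- conditionMessage(e)
                     out$aor <- NA_real_
                     out
                   }))
                 })
      }
      if (mode == "separate") {
        for (pr in preds) rows[[length(rows) + 1]] <- run_one(pr)
      } else {
        rows[[length(rows) + 1]] <- run_one(preds)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape the battery into the published table layout
#'
#' Rows are outcomes (behaviors as AOR, trait scores as B), columns are
#' instrument-by-crowd cells; failed cells render as `"FAILED"` rather than
#' blank.
#'
#' @param battery Long battery from [run_prediction_battery()].
#' @param digits Rounding for display.
#' @return Data frame in wide layout.
#' @export
format_battery_table <- function(battery, digits = 2) {
  cell <- function(row) {
    if (row$failed) return("FAILED")
    val <- if (row$family == "binary") row$aor else row$coefficient
    stars <- if (is.na(row$p)) "" else if (row$p < 0.001) "***"
    else if (row$p < 0.01) "**" else if (row$p < 0.05) "*" else ""
    paste0(format(round(val, digits), nsmall = digits), stars)
  }
  outcomes <- unique(battery$outcome)
  cols <- unique(paste(battery$crowd, battery$instrument, sep = "."))
  wide <- data.frame(outcome = outcomes, stringsAsFactors = FALSE)
  for (cl in cols) wide[[cl]] <- NA_character_
  for (i in seq_len(nrow(battery))) {
    row <- battery[i, ]
    wide[wide$outcome == row$outcome,
         paste(row$crowd, row$instrument, sep = ".")] <- cell(row)
  }
  wide
}
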