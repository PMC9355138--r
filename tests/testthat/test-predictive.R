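test_that("IRLS agrees with direct likelihood maximization on a tiny dataset", {
  tiny <- data.frame(
    y = c(0, 1, 0, 1, 0, 1, 1, 0),
    vmls_hiphop = c(2, 3, 4, 5, 5, 4, 6, 3),
    age = c(13, 14, 15, 16, 16, 17, 18, 15)
  )
  est <- fit_logistic(tiny, "y", "vmls_hiphop", covariates = "age")
  X <- cbind(1, tiny$vmls_hiphop, tiny$age)
  beta <- oracle_logistic(tiny$y, X)
  expect_equal(est$coefficient, beta[2], tolerance = 5e-4)
  expect_equal(est$aor, exp(est$coefficient))
})

test_that("logistic regression recovers injected per-point effects", {
  cfg <- cohort_config(n_respondents = 20000, seed = 41)
  scored <- scored_cohort(cfg)
  set.seed(411)
  eta <- -1.5 + 0.10 * scored$vmls_hiphop
  scored$synthetic_use <- stats::rbinom(nrow(scored), 1, stats::plogis(eta))
  est <- fit_logistic(scored, "synthetic_use", "vmls_hiphop")
  expect_lt(abs(est$coefficient - 0.10), 0.03)
  expect_equal(est$n, nrow(scored))
})

test_that("logistic regression rejects degenerate outcomes", {
  cfg <- cohort_config(n_respondents = 200, seed = 42)
  scored <- scored_cohort(cfg)
  scored$always <- 1
  expect_error(fit_logistic(scored, "always", "vmls_hiphop"), "one class")
  scored$not_binary <- scored$ace
  expect_error(fit_logistic(scored, "not_binary", "vmls_hiphop"), "not binary")
})

test_that("linear regression is exact on constructed data and recovers effects", {
  cfg <- cohort_config(n_respondents = 2000, seed = 43)
  scored <- scored_cohort(cfg)
  scored$linear_outcome <- 3 + 0.25 * scored$ibase_country
  # base R warns about the (intentional) perfect fit
  est <- suppressWarnings(fit_linear(scored, "linear_outcome", "ibase_country",
                                     covariates = character(0)))
  expect_equal(est$coefficient, 0.25, tolerance = 1e-10)
  expect_lt(est$se, 1e-8)

  # slope equals the Pearson-based slope when no covariates enter
  set.seed(431)
  scored$noisy <- 0.1 * scored$vmls_popular + stats::rnorm(nrow(scored))
  est2 <- fit_linear(scored, "noisy", "vmls_popular",
                     covariates = character(0))
  r <- stats::cor(scored$noisy, scored$vmls_popular)
  expect_equal(est2$coefficient,
               r * stats::sd(scored$noisy) / stats::sd(scored$vmls_popular),
               tolerance = 1e-10)

  # injected adversity shift per mindset point
  big <- scored_cohort(cohort_config(n_respondents = 20000, seed = 44))
  set.seed(441)
  big$synthetic_ace <- 2 + 0.07 * big$vmls_hiphop + stats::rnorm(nrow(big), 0, 2)
  est3 <- fit_linear(big, "synthetic_ace", "vmls_hiphop")
  expect_lt(abs(est3$coefficient - 0.07), 0.02)

  scored$dup <- scored$vmls_popular
  expect_error(fit_linear(scored, "noisy", c("vmls_popular", "dup"),
                          covariates = character(0)), "collinear")
})

test_that("null effects stay null", {
  scored <- scored_cohort(null_config(5000, seed = 45))
  est <- fit_logistic(scored, "use_vape", "vmls_hiphop")
  expect_true(est$aor > 0.97 && est$aor < 1.03)
  est_lin <- fit_linear(scored, "ace", "ibase_popular")
  expect_lt(abs(est_lin$coefficient), 3 * est_lin$se)
})

test_that("the battery produces 110 unique cells and flags failures", {
  scored <- scored_cohort(cohort_config(n_respondents = 800, seed = 46))
  battery <- run_prediction_battery(scored)
  expect_equal(nrow(battery), 110)
  key <- paste(battery$instrument, battery$crowd, battery$outcome)
  expect_equal(anyDuplicated(key), 0)
  expect_true(all(battery$aor[battery$family == "binary" & !battery$failed] > 0))
  expect_true(all(is.na(battery$aor[battery$family == "continuous"])))

  # a degenerate outcome is flagged, not fatal
  broken <- scored
  broken$use_smokeless <- 0
  battery2 <- run_prediction_battery(broken)
  failed <- battery2[battery2$outcome == "use_smokeless", ]
  expect_true(all(failed$failed))
  expect_match(failed$error[1], "one class")
  expect_equal(nrow(battery2), 110)

  wide <- format_battery_table(battery2)
  expect_equal(nrow(wide), 11)
  expect_true(any(wide[wide$outcome == "use_smokeless", -1] == "FAILED"))
})

test_that("significant battery cells agree in sign with the induced effects", {
  cfg <- fid_config(20000, 0.8, seed = 47)
  cohort <- generate_cohort(cfg)
  scored <- score_cohort(cohort, cfg$grid_spec)
  battery <- run_prediction_battery(scored)
  crowds <- peer_crowds()
  latent_idx <- match(cohort$latent_crowd, crowds)

  # induced association oracle: sign of cov(score, injected linear predictor)
  induced_sign <- function(instrument, crowd, outcome) {
    score <- scored[[paste0(instrument, "_", tolower(crowd))]]
    eta <- if (outcome %in% c("ace", "brs", "spi", "bsss")) {
      if (outcome == "ace") {
        rowSums(cfg$ace_prob)[latent_idx]
      } else {
        cfg$trait_means[[outcome]][latent_idx]
      }
    } else {
      bname <- sub("^use_", "", outcome)
      cfg$behavior_crowd_logodds[latent_idx, bname]
    }
    if (stats::sd(eta) == 0) return(NA)
    sign(stats::cov(score, eta))
  }

  sig <- battery[!battery$failed & battery$p < 0.05, ]
  expected <- mapply(induced_sign, sig$instrument, sig$crowd, sig$outcome)
  keep <- !is.na(expected)
  agreement <- mean(sign(sig$coefficient[keep]) == expected[keep])
  expect_gte(agreement, 0.95)
})
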