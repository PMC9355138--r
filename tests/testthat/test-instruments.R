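test_that("mindset scoring follows the published point rule", {
  s <- score_vmls(rep("HipHop", 7), rep("Country", 7))
  expect_equal(unname(s[c("HipHop", "Country")]), c(14, 7))
  expect_equal(unname(s[c("Alternative", "Mainstream", "Popular")]), rep(0, 3))

  # half-point rank-2 weight for the desirability-prone crowds
  s2 <- score_vmls(rep("Popular", 7), rep("Alternative", 7))
  expect_equal(unname(s2[["Alternative"]]), 3.5)
  expect_equal(unname(s2[["Popular"]]), 14)

  s3 <- score_vmls(c(rep("Country", 4), rep("Mainstream", 3)),
                   c(rep("Mainstream", 4), rep("Country", 3)))
  expect_equal(unname(s3[["Country"]]), 11)
  expect_equal(unname(s3[["Mainstream"]]), 8)
  expect_equal(sum(s3), 19)
})

test_that("mindset scoring validates its input per question", {
  expect_error(score_vmls(rep("HipHop", 6), rep("Country", 6)), "7")
  r1 <- rep("HipHop", 7); r2 <- rep("Country", 7)
  r2[4] <- "HipHop"
  expect_error(score_vmls(r1, r2), "question 4")
  r2[4] <- "Nope"
  expect_error(score_vmls(r1, r2), "question 4")
})

test_that("exhaustive enumeration over 2-question patterns matches the scorer", {
  crowds <- peer_crowds()
  pairs <- expand.grid(r1 = crowds, r2 = crowds, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$r1 != pairs$r2, ]
  pad_r1 <- c("Country", "HipHop", "Popular", "Alternative", "Mainstream")
  pad_r2 <- c("HipHop", "Country", "Mainstream", "Popular", "Country")
  grid <- two_question_patterns()
  for (i in seq_len(nrow(grid))) {
    r1 <- c(pairs$r1[grid$q1[i]], pairs$r1[grid$q2[i]], pad_r1)
    r2 <- c(pairs$r2[grid$q1[i]], pairs$r2[grid$q2[i]], pad_r2)
    expect_equal(score_vmls(r1, r2), oracle_vmls(r1, r2),
                 ignore_attr = TRUE)
  }
})

test_that("mindset score bounds and the per-respondent total hold on random input", {
  set.seed(11)
  cfg <- cohort_config(n_respondents = 500, seed = 11)
  cohort <- generate_cohort(cfg)
  scored <- score_cohort(cohort, cfg$grid_spec)
  vm <- as.matrix(scored[paste0("vmls_", tolower(peer_crowds()))])
  expect_true(all(vm >= 0 & vm <= 14))
  expect_true(all(vm * 2 == round(vm * 2)))  # 0.5 granularity, never rounded
  # total = 14 + sum of rank-2 weights, computable exactly from the choices
  w <- vmls_rank2_weights()
  r2 <- as.matrix(cohort[sprintf("vmls_q%d_rank2", 1:7)])
  expected_total <- 14 + rowSums(matrix(w[r2], nrow = nrow(cohort)))
  expect_equal(unname(rowSums(vm)), unname(expected_total))
  expect_true(all(expected_total >= 17.5 & expected_total <= 21))
})

test_that("photo-grid scoring earns signed points and hits the stated range", {
  grid3 <- default_grid_spec(photos_per_crowd = 3)
  own <- grid3$photo_id[grid3$crowd == "Country"]
  other <- grid3$photo_id[grid3$crowd == "Popular"]
  s <- score_ibase(best = own, least = other, grid_spec = grid3)
  expect_equal(unname(s[["Country"]]), 12)
  expect_equal(unname(s[["Popular"]]), -12)
  expect_equal(unname(s[["HipHop"]]), 0)  # never selected

  expect_error(score_ibase(c(own[-1], "mystery"), other, grid_spec = grid3),
               "unknown photo id")
  expect_error(score_ibase(own, c(own[1], other[-1]), grid_spec = grid3),
               "overlap")

  # equal +/- magnitudes: per-respondent scores sum to zero
  set.seed(12)
  cfg <- cohort_config(n_respondents = 400, seed = 12)
  scored <- scored_cohort(cfg)
  ib <- as.matrix(scored[paste0("ibase_", tolower(peer_crowds()))])
  expect_true(all(rowSums(ib) == 0))
  expect_true(all(ib >= -12 & ib <= 12))
  expect_true(all(ib %% 2 == 0))
})

test_that("primary crowd assignment takes the unique argmax else Tied", {
  crowds <- peer_crowds()
  expect_equal(assign_primary_crowd(stats::setNames(c(14, 0, 0, 0, 0), crowds)),
               "Alternative")
  expect_equal(assign_primary_crowd(stats::setNames(c(7, 7, 0, 0, 0), crowds)),
               "Tied")
  expect_equal(assign_primary_crowd(stats::setNames(rep(0, 5), crowds)),
               "Tied")
})

test_that("auxiliary scales score to their published ranges", {
  expect_equal(score_ace(rep(0, 9)), 0)
  expect_equal(score_ace(rep(1, 9)), 9)
  expect_equal(score_ace(c(1, 1, 0, 1, 0, 0, 0, 0, 1)), 4)

  expect_equal(score_brs(c(5, 1, 5, 1, 5, 1)), 5)
  expect_equal(score_brs(c(1, 5, 1, 5, 1, 5)), 1)
  expect_equal(score_brs(rep(3, 6)), 3)

  expect_equal(score_spi(rep(5, 8)), 10)
  expect_equal(score_spi(rep(1, 8)), 0)
  expect_equal(score_spi(rep(3, 8)), 5)

  expect_equal(score_bsss(rep(5, 8)), 5)
  expect_equal(score_bsss(rep(1, 8)), 1)
  expect_equal(score_bsss(c(1, 2, 3, 4, 5, 5, 4, 3)), 3.375)

  expect_error(score_brs(c(0, 1, 1, 1, 1, 1)), "BRS")
  expect_error(score_ace(rep(1, 8)), "9 items")

  expect_equal(dichotomize_behavior(c(0, 1, 30)), c(0L, 1L, 1L))
  expect_error(dichotomize_behavior(-1), "0, 30")
  expect_error(dichotomize_behavior(31), "0, 30")
})

test_that("cohort-level scoring agrees with per-respondent scoring", {
  cfg <- cohort_config(n_respondents = 25, seed = 13)
  cohort <- generate_cohort(cfg)
  scored <- score_cohort(cohort, cfg$grid_spec)
  grids <- sort(unique(cfg$grid_spec$grid))
  for (i in c(1, 10, 25)) {
    r1 <- unlist(cohort[i, sprintf("vmls_q%d_rank1", 1:7)])
    r2 <- unlist(cohort[i, sprintf("vmls_q%d_rank2", 1:7)])
    expect_equal(
      as.numeric(scored[i, paste0("vmls_", tolower(peer_crowds()))]),
      as.numeric(score_vmls(r1, r2)))
    best <- unlist(lapply(grids, function(g)
      cohort[i, sprintf("ibase_g%d_best%d", g, 1:3)]))
    least <- unlist(lapply(grids, function(g)
      cohort[i, sprintf("ibase_g%d_least%d", g, 1:3)]))
    expect_equal(
      as.numeric(scored[i, paste0("ibase_", tolower(peer_crowds()))]),
      as.numeric(score_ibase(best, least, cfg$grid_spec)))
  }
})
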