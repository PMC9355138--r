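make_matrix <- function(r, p, omega = rep(0.7, 10)) {
  peercrowds:::new_mtmm_matrix(r, p, omega)
}

test_that("pearson_with_p matches hand computation and the t reference", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_with_p(x, x)$r, 1)
  expect_equal(pearson_with_p(x, x)$p, 0)
  expect_equal(pearson_with_p(x, -x)$r, -1)

  est <- pearson_with_p(x, c(2, 1, 4, 3))
  expect_equal(est$r, 0.6)
  ref <- stats::cor.test(x, c(2, 1, 4, 3))
  expect_equal(est$p, ref$p.value)

  set.seed(31)
  a <- stats::rnorm(60); b <- 0.4 * a + stats::rnorm(60)
  est2 <- pearson_with_p(a, b)
  ref2 <- stats::cor.test(a, b)
  expect_equal(est2$r, unname(ref2$estimate))
  expect_equal(est2$p, ref2$p.value)

  expect_error(pearson_with_p(x, rep(1, 4)), "zero variance")
  expect_error(pearson_with_p(x, c(1, 2)), "equal length")
  expect_error(pearson_with_p(c(1, 2), c(3, 4)), "3 observations")
})

test_that("the MTMM is symmetric with omega on the diagonal", {
  cfg <- cohort_config(n_respondents = 300, seed = 32)
  cohort <- generate_cohort(cfg)
  scored <- score_cohort(cohort, cfg$grid_spec)
  rel <- reliability_table(cohort, cfg$grid_spec)
  m <- build_mtmm(scored, rel)
  expect_true(isSymmetric(m$correlations))
  expect_equal(unname(diag(m$correlations)), rel$omega)
  expect_true(all(abs(m$correlations[upper.tri(m$correlations)]) <= 1))

  # duplicated scores give perfect convergent cells
  dup <- scored
  for (crowd in tolower(peer_crowds())) {
    dup[[paste0("ibase_", crowd)]] <- dup[[paste0("vmls_", crowd)]]
  }
  m_dup <- build_mtmm(dup, rel)
  for (crowd in peer_crowds()) {
    expect_equal(m_dup$correlations[paste0("IBase.", crowd),
                                    paste0("VMLS.", crowd)], 1)
  }

  expect_error(build_mtmm(scored[1:2, ], rel), "insufficient")
})

test_that("independent scores produce a null matrix", {
  set.seed(33)
  n <- 5000
  scored <- as.data.frame(matrix(stats::rnorm(n * 10), ncol = 10))
  names(scored) <- c(paste0("ibase_", tolower(peer_crowds())),
                     paste0("vmls_", tolower(peer_crowds())))
  m <- build_mtmm(scored, rep(NA_real_, 10))
  expect_lt(max(abs(m$correlations[upper.tri(m$correlations)])), 0.05)
})

test_that("the printed matrix fixture reproduces the published verdict", {
  m <- mtmm_table3_fixture()
  expect_true(isSymmetric(m$correlations))
  report <- evaluate_validity(m, alpha = 0.05)
  expect_equal(report$n_convergent_pass, 5)
  expect_true(all(report$convergent$pass))
  expect_equal(min(report$convergent$r), 0.17)
  expect_equal(max(report$convergent$r), 0.55)
  expect_equal(report$n_violations, 1)
  expect_equal(report$violations$cell_row, "VMLS.Popular")
  expect_equal(report$violations$cell_col, "IBase.HipHop")
  expect_equal(report$violations$r, 0.18)
  expect_match(report$violations$fails_against, "HipHop")
})

test_that("validity decision rules follow the stated logic", {
  crowds <- peer_crowds()
  r <- matrix(0, 10, 10)
  p <- matrix(0.8, 10, 10)
  for (i in 1:5) {
    r[i, i + 5] <- r[i + 5, i] <- 0.9
    p[i, i + 5] <- p[i + 5, i] <- 1e-6
  }
  clean <- evaluate_validity(make_matrix(r, p))
  expect_equal(clean$n_convergent_pass, 5)
  expect_equal(clean$n_violations, 0)

  # a negative convergent cell fails that crowd
  r_neg <- r; r_neg[2, 7] <- r_neg[7, 2] <- -0.4
  neg <- evaluate_validity(make_matrix(r_neg, p))
  expect_equal(neg$n_convergent_pass, 4)
  expect_false(neg$convergent$pass[neg$convergent$crowd == "Country"])

  # significant positive heterotrait cell >= a convergent coefficient
  r_v <- r; p_v <- p
  r_v[1, 2] <- r_v[2, 1] <- 0.95
  p_v[1, 2] <- p_v[2, 1] <- 1e-6
  viol <- evaluate_validity(make_matrix(r_v, p_v))
  expect_equal(viol$n_violations, 1)
  # significant but negative heterotrait cells are fine
  r_n <- r; p_n <- p
  r_n[1, 3] <- r_n[3, 1] <- -0.95
  p_n[1, 3] <- p_n[3, 1] <- 1e-6
  expect_equal(evaluate_validity(make_matrix(r_n, p_n))$n_violations, 0)
})

test_that("the report is invariant to simultaneous crowd relabeling", {
  cfg <- fid_config(800, 0.6, seed = 34)
  scored <- scored_cohort(cfg)
  rel <- reliability_table(generate_cohort(cfg), cfg$grid_spec)
  base <- evaluate_validity(build_mtmm(scored, rel))

  # swap Country and Popular in both instruments (scores and omegas)
  swapped <- scored
  for (instr in c("ibase_", "vmls_")) {
    tmp <- swapped[[paste0(instr, "country")]]
    swapped[[paste0(instr, "country")]] <- swapped[[paste0(instr, "popular")]]
    swapped[[paste0(instr, "popular")]] <- tmp
  }
  rel_sw <- rel
  for (instr in c("ibase", "vmls")) {
    i <- which(rel_sw$instrument == instr & rel_sw$crowd == "Country")
    j <- which(rel_sw$instrument == instr & rel_sw$crowd == "Popular")
    rel_sw$omega[c(i, j)] <- rel_sw$omega[c(j, i)]
  }
  sw <- evaluate_validity(build_mtmm(swapped, rel_sw))
  expect_equal(sw$n_convergent_pass, base$n_convergent_pass)
  expect_equal(sw$n_violations, base$n_violations)
  relabel <- function(x) {
    x <- gsub("Country", "@tmp@", x)
    x <- gsub("Popular", "Country", x)
    gsub("@tmp@", "Popular", x)
  }
  expect_setequal(paste(relabel(sw$violations$cell_row),
                        relabel(sw$violations$cell_col)),
                  paste(base$violations$cell_row, base$violations$cell_col))
})

test_that("MTMM CSV round-trips", {
  cfg <- cohort_config(n_respondents = 200, seed = 35)
  cohort <- generate_cohort(cfg)
  m <- build_mtmm(score_cohort(cohort, cfg$grid_spec),
                  reliability_table(cohort, cfg$grid_spec))
  path <- tempfile(fileext = ".csv")
  write_mtmm_csv(m, path)
  back <- read_mtmm_csv(path)
  expect_equal(back$correlations, m$correlations, tolerance = 1e-12)
  expect_equal(back$p_values[upper.tri(back$p_values)],
               m$p_values[upper.tri(m$p_values)], tolerance = 1e-12)
})
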