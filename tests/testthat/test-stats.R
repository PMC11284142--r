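test_that("summaries compute the full row and gate the display on normality", {
  s <- summarize_angles(c(1, 2, 3), "toy")
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_equal(s$sd, 1)
  expect_equal(c(s$min, s$max), c(1, 3))
  expect_equal(s$missing, 0)

  # a large normal sample takes the mean +/- SD display
  set.seed(7)
  s <- summarize_angles(rnorm(200, 17.2, 16.9), "TA")
  expect_gt(s$shapiro_p, 0.05)
  expect_identical(s$display, "mean_sd")

  # a strongly skewed sample takes the median [range] display
  set.seed(7)
  s <- summarize_angles(exp(rnorm(200)), "skewed")
  expect_lt(s$shapiro_p, 0.05)
  expect_identical(s$display, "median_range")

  s <- summarize_angles(rep(4, 10), "const")
  expect_equal(s$sd, 0)
  expect_identical(s$display, "degenerate")
  expect_error(summarize_angles(c(1, 2), "short"), ">= 3")

  # permutation invariance and shift equivariance
  v <- rnorm(50)
  s1 <- summarize_angles(v, "v")
  s2 <- summarize_angles(sample(v), "v")
  expect_equal(s1[c("mean", "median", "sd", "min", "max")],
               s2[c("mean", "median", "sd", "min", "max")])
  s3 <- summarize_angles(v + 5, "v")
  expect_equal(s3$mean, s1$mean + 5)
  expect_equal(s3$sd, s1$sd)
})

test_that("summary table covers the four methods in order", {
  sp <- cohort_spec(n_subjects = 10, raters = 1, sessions = 1, seed = 2)
  rec <- measure_cohort(simulate_cohort(sp)$landmarks)$records
  tab <- angle_summary_table(rec)
  expect_identical(tab$method, c("PTTA", "PMTPA", "IMA", "TA"))
  expect_true(all(tab$min <= tab$median & tab$median <= tab$max))
  expect_error(angle_summary_table(rec[, -3]), "missing method column")
})

test_that("paired comparison branches on the normality of differences", {
  x <- c(1, 2, 3, 4, 5)
  same <- paired_compare(x, x)
  expect_identical(same$test_name, "degenerate")
  expect_equal(same$mean_difference, 0)
  expect_true(is.na(same$statistic))

  set.seed(11)
  a <- rnorm(40); b <- a + rnorm(40, 0.5, 0.3)
  res <- paired_compare(a, b)
  expect_identical(res$test_name, "paired-t")
  expect_equal(res$mean_difference, mean(a - b))
  expect_lt(res$p_value, 0.01)

  # heavy-tailed differences force the signed-rank branch
  set.seed(12)
  d <- rexp(60)^2 * sample(c(-1, 1), 60, TRUE)
  res <- paired_compare(d, rep(0, 60))
  expect_identical(res$test_name, "wilcoxon-signed-rank")
  expect_lt(res$normality_p, 0.05)

  expect_error(paired_compare(1:5, 1:4), "equal length")
})

test_that("Pearson correlation matches the product-moment formula with Fisher-z CI", {
  expect_equal(pearson_with_ci(1:10, 2 * (1:10) + 3)$r, 1)

  a <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  b <- c(2.0, 3.1, 2.9, 6.2, 3.5)
  # direct product-moment formula as an independent oracle
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  res <- pearson_with_ci(a, b)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_true(res$ci_low <= res$r && res$r <= res$ci_high)

  ci <- fisher_z_ci(0.95, 200)
  expect_equal(ci, c(0.9342, 0.9621), tolerance = 1e-3)

  # CI shrinks monotonically with n at fixed r
  widths <- vapply(c(20, 50, 100, 500), function(n) diff(fisher_z_ci(0.8, n)),
                   numeric(1))
  expect_true(all(diff(widths) < 0))

  expect_error(pearson_with_ci(rep(1, 5), 1:5), "zero variance")
})

test_that("Fisher-z interval covers the true correlation at its nominal rate", {
  set.seed(13)
  rho <- 0.6
  n <- 30
  hits <- 0L
  for (i in 1:1000) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- fisher_z_ci(cor(x, y), n)
    if (ci[1] <= rho && rho <= ci[2]) hits <- hits + 1L
  }
  expect_gt(hits / 1000, 0.93)
  expect_lt(hits / 1000, 0.97)
})

test_that("ICC matches the two-way ANOVA oracle and orders agreement below consistency", {
  # identical columns: perfect reliability
  m <- cbind(1:6, 1:6)
  res <- icc(m)
  expect_equal(res$estimate, 1)
  expect_identical(res$band, "excellent")

  # constant +2 rater offset: absolute agreement penalized, consistency not
  m <- cbind(c(3, 5, 9, 2, 7, 6), c(3, 5, 9, 2, 7, 6) + 2)
  abs1 <- icc(m, "two-way-random-absolute")
  con1 <- icc(m, "two-way-mixed-consistency")
  expect_lt(abs1$estimate, con1$estimate)
  expect_equal(con1$estimate, 1)
  expect_equal(abs1$estimate, oracle_icc(m, "two-way-random-absolute"),
               tolerance = 1e-9)

  # property sweep: random matrices up to 8 x 3 against the aov oracle
  set.seed(14)
  for (i in 1:40) {
    n <- sample(5:8, 1); k <- sample(2:3, 1)
    subj <- rnorm(n, sd = 3)
    m <- outer(subj, rep(1, k)) + outer(rep(1, n), rnorm(k)) +
      matrix(rnorm(n * k), n, k)
    for (mod in c("two-way-random-absolute", "two-way-mixed-consistency")) {
      expect_equal(icc(m, mod)$estimate, oracle_icc(m, mod), tolerance = 1e-9)
    }
  }

  expect_error(icc(cbind(1:4, 4:1)), ">= 5 subjects")
  expect_error(icc(cbind(c(1, NA, 3, 4, 5), 1:5)), "missing cells")
})

test_that("reliability bands follow the stated cut-points", {
  expect_identical(icc_band(c(0.2, 0.5, 0.6, 0.75, 0.8, 0.9, 0.95)),
                   c("poor", "moderate", "moderate", "moderate", "good",
                     "good", "excellent"))
})

test_that("reliability designs behave on simulated cohorts", {
  # noise-free cohort: every ICC is exactly 1
  sp0 <- cohort_spec(n_subjects = 15, rater_noise_sd = 0, seed = 15)
  co0 <- simulate_cohort(sp0)
  rel0 <- reliability_study(co0, "intra", n_images = 10, seed = 15)
  for (m in c("PTTA", "PMTPA", "IMA", "TA")) {
    expect_equal(rel0[[m]]$estimate, 1, tolerance = 1e-9)
    expect_identical(rel0[[m]]$band, "excellent")
  }

  # default noise: excellent reliability; doubling the noise lowers it
  sp1 <- cohort_spec(n_subjects = 15, rater_noise_sd = 0.5, seed = 13)
  sp2 <- cohort_spec(n_subjects = 15, rater_noise_sd = 1.0, seed = 13)
  rel1 <- reliability_study(simulate_cohort(sp1), "intra", n_images = 12, seed = 13)
  rel2 <- reliability_study(simulate_cohort(sp2), "intra", n_images = 12, seed = 13)
  expect_gt(rel1$PTTA$estimate, 0.9)
  for (m in c("PTTA", "PMTPA", "IMA", "TA")) {
    expect_lt(rel2[[m]]$estimate, rel1[[m]]$estimate)
  }

  # designs unsupported by the cohort are configuration errors
  one_rater <- simulate_cohort(cohort_spec(n_subjects = 6, raters = 1, seed = 1))
  expect_error(reliability_study(one_rater, "inter"), "raters")
  one_session <- simulate_cohort(cohort_spec(n_subjects = 6, sessions = 1, seed = 1))
  expect_error(reliability_study(one_session, "intra"), "sessions")

  # records-based route agrees with the cohort-based route
  co <- simulate_cohort(cohort_spec(n_subjects = 8, seed = 21))
  recs <- do.call(rbind, lapply(1:2, function(r) {
    do.call(rbind, lapply(1:2, function(s) {
      measure_cohort(cohort_replicate(co, r, s))$records
    }))
  }))
  a <- reliability_study(co, "intra", n_images = 10, seed = 5)
  b <- reliability_from_records(recs, "intra", n_images = 10, seed = 5)
  expect_equal(a$PTTA$estimate, b$PTTA$estimate, tolerance = 1e-12)
  expect_equal(a$TA$ci_low, b$TA$ci_low, tolerance = 1e-12)
})
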