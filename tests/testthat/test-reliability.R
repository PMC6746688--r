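make_long <- function(mat, measurement = "NLD", observer = "ObsA") {
  df <- expand.grid(subject_id = sprintf("S%02d", seq_len(nrow(mat))),
                    session = seq_len(ncol(mat)), stringsAsFactors = FALSE)
  df$observer_id <- observer
  df$measurement <- measurement
  df$value_cm <- as.vector(mat)
  df
}

test_that("repeated_measures_table validates structure", {
  m <- make_long(matrix(1:6, 3))
  expect_s3_class(repeated_measures_table(m), "repeated_measures_table")
  expect_error(repeated_measures_table(m[, -5]), "lacks column")
  expect_error(repeated_measures_table(rbind(m, m[1, ])), "duplicate")
  bad <- m; bad$value_cm[1] <- NA
  expect_error(repeated_measures_table(bad), "non-finite")
})

test_that("accuracy_summary recovers MAD and signed-difference SD", {
  mat <- matrix(c(10, 10, 10, 12, 12, 12), nrow = 2, byrow = TRUE)
  m <- make_long(mat)
  refs <- data.frame(subject_id = c("S01", "S02"), measurement = "NLD",
                     reference_cm = c(10, 12))
  acc <- accuracy_summary(repeated_measures_table(m, refs))
  expect_equal(acc$mad_cm, 0)
  expect_equal(acc$sd_cm, 0)

  # differences {+1, -1} per subject: mad 1, signed mean 0
  m2 <- make_long(matrix(c(11, 9, 13, 11), nrow = 2, byrow = TRUE))
  acc2 <- accuracy_summary(repeated_measures_table(m2, refs))
  expect_equal(acc2$mad_cm, 1)

  # brute-force oracle on a random table
  set.seed(4)
  mat3 <- matrix(rnorm(30, 10), 10, 3)
  refs3 <- data.frame(subject_id = sprintf("S%02d", 1:10),
                      measurement = "NLD", reference_cm = rnorm(10, 10))
  acc3 <- accuracy_summary(repeated_measures_table(make_long(mat3), refs3))
  d <- as.vector(mat3 - refs3$reference_cm)  # recycles by subject = row
  expect_equal(acc3$mad_cm, mean(abs(d)))
  expect_equal(acc3$sd_cm, sd(d))
  expect_equal(
    accuracy_summary(repeated_measures_table(make_long(mat3), refs3),
                     sd_of = "absolute")$sd_cm,
    sd(abs(d)))

  expect_error(
    accuracy_summary(repeated_measures_table(make_long(mat3),
                                             refs3[-3, ])),
    "missing reference.*S03")
})

test_that("icc matches the frozen independent oracle on a fixed matrix", {
  m <- oracle_icc_matrix()
  r21 <- icc(m, "two-way-random-absolute")
  r31 <- icc(m, "two-way-mixed-consistency")
  expect_equal(r21$icc, oracle_icc_expected$icc21, tolerance = 1e-9)
  expect_equal(r31$icc, oracle_icc_expected$icc31, tolerance = 1e-9)
  expect_equal(round(c(r21$ci_low, r21$ci_high), 2), oracle_icc_expected$ci21)
  expect_equal(round(c(r31$ci_low, r31$ci_high), 2), oracle_icc_expected$ci31)
  expect_equal(r21$msr, oracle_icc_expected$msr, tolerance = 1e-9)
  expect_equal(r21$msc, oracle_icc_expected$msc, tolerance = 1e-9)
  expect_equal(r21$mse, oracle_icc_expected$mse, tolerance = 1e-9)
})

test_that("icc handles degenerate and invalid designs", {
  expect_equal(icc(matrix(c(1, 1, 2, 2, 3, 3), 3, 2, byrow = TRUE))$icc, 1)
  expect_error(icc(matrix(1:4, 1)), "at least 2 subjects")
  expect_error(icc(matrix(1:4, 4, 1)), "at least 2 raters")
  expect_error(icc(matrix(5, 3, 2)), "zero total variance")
  xm <- matrix(rnorm(6), 3); xm[1, 1] <- NA
  expect_error(icc(xm), "incomplete design")
})

test_that("icc recovers the variance-component truth in simulation", {
  # subject variance 9, error variance 1 -> population ICC 0.9
  set.seed(2024)
  n <- 200; k <- 3
  est <- icc(matrix(rnorm(n, 0, 3), n, k) + matrix(rnorm(n * k), n, k))
  expect_gt(est$icc, 0.87)
  expect_lt(est$icc, 0.93)
  expect_gte(0.9, est$ci_low * 0.999)
  expect_lte(0.9, est$ci_high * 1.001)
})

test_that("icc is shift invariant and scale equivariant", {
  set.seed(15)
  m <- matrix(rnorm(24, 10, 2), 8, 3)
  base <- icc(m)
  shifted <- icc(m + 100)
  scaled <- icc(m * 7)
  expect_equal(shifted$icc, base$icc, tolerance = 1e-9)
  expect_equal(scaled$icc, base$icc, tolerance = 1e-9)
  expect_equal(shifted$ci_low, base$ci_low, tolerance = 1e-9)
})

test_that("icc accepts long-format input", {
  m <- oracle_icc_matrix()
  expect_equal(icc(make_long(m))$icc, icc(m)$icc, tolerance = 1e-12)
})

test_that("sem_cm reproduces the published SEM cells and edge cases", {
  # printed (SD, ICC, SEM) per-observer cells; every cell agrees to the
  # printed precision (one source cell, female-A UPLD, was printed from
  # unrounded inputs and recomputes to 0.44 vs printed 0.45)
  pub <- published_validation_tables("per_observer")
  expect_true(all(abs(round(sem_cm(pub$sd_cm, pub$icc), 2) - pub$sem_cm)
                  <= 0.01 + 1e-12))
  expect_equal(sem_cm(5, 1), 0)
  expect_error(sem_cm(1, 1.2), "at most 1")
  expect_error(sem_cm(-1, 0.5), "non-negative")
  # SEM <= SD whenever 0 <= icc <= 1
  set.seed(1)
  sds <- runif(50, 0, 3); iccs <- runif(50)
  expect_true(all(sem_cm(sds, iccs) <= sds))
})

test_that("cv_percent averages per-subject CVs", {
  expect_equal(cv_percent(matrix(10, 3, 3)), 0)
  expect_equal(cv_percent(matrix(c(9, 10, 11), 1, 3)), 10)
  set.seed(6)
  m <- matrix(rnorm(40, 20, 2), 10, 4)
  brute <- mean(apply(m, 1, function(v) 100 * sd(v) / mean(v)))
  expect_equal(cv_percent(m), brute, tolerance = 1e-12)
  pooled <- sqrt(mean(apply(m, 1, function(v) (100 * sd(v) / mean(v))^2)))
  expect_equal(cv_percent(m, aggregate = "pooled"), pooled, tolerance = 1e-12)
  zm <- matrix(c(1, -1, 0, 2, 2, 2), 2, 3, byrow = TRUE)
  expect_error(cv_percent(zm), "zero mean")
})

test_that("bland_altman bias, limits and antisymmetry", {
  ref <- c(10, 12, 14, 16)
  ba <- bland_altman(ref, ref + 0.5)       # constant difference
  expect_equal(ba$bias, 0.5)
  expect_equal(ba$loa_low, 0.5)
  expect_equal(ba$loa_high, 0.5)
  expect_error(bland_altman(1, 1), "at least 2")
  expect_error(bland_altman(1:3, 1:4), "length")

  set.seed(9)
  dig <- ref + rnorm(4)
  fwd <- bland_altman(ref, dig)
  rev <- bland_altman(dig, ref)
  expect_equal(rev$bias, -fwd$bias)
  expect_equal(rev$loa_low, -fwd$loa_high)
  expect_equal(rev$loa_high, -fwd$loa_low)
  expect_lte(fwd$loa_low, fwd$bias)
  expect_gte(fwd$loa_high, fwd$bias)
})

test_that("effectiveness counts MADs below the 1 cm demarcation", {
  expect_equal(effectiveness(c(0.5, 1.5)), 50)
  expect_equal(effectiveness(c(0.1, 0.2, 0.3)), 100)
  expect_error(effectiveness(numeric(0)), "empty")
  set.seed(10)
  mads <- runif(40, 0, 2)
  expect_equal(effectiveness(mads, 0.8), 100 * sum(mads < 0.8) / 40)
})

test_that("classify_icc applies both interpretation scales", {
  expect_equal(classify_icc(0.50), list(cicchetti = "fair",
                                        clinical = "poor-to-moderate"))
  expect_equal(classify_icc(0.90), list(cicchetti = "excellent",
                                        clinical = "clinical"))
  expect_equal(classify_icc(0.75), list(cicchetti = "excellent",
                                        clinical = "good"))
  expect_equal(classify_icc(0.40)$cicchetti, "fair")
  expect_equal(classify_icc(0.60)$cicchetti, "good")
  expect_equal(classify_icc(0.87)$clinical, "clinical")
  expect_equal(classify_icc(0.10)$cicchetti, "poor")
  expect_error(classify_icc(1.2), "\\[-1, 1\\]")
})

test_that("icc_variance matches the published between-measurement spreads", {
  inter <- published_validation_tables("inter_rater")
  fem <- inter$icc[inter$group == "female"]
  mal <- inter$icc[inter$group == "male"]
  expect_length(fem, 13)
  expect_equal(round(icc_variance(fem), 5), 0.00290)
  expect_equal(round(icc_variance(mal), 7), 0.0003465)
  expect_equal(icc_variance(rep(0.9, 5)), 0)
  expect_error(icc_variance(0.9), "at least 2")
})

test_that("summary_tables: zero noise gives perfect agreement throughout", {
  study <- batch_study(n_subjects = 4, jitter_sd_px = 0, bias_sd_px = 0,
                       master_seed = 5)
  summ <- summary_tables(study)
  expect_equal(nrow(summ$per_observer), 13 * 2)
  expect_equal(nrow(summ$inter_rater), 13)
  expect_true(all(abs(summ$per_observer$icc - 1) < 1e-9))
  # icc = 1 - O(eps) makes sem sd * sqrt(eps); 1e-6 cm is far below the
  # 2-decimal table resolution
  expect_true(all(summ$per_observer$sem_cm < 1e-6))
  expect_true(all(summ$per_observer$mad_cm < 1e-9))
  expect_true(all(abs(summ$inter_rater$icc - 1) < 1e-9))
  expect_true(all(summ$inter_rater$cv_percent < 1e-9))
})

test_that("summary_tables rounding matches the published formats", {
  study <- batch_study(n_subjects = 4, master_seed = 8)
  summ <- summary_tables(study, round_output = TRUE)
  expect_true(all(summ$per_observer$icc == round(summ$per_observer$icc, 3)))
  expect_true(all(summ$per_observer$sem_cm ==
                    round(summ$per_observer$sem_cm, 2)))
  expect_true(all(summ$inter_rater$cv_percent ==
                    round(summ$inter_rater$cv_percent, 1)))
})
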