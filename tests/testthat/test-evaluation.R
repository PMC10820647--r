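test_that("alignment pairs estimates with their nearest truth samples", {
  est <- data.frame(timestamp_s = seq(0, 0.9, 0.1), theta_deg = 1:10)
  truth <- data.frame(timestamp_s = seq(0, 0.9, 0.1), angle_deg = 11:20)
  p <- align_series(est, truth)
  expect_equal(nrow(p), 10L)
  expect_equal(p$truth_deg, 11:20)

  # truth at twice the rate: nearest sample verified exhaustively
  truth2 <- data.frame(timestamp_s = seq(0, 0.95, 0.05), angle_deg = 1:20)
  p2 <- align_series(est, truth2)
  for (i in seq_len(nrow(p2))) {
    d <- abs(truth2$timestamp_s - p2$timestamp_s[i])
    expect_equal(p2$truth_deg[i], truth2$angle_deg[which.min(d)])
  }

  # disjoint ranges fail; out-of-gap estimates are dropped and counted
  far <- data.frame(timestamp_s = 100 + est$timestamp_s, angle_deg = 1:10)
  expect_error(align_series(est, far), "overlap")
  gap <- data.frame(timestamp_s = c(0, 0.1, 0.9), theta_deg = c(1, 2, 3))
  short <- data.frame(timestamp_s = c(0, 0.1), angle_deg = c(5, 6))
  pg <- align_series(gap, short)
  expect_equal(nrow(pg), 2L)
  expect_equal(attr(pg, "n_dropped"), 1L)
})

test_that("metrics hit their closed forms for perfect and bias-only fits", {
  truth <- c(10, 30, 50, 70)
  perfect <- compute_metrics(data.frame(estimate_deg = truth,
                                        truth_deg = truth))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$nrmse, 0)
  expect_equal(perfect$r_squared, 1)

  biased <- compute_metrics(data.frame(estimate_deg = truth + 2,
                                       truth_deg = truth))
  expect_equal(biased$mae, 2)
  expect_equal(biased$rmse, 2)
  expect_equal(biased$std, 0)
})

test_that("metrics match independent formula evaluations on random series", {
  set.seed(55)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    truth <- runif(n, 5, 170)
    est <- truth + rnorm(n, 0, 4)
    got <- compute_metrics(data.frame(estimate_deg = est, truth_deg = truth))
    ref <- oracle_metrics(est, truth)
    for (m in names(ref)) expect_lt(abs(got[[m]] - ref[[m]]), 1e-9)
    expect_lte(got$mae, got$rmse + 1e-12)
    # reordering the pairs changes nothing
    perm <- sample.int(n)
    got2 <- compute_metrics(data.frame(estimate_deg = est[perm],
                                       truth_deg = truth[perm]))
    expect_equal(got, got2)
  }
})

test_that("degenerate truth series degrade to NA, not errors", {
  const <- compute_metrics(data.frame(estimate_deg = c(1, 2), truth_deg = c(5, 5)))
  expect_true(is.na(const$nrmse))
  expect_true(is.na(const$r_squared))
  zero <- compute_metrics(data.frame(estimate_deg = c(1, 2, 3),
                                     truth_deg = c(0, 10, 20)))
  expect_equal(zero$mape_excluded, 1L)
  expect_equal(zero$mape, 100 * mean(c(abs(2 - 10) / 10, abs(3 - 20) / 20)))
  expect_error(compute_metrics(data.frame(estimate_deg = 1, truth_deg = 1)),
               "at least 2")
})

test_that("run summaries aggregate duplicate conditions with counts", {
  m <- compute_metrics(data.frame(estimate_deg = c(1, 2, 3),
                                  truth_deg = c(2, 2, 2.5)))
  one <- summarize_runs(list(list(exercise = "RA", view = "frontal",
                                  distance = 3, method = "F", metrics = m)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_runs, 1L)

  m2 <- compute_metrics(data.frame(estimate_deg = c(5, 6, 9),
                                   truth_deg = c(4, 7, 8)))
  dup <- summarize_runs(list(
    list(exercise = "RA", view = "frontal", distance = 3, method = "F",
         metrics = m),
    list(exercise = "RA", view = "frontal", distance = 3, method = "F",
         metrics = m2)))
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$n_runs, 2L)
  expect_equal(dup$mae, mean(c(m$mae, m2$mae)))
  expect_error(summarize_runs(list()), "no runs")

  path <- withr::local_tempfile(fileext = ".csv")
  summarize_runs(list(list(exercise = "R7", view = "lateral", distance = 4,
                           method = "S", metrics = m)), path = path)
  expect_true(file.exists(path))
  expect_equal(utils::read.csv(path)$exercise, "R7")
})
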