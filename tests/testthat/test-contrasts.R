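test_that("baseline correction and acute pooling are the stated arithmetic", {
  expect_equal(baseline_correct(1.2, 0.2), 1.0)
  expect_equal(baseline_correct(0.5, 0.5), 0.0)
  expect_equal(pool_acute(1, 2, 3), 2)
  expect_equal(pool_acute(0.7, 0.7, 0.7), 0.7)
  expect_equal(pool_acute(3, 1, 2), pool_acute(1, 2, 3))
  expect_error(baseline_correct(NA, 0), class = "coinet_bad_argument")
  expect_error(pool_acute(1, Inf, 2), class = "coinet_bad_argument")
})

test_that("paired t-test reproduces the hand-computed example", {
  # differences 1,2,3,4: mean 2.5, sd sqrt(5/3), t = 2.5/sqrt(5/12)
  res <- paired_ttest(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(res$t, 2.5 / sqrt((5 / 3) / 4), tolerance = 1e-10)
  expect_equal(res$t, 3.87298, tolerance = 1e-5)
  expect_equal(res$df, 3)
  expect_equal(res$p, 0.0305, tolerance = 1e-2)
})

test_that("paired t-test agrees with stats::t.test on random inputs", {
  withr::local_seed(10)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    ket <- rnorm(n)
    pla <- rnorm(n)
    res <- paired_ttest(ket, pla)
    ref <- t.test(ket, pla, paired = TRUE)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$df, unname(ref$parameter))
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate and malformed pairings are rejected", {
  expect_error(paired_ttest(c(1, 2, 3), c(1, 2, 3)), class = "coinet_degenerate")
  expect_error(paired_ttest(c(1, 2, 3), c(0, 1)), class = "coinet_bad_argument")
  expect_error(paired_ttest(c(1, 2), c(0, 1)), class = "coinet_bad_argument")
})

make_small_conn <- function(seed = 21, n_subjects = 6, effect = NULL) {
  des <- study_design(n_subjects = n_subjects, t_per_scan = 40)
  gt <- make_ground_truth(
    data.frame(region_i = c("A", "B"), region_j = c("B", "C"), r = c(0.3, 0.2)),
    nodes = c("A", "B", "C", "D")
  )
  st <- simulate_study(des, gt, effect = effect, seed = seed)
  connectivity(st)
}

test_that("run_contrasts returns 2 x C(K,2) rows with sane fields", {
  conn <- make_small_conn()
  res <- run_contrasts(conn)
  expect_equal(nrow(res), 2 * choose(4, 2))
  expect_setequal(unique(res$phase), c("acute", "delayed"))
  expect_true(all(res$df == 5))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(is.finite(res$t)))
  expect_true(all(c("mean_ket", "sd_ket", "mean_pla", "sd_pla") %in% names(res)))
  # t is consistent with per-condition summaries via the scalar op
  conn15 <- make_small_conn(seed = 33, n_subjects = 4)
  res15 <- run_contrasts(conn15)
  expect_equal(nrow(res15), 12)
})

test_that("full 15-region study yields 210 connection tests", {
  des <- study_design(n_subjects = 4, t_per_scan = 60)
  st <- simulate_study(des, default_ground_truth(), seed = 2)
  res <- run_contrasts(connectivity(st))
  expect_equal(nrow(res), 210)
})

test_that("swapping treatment labels negates every t and keeps p", {
  conn <- make_small_conn(seed = 5)
  res <- run_contrasts(conn)
  swapped <- conn
  swapped$treatment <- ifelse(conn$treatment == "ketamine", "placebo", "ketamine")
  res_sw <- run_contrasts(swapped)
  ord <- order(res$connection, res$phase)
  ord_sw <- order(res_sw$connection, res_sw$phase)
  expect_equal(res_sw$t[ord_sw], -res$t[ord], tolerance = 1e-12)
  expect_equal(res_sw$p[ord_sw], res$p[ord], tolerance = 1e-12)
})

test_that("adding a constant to all period-1 scans leaves every t unchanged", {
  conn <- make_small_conn(seed = 6)
  res <- run_contrasts(conn)
  shifted <- conn
  shifted$z[shifted$period == 1] <- shifted$z[shifted$period == 1] + 2.5
  res_sh <- run_contrasts(shifted)
  ord <- order(res$connection, res$phase)
  ord_sh <- order(res_sh$connection, res_sh$phase)
  expect_equal(res_sh$t[ord_sh], res$t[ord], tolerance = 1e-10)
})

test_that("matrix t path agrees with the scalar paired test per connection", {
  conn <- make_small_conn(seed = 7)
  res <- run_contrasts(conn)
  # recompute one connection by hand through the scalar API
  pick <- "A--B"
  wide <- tidyr::pivot_wider(
    conn[conn$connection == pick, c("subject", "treatment", "timepoint", "z")],
    names_from = "timepoint", values_from = "z"
  )
  wide$acute <- (wide$post50min + wide$post80min + wide$post165min) / 3 - wide$baseline
  ket <- wide$acute[wide$treatment == "ketamine"][order(wide$subject[wide$treatment == "ketamine"])]
  pla <- wide$acute[wide$treatment == "placebo"][order(wide$subject[wide$treatment == "placebo"])]
  ref <- paired_ttest(ket, pla)
  got <- res[res$connection == pick & res$phase == "acute", ]
  expect_equal(got$t, ref$t, tolerance = 1e-12)
  expect_equal(got$p, ref$p, tolerance = 1e-12)
  expect_equal(got$mean_ket, mean(ket), tolerance = 1e-12)
  expect_equal(got$sd_pla, sd(pla), tolerance = 1e-12)
})

test_that("subjects with missing scans are dropped listwise per phase", {
  conn <- make_small_conn(seed = 8)
  # remove subject 3's ketamine 24-h scan only
  drop_rows <- conn$subject == 3 & conn$treatment == "ketamine" &
    conn$timepoint == "post24h"
  conn2 <- conn[!drop_rows, ]
  expect_message(res <- run_contrasts(conn2), "Dropping subject")
  expect_true(all(res$n[res$phase == "delayed"] == 5))
  expect_true(all(res$n[res$phase == "acute"] == 6))
})
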