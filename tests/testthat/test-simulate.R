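test_that("simulated scans are deterministic under a fixed seed", {
  gt <- default_ground_truth()
  a <- simulate_scan(gt, t_len = 50, seed = 7)
  b <- simulate_scan(gt, t_len = 50, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, simulate_scan(gt, t_len = 50, seed = 8)))
})

test_that("independent two-node truth yields near-zero sample correlation", {
  gt <- make_ground_truth(NULL, nodes = c("A", "B"))
  t_len <- 2000
  ts <- simulate_scan(gt, t_len = t_len, seed = 1)
  expect_lt(abs(cor(ts[, 1], ts[, 2])), 4 / sqrt(t_len))
})

test_that("chain-graph partial correlations are recovered at large T", {
  gt <- chain_gt(0.4, -0.3)
  ts <- simulate_scan(gt, t_len = 10000, seed = 2)
  est <- oracle_partial_correlation(ts)
  expect_lt(abs(est["A", "B"] - gt$partial["A", "B"]), 0.05)
  expect_lt(abs(est["B", "C"] - gt$partial["B", "C"]), 0.05)
  expect_lt(abs(est["A", "C"] - gt$partial["A", "C"]), 0.05)
})

test_that("scan length below K+5 is rejected and effects cannot reach |r|=1", {
  gt <- default_ground_truth()
  expect_error(simulate_scan(gt, t_len = 10), class = "coinet_bad_argument")
  expect_error(effect_spec("vmPFC", "NAcc", delta_z = Inf, phase = "acute"),
               class = "coinet_bad_argument")
  # finite but huge delta drives tanh to exactly 1 in doubles
  eff <- effect_spec("vmPFC", "NAcc", delta_z = 50, phase = "acute")
  expect_error(simulate_scan(gt, effect = eff, t_len = 220, seed = 1),
               class = "coinet_bad_partial_correlation")
})

test_that("effects shift the sampled partial correlation on the target edge", {
  gt <- default_ground_truth(r = 0.2)
  eff <- effect_spec("vmPFC", "NAcc", delta_z = 1.0, phase = "acute")
  ts0 <- simulate_scan(gt, t_len = 8000, seed = 3)
  ts1 <- simulate_scan(gt, effect = eff, t_len = 8000, seed = 3)
  r0 <- oracle_partial_correlation(ts0)["vmPFC", "NAcc"]
  r1 <- oracle_partial_correlation(ts1)["vmPFC", "NAcc"]
  # eigendecomposition oracle for the post-effect, post-repair truth
  n <- gt$nodes
  P <- gt$precision
  i <- match("vmPFC", n); j <- match("NAcc", n)
  r_new <- tanh(atanh(gt$partial[i, j]) + 1.0)
  P[i, j] <- P[j, i] <- -r_new * sqrt(P[i, i] * P[j, j])
  lam <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
  if (lam < 1e-6) P <- P + diag(1e-6 - lam, 15)
  target <- -P[i, j] / sqrt(P[i, i] * P[j, j])
  expect_gt(r1, r0 + 0.2)
  expect_lt(abs(r1 - target), 0.1)
})

test_that("study layout: one scan per subject x period x timepoint, balanced order", {
  des <- study_design(n_subjects = 16, t_per_scan = 30)
  gt <- make_ground_truth(NULL, nodes = c("A", "B", "C"))
  st <- simulate_study(des, gt, seed = 1, subject_sd = 0)
  expect_length(st$scans, 160)
  expect_equal(nrow(st$meta), 160)
  expect_equal(dim(st$scans[[1]]), c(30, 3))
  # cross-over balance: exactly half the subjects get active drug in period 1
  p1 <- st$meta[st$meta$period == 1 & st$meta$timepoint == "baseline", ]
  expect_equal(sum(p1$treatment == "ketamine"), 8)
  # every subject sees both treatments
  per_subj <- table(st$meta$subject, st$meta$treatment)
  expect_true(all(per_subj == 5))
})

test_that("effects are applied only to post-dose scans of the active period", {
  des <- study_design(n_subjects = 4, t_per_scan = 30)
  gt <- default_ground_truth()
  eff <- rbind(effect_spec("vmPFC", "NAcc", 1.0, "acute"),
               effect_spec("omPFC", "PCC", 1.0, "delayed"))
  st <- simulate_study(des, gt, effect = eff, seed = 1)
  m <- st$meta
  expect_true(all(m$effect_applied[m$treatment == "ketamine" & m$timepoint != "baseline"]))
  expect_false(any(m$effect_applied[m$treatment == "placebo"]))
  expect_false(any(m$effect_applied[m$timepoint == "baseline"]))

  acute_only <- effect_spec("vmPFC", "NAcc", 1.0, "acute")
  st2 <- simulate_study(des, gt, effect = acute_only, seed = 1)
  m2 <- st2$meta
  expect_false(any(m2$effect_applied[m2$timepoint == "post24h"]))
  expect_true(all(m2$effect_applied[m2$treatment == "ketamine" &
                                      m2$timepoint %in% c("post50min", "post80min", "post165min")]))
})

test_that("studies are reproducible and subject networks stay PD", {
  des <- study_design(n_subjects = 4, t_per_scan = 30)
  gt <- default_ground_truth()
  s1 <- simulate_study(des, gt, seed = 5)
  s2 <- simulate_study(des, gt, seed = 5)
  expect_identical(s1$scans, s2$scans)
  for (net in s1$networks) {
    ev <- eigen(net$precision, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), 1e-6 - 1e-12)
  }
})

test_that("recovery error of the connectivity stage shrinks with scan length", {
  gt <- default_ground_truth(r = 0.2)
  t_grid <- c(100, 220, 1000, 10000)
  err <- vapply(seq_along(t_grid), function(gi) {
    errs <- vapply(1:8, function(rep) {
      ts <- simulate_scan(gt, t_len = t_grid[gi], seed = 100 * gi + rep)
      est <- partial_correlation(ts)
      truth <- gt$partial
      diag(truth) <- 0
      mean(abs(est - truth)[upper.tri(est)])
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("tidy export and CSV round-trip preserve the scans", {
  des <- study_design(n_subjects = 2, t_per_scan = 25)
  gt <- make_ground_truth(data.frame(region_i = "A", region_j = "B", r = 0.4),
                          nodes = c("A", "B", "C"))
  st <- simulate_study(des, gt, seed = 9)
  df <- tibble::as_tibble(st)
  expect_equal(nrow(df), 2 * 2 * 5 * 25)
  expect_true(all(c("subject", "period", "treatment", "timepoint", "frame",
                    "A", "B", "C") %in% names(df)))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  rt <- read_timeseries_csv(file.path(dir, "timeseries.csv"))
  expect_setequal(names(rt$scans), names(st$scans))
  expect_equal(rt$scans[[names(st$scans)[1]]],
               unname(st$scans[[1]]), ignore_attr = TRUE)
  gt_json <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                 simplifyVector = TRUE)
  expect_equal(gt_json$seed, 9)
  expect_equal(gt_json$nodes, c("A", "B", "C"))
})
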