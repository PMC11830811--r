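test_that("pre-dose samples report zero concentration", {
  pk <- pk_ground_truth(noise_cv = 0)
  prof <- simulate_pk_profile(pk, seed = 1)
  expect_equal(prof$conc_ng_per_ml[prof$time_min < 0], 0)
  pk_noisy <- pk_ground_truth(noise_cv = 0.2)
  prof2 <- simulate_pk_profile(pk_noisy, seed = 1)
  expect_equal(prof2$conc_ng_per_ml[prof2$time_min < 0], 0)
})

test_that("the infusion form converges to the bolus biexponential", {
  tt <- c(1, 5, 20, 60, 240, 1440)
  pk_small <- pk_ground_truth(infusion_duration = 1e-8,
                              sampling_times = tt, noise_cv = 0)
  prof <- simulate_pk_profile(pk_small)
  bolus <- pk_small$A * exp(-pk_small$alpha * tt) +
    pk_small$B * exp(-pk_small$beta * tt)
  expect_equal(prof$conc_ng_per_ml, bolus, tolerance = 1e-6)
  # exact zero-duration branch
  pk0 <- pk_ground_truth(infusion_duration = 0, sampling_times = tt)
  expect_equal(simulate_pk_profile(pk0)$conc_ng_per_ml, bolus, tolerance = 1e-12)
})

test_that("dense-grid trapezoid matches the analytic bolus AUC within 0.1%", {
  pk <- pk_ground_truth(infusion_duration = 0, noise_cv = 0,
                        sampling_times = seq(0, 2000, by = 0.5))
  prof <- simulate_pk_profile(pk)
  auc_num <- auc_linear_trapezoid(prof)
  auc_analytic <- (pk$A / pk$alpha * (1 - exp(-pk$alpha * 2000)) +
                     pk$B / pk$beta * (1 - exp(-pk$beta * 2000))) / 60
  expect_equal(auc_num, auc_analytic, tolerance = 1e-3)
})

test_that("profile noise is deterministic under a seed and has the right scale", {
  pk <- pk_ground_truth(noise_cv = 0.15)
  a <- simulate_pk_profile(pk, seed = 3)
  b <- simulate_pk_profile(pk, seed = 3)
  expect_identical(a, b)
  # mean-1 multiplicative error: large-sample average ratio near 1
  pk_dense <- pk_ground_truth(noise_cv = 0.15,
                              sampling_times = seq(1, 5000, length.out = 4000))
  noisy <- simulate_pk_profile(pk_dense, seed = 4)$conc_ng_per_ml
  clean <- simulate_pk_profile(pk_ground_truth(noise_cv = 0,
                                               sampling_times = pk_dense$sampling_times))$conc_ng_per_ml
  expect_equal(mean(noisy / clean), 1, tolerance = 0.02)
})

test_that("cmax/tmax find the observed maximum with earliest-time ties", {
  prof <- data.frame(time_min = c(0, 30, 60), conc_ng_per_ml = c(0, 5, 3))
  ct <- cmax_tmax(prof)
  expect_equal(ct$cmax, 5)
  expect_equal(ct$tmax_h, 0.5)
  tie <- data.frame(time_min = c(0, 30, 60, 90), conc_ng_per_ml = c(0, 5, 5, 1))
  expect_equal(cmax_tmax(tie)$tmax_h, 0.5)
  mono <- data.frame(time_min = seq(0, 100, 5),
                     conc_ng_per_ml = 100 * exp(-0.05 * seq(0, 100, 5)))
  expect_equal(cmax_tmax(mono)$tmax_h, 0)
  expect_error(cmax_tmax(data.frame(time_min = c(-5, 0), conc_ng_per_ml = c(0, 0))),
               class = "coinet_degenerate")
})

test_that("trapezoidal AUC handles rectangles, triangles and anchors", {
  expect_equal(auc_linear_trapezoid(
    data.frame(time_min = c(0, 60), conc_ng_per_ml = c(10, 10))), 10)
  expect_equal(auc_linear_trapezoid(
    data.frame(time_min = c(0, 60), conc_ng_per_ml = c(0, 2))), 1)
  # missing t=0 sample gets a zero anchor; pre-dose samples are excluded
  with_anchor <- auc_linear_trapezoid(
    data.frame(time_min = c(-5, 30, 60), conc_ng_per_ml = c(99, 2, 2)))
  expect_equal(with_anchor, (30 * 1 + 30 * 2) / 60)
  expect_error(auc_linear_trapezoid(
    data.frame(time_min = 30, conc_ng_per_ml = 5), t_end = 60),
    class = "coinet_bad_argument")
  # partial end interval interpolates linearly
  expect_equal(auc_linear_trapezoid(
    data.frame(time_min = c(0, 60), conc_ng_per_ml = c(0, 2)), t_end = 30),
    0.25)
})

test_that("AUC is additive over adjacent intervals on the same grid", {
  pk <- pk_ground_truth(noise_cv = 0.1)
  prof <- simulate_pk_profile(pk, seed = 5)
  full <- auc_linear_trapezoid(prof)
  left <- auc_linear_trapezoid(prof, t_end = 95)
  # right piece computed directly from the trapezoids between 95 and 1440
  keep <- prof$time_min >= 95
  tt <- prof$time_min[keep]
  cc <- prof$conc_ng_per_ml[keep]
  right <- sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2) / 60
  expect_equal(left + right, full, tolerance = 1e-12)
})

test_that("grid refinement reduces trapezoid overestimation monotonically", {
  auc_at <- function(step) {
    pk <- pk_ground_truth(infusion_duration = 0, noise_cv = 0,
                          sampling_times = seq(0, 1440, by = step))
    auc_linear_trapezoid(simulate_pk_profile(pk))
  }
  aucs <- vapply(c(240, 120, 60, 30), auc_at, numeric(1))
  expect_true(all(diff(aucs) < 0))  # shrinking toward the analytic value
})

test_that("terminal slope is exact on a monoexponential", {
  tt <- seq(10, 600, by = 10)
  prof <- data.frame(time_min = tt, conc_ng_per_ml = 100 * exp(-0.002 * tt))
  lz <- terminal_lambda_z(prof)
  expect_equal(lz$lambda_z_per_h, 0.002 * 60, tolerance = 1e-10)
  expect_equal(lz$r2_adj, 1, tolerance = 1e-12)
  inc <- data.frame(time_min = c(0, 10, 20, 30, 40),
                    conc_ng_per_ml = c(5, 1, 2, 3, 4))
  expect_error(terminal_lambda_z(inc), class = "coinet_degenerate")
  few <- data.frame(time_min = c(0, 10, 20), conc_ng_per_ml = c(1, 5, 3))
  expect_error(terminal_lambda_z(few), class = "coinet_degenerate")
})

test_that("biexponential terminal fit recovers beta within 5%", {
  pk <- pk_ground_truth(infusion_duration = 0, noise_cv = 0)
  prof <- simulate_pk_profile(pk)
  lz <- terminal_lambda_z(prof)
  expect_equal(lz$lambda_z_per_h, pk$beta * 60, tolerance = 0.05)
  # explicit selection override uses exactly the requested points
  lz2 <- terminal_lambda_z(prof, select = c(95, 240, 1440))
  expect_equal(lz2$n_lambda_points, 3)
})

test_that("AUC extrapolation follows C_last / lambda_z with flagged edge cases", {
  expect_equal(extrapolate_auc_inf(0, 10, 1)$auc_inf, 10)
  ext <- extrapolate_auc_inf(100, 0, 0.5)
  expect_equal(ext$auc_inf, 100)
  expect_false(ext$extrapolated)
  expect_equal(extrapolate_auc_inf(100, 10, 1e9)$auc_inf, 100, tolerance = 1e-6)
  # monoexponential truncated tail matches C(t)/k
  k_h <- 0.12
  c_t <- 37
  expect_equal(extrapolate_auc_inf(0, c_t, k_h)$auc_inf, c_t / k_h)
  expect_error(extrapolate_auc_inf(10, 5, -1), class = "coinet_bad_argument")
})

test_that("NCA on the 9-point schedule recovers bolus truth within 10%", {
  pk <- pk_ground_truth(infusion_duration = 0, noise_cv = 0)
  prof <- simulate_pk_profile(pk)
  res <- nca(prof, dose_mg = pk$dose_mg)
  t_half_true <- log(2) / (pk$beta * 60)
  auc_inf_true <- (pk$A / pk$alpha + pk$B / pk$beta) / 60
  expect_equal(res$t_half_h, t_half_true, tolerance = 0.10)
  expect_equal(res$auc_inf, auc_inf_true, tolerance = 0.10)
  expect_equal(res$cl_l_per_h, pk$dose_mg * 1e6 / auc_inf_true / 1000,
               tolerance = 0.10)
  expect_gte(res$auc_inf, res$auc_last)
  expect_equal(res$t_half_h, log(2) / res$lambda_z_per_h, tolerance = 1e-12)
})

test_that("NCA on dense monoexponential sampling matches closed forms to 0.1%", {
  k_min <- 0.004
  tt <- seq(0, 2400, by = 1)
  prof <- data.frame(time_min = tt, conc_ng_per_ml = 50 * exp(-k_min * tt))
  res <- nca(prof)
  expect_equal(res$lambda_z_per_h, k_min * 60, tolerance = 1e-3)
  expect_equal(res$t_half_h, log(2) / (k_min * 60), tolerance = 1e-3)
  auc_true <- 50 / k_min / 60  # full integral to infinity
  expect_equal(res$auc_inf, auc_true, tolerance = 1e-3)
  expect_equal(res$auc_last,
               50 / k_min * (1 - exp(-k_min * 2400)) / 60, tolerance = 1e-3)
})

test_that("the default study profile reproduces the intended summaries", {
  pk <- pk_ground_truth(noise_cv = 0)
  prof <- simulate_pk_profile(pk)
  res <- nca(prof, dose_mg = pk$dose_mg)
  expect_equal(res$cmax, 208.56, tolerance = 0.01)
  expect_equal(res$tmax_h, 40 / 60, tolerance = 1e-12)
  expect_equal(res$auc_last, 557, tolerance = 0.01)
  # sparse terminal sampling biases the half-life slightly low
  expect_equal(res$t_half_h, 5.25, tolerance = 0.03)
})

test_that("nca_summary reports n/mean/sd/median/min/max per analyte", {
  pk <- pk_ground_truth(noise_cv = 0.15)
  profs <- dplyr::bind_rows(lapply(1:6, function(s) {
    simulate_pk_profile(pk, seed = s, subject = s)
  }))
  tab <- dplyr::bind_rows(lapply(split(profs, profs$subject), nca,
                                 dose_mg = pk$dose_mg))
  expect_equal(nrow(tab), 6)
  summ <- nca_summary(tab)
  expect_setequal(unique(summ$parameter),
                  c("cmax", "tmax_h", "auc_last", "t_half_h", "auc_inf",
                    "cl_l_per_h"))
  expect_true(all(summ$n == 6))
  expect_true(all(summ$min <= summ$median & summ$median <= summ$max))
})
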