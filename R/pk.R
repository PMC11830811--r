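# PK profile simulation (zero-order infusion, biexponential disposition)
# and noncompartmental analysis.

#' Ground truth for a simulated PK profile
#'
#' Parameterizes a two-compartment (biexponential) disposition with a
#' zero-order intravenous infusion, in macro-constant form: `A` and `B` are
#' the bolus-equivalent intercepts (ng/ml) and `alpha > beta > 0` the
#' disposition rate constants (1/min). Defaults emulate a 0.5 mg/kg
#' racemic ketamine infusion over 40 min in a 75-kg adult: Cmax 208.6
#' ng/ml at end of infusion, terminal half-life 5.25 h, and — because
#' sparse-schedule trapezoidal AUC is what NCA reports — a linear
#' trapezoidal AUC0-last of 557 ng.h/ml on the default 9-point schedule.
#'
#' @param dose_per_kg Dose in mg/kg (default 0.5).
#' @param body_mass_kg Body mass in kg (default 75).
#' @param infusion_duration Infusion length in minutes (default 40).
#' @param A,B Macro amplitudes in ng/ml (defaults 463, 45.7).
#' @param alpha,beta Macro rate constants in 1/min (defaults 0.065,
#'   0.0022, i.e. distribution half-life 10.7 min, terminal 5.25 h).
#' @param sampling_times Sampling schedule in minutes from infusion start
#'   (default -5, 20, 30, 40, 50, 65, 95, 240, 1440).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   assay error (default 0).
#' @param analyte Analyte label (default `"ketamine"`).
#' @return Object of class `pk_ground_truth` (a list of the above, plus
#'   `dose_mg = dose_per_kg * body_mass_kg`).
#' @export
pk_ground_truth <- function(dose_per_kg = 0.5, body_mass_kg = 75,
                            infusion_duration = 40,
                            A = 463, B = 45.7, alpha = 0.065, beta = 0.0022,
                            sampling_times = c(-5, 20, 30, 40, 50, 65, 95, 240, 1440),
                            noise_cv = 0, analyte = "ketamine") {
  if (!(alpha > beta && beta > 0)) {
    abort("Require alpha > beta > 0.", class = "coinet_bad_argument")
  }
  if (A <= 0 || B <= 0) {
    abort("Macro amplitudes A and B must be positive.", class = "coinet_bad_argument")
  }
  if (is.unsorted(sampling_times, strictly = TRUE)) {
    abort("`sampling_times` must be strictly increasing.", class = "coinet_bad_argument")
  }
  if (infusion_duration < 0) {
    abort("`infusion_duration` must be nonnegative.", class = "coinet_bad_argument")
  }
  structure(
    list(dose_per_kg = dose_per_kg, body_mass_kg = body_mass_kg,
         dose_mg = dose_per_kg * body_mass_kg,
         infusion_duration = infusion_duration,
         A = A, B = B, alpha = alpha, beta = beta,
         sampling_times = sampling_times, noise_cv = noise_cv,
         analyte = analyte),
    class = "pk_ground_truth"
  )
}

# Noise-free concentration at time t (minutes) for a zero-order infusion of
# duration tinf with bolus-equivalent macro constants (A, alpha), (B, beta).
# During infusion: C(t) = sum_i A_i/(lambda_i tinf) (1 - e^{-lambda_i t});
# after: the t = tinf value washes out as e^{-lambda_i (t - tinf)}.
# As tinf -> 0 this converges to the bolus form A e^{-alpha t} + B e^{-beta t}.
pk_concentration <- function(t, pk) {
  tinf <- pk$infusion_duration
  term <- function(a_i, l_i) {
    if (tinf == 0) return(a_i * exp(-l_i * pmax(t, 0)))
    scale <- a_i / (l_i * tinf)
    during <- scale * (1 - exp(-l_i * pmin(t, tinf)))
    ifelse(t <= tinf, during, during * exp(-l_i * (t - tinf)))
  }
  conc <- term(pk$A, pk$alpha) + term(pk$B, pk$beta)
  ifelse(t < 0, 0, conc)
}

#' Simulate a concentration-time profile
#'
#' Evaluates the zero-order-infusion biexponential closed form at the
#' sampling schedule and multiplies by lognormal proportional error with
#' the requested CV (mean-1 parameterization). Pre-dose samples (t < 0)
#' are reported as 0, matching a drug-naive pre-dose draw.
#'
#' @param pk A [pk_ground_truth()].
#' @param seed Integer seed for the error draw.
#' @param subject Optional subject id recorded in the output.
#' @param treatment Treatment label recorded in the output
#'   (default `"ketamine"`).
#' @return Tibble with columns `subject`, `treatment`, `analyte`,
#'   `time_min`, `conc_ng_per_ml`.
#' @export
#' @examples
#' simulate_pk_profile(pk_ground_truth(), seed = 1)
simulate_pk_profile <- function(pk, seed = NULL, subject = 1L,
                                treatment = "ketamine") {
  stopifnot(inherits(pk, "pk_ground_truth"))
  conc <- pk_concentration(pk$sampling_times, pk)
  if (pk$noise_cv > 0) {
    sigma <- sqrt(log(1 + pk$noise_cv^2))
    eps <- with_seed_or_global(seed, exp(rnorm(length(conc), -sigma^2 / 2, sigma)))
    conc <- conc * eps
    conc[pk$sampling_times < 0] <- 0
  }
  tibble(subject = subject, treatment = treatment, analyte = pk$analyte,
         time_min = pk$sampling_times, conc_ng_per_ml = conc)
}

# Usable post-dose samples: drop t < 0; insert a zero anchor at t = 0 when
# no sample sits there (standard NCA convention for dosing-time anchoring).
nca_prepare <- function(time_min, conc) {
  keep <- time_min >= 0
  time_min <- time_min[keep]
  conc <- conc[keep]
  if (!length(time_min) || time_min[1] > 0) {
    time_min <- c(0, time_min)
    conc <- c(0, conc)
  }
  list(time = time_min, conc = conc)
}

#' Maximum concentration and its time
#'
#' @param profile Data frame with columns `time_min`, `conc_ng_per_ml`
#'   (pre-dose rows allowed; they never win the argmax).
#' @return One-row tibble: `cmax` (ng/ml), `tmax_h` (hours; ties broken by
#'   the earliest time).
#' @export
#' @examples
#' cmax_tmax(data.frame(time_min = c(0, 30, 60), conc_ng_per_ml = c(0, 5, 3)))
cmax_tmax <- function(profile) {
  conc <- profile$conc_ng_per_ml
  tt <- profile$time_min
  post <- tt >= 0
  if (!any(post & conc > 0)) {
    abort("Profile has no positive post-dose concentration.",
          class = "coinet_degenerate")
  }
  i <- which(post & conc == max(conc[post]))[1]
  tibble(cmax = conc[i], tmax_h = tt[i] / 60)
}

#' Linear-trapezoidal AUC from time 0
#'
#' Sums trapezoids over consecutive post-dose samples from 0 to `t_end`
#' minutes. Pre-dose samples are excluded; a zero-concentration anchor at
#' t = 0 is inserted when no sample sits at 0. If `t_end` falls between
#' samples the last partial trapezoid uses linear interpolation.
#'
#' @param profile Data frame with `time_min`, `conc_ng_per_ml`.
#' @param t_end End of integration in minutes (default: last sample).
#' @return AUC in ng.h/ml.
#' @export
#' @examples
#' auc_linear_trapezoid(data.frame(time_min = c(0, 60),
#'                                 conc_ng_per_ml = c(0, 2)))  # 1 ng.h/ml
auc_linear_trapezoid <- function(profile, t_end = NULL) {
  pp <- nca_prepare(profile$time_min, profile$conc_ng_per_ml)
  if (is.null(t_end)) t_end <- max(pp$time)
  if (t_end > max(pp$time)) {
    abort("`t_end` exceeds the last sampling time.", class = "coinet_bad_argument")
  }
  keep <- pp$time <= t_end
  tt <- pp$time[keep]
  cc <- pp$conc[keep]
  if (t_end > max(tt)) {
    c_end <- stats::approx(pp$time, pp$conc, xout = t_end)$y
    tt <- c(tt, t_end)
    cc <- c(cc, c_end)
  }
  if (length(tt) < 2) {
    abort("Fewer than 2 usable samples for the trapezoidal AUC.",
          class = "coinet_degenerate")
  }
  sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2) / 60
}

#' Terminal elimination rate constant
#'
#' Ordinary least squares of `log(conc)` on time over terminal points
#' strictly after Tmax with positive concentration. Automatic selection
#' maximizes adjusted R-squared over suffixes with at least 3 points (ties
#' go to the longer suffix); `lambda_z = -slope` must be positive.
#'
#' @param profile Data frame with `time_min`, `conc_ng_per_ml`.
#' @param select Optional explicit vector of times (minutes) to use
#'   instead of automatic selection.
#' @return One-row tibble: `lambda_z_per_h`, `n_lambda_points`, `r2_adj`.
#' @export
terminal_lambda_z <- function(profile, select = NULL) {
  ct <- cmax_tmax(profile)
  tmax_min <- ct$tmax_h * 60
  cand <- profile$time_min > tmax_min & profile$conc_ng_per_ml > 0
  tt <- profile$time_min[cand]
  cc <- profile$conc_ng_per_ml[cand]
  if (!is.null(select)) {
    keep <- tt %in% select
    tt <- tt[keep]
    cc <- cc[keep]
    if (length(tt) < 3) {
      abort("Explicit selection leaves fewer than 3 usable terminal points.",
            class = "coinet_degenerate")
    }
    fits <- list(fit_loglinear(tt, cc))
  } else {
    if (length(tt) < 3) {
      abort("Fewer than 3 positive concentrations after Tmax.",
            class = "coinet_degenerate")
    }
    starts <- seq_len(length(tt) - 2)
    fits <- lapply(starts, function(s) fit_loglinear(tt[s:length(tt)], cc[s:length(cc)]))
    # best adjusted R^2; ties (within 1e-10) to the longer suffix
    r2s <- vapply(fits, `[[`, numeric(1), "r2_adj")
    fits <- fits[order(-round(r2s, 10), starts)][1]
  }
  fit <- fits[[1]]
  if (fit$slope >= 0) {
    abort("No terminal decline (nonpositive log-linear slope).",
          class = "coinet_degenerate")
  }
  tibble(lambda_z_per_h = -fit$slope * 60,
         n_lambda_points = fit$n, r2_adj = fit$r2_adj)
}

fit_loglinear <- function(tt, cc) {
  n <- length(tt)
  y <- log(cc)
  xm <- mean(tt)
  ym <- mean(y)
  sxx <- sum((tt - xm)^2)
  slope <- sum((tt - xm) * (y - ym)) / sxx
  resid <- y - (ym + slope * (tt - xm))
  sst <- sum((y - ym)^2)
  r2 <- if (sst == 0) 1 else 1 - sum(resid^2) / sst
  r2_adj <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
  list(slope = slope, n = n, r2_adj = r2_adj)
}

#' Extrapolate AUC to infinity
#'
#' `AUC0-inf = AUC0-last + C_last / lambda_z` with all quantities in hour
#' units. When the last concentration is 0 the tail is undefined; the
#' function returns `auc_last` with `extrapolated = FALSE`.
#'
#' @param auc_last AUC0-last in ng.h/ml.
#' @param c_last Last measured concentration in ng/ml.
#' @param lambda_z Terminal rate constant in 1/h.
#' @return One-row tibble: `auc_inf`, `extrapolated`.
#' @export
extrapolate_auc_inf <- function(auc_last, c_last, lambda_z) {
  if (c_last < 0) {
    abort("`c_last` must be nonnegative.", class = "coinet_bad_argument")
  }
  if (c_last == 0) {
    return(tibble(auc_inf = auc_last, extrapolated = FALSE))
  }
  if (lambda_z <= 0) {
    abort("`lambda_z` must be positive.", class = "coinet_bad_argument")
  }
  tibble(auc_inf = auc_last + c_last / lambda_z, extrapolated = TRUE)
}

#' Noncompartmental analysis of one concentration-time profile
#'
#' Computes Cmax, Tmax, AUC0-last (linear trapezoidal), terminal lambda_z
#' (automatic best-adjusted-R-squared suffix), half-life, AUC0-inf and —
#' when `dose_mg` is supplied — apparent clearance `dose / AUC0-inf`.
#' Times are handled internally in minutes and reported in hours.
#'
#' @param profile Data frame with `time_min`, `conc_ng_per_ml` (extra
#'   columns such as `subject`, `analyte` are carried through if present).
#' @param dose_mg Administered dose in mg (optional).
#' @param lambda_select Optional explicit terminal times (minutes) passed
#'   to [terminal_lambda_z()].
#' @return One-row tibble: `cmax`, `tmax_h`, `auc_last`, `lambda_z_per_h`,
#'   `t_half_h`, `auc_inf`, `cl_l_per_h` (NA without `dose_mg`),
#'   `n_lambda_points`, `r2_adj`, plus any carried metadata.
#' @export
#' @examples
#' prof <- simulate_pk_profile(pk_ground_truth(), seed = 1)
#' nca(prof, dose_mg = 37.5)
nca <- function(profile, dose_mg = NULL, lambda_select = NULL) {
  ct <- cmax_tmax(profile)
  auc_last <- auc_linear_trapezoid(profile)
  lz <- terminal_lambda_z(profile, select = lambda_select)
  post <- profile$time_min >= 0
  c_last <- profile$conc_ng_per_ml[post][which.max(profile$time_min[post])]
  ext <- extrapolate_auc_inf(auc_last, c_last, lz$lambda_z_per_h)
  cl <- if (!is.null(dose_mg)) dose_mg * 1e6 / ext$auc_inf / 1000 else NA_real_
  out <- tibble(
    cmax = ct$cmax, tmax_h = ct$tmax_h, auc_last = auc_last,
    lambda_z_per_h = lz$lambda_z_per_h,
    t_half_h = log(2) / lz$lambda_z_per_h,
    auc_inf = ext$auc_inf, cl_l_per_h = cl,
    n_lambda_points = lz$n_lambda_points, r2_adj = lz$r2_adj
  )
  for (meta in c("subject", "treatment", "analyte")) {
    if (meta %in% names(profile)) {
      out[[meta]] <- profile[[meta]][1]
    }
  }
  dplyr::relocate(out, dplyr::any_of(c("subject", "treatment", "analyte")))
}

#' Summary statistics of NCA parameters
#'
#' Per analyte (and any other grouping columns present), the reporting
#' summary: n, mean, SD, median, min, max of each NCA parameter.
#'
#' @param nca_table Row-bound output of [nca()] over profiles.
#' @param params Parameter columns to summarize (default the standard set).
#' @return Long tibble: grouping columns, `parameter`, `n`, `mean`, `sd`,
#'   `median`, `min`, `max`.
#' @export
nca_summary <- function(nca_table,
                        params = c("cmax", "tmax_h", "auc_last", "t_half_h",
                                   "auc_inf", "cl_l_per_h")) {
  params <- intersect(params, names(nca_table))
  groups <- intersect(c("treatment", "analyte"), names(nca_table))
  long <- tidyr::pivot_longer(nca_table[, c(groups, params)],
                              dplyr::all_of(params),
                              names_to = "parameter", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(groups, "parameter")))),
    n = sum(is.finite(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    median = stats::median(.data$value, na.rm = TRUE),
    min = suppressWarnings(min(.data$value, na.rm = TRUE)),
    max = suppressWarnings(max(.data$value, na.rm = TRUE)),
    .groups = "drop"
  )
}
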