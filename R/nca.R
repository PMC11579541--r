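#' Trapezoidal AUC and AUMC
#'
#' Piecewise trapezoidal integration of concentration and of its first
#' moment (t * C) up to `t_end`.  The default is the plain linear trapezoid;
#' `"linear_up_log_down"` uses the log trapezoid on strictly decreasing
#' positive segments.  BLOQ values are carried as 0 (see
#' [conc_time_profile()]); if `t_end` falls between sampling times the
#' profile is linearly interpolated at `t_end`.
#'
#' @param profile A [conc_time_profile()].
#' @param t_end Upper limit of integration in hours; defaults to the last
#'   sampling time.
#' @param method `"linear"` or `"linear_up_log_down"`.
#' @return A list with `auc` (ug/L*h) and `aumc` (ug/L*h^2).
#' @examples
#' p <- conc_time_profile("s1", 0:3, c(0, 10, 10, 0), dose = 1)
#' auc_trapezoid(p)$auc  # 20
#' @export
auc_trapezoid <- function(profile, t_end = NULL,
                          method = c("linear", "linear_up_log_down")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "conc_time_profile"))
  profile <- impute_bloq(profile)
  t <- profile$times; c <- profile$concentrations
  if (sum(!is.na(c)) < 2) stop("need >= 2 quantifiable points", call. = FALSE)
  if (is.null(t_end)) t_end <- t[length(t)]
  if (t_end < t[2]) stop("t_end before second time point", call. = FALSE)
  if (t_end < max(t)) {
    c_end <- stats::approx(t, c, xout = t_end)$y
    keep <- t < t_end
    t <- c(t[keep], t_end); c <- c(c[keep], c_end)
  }
  auc <- 0; aumc <- 0
  for (i in seq_len(length(t) - 1)) {
    dt <- t[i + 1] - t[i]
    c1 <- c[i]; c2 <- c[i + 1]
    if (method == "linear_up_log_down" && c2 < c1 && c2 > 0) {
      k <- log(c1 / c2) / dt
      auc <- auc + (c1 - c2) / k
      # first moment of c1*exp(-k(t-t1)) over [t1, t2]
      aumc <- aumc + (t[i] * c1 - t[i + 1] * c2) / k + (c1 - c2) / k^2
    } else {
      auc <- auc + dt * (c1 + c2) / 2
      aumc <- aumc + dt * (t[i] * c1 + t[i + 1] * c2) / 2
    }
  }
  list(auc = auc, aumc = aumc)
}

#' Terminal elimination rate constant
#'
#' Log-linear regression on the terminal quantifiable points.  Candidate sets
#' are the last 3, 4, ... eligible points; the set with the highest adjusted
#' r-squared wins, ties broken toward more points.  For extravascular
#' profiles the point at Cmax is excluded from candidates; BLOQ values never
#' enter the fit.  Supply `points` to force a manual selection (indices into
#' the profile's times).
#'
#' @param profile A [conc_time_profile()].
#' @param points Optional integer indices of the points to use.
#' @return A list of class `lambda_z_fit`: `lambda_z` (1/h), `t_half_z` (h),
#'   `r2adj`, `n_lambda`, `intercept` (log scale) and the time indices used;
#'   `lambda_z` is `NA` when no admissible fit exists.
#' @export
fit_lambda_z <- function(profile, points = NULL) {
  stopifnot(inherits(profile, "conc_time_profile"))
  q <- quantifiable(profile)
  none <- structure(
    list(lambda_z = NA_real_, t_half_z = NA_real_, r2adj = NA_real_,
         n_lambda = 0L, intercept = NA_real_, idx = integer(0)),
    class = "lambda_z_fit"
  )
  if (length(q$times) < 3) return(none)
  i_cmax <- q$idx[which.max(q$conc)]
  t_cmax <- profile$times[i_cmax]
  eligible <- q$idx[profile$times[q$idx] >= t_cmax & q$conc > 0]
  if (profile$route == "oral") {
    eligible <- setdiff(eligible, i_cmax)
  }
  fit_set <- function(idx) {
    t <- profile$times[idx]; y <- log(profile$concentrations[idx])
    fit <- stats::lm(y ~ t)
    s <- suppressWarnings(summary(fit))
    list(lambda = -unname(stats::coef(fit)[2]),
         r2adj = s$adj.r.squared,
         intercept = unname(stats::coef(fit)[1]))
  }
  if (!is.null(points)) {
    if (length(points) < 3) stop("manual lambda-z selection needs >= 3 points", call. = FALSE)
    f <- fit_set(points)
    if (f$lambda <= 0) return(none)
    return(structure(
      list(lambda_z = f$lambda, t_half_z = log(2) / f$lambda, r2adj = f$r2adj,
           n_lambda = length(points), intercept = f$intercept, idx = points),
      class = "lambda_z_fit"
    ))
  }
  n <- length(eligible)
  if (n < 3) return(none)
  best <- NULL
  for (k in 3:n) {
    idx <- utils::tail(eligible, k)
    f <- fit_set(idx)
    if (!is.finite(f$lambda) || f$lambda <= 0) next
    # >= breaks adjusted-r2 ties toward the larger point set
    if (is.null(best) || f$r2adj >= best$r2adj - 1e-12) best <- c(f, list(idx = idx))
  }
  if (is.null(best)) return(none)
  structure(
    list(lambda_z = best$lambda, t_half_z = log(2) / best$lambda,
         r2adj = best$r2adj, n_lambda = length(best$idx),
         intercept = best$intercept, idx = best$idx),
    class = "lambda_z_fit"
  )
}

#' Single-dose non-compartmental analysis
#'
#' Computes the standard single-dose NCA parameter set from an observed
#' concentration-time profile: Cmax/Tmax, AUC and AUMC to the last
#' quantifiable time and extrapolated to infinity, MRT, terminal half-life,
#' and dose-normalized apparent clearance and volume.  Extrapolation uses
#' the observed last quantifiable concentration: AUC(0-inf) = AUC(0-t) +
#' Clast/lambda_z; AUMC adds t_last*Clast/lambda_z + Clast/lambda_z^2.
#' CL/F = dose/AUC(0-inf) and Vz/F = CL/F / lambda_z, converted to L/h/kg
#' and L/kg (dose mg/kg over AUC ug/L*h carries a factor 1000).
#'
#' @param profile A [conc_time_profile()] with route and dose set.
#' @param method Trapezoid flavor, see [auc_trapezoid()].
#' @param lambda_points Optional manual lambda-z point selection.
#' @param extrap_warn Extrapolated-AUC percentage above which the
#'   `high_extrapolation` flag is raised (default 20).
#' @return A list of class `nca_result` with fields `cmax`, `tmax`,
#'   `auc_0t`, `auc_0inf`, `aumc_0t`, `aumc_0inf`, `mrt_0t`, `mrt_0inf`,
#'   `lambda_z`, `t_half_z`, `cl_f`, `vz_f`, `n_lambda`, `lambda_r2adj`,
#'   `extrap_pct` and `flags`.  Fields depending on a missing lambda-z are
#'   `NA` with `flags$no_lambda_z` set.
#' @export
single_dose_nca <- function(profile, method = "linear", lambda_points = NULL,
                            extrap_warn = 20) {
  stopifnot(inherits(profile, "conc_time_profile"))
  q <- quantifiable(profile)
  if (length(q$conc) == 0 || all(q$conc == 0)) {
    stop("no quantifiable data", call. = FALSE)
  }
  cmax <- max(q$conc)
  tmax <- q$times[which.max(q$conc)]  # earliest time achieving the max
  t_last <- max(q$times[q$conc > 0])
  c_last <- q$conc[q$times == t_last]
  a <- auc_trapezoid(profile, t_end = t_last, method = method)
  lz <- fit_lambda_z(profile, points = lambda_points)
  flags <- list(no_lambda_z = is.na(lz$lambda_z), high_extrapolation = FALSE)

  if (is.na(lz$lambda_z)) {
    auc_inf <- aumc_inf <- mrt_inf <- cl_f <- vz_f <- extrap <- NA_real_
  } else {
    auc_inf <- a$auc + c_last / lz$lambda_z
    aumc_inf <- a$aumc + t_last * c_last / lz$lambda_z + c_last / lz$lambda_z^2
    mrt_inf <- aumc_inf / auc_inf
    extrap <- 100 * (auc_inf - a$auc) / auc_inf
    flags$high_extrapolation <- extrap > extrap_warn
    if (!is.na(profile$dose)) {
      cl_f <- 1000 * profile$dose / auc_inf     # (mg/kg)/(ug/L*h) -> L/h/kg
      vz_f <- cl_f / lz$lambda_z                # L/kg
    } else {
      cl_f <- vz_f <- NA_real_
    }
  }
  structure(
    list(
      subject_id = profile$subject_id, route = profile$route,
      dose = profile$dose,
      cmax = cmax, tmax = tmax,
      auc_0t = a$auc, auc_0inf = auc_inf,
      aumc_0t = a$aumc, aumc_0inf = aumc_inf,
      mrt_0t = a$aumc / a$auc, mrt_0inf = mrt_inf,
      lambda_z = lz$lambda_z, t_half_z = lz$t_half_z,
      cl_f = cl_f, vz_f = vz_f,
      n_lambda = lz$n_lambda, lambda_r2adj = lz$r2adj,
      extrap_pct = extrap, flags = flags
    ),
    class = "nca_result"
  )
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> subject %s (%s, %g mg/kg)\n", x$subject_id, x$route, x$dose))
  fields <- c(cmax = "ug/L", tmax = "h", auc_0t = "ug/L*h", auc_0inf = "ug/L*h",
              mrt_0t = "h", mrt_0inf = "h", t_half_z = "h",
              cl_f = "L/h/kg", vz_f = "L/kg", extrap_pct = "%")
  for (f in names(fields)) {
    cat(sprintf("  %-10s %12.4g %s\n", f, x[[f]], fields[[f]]))
  }
  invisible(x)
}

#' Absolute oral bioavailability
#'
#' F (%) from oral and intravenous NCA results, dose-normalized:
#' `"by_subject"` (crossover default) averages per-subject ratios matched by
#' subject id; `"ratio_of_means"` divides group mean AUCs.
#'
#' @param po,iv Lists of [single_dose_nca()] results (oral and iv arms).
#' @param pairing `"by_subject"` or `"ratio_of_means"`.
#' @param metric AUC field to use, `"auc_0t"` or `"auc_0inf"`.
#' @return A list with `f_pct`, `f_sd` (by-subject pairing only), `pairing`,
#'   `metric` and `n`.
#' @export
bioavailability <- function(po, iv, pairing = c("by_subject", "ratio_of_means"),
                            metric = c("auc_0t", "auc_0inf")) {
  pairing <- match.arg(pairing); metric <- match.arg(metric)
  if (length(iv) == 0) stop("missing iv arm", call. = FALSE)
  if (length(po) == 0) stop("missing oral arm", call. = FALSE)
  get <- function(lst, f) vapply(lst, function(r) as.numeric(r[[f]]), numeric(1))
  auc_po <- get(po, metric) / get(po, "dose")
  auc_iv <- get(iv, metric) / get(iv, "dose")
  if (pairing == "by_subject") {
    ids_po <- vapply(po, `[[`, character(1), "subject_id")
    ids_iv <- vapply(iv, `[[`, character(1), "subject_id")
    m <- match(ids_po, ids_iv)
    if (anyNA(m)) stop("by_subject pairing: unmatched subject ids", call. = FALSE)
    ratios <- 100 * auc_po / auc_iv[m]
    list(f_pct = mean(ratios), f_sd = stats::sd(ratios),
         pairing = pairing, metric = metric, n = length(ratios))
  } else {
    list(f_pct = 100 * mean(auc_po) / mean(auc_iv), f_sd = NA_real_,
         pairing = pairing, metric = metric, n = length(auc_po))
  }
}

#' Steady-state exposure metrics over one dosing interval
#'
#' From a last-dose profile covering one dosing interval tau:
#' AUCss (trapezoid over [0, tau]), Cav = AUCss/tau, observed Cmax and Cmin
#' within the interval, degree of fluctuation DF = (Cmax - Cmin)/Cav, and,
#' when first-dose exposure is supplied, the accumulation index
#' AUCss/AUC(0-tau, first dose).  Pre-dose trough concentrations, if given,
#' are checked for a time trend (linear regression, 5% level) to confirm
#' steady state.
#'
#' @param profile A [conc_time_profile()] with `tau` set and times covering
#'   `[0, tau]`.
#' @param first_dose_auc_0tau Optional AUC(0-tau) after the first dose,
#'   ug/L*h.
#' @param troughs Optional numeric vector of successive pre-dose trough
#'   concentrations, ug/L.
#' @param method Trapezoid flavor.
#' @return A list of class `steady_state_result` with `auc_ss`, `c_av`,
#'   `c_min`, `c_max`, `df`, `accumulation_index`, and `trough_trend_p` /
#'   `at_steady_state` when troughs were supplied.
#' @export
steady_state_metrics <- function(profile, first_dose_auc_0tau = NULL,
                                 troughs = NULL, method = "linear") {
  stopifnot(inherits(profile, "conc_time_profile"))
  tau <- profile$tau
  if (is.null(tau) || is.na(tau)) stop("tau missing", call. = FALSE)
  if (max(profile$times) < tau) {
    stop("profile does not cover one dosing interval", call. = FALSE)
  }
  auc_ss <- auc_trapezoid(profile, t_end = tau, method = method)$auc
  in_tau <- profile$times <= tau
  conc <- impute_bloq(profile)$concentrations[in_tau]
  c_av <- auc_ss / tau
  c_max <- max(conc); c_min <- min(conc)
  res <- list(
    auc_ss = auc_ss, c_av = c_av, c_min = c_min, c_max = c_max,
    df = if (c_av > 0) (c_max - c_min) / c_av else NA_real_,
    accumulation_index = if (!is.null(first_dose_auc_0tau)) {
      auc_ss / first_dose_auc_0tau
    } else NA_real_,
    trough_trend_p = NA_real_, at_steady_state = NA
  )
  if (!is.null(troughs) && length(troughs) >= 3) {
    fit <- stats::lm(troughs ~ seq_along(troughs))
    res$trough_trend_p <- summary(fit)$coefficients[2, 4]
    res$at_steady_state <- res$trough_trend_p > 0.05
  }
  structure(res, class = "steady_state_result")
}

#' Dose-proportionality ratios
#'
#' Group-mean exposure metric per dose level, normalized to the lowest dose
#' group, with the corresponding dose ratios for comparison.  Ratios growing
#' faster than dose suggest saturable (supra-proportional) elimination.
#'
#' @param results Named or unnamed list: one element per dose group, each a
#'   list of [single_dose_nca()] results at that dose.
#' @param metric `"auc_0t"` or `"cmax"`.
#' @return A data.frame with `dose`, `mean_metric`, `metric_ratio` and
#'   `dose_ratio`, ordered by dose.
#' @export
dose_proportionality <- function(results, metric = c("auc_0t", "cmax")) {
  metric <- match.arg(metric)
  if (length(results) < 2) stop("need >= 2 dose groups", call. = FALSE)
  if (any(vapply(results, length, integer(1)) == 0)) {
    stop("empty dose group", call. = FALSE)
  }
  dose <- vapply(results, function(g) g[[1]]$dose, numeric(1))
  means <- vapply(results, function(g) {
    mean(vapply(g, function(r) as.numeric(r[[metric]]), numeric(1)))
  }, numeric(1))
  ord <- order(dose)
  dose <- dose[ord]; means <- means[ord]
  data.frame(
    dose = dose,
    mean_metric = means,
    metric_ratio = means / means[1],
    dose_ratio = dose / dose[1]
  )
}
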