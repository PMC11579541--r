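#' CYP phenotyping transformation ratio
#'
#' Fraction of parent compound metabolized by a recombinant CYP isoform over
#' the incubation, relative to the zero-time control:
#' transformed % = 100 * (1 - remaining/control).  A run is only valid when
#' the NADPH-free negative control shows essentially no turnover; pass its
#' transformation to `negative_control_pct` to have that checked.
#'
#' @param parent_remaining Parent concentration after incubation.
#' @param zero_time_control Parent concentration in the zero-time control
#'   (> 0), same units.
#' @param isoform Isoform label (e.g. `"2C19"`).
#' @param negative_control_pct Optional transformed % observed in the
#'   NADPH-free control; above `5` invalidates the run.
#' @return A list of class `phenotyping_result` with `isoform`,
#'   `residual_pct`, `transformed_pct` and `valid_run`.
#' @examples
#' transformation_ratio(0.7373, 1, "2C19")$transformed_pct  # 26.27
#' @export
transformation_ratio <- function(parent_remaining, zero_time_control,
                                 isoform = NA_character_,
                                 negative_control_pct = NULL) {
  if (zero_time_control <= 0) stop("zero-time control must be > 0", call. = FALSE)
  residual <- 100 * parent_remaining / zero_time_control
  if (residual < -5 || residual > 105) {
    stop("residual percentage outside [-5, 105]; check controls", call. = FALSE)
  }
  structure(
    list(isoform = isoform, residual_pct = residual,
         transformed_pct = 100 - residual,
         valid_run = if (is.null(negative_control_pct)) NA
                     else abs(negative_control_pct) <= 5),
    class = "phenotyping_result"
  )
}

#' Cocktail-inhibition series
#'
#' Percent remaining activity of a CYP probe reaction versus inhibitor
#' concentration, normalized so the zero-inhibitor blank defines 100%.
#' The blank is the normalizer, not a fitted point (the fit lives on the
#' log-concentration scale).
#'
#' @param isoform CYP isoform label (one of the nine cocktail isoforms).
#' @param inhibitor_conc Inhibitor concentrations, umol/L, > 0, increasing.
#' @param activity_pct Matrix (conc x replicate) or vector of % activity.
#' @param substrate,substrate_conc Probe substrate and its concentration
#'   (umol/L, designed near Km); metadata only.
#' @return An object of class `inhibition_series`.
#' @export
inhibition_series <- function(isoform, inhibitor_conc, activity_pct,
                              substrate = NA_character_,
                              substrate_conc = NA_real_) {
  inhibitor_conc <- as.numeric(inhibitor_conc)
  activity_pct <- as.matrix(activity_pct)
  if (any(inhibitor_conc <= 0)) stop("inhibitor_conc must be > 0", call. = FALSE)
  if (any(diff(inhibitor_conc) <= 0)) stop("inhibitor_conc must be increasing", call. = FALSE)
  if (nrow(activity_pct) != length(inhibitor_conc)) {
    stop("activity_pct must have one row per concentration", call. = FALSE)
  }
  structure(
    list(isoform = isoform, inhibitor_conc = inhibitor_conc,
         activity_pct = activity_pct, substrate = substrate,
         substrate_conc = substrate_conc),
    class = "inhibition_series"
  )
}

#' Fit an IC50 with censoring
#'
#' Four-parameter logistic of % activity against log10 inhibitor
#' concentration: activity = bottom + (top - bottom)/(1 + (I/IC50)^hill).
#' The top is constrained to [90, 110]% (the blank defines 100%).  By
#' default the bottom is fixed at 0% — complete inhibition is attainable for
#' a competitive inhibitor, and freeing the bottom makes shallow curves
#' non-identifiable when the tested range only partially spans the descent;
#' pass `bottom = NULL` to estimate it (bounded to be non-negative).  If the
#' mean observed activity never falls below 50% of control, the IC50 is
#' censored at the highest tested concentration and reported as "> max";
#' the same happens on a non-convergent fit.
#'
#' @param series An [inhibition_series()].
#' @param bottom Fixed lower asymptote in % (default 0), or `NULL` to
#'   estimate it.
#' @return A list of class `ic50_result`: `ic50` (umol/L, `NA` when
#'   censored), `hill`, `ci` (95%, umol/L), `censored`, `censor_bound`,
#'   `max_inhibition_pct` (100 minus the mean activity at the top tested
#'   concentration) and `isoform`.
#' @export
fit_ic50 <- function(series, bottom = 0) {
  stopifnot(inherits(series, "inhibition_series"))
  conc <- series$inhibitor_conc
  if (length(conc) < 4) stop("need >= 4 inhibitor concentrations", call. = FALSE)
  act <- rowMeans(series$activity_pct)
  top_conc <- max(conc)
  max_inh <- 100 - act[length(act)]
  censored <- function(reason) {
    structure(
      list(isoform = series$isoform, ic50 = NA_real_, hill = NA_real_,
           ci = c(NA_real_, NA_real_), censored = TRUE,
           censor_bound = top_conc, label = paste(">", top_conc),
           max_inhibition_pct = max_inh, reason = reason),
      class = "ic50_result"
    )
  }
  if (min(act) >= 50) return(censored("activity never falls below 50% of control"))

  x <- log10(conc)
  y <- as.vector(series$activity_pct)
  xr <- rep(x, times = ncol(series$activity_pct))
  logIC50_start <- stats::approx(act, x, xout = 50, ties = mean)$y
  if (is.na(logIC50_start)) logIC50_start <- stats::median(x)
  fit <- tryCatch(
    if (is.null(bottom)) {
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (xr - logIC50))),
        start = list(top = 100, bottom = max(min(act), 0),
                     logIC50 = logIC50_start, hill = 1),
        lower = c(top = 90, bottom = 0, logIC50 = min(x) - 3, hill = 0.1),
        upper = c(top = 110, bottom = 100, logIC50 = max(x) + 3, hill = 5),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    } else {
      b0 <- bottom
      minpack.lm::nlsLM(
        y ~ b0 + (top - b0) / (1 + 10^(hill * (xr - logIC50))),
        start = list(top = 100, logIC50 = logIC50_start, hill = 1),
        lower = c(top = 90, logIC50 = min(x) - 3, hill = 0.1),
        upper = c(top = 110, logIC50 = max(x) + 3, hill = 5),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
    },
    error = function(e) NULL
  )
  if (is.null(fit)) return(censored("non-convergent logistic fit"))
  p <- as.list(stats::coef(fit))
  if (!is.null(bottom)) p$bottom <- bottom
  se <- tryCatch(sqrt(stats::vcov(fit)["logIC50", "logIC50"]), error = function(e) NA_real_)
  structure(
    list(isoform = series$isoform, ic50 = 10^p$logIC50, hill = p$hill,
         ci = 10^(p$logIC50 + c(-1.96, 1.96) * se), censored = FALSE,
         censor_bound = NA_real_, label = format(10^p$logIC50, digits = 4),
         max_inhibition_pct = max_inh, reason = NULL),
    class = "ic50_result"
  )
}

#' @export
print.ic50_result <- function(x, ...) {
  cat(sprintf("<ic50_result> CYP%s: IC50 %s umol/L (max inhibition %.1f%%)\n",
              x$isoform, x$label, x$max_inhibition_pct))
  invisible(x)
}

#' Classify an inhibition result
#'
#' Standard potency bands: IC50 < 10 umol/L potent, 10-50 moderate,
#' above 50 weak.  A result censored above the tested range is negligible,
#' unless the maximal observed inhibition at the top concentration still
#' reached 25% or more, in which case it is downgraded only to weak.
#'
#' @param result An [fit_ic50()] result.
#' @return One of `"negligible"`, `"weak"`, `"moderate"`, `"potent"`.
#' @export
classify_inhibition <- function(result) {
  stopifnot(inherits(result, "ic50_result"))
  if (result$censored) {
    if (result$max_inhibition_pct >= 25) "weak" else "negligible"
  } else if (result$ic50 < 10) {
    "potent"
  } else if (result$ic50 <= 50) {
    "moderate"
  } else {
    "weak"
  }
}
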