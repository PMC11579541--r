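#' Microsomal depletion series
#'
#' Remaining parent compound (percent of t = 0, or concentration) versus
#' incubation time in a liver-microsome stability assay.  Replicates are kept
#' separate so that kinetic parameters can be estimated per replicate and
#' summarized as mean +/- SD, matching how replicate incubations are usually
#' reported.
#'
#' @param species Species of the microsomes.
#' @param times Incubation times in minutes (must include 0).
#' @param remaining Numeric vector (single replicate) or matrix with one
#'   column per replicate, same number of rows as `times`.
#' @param incubation_protein Microsomal protein concentration in the
#'   incubation, mg/mL (default 0.2).
#' @param linear_window `NULL` for automatic detection, or `c(t_start, t_end)`
#'   in minutes restricting the log-linear fit.
#' @return An object of class `depletion_series`.
#' @export
depletion_series <- function(species, times, remaining,
                             incubation_protein = 0.2, linear_window = NULL) {
  match_species(species)
  times <- as.numeric(times)
  remaining <- as.matrix(remaining)
  if (nrow(remaining) != length(times)) {
    stop("remaining must have one row per time point", call. = FALSE)
  }
  if (!any(times == 0)) stop("times must include 0", call. = FALSE)
  if (any(times < 0)) stop("negative incubation time", call. = FALSE)
  if (any(remaining[times == 0, ] <= 0)) {
    stop("remaining at t = 0 must be > 0", call. = FALSE)
  }
  if (incubation_protein <= 0) stop("incubation_protein must be > 0", call. = FALSE)
  structure(
    list(species = species, times = times, remaining = remaining,
         incubation_protein = incubation_protein, linear_window = linear_window),
    class = "depletion_series"
  )
}

# Longest prefix of time points (>= 3) whose ln(remaining) ~ t regression has
# r^2 >= r2_min; when no prefix qualifies (noise-dominated series) the prefix
# with the highest r^2 is used.  Species with saturating depletion plateau
# after an initial log-linear phase; the window keeps the fit on that phase.
detect_linear_window <- function(times, remaining, r2_min = 0.95) {
  ok <- remaining > 0
  times <- times[ok]; remaining <- remaining[ok]
  n <- length(times)
  if (n < 3) stop("need >= 3 positive points for window detection", call. = FALSE)
  r2 <- vapply(3:n, function(k) {
    fit <- stats::lm(log(remaining[1:k]) ~ times[1:k])
    v <- suppressWarnings(summary(fit)$r.squared)
    if (is.nan(v)) 1 else v  # flat series: perfectly 'linear'
  }, numeric(1))
  qualifying <- which(r2 >= r2_min)
  best <- if (length(qualifying)) 2L + max(qualifying) else 2L + which.max(r2)
  c(times[1], times[best])
}

#' Fit first-order depletion kinetics
#'
#' Estimates the elimination rate constant from the slope of
#' ln(remaining) versus time over the log-linear window, per replicate:
#' ke = -slope, t1/2 = 0.693/ke.  A non-negative slope yields an infinite
#' half-life and a `stable` flag.
#'
#' @param series A [depletion_series()].
#' @param half_life_constant Numerator of the half-life relation; `0.693` by
#'   default (the rounded constant conventional in microsomal-stability
#'   reporting), or `log(2)` for full precision.
#' @return A list of class `depletion_fit` with per-replicate `ke` (1/min),
#'   `t_half` (min), `r2`, the `window` used, the replicate means, and a
#'   `stable` flag.
#' @examples
#' s <- depletion_series("human", c(0, 15, 30, 60), 100 * exp(-0.00278 * c(0, 15, 30, 60)))
#' fit_depletion(s)$t_half_mean
#' @export
fit_depletion <- function(series, half_life_constant = 0.693) {
  stopifnot(inherits(series, "depletion_series"))
  window <- series$linear_window
  if (is.null(window)) {
    window <- detect_linear_window(series$times, rowMeans(series$remaining))
  }
  in_win <- series$times >= window[1] & series$times <= window[2]
  if (sum(in_win) < 3) stop("fewer than 3 points inside the linear window", call. = FALSE)

  fit_one <- function(y) {
    t <- series$times[in_win]; y <- y[in_win]
    if (any(y <= 0)) stop("non-positive remaining inside the linear window", call. = FALSE)
    fit <- stats::lm(log(y) ~ t)
    slope <- unname(stats::coef(fit)[2])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    ke <- -slope
    if (abs(ke) < 1e-10) ke <- 0  # numerically flat series
    list(ke = ke,
         t_half = if (ke > 0) half_life_constant / ke else Inf,
         r2 = if (is.nan(r2)) 1 else r2)
  }
  reps <- apply(series$remaining, 2, fit_one)
  ke <- vapply(reps, `[[`, numeric(1), "ke")
  t_half <- vapply(reps, `[[`, numeric(1), "t_half")
  structure(
    list(
      species = series$species,
      ke = ke, t_half = t_half,
      r2 = vapply(reps, `[[`, numeric(1), "r2"),
      ke_mean = mean(ke), t_half_mean = mean(t_half),
      t_half_sd = if (length(t_half) > 1) stats::sd(t_half) else NA_real_,
      window = window,
      stable = all(ke <= 0)
    ),
    class = "depletion_fit"
  )
}

#' Intrinsic clearance from depletion half-life
#'
#' Scales the in-vitro half-life to whole-body intrinsic clearance:
#' CLint = (0.693 / t1/2) x (1 / protein mg/mL) x MPPGL x liver g per kg BW,
#' in mL/min/kg.
#'
#' @param t_half Depletion half-life in minutes (> 0; `Inf` gives 0).
#' @param incubation_protein Microsomal protein in the incubation, mg/mL.
#' @param species Species for the scaling constants.
#' @param scaling A [species_scaling()]; defaults to the species lookup.
#' @param half_life_constant `0.693` (default) or `log(2)`.
#' @return Intrinsic clearance in mL/min/kg.
#' @examples
#' intrinsic_clearance(249.30, 0.2, "human")  # ~16.07 mL/min/kg
#' @export
intrinsic_clearance <- function(t_half, incubation_protein = 0.2, species,
                                scaling = species_scaling(species),
                                half_life_constant = 0.693) {
  if (any(t_half <= 0)) stop("t_half must be > 0", call. = FALSE)
  if (incubation_protein <= 0) stop("incubation_protein must be > 0", call. = FALSE)
  (half_life_constant / t_half) * (1 / incubation_protein) *
    scaling$mppgl * scaling$liver_per_bw
}

#' Well-stirred hepatic clearance
#'
#' CLh = Qh * CLint / (Qh + CLint): hepatic clearance under the well-stirred
#' liver model, bounded above by hepatic blood flow Qh.  Binding corrections
#' (fu,p / fu,mic) are intentionally not applied.
#'
#' @param cl_int Intrinsic clearance, mL/min/kg (>= 0).
#' @param species Species for Qh.
#' @param scaling A [species_scaling()].
#' @return Hepatic clearance in mL/min/kg.
#' @examples
#' hepatic_clearance(16.08, "human")  # ~9.05 mL/min/kg
#' @export
hepatic_clearance <- function(cl_int, species, scaling = species_scaling(species)) {
  if (any(cl_int < 0)) stop("cl_int must be >= 0", call. = FALSE)
  scaling$qh * cl_int / (scaling$qh + cl_int)
}

#' Full microsomal stability analysis for one species
#'
#' Convenience wrapper: fits depletion kinetics, then scales to intrinsic and
#' hepatic clearance with the species constants.
#'
#' @inheritParams fit_depletion
#' @return A list of class `stability_result` with `ke` (1/min), `t_half`
#'   (min), `cl_int` and `cl_h` (mL/min/kg), per-replicate values and means,
#'   `r2`, and the window used.
#' @export
microsomal_stability <- function(series, half_life_constant = 0.693) {
  fit <- fit_depletion(series, half_life_constant = half_life_constant)
  scaling <- species_scaling(series$species)
  if (fit$stable) {
    cl_int <- rep(0, length(fit$t_half))
  } else {
    cl_int <- intrinsic_clearance(fit$t_half, series$incubation_protein,
                                  scaling = scaling,
                                  half_life_constant = half_life_constant)
  }
  cl_h <- hepatic_clearance(cl_int, scaling = scaling)
  structure(
    c(fit, list(
      cl_int = cl_int, cl_h = cl_h,
      cl_int_mean = mean(cl_int), cl_h_mean = mean(cl_h),
      qh = scaling$qh
    )),
    class = c("stability_result", class(fit))
  )
}

#' Rank species by microsomal turnover
#'
#' Orders species by descending elimination rate constant; equal rates are
#' flagged as ties.
#'
#' @param results Named list (by species) of objects carrying `ke_mean`
#'   ([fit_depletion()] or [microsomal_stability()] results).
#' @return A data.frame with `species`, `ke` and a `tied` flag, fastest first.
#' @export
species_rank <- function(results) {
  if (length(results) < 1) stop("no results to rank", call. = FALSE)
  ke <- vapply(results, function(r) r$ke_mean, numeric(1))
  ord <- order(-ke)
  ke <- ke[ord]
  data.frame(
    species = names(ke),
    ke = unname(ke),
    tied = duplicated(ke) | duplicated(ke, fromLast = TRUE),
    stringsAsFactors = FALSE
  )
}
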