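#' Bidirectional monolayer transport experiment
#'
#' One direction of a Transwell permeability experiment across an MDCK-MDR1
#' (or similar) monolayer: donor concentration at t = 0, the receiver-well
#' sampling time course, and the well geometry needed to convert receiver
#' concentrations into cumulative transported amounts.
#'
#' @param direction `"AtoB"` (apical to basolateral) or `"BtoA"`.
#' @param c0 Donor concentration at t = 0, ug/mL.
#' @param times Receiver sampling times in minutes, strictly increasing, > 0.
#' @param receiver_conc Measured receiver concentrations at `times`, ug/mL.
#' @param area Monolayer surface area, cm^2 (default 0.33).
#' @param donor_volume,receiver_volume,sample_volume Volumes in uL.  Each
#'   receiver sample of `sample_volume` is assumed replaced with blank buffer,
#'   which the cumulative-amount correction accounts for.
#' @param inhibitor Name of a co-applied inhibitor (e.g. `"verapamil"`), or
#'   `NA` for none.
#' @return An object of class `transport_experiment`.
#' @export
transport_experiment <- function(direction = c("AtoB", "BtoA"), c0,
                                 times, receiver_conc,
                                 area = 0.33,
                                 donor_volume = 400, receiver_volume = 1200,
                                 sample_volume = 50, inhibitor = NA_character_) {
  direction <- match.arg(direction)
  times <- as.numeric(times); receiver_conc <- as.numeric(receiver_conc)
  if (length(times) != length(receiver_conc)) {
    stop("times and receiver_conc differ in length", call. = FALSE)
  }
  if (any(times <= 0) || any(diff(times) <= 0)) {
    stop("sample times must be strictly increasing and > 0", call. = FALSE)
  }
  if (sample_volume >= receiver_volume) {
    stop("sample_volume must be < receiver_volume", call. = FALSE)
  }
  if (c0 <= 0) stop("c0 must be > 0", call. = FALSE)
  if (area <= 0) stop("area must be > 0", call. = FALSE)
  structure(
    list(direction = direction, c0 = c0, times = times,
         receiver_conc = receiver_conc, area = area,
         donor_volume = donor_volume, receiver_volume = receiver_volume,
         sample_volume = sample_volume, inhibitor = inhibitor),
    class = "transport_experiment"
  )
}

#' Cumulative amount transported into the receiver well
#'
#' Receiver sampling removes analyte: each aliquot taken at an earlier time
#' point is replaced with blank buffer, so later concentrations understate
#' the true cumulative transport.  The corrected cumulative amount is
#' Q(t_n) = C_n * V_receiver + sum_{i<n} C_i * V_sample (amounts in ug,
#' volumes converted from uL to mL).  With `correct_sampling = FALSE` (or a
#' zero sample volume) this reduces to the naive C_n * V_receiver.
#'
#' @param exp A [transport_experiment()].
#' @param correct_sampling Apply the sampling-replacement correction
#'   (default `TRUE`).
#' @return A data.frame with `time` (min) and `q` (ug).
#' @examples
#' e <- transport_experiment("AtoB", c0 = 1, times = c(30, 60),
#'                           receiver_conc = c(1, 1))
#' cumulative_receiver_amount(e)$q  # 1.20, 1.25
#' @export
cumulative_receiver_amount <- function(exp, correct_sampling = TRUE) {
  stopifnot(inherits(exp, "transport_experiment"))
  vr <- exp$receiver_volume / 1000  # mL
  vs <- if (correct_sampling) exp$sample_volume / 1000 else 0
  conc <- exp$receiver_conc
  removed <- c(0, cumsum(conc * vs)[-length(conc)])
  data.frame(time = exp$times, q = conc * vr + removed)
}

#' Apparent permeability coefficient
#'
#' Papp = (dQ/dt) / (A * C0), with dQ/dt the least-squares slope of the
#' cumulative transported amount versus time in seconds.  An A-to-B Papp
#' above 3e-6 cm/s flags ready passage across the blood-brain barrier; a
#' non-positive slope is floored at 0 with a warning flag.  A receiver
#' concentration exceeding 10% of the donor C0 violates the sink assumption
#' and raises `sink_violation`.
#'
#' @inheritParams cumulative_receiver_amount
#' @param bbb_threshold Permeability threshold (cm/s) for the BBB flag.
#' @return A list of class `papp_result`: `papp` (cm/s), `slope_r2`,
#'   `direction`, `er` (`NA` until paired), and `flags`.
#' @export
apparent_permeability <- function(exp, correct_sampling = TRUE,
                                  bbb_threshold = 3e-6) {
  stopifnot(inherits(exp, "transport_experiment"))
  if (length(exp$times) < 3) stop("need >= 3 sampled time points", call. = FALSE)
  q <- cumulative_receiver_amount(exp, correct_sampling)
  fit <- stats::lm(q$q ~ I(q$time * 60))  # ug per second
  slope <- unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  flags <- list(
    nonpositive_slope = slope <= 0,
    sink_violation = any(exp$receiver_conc > 0.1 * exp$c0),
    bbb_permeable = NA
  )
  if (flags$nonpositive_slope) {
    warning("non-positive receiver flux; Papp floored at 0")
    papp <- 0
  } else {
    papp <- slope / (exp$area * exp$c0)  # (ug/s) / (cm^2 * ug/cm^3) = cm/s
  }
  if (exp$direction == "AtoB") flags$bbb_permeable <- papp > bbb_threshold
  structure(
    list(papp = papp, slope_r2 = if (is.nan(r2)) NA_real_ else r2,
         direction = exp$direction, c0 = exp$c0,
         inhibitor = exp$inhibitor, er = NA_real_, flags = flags),
    class = "papp_result"
  )
}

#' Efflux ratio from paired bidirectional permeabilities
#'
#' ER = Papp(B->A) / Papp(A->B).  An ER above 1.5 indicates carrier-mediated
#' efflux (P-gp substrate).  A zero A-to-B Papp leaves the ratio undefined
#' (censored).
#'
#' @param ab,ba `papp_result` objects for the A-to-B and B-to-A directions.
#' @param threshold ER above which the compound is flagged a P-gp substrate.
#' @return The `ab` result augmented with `er`, `papp_ba` and flags
#'   `pgp_substrate` / `er_censored`.
#' @export
efflux_ratio <- function(ab, ba, threshold = 1.5) {
  stopifnot(inherits(ab, "papp_result"), inherits(ba, "papp_result"))
  if (ab$direction != "AtoB" || ba$direction != "BtoA") {
    stop("efflux_ratio() needs one AtoB and one BtoA result, in that order",
         call. = FALSE)
  }
  out <- ab
  out$papp_ba <- ba$papp
  if (ab$papp <= 0) {
    out$er <- NA_real_
    out$flags$er_censored <- TRUE
    out$flags$pgp_substrate <- NA
  } else {
    out$er <- ba$papp / ab$papp
    out$flags$er_censored <- FALSE
    out$flags$pgp_substrate <- out$er > threshold
  }
  out
}

#' Inhibitor effect on directional transport
#'
#' Compares matched transport experiments run with and without an efflux
#' inhibitor: per (direction, donor concentration) cell, the Papp with and
#' without inhibitor and the fold-change, plus an efflux-ratio collapse
#' summary when both directions are present at a concentration.
#'
#' @param base List of [transport_experiment()]s without inhibitor.
#' @param inhibited Matched list with inhibitor; same directions and donor
#'   concentrations.
#' @param correct_sampling Passed through to [apparent_permeability()].
#' @return A list with `comparison` (data.frame: direction, c0, papp_base,
#'   papp_inhibited, fold_change) and `er_summary` (data.frame: c0, er_base,
#'   er_inhibited) for concentrations with both directions.
#' @export
inhibitor_effect <- function(base, inhibited, correct_sampling = TRUE) {
  if (length(inhibited) == 0 || length(base) == 0) {
    stop("empty experiment set", call. = FALSE)
  }
  key <- function(e) paste(e$direction, format(e$c0))
  kb <- vapply(base, key, character(1))
  ki <- vapply(inhibited, key, character(1))
  if (length(kb) != length(ki) || !setequal(kb, ki)) {
    stop("unmatched designs: base and inhibited must share (direction, c0) cells",
         call. = FALSE)
  }
  pb <- lapply(base, apparent_permeability, correct_sampling = correct_sampling)
  pi_ <- lapply(inhibited[match(kb, ki)], apparent_permeability,
                correct_sampling = correct_sampling)
  comparison <- data.frame(
    direction = vapply(base, `[[`, character(1), "direction"),
    c0 = vapply(base, `[[`, numeric(1), "c0"),
    papp_base = vapply(pb, `[[`, numeric(1), "papp"),
    papp_inhibited = vapply(pi_, `[[`, numeric(1), "papp"),
    stringsAsFactors = FALSE
  )
  comparison$fold_change <- comparison$papp_inhibited / comparison$papp_base

  er_for <- function(papps, dirs, c0s, conc) {
    a <- which(dirs == "AtoB" & c0s == conc); b <- which(dirs == "BtoA" & c0s == conc)
    if (length(a) == 1 && length(b) == 1 && papps[a] > 0) papps[b] / papps[a] else NA_real_
  }
  concs <- sort(unique(comparison$c0))
  er_summary <- data.frame(
    c0 = concs,
    er_base = vapply(concs, function(cc)
      er_for(comparison$papp_base, comparison$direction, comparison$c0, cc), numeric(1)),
    er_inhibited = vapply(concs, function(cc)
      er_for(comparison$papp_inhibited, comparison$direction, comparison$c0, cc), numeric(1))
  )
  list(comparison = comparison, er_summary = er_summary)
}

#' Fit a TC50 from an MTT cytotoxicity curve
#'
#' Fits a four-parameter logistic of relative growth rate (RGR, % of blank
#' control) against the natural logarithm of concentration and reports the
#' concentration at which RGR crosses 50%.  Bottom and top are bounded to
#' [0, 120]% to keep shallow curves identifiable.  When the fitted curve
#' never reaches 50% inside the tested range (or the fit fails), the result
#' is censored at the highest tested concentration.
#'
#' @param concentrations Tested concentrations, ug/mL (> 0).
#' @param rgr Relative growth rate per concentration, % (replicate means).
#' @return A list of class `tc50_fit`: `tc50` (ug/mL or `NA`), `se_log`
#'   (standard error on the ln scale), `ci` (95%, ug/mL), `censored`,
#'   `censor_bound`, and the fitted parameters.
#' @export
fit_tc50 <- function(concentrations, rgr) {
  if (length(concentrations) < 5) {
    stop("need >= 5 concentrations spanning the response", call. = FALSE)
  }
  if (any(concentrations <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (any(!is.finite(rgr))) stop("rgr must be finite", call. = FALSE)
  x <- log(concentrations)
  cmax <- max(concentrations)
  censored <- function(reason) {
    structure(list(tc50 = NA_real_, se_log = NA_real_, ci = c(NA_real_, NA_real_),
                   censored = TRUE, censor_bound = cmax, reason = reason,
                   pars = NULL),
              class = "tc50_fit")
  }
  if (min(rgr) > 50) return(censored("response never falls below 50% RGR"))

  start <- list(top = min(max(rgr), 110), bottom = max(min(rgr), 5),
                xmid = stats::approx(rgr, x, xout = 50, ties = mean)$y,
                scal = 1)
  if (is.na(start$xmid)) start$xmid <- stats::median(x)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rgr ~ bottom + (top - bottom) / (1 + exp((x - xmid) / scal)),
      start = start,
      lower = c(top = 0, bottom = 0, xmid = min(x) - 5, scal = 1e-3),
      upper = c(top = 120, bottom = 120, xmid = max(x) + 5, scal = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(censored("non-convergent logistic fit"))
  p <- as.list(stats::coef(fit))
  # ln-concentration at RGR = 50 on the fitted curve
  if (!(min(p$bottom, p$top) < 50 && 50 < max(p$bottom, p$top))) {
    return(censored("fitted curve does not span 50% RGR"))
  }
  x50 <- p$xmid + p$scal * log((p$top - 50) / (50 - p$bottom))
  if (x50 > log(cmax)) return(censored("fitted midpoint beyond tested range"))
  se <- tryCatch(sqrt(stats::vcov(fit)["xmid", "xmid"]), error = function(e) NA_real_)
  structure(
    list(tc50 = exp(x50), se_log = se,
         ci = exp(x50 + c(-1.96, 1.96) * se),
         censored = FALSE, censor_bound = NA_real_, reason = NULL, pars = p),
    class = "tc50_fit"
  )
}
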