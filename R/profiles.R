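#' Concentration-time profile for one subject in one matrix
#'
#' The substrate of all non-compartmental computations: an ordered series of
#' analyte concentrations for a single subject in a single matrix (plasma,
#' blood, a tissue, urine, feces or bile), with dose and route metadata.
#' Concentrations are canonically in ug/L (= ng/mL; tissue homogenates in
#' ng/g are numerically commensurate), times in hours.
#'
#' Values below the limit of quantification (LOQ) are retained and flagged
#' BLOQ rather than dropped; the BLOQ handling policy lives in the consumers
#' (see [auc_trapezoid()] and [fit_lambda_z()]).
#'
#' @param subject_id Subject identifier (character).
#' @param times Sampling times in hours, strictly increasing, first >= 0.
#' @param concentrations Concentrations in ug/L, non-negative.
#' @param dose Dose in mg/kg (must be > 0 for clearance/volume computations).
#' @param route `"oral"` or `"iv"`.
#' @param species `"rat"`, `"dog"`, `"monkey"` or `"human"`.
#' @param matrix Matrix name; `"plasma"`, `"blood"`, `"urine"`, `"feces"`,
#'   `"bile"` or `"tissue:<name>"`.
#' @param tau Dosing interval in hours (multiple-dose profiles), or `NA`.
#' @param loq Limit of quantification in ug/L; concentrations strictly below
#'   it are flagged BLOQ. `0` disables flagging.
#' @return An object of class `conc_time_profile`.
#' @export
conc_time_profile <- function(subject_id, times, concentrations,
                              dose = NA_real_, route = c("oral", "iv"),
                              species = "rat", matrix = "plasma",
                              tau = NA_real_, loq = 0) {
  route <- match.arg(route)
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  dose <- as.numeric(dose); tau <- as.numeric(tau); loq <- as.numeric(loq)
  if (length(times) != length(concentrations)) {
    stop("times and concentrations differ in length", call. = FALSE)
  }
  if (length(times) > 0) {
    if (any(diff(times) <= 0)) stop("non-monotone times", call. = FALSE)
    if (times[1] < 0) stop("first time must be >= 0", call. = FALSE)
  }
  if (any(concentrations < 0, na.rm = TRUE)) {
    stop("negative concentration", call. = FALSE)
  }
  if (!is.na(dose) && dose <= 0) stop("dose must be > 0", call. = FALSE)
  structure(
    list(
      subject_id = as.character(subject_id),
      species = species, matrix = matrix, route = route,
      dose = dose, tau = tau,
      times = times, concentrations = concentrations,
      loq = loq, bloq = !is.na(concentrations) & concentrations < loq
    ),
    class = "conc_time_profile"
  )
}

#' @export
print.conc_time_profile <- function(x, ...) {
  cat(sprintf(
    "<conc_time_profile> subject %s (%s, %s, %s), %d points over %g-%g h, dose %g mg/kg\n",
    x$subject_id, x$species, x$matrix, x$route, length(x$times),
    if (length(x$times)) min(x$times) else NA, if (length(x$times)) max(x$times) else NA,
    x$dose
  ))
  invisible(x)
}

#' @export
as.data.frame.conc_time_profile <- function(x, ...) {
  data.frame(
    subject_id = x$subject_id, species = x$species, matrix = x$matrix,
    route = x$route, dose_mg_per_kg = x$dose, tau_h = x$tau,
    time = x$times, time_unit = "h",
    conc = x$concentrations, conc_unit = "ug/L",
    loq = x$loq, bloq = x$bloq,
    stringsAsFactors = FALSE
  )
}

# Quantifiable observations: non-missing and not BLOQ.
quantifiable <- function(profile) {
  ok <- !is.na(profile$concentrations) & !profile$bloq
  list(times = profile$times[ok], conc = profile$concentrations[ok], idx = which(ok))
}

# BLOQ policy (NCA convention; applied before any trapezoid/terminal fit):
# values before the first quantifiable point are set to 0; BLOQ values after
# that point are retained as 0 for trapezoids but excluded from lambda-z fits.
impute_bloq <- function(profile) {
  conc <- profile$concentrations
  conc[profile$bloq] <- 0
  profile$concentrations <- conc
  profile
}
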