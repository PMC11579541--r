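#' Per-interval excretion record
#'
#' One collection interval of one excretion route: the amount of matrix
#' collected (urine/bile volume in mL, or fecal homogenate volume in mL with
#' its dilution factor) and the analyte concentration measured in it.
#'
#' @param route `"urine"`, `"feces"` or `"bile"`.
#' @param interval `c(start, end)` in hours.
#' @param matrix_amount Collected volume (mL).  For homogenates this is the
#'   homogenate volume; the dilution factor converts to source amount.
#' @param conc Analyte concentration in the measured matrix, ug/mL
#'   (numerically = mg/L).
#' @param dilution_factor Homogenate dilution factor (10 for a 10%
#'   homogenate); must be supplied for `"feces"`, defaults to 1 otherwise.
#' @return An object of class `excretion_record`.
#' @export
excretion_record <- function(route = c("urine", "feces", "bile"),
                             interval, matrix_amount, conc,
                             dilution_factor = NULL) {
  route <- match.arg(route)
  if (length(interval) != 2 || interval[2] <= interval[1] || interval[1] < 0) {
    stop("interval must be c(start, end) with 0 <= start < end", call. = FALSE)
  }
  if (matrix_amount < 0 || conc < 0) stop("negative amount or concentration", call. = FALSE)
  if (is.null(dilution_factor)) {
    if (route == "feces") {
      stop("dilution factor required for homogenate matrices", call. = FALSE)
    }
    dilution_factor <- 1
  }
  structure(
    list(route = route, interval = as.numeric(interval),
         matrix_amount = matrix_amount, conc = conc,
         dilution_factor = dilution_factor),
    class = "excretion_record"
  )
}

#' Percent of dose excreted in one interval
#'
#' amount (ug) = conc * matrix volume * dilution factor;
#' pct of dose = 100 * amount / (dose * body weight), with dose in mg/kg
#' converted to ug.
#'
#' @param rec An [excretion_record()].
#' @param dose_mg_per_kg Administered dose, mg/kg (> 0).
#' @param body_weight_kg Animal body weight, kg (> 0).
#' @return Percentage of the administered dose.
#' @export
interval_pct_dose <- function(rec, dose_mg_per_kg, body_weight_kg) {
  stopifnot(inherits(rec, "excretion_record"))
  if (dose_mg_per_kg <= 0 || body_weight_kg <= 0) {
    stop("dose and body weight must be > 0", call. = FALSE)
  }
  amount_ug <- rec$conc * rec$matrix_amount * rec$dilution_factor
  100 * amount_ug / (dose_mg_per_kg * body_weight_kg * 1000)
}

#' Cumulative excretion curve for one route
#'
#' Running sum of per-interval percent-of-dose values; intervals must be
#' contiguous and non-overlapping, and the curve is monotone non-decreasing
#' by construction.
#'
#' @param pct_dose Per-interval percent-of-dose values, ordered by interval.
#' @param intervals Optional matrix/list of `c(start, end)` pairs to validate
#'   contiguity.
#' @return Numeric vector of cumulative percentages at each interval end.
#' @examples
#' cumulative_curve(c(0.010, 0.206, 0.145, 0.019, 0.002))
#' @export
cumulative_curve <- function(pct_dose, intervals = NULL) {
  if (any(pct_dose < 0)) stop("negative interval excretion", call. = FALSE)
  if (!is.null(intervals)) {
    ends <- vapply(intervals, `[`, numeric(1), 2)
    starts <- vapply(intervals, `[`, numeric(1), 1)
    if (any(abs(starts[-1] - ends[-length(ends)]) > 1e-9)) {
      stop("intervals must be contiguous per route", call. = FALSE)
    }
  }
  cumsum(pct_dose)
}

#' Total recovery across excretion routes
#'
#' Sum of the final cumulative percent-of-dose over all routes.  A total
#' below `metabolism_threshold` (default 5%) flags extensive metabolic
#' transformation as the dominant elimination pathway.
#'
#' @param route_finals Named numeric vector of final cumulative percentages
#'   per route.
#' @param metabolism_threshold Total recovery (%) below which the
#'   `extensive_metabolism` flag is set.
#' @return A list with `total_pct`, `route_finals` and
#'   `extensive_metabolism`.
#' @export
total_recovery <- function(route_finals, metabolism_threshold = 5) {
  if (length(route_finals) < 1) stop("need >= 1 route", call. = FALSE)
  total <- sum(route_finals)
  list(total_pct = total, route_finals = route_finals,
       extensive_metabolism = total < metabolism_threshold)
}
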