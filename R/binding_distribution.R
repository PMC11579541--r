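#' Plasma-protein binding rate from an ultrafiltration pair
#'
#' Bound fraction from total and free (ultrafiltrate) plasma concentrations:
#' binding % = 100 * (Ct - Cf) / Ct.  A free concentration above the total
#' indicates a pre-saturation or nonspecific-binding artifact and errors.
#'
#' @param ct Total plasma concentration (> 0).
#' @param cf Free (ultrafiltrate) concentration, same units, 0 <= cf <= ct.
#' @return Binding percentage in [0, 100].
#' @examples
#' ppb_rate(100, 46.38)  # 53.62
#' @export
ppb_rate <- function(ct, cf) {
  if (any(ct <= 0)) stop("total concentration must be > 0", call. = FALSE)
  if (any(cf < 0)) stop("free concentration must be >= 0", call. = FALSE)
  if (any(cf > ct)) {
    stop("free concentration exceeds total (ultrafiltration artifact)", call. = FALSE)
  }
  100 * (ct - cf) / ct
}

#' Tissue-distribution panel (composite design)
#'
#' Mean analyte concentrations per tissue per time point from a destructive
#' sampling design (one group of animals killed per time point).  Blood is
#' the mandatory reference matrix; tissue concentrations (ng/g) and blood
#' (ug/L) are treated as numerically commensurate for ratio purposes.
#'
#' @param times Sampling times in hours.
#' @param conc Matrix of mean concentrations, one row per time in `times`,
#'   one named column per matrix; must contain a `blood` column.
#' @param n_per_timepoint Animals per time point (metadata).
#' @return An object of class `tissue_panel`.
#' @export
tissue_panel <- function(times, conc, n_per_timepoint = NA_integer_) {
  conc <- as.matrix(conc)
  if (nrow(conc) != length(times)) {
    stop("conc must have one row per time point", call. = FALSE)
  }
  if (!"blood" %in% colnames(conc)) stop("missing blood reference", call. = FALSE)
  if (any(conc < 0, na.rm = TRUE)) stop("negative concentration", call. = FALSE)
  if (length(times) < 2) stop("need >= 2 time points", call. = FALSE)
  structure(
    list(times = as.numeric(times), conc = conc,
         n_per_timepoint = n_per_timepoint),
    class = "tissue_panel"
  )
}

#' Composite tissue AUCs, tissue-to-blood ratios and exposure fractions
#'
#' Sparse-design trapezoidal AUC(0-t) on the per-time-point mean
#' concentration of each matrix, tissue-to-blood exposure ratio
#' AUC(tissue)/AUC(blood), and each matrix's share of the summed exposure
#' (fractions over all matrices add to 100%).
#'
#' @param panel A [tissue_panel()].
#' @return A data.frame with one row per matrix: `matrix`, `auc_0t`,
#'   `ratio_to_blood` and `fraction_of_total` (%).
#' @export
composite_tissue_auc <- function(panel) {
  stopifnot(inherits(panel, "tissue_panel"))
  t <- panel$times
  auc <- apply(panel$conc, 2, function(c) {
    sum(diff(t) * (utils::head(c, -1) + utils::tail(c, -1)) / 2)
  })
  blood <- auc[["blood"]]
  data.frame(
    matrix = names(auc),
    auc_0t = unname(auc),
    ratio_to_blood = unname(auc) / blood,
    fraction_of_total = 100 * unname(auc) / sum(auc),
    stringsAsFactors = FALSE
  )
}

#' Observed peak and terminal decline per tissue
#'
#' Observed Tmax and Cmax per matrix plus an accumulation screen: the
#' concentration at the last sampling time as a percentage of the peak.
#' Values above `accumulation_threshold` (default 20%) flag possible tissue
#' retention; when no matrix exceeds it the panel as a whole is flagged
#' free of tissue accumulation.
#'
#' @param panel A [tissue_panel()].
#' @param accumulation_threshold Terminal %-of-peak above which a matrix is
#'   flagged (default 20).
#' @return A list with `summary` (data.frame: matrix, tmax_obs, cmax_obs,
#'   terminal_pct_of_peak, accumulation_flag) and `no_tissue_accumulation`.
#' @export
peak_profile_summary <- function(panel, accumulation_threshold = 20) {
  stopifnot(inherits(panel, "tissue_panel"))
  t <- panel$times
  rows <- lapply(colnames(panel$conc), function(m) {
    c <- panel$conc[, m]
    i <- which.max(c)
    terminal <- 100 * c[length(c)] / c[i]
    data.frame(
      matrix = m, tmax_obs = t[i], cmax_obs = c[i],
      terminal_pct_of_peak = terminal,
      accumulation_flag = terminal > accumulation_threshold,
      stringsAsFactors = FALSE
    )
  })
  summary <- do.call(rbind, rows)
  list(summary = summary,
       no_tissue_accumulation = !any(summary$accumulation_flag))
}
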