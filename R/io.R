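#' Read concentration-time profiles from a long-format table
#'
#' Reads a CSV/TSV with header columns `subject_id, species, matrix, route,
#' dose_mg_per_kg, time, time_unit, conc, conc_unit, loq` (an optional
#' `period` column separates repeated occasions within a subject) and
#' returns one [conc_time_profile()] per (subject, matrix, period).  Units
#' are canonicalized at this boundary: times to hours (`h` or `min`),
#' concentrations to ug/L (`ug/L`, `ng/mL`, `ng/g` are numerically
#' identical; `mg/L` is scaled by 1000).  BLOQ cells are coded, not dropped.
#'
#' @param path Path to the table; tab-delimited when the extension is
#'   `.tsv`, comma-delimited otherwise.
#' @return A list of [conc_time_profile()] objects.
#' @export
read_profiles <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("subject_id", "species", "matrix", "route", "dose_mg_per_kg",
                "time", "time_unit", "conc", "conc_unit")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"loq" %in% names(df)) df$loq <- 0
  if (!"period" %in% names(df)) df$period <- 1L
  df$time_h <- convert_time(df$time, df$time_unit)
  df$conc_ugL <- convert_conc(df$conc, df$conc_unit)
  keys <- interaction(df$subject_id, df$matrix, df$period, drop = TRUE)
  lapply(split(df, keys), function(g) {
    if (any(diff(g$time_h) <= 0)) stop("non-monotone times", call. = FALSE)
    tau <- if ("tau_h" %in% names(g)) g$tau_h[1] else NA_real_
    conc_time_profile(
      g$subject_id[1], g$time_h, g$conc_ugL,
      dose = g$dose_mg_per_kg[1], route = g$route[1],
      species = g$species[1], matrix = g$matrix[1],
      tau = tau, loq = convert_conc(g$loq[1], g$conc_unit[1])
    )
  })
}

#' Write concentration-time profiles back to the long CSV schema
#'
#' Inverse of [read_profiles()]: canonical units (hours, ug/L), numerics at
#' full (17 significant digit) precision so a written-then-reread profile is
#' bitwise equal to the original.
#'
#' @param profiles A list of [conc_time_profile()]s (or one profile).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "conc_time_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, as.data.frame))
  df$bloq <- NULL
  if (all(is.na(df$tau_h))) df$tau_h <- NULL
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

convert_time <- function(x, unit) {
  mult <- c(h = 1, hr = 1, hour = 1, min = 1 / 60)[tolower(unit)]
  if (anyNA(mult)) stop("unknown time unit: ", paste(unique(unit[is.na(mult)]), collapse = ", "),
                        call. = FALSE)
  x * unname(mult)
}

convert_conc <- function(x, unit) {
  key <- tolower(gsub("µ", "u", unit))
  mult <- c("ug/l" = 1, "ng/ml" = 1, "ng/g" = 1, "mg/l" = 1000, "ug/ml" = 1000)[key]
  if (anyNA(mult)) stop("unknown concentration unit: ",
                        paste(unique(unit[is.na(mult)]), collapse = ", "), call. = FALSE)
  x * unname(mult)
}

#' Assemble an analysis report
#'
#' The common result container every assay analysis emits: a parameter table
#' in which every numeric value carries units and flags, plus provenance
#' (input-file MD5 digests, package version, configuration echo).
#'
#' @param assay Assay name.
#' @param parameters A data.frame with columns `name`, `value`, `units`,
#'   `flags` (character; `""` for none).
#' @param files Character vector of input files digested into provenance.
#' @param config The configuration list echoed into the report.
#' @return An object of class `analysis_report`.
#' @export
analysis_report <- function(assay, parameters, files = character(0), config = list()) {
  stopifnot(all(c("name", "value", "units") %in% names(parameters)))
  if (!"flags" %in% names(parameters)) parameters$flags <- ""
  rownames(parameters) <- NULL
  if (any(!is.na(parameters$value) & !nzchar(parameters$units))) {
    stop("every numeric parameter must carry units", call. = FALSE)
  }
  digests <- if (length(files)) as.list(tools::md5sum(files)) else list()
  structure(
    list(assay = assay, parameters = parameters,
         provenance = list(
           files = digests,
           package = "dmpkr",
           version = as.character(utils::packageVersion("dmpkr")),
           config = config
         )),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> assay: %s (%d parameters)\n",
              x$assay, nrow(x$parameters)))
  print(x$parameters, row.names = FALSE)
  invisible(x)
}

#' Serialize an analysis report
#'
#' Writes the report as JSON (`<path>`) and, optionally, the flat parameter
#' table as CSV.
#'
#' @param report An [analysis_report()].
#' @param path Output JSON path.
#' @param csv_path Optional CSV path for the parameter table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv_path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  if (!is.null(csv_path)) {
    utils::write.csv(report$parameters, csv_path, row.names = FALSE)
  }
  invisible(path)
}
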