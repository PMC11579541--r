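#' Physiological scaling constants for IVIVE
#'
#' Species-level constants used to scale microsomal intrinsic clearance to
#' whole-body units and to bound hepatic clearance by liver blood flow:
#' microsomal protein yield (MPPGL, mg microsomal protein per g liver,
#' 45 for all species), liver weight per kg body weight (g/kg) and hepatic
#' blood flow Qh (mL/min/kg).
#'
#' @param species One of `"rat"`, `"dog"`, `"monkey"`, `"human"`.
#' @return A list of class `species_scaling` with elements `species`,
#'   `mppgl` (mg/g), `liver_per_bw` (g/kg) and `qh` (mL/min/kg).
#' @examples
#' species_scaling("human")$qh   # 20.7 mL/min/kg
#' @export
species_scaling <- function(species) {
  species <- match_species(species)
  structure(
    list(
      species      = species,
      mppgl        = 45,
      liver_per_bw = c(rat = 40, dog = 32, monkey = 30, human = 25.7)[[species]],
      qh           = c(rat = 55.2, dog = 30.9, monkey = 43.6, human = 20.7)[[species]]
    ),
    class = "species_scaling"
  )
}

#' @export
print.species_scaling <- function(x, ...) {
  cat(sprintf(
    "<species_scaling> %s: MPPGL %g mg/g, liver %g g/kg BW, Qh %g mL/min/kg\n",
    x$species, x$mppgl, x$liver_per_bw, x$qh
  ))
  invisible(x)
}

# Loud lookup: an unknown species must never fall through to a default.
match_species <- function(species) {
  known <- c("rat", "dog", "monkey", "human")
  if (length(species) != 1L || is.na(species) || !species %in% known) {
    stop("unknown species '", paste(species, collapse = ","),
         "'; expected one of: ", paste(known, collapse = ", "), call. = FALSE)
  }
  species
}
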