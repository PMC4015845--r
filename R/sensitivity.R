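#' Molar concentration from a mass concentration
#'
#' Converts a protein mass concentration (ng/ml) and molecular weight (Da)
#' into a molar concentration in picomolar: a 50,000 Da protein at 1 ng/ml
#' is 20 pM. Exact arithmetic, vectorised.
#'
#' @param mass_concentration Mass concentration in ng/ml (> 0).
#' @param molecular_weight Molecular weight in Da (> 0).
#' @return Molarity in pM.
#' @examples
#' molarity_from_mass_conc(1, 50000) # 20 pM
#' @export
molarity_from_mass_conc <- function(mass_concentration, molecular_weight) {
  check_positive(mass_concentration, "mass_concentration")
  check_positive(molecular_weight, "molecular_weight")
  # ng/ml = 1e-6 g/L; divide by g/mol -> mol/L; 1 mol/L = 1e12 pM
  (mass_concentration * 1e-6 / molecular_weight) * 1e12
}

#' Mass concentration from a molar concentration
#'
#' Inverse of [molarity_from_mass_conc()].
#'
#' @param molarity Molarity in pM (> 0).
#' @param molecular_weight Molecular weight in Da (> 0).
#' @return Mass concentration in ng/ml.
#' @export
mass_conc_from_molarity <- function(molarity, molecular_weight) {
  check_positive(molarity, "molarity")
  check_positive(molecular_weight, "molecular_weight")
  molarity * 1e-12 * molecular_weight / 1e-6
}

#' Femtomoles delivered on column
#'
#' Amount of analyte loaded into the LC-MS system from a sample of given
#' molarity and volume: `molarity x volume x recovery`. At 20 pM and 100 µl
#' with perfect recovery, 2 fmol reaches the column — inside the 1–10 fmol
#' window an ion trap needs for identification.
#'
#' @param molarity Molarity in pM (> 0).
#' @param volume Sample volume in µl (> 0).
#' @param recovery Fraction of the analyte recovered through capture and
#'   fractionation, in (0, 1]; default 1 (efficient capture).
#' @return Amount in fmol.
#' @examples
#' amount_on_column(20, 100) # 2 fmol
#' @export
amount_on_column <- function(molarity, volume, recovery = 1) {
  check_positive(molarity, "molarity")
  check_positive(volume, "volume")
  if (any(recovery <= 0) || any(recovery > 1)) {
    abort("recovery must be in (0, 1]", class = "fedprot_domain_error")
  }
  # pM * µl = 1e-12 mol/L * 1e-6 L = 1e-18 mol = 1e-3 fmol
  molarity * volume * recovery * 1e-3
}

#' Is a protein detectable under a scenario?
#'
#' Full detection-limit arithmetic for a scenario (mass concentration,
#' molecular weight, sample volume, instrument limit): converts to molarity,
#' computes the femtomoles on column, and compares against the instrument
#' limit. Default limits of interest: 1 fmol (ion-trap detection limit) and
#' 10 fmol (reproducible confident identification).
#'
#' @param mass_concentration ng/ml (> 0).
#' @param molecular_weight Da (> 0).
#' @param sample_volume µl (> 0).
#' @param instrument_limit fmol on column required (default 1).
#' @param recovery Recovery fraction in (0, 1]; default 1.
#' @return A tibble with the inputs plus `molarity_pM`, `fmol_on_column`,
#'   `detectable` (`fmol_on_column >= instrument_limit`) and `margin`
#'   (ratio of delivered to required amount). Vectorised over all arguments.
#' @examples
#' detectable(1, 50000, 100) # 2 fmol vs 1 fmol: detectable, margin 2
#' @export
detectable <- function(mass_concentration, molecular_weight, sample_volume,
                       instrument_limit = 1, recovery = 1) {
  check_positive(instrument_limit, "instrument_limit")
  molarity <- molarity_from_mass_conc(mass_concentration, molecular_weight)
  fmol <- amount_on_column(molarity, sample_volume, recovery)
  tibble(
    mass_concentration = mass_concentration,
    molecular_weight = molecular_weight,
    sample_volume = sample_volume,
    instrument_limit = instrument_limit,
    recovery = recovery,
    molarity_pM = molarity,
    fmol_on_column = fmol,
    detectable = fmol >= instrument_limit,
    margin = fmol / instrument_limit
  )
}

#' Detection-limit grid
#'
#' Evaluates [detectable()] over the Cartesian grid of the supplied values —
#' handy for mapping which concentration/volume combinations clear the
#' instrument limit.
#'
#' @inheritParams detectable
#' @return A tibble, one row per grid point.
#' @export
detection_grid <- function(mass_concentration, molecular_weight, sample_volume,
                           instrument_limit = c(1, 10), recovery = 1) {
  grid <- tidyr::expand_grid(
    mass_concentration = mass_concentration,
    molecular_weight = molecular_weight,
    sample_volume = sample_volume,
    instrument_limit = instrument_limit,
    recovery = recovery
  )
  detectable(
    grid$mass_concentration, grid$molecular_weight, grid$sample_volume,
    grid$instrument_limit, grid$recovery
  )
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0)) {
    abort(sprintf("%s must be strictly positive", name), class = "fedprot_domain_error")
  }
  invisible(x)
}
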