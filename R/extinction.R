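## Hemoglobin extinction handling. The coefficients are configuration, not
## constants: the shipped CSV approximates a standard tabulated
## compilation and only anchors the 532/558-nm unmixing system; supply
## your own table for quantitative spectroscopy.

#' Read a molar extinction table
#'
#' @param path CSV with header `wavelength_nm,eps_hbo2,eps_hbr`
#'   (L mol^-1 cm^-1).
#' @return an [ExtinctionTable].
#' @export
readExtinctionTable <- function(path) {
  if (!file.exists(path)) stop("extinction table not found: ", path)
  d <- utils::read.csv(path, comment.char = "#")
  new("ExtinctionTable", data = d)
}

#' @describeIn readExtinctionTable the table shipped with the package.
#' @export
defaultExtinctionTable <- function() {
  readExtinctionTable(system.file("extdata", "hemoglobin_extinction.csv",
                                  package = "dcpam", mustWork = TRUE))
}

## epsilon lookup for one wavelength; exact match required
extinctionAt <- function(table, wavelengthNm) {
  d <- table@data
  i <- match(wavelengthNm, d$wavelength_nm)
  if (is.na(i))
    stop(sprintf("wavelength %g nm not in table; available: %s",
                 wavelengthNm,
                 paste(d$wavelength_nm, collapse = ", ")))
  c(eps_hbo2 = d$eps_hbo2[i], eps_hbr = d$eps_hbr[i])
}

## 2x2 extinction matrix at (532, 558); rows = wavelengths, cols =
## (HbO2, HbR)
extinctionMatrix2 <- function(table, wavelengths = c(532, 558)) {
  rbind(extinctionAt(table, wavelengths[1]),
        extinctionAt(table, wavelengths[2]))
}

#' Optical absorption coefficient of a hemoglobin mixture
#'
#' Beer-Lambert composition, `mu_a = ln(10) * (eps_HbO2(lambda) * c_HbO2 +
#' eps_HbR(lambda) * c_HbR)` in cm^-1 (molar extinction uses the base-10
#' convention, hence the explicit ln(10); the factor is common to both
#' wavelengths and cancels in sO2).
#'
#' @param cHbO2,cHbR concentrations (mol/L); scalars or equally shaped
#'   arrays.
#' @param wavelengthNm excitation wavelength; must be present in `table`.
#' @param table an [ExtinctionTable].
#' @return absorption coefficient(s), cm^-1.
#' @examples
#' absorptionCoefficient(2.3e-3, 0, 532, defaultExtinctionTable())
#' @export
absorptionCoefficient <- function(cHbO2, cHbR, wavelengthNm, table) {
  if (any(cHbO2 < 0) || any(cHbR < 0)) stop("concentrations must be >= 0")
  eps <- extinctionAt(table, wavelengthNm)
  log(10) * (eps[["eps_hbo2"]] * cHbO2 + eps[["eps_hbr"]] * cHbR)
}

## mu_a volume [y, x, z] of a phantom at one wavelength
absorptionVolume <- function(phantom, wavelengthNm, table) {
  absorptionCoefficient(phantom@cHbO2, phantom@cHbR, wavelengthNm, table)
}
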