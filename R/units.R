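#' Unit conversions
#'
#' The solver works internally in CGS units: lengths in cm, mass in g,
#' time in s, stress and pressure in dyne/cm^2 (barye). Configuration
#' interfaces use the clinical/constitutive literature units instead:
#' stresses in kPa, pressures in mmHg, volumes in ml. These helpers
#' convert between the two; 1 kPa = 1e4 dyne/cm^2 and
#' 1 mmHg = 1333.22 dyne/cm^2.
#'
#' @param x numeric vector of values to convert.
#' @return Numeric vector of converted values.
#' @examples
#' kpa_to_barye(100)        # the volumetric penalty scale, 1e6 dyne/cm^2
#' mmhg_to_barye(8)         # a typical end-diastolic pressure
#' barye_to_kpa(mmhg_to_barye(150))
#' @name units
NULL

#' @rdname units
#' @export
kpa_to_barye <- function(x) x * 1e4

#' @rdname units
#' @export
barye_to_kpa <- function(x) x * 1e-4

#' @rdname units
#' @export
mmhg_to_barye <- function(x) x * 1333.22

#' @rdname units
#' @export
barye_to_mmhg <- function(x) x / 1333.22
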