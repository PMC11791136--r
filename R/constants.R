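#' Physical constants for Nernstian calculations
#'
#' Bundle of the Faraday constant, the ideal gas constant and the working
#' temperature used throughout the package.  The defaults are the values
#' used for the spectroelectrochemical analysis of the diheme cytochrome:
#' F = 96485.34 J V^-1 mol^-1, R = 8.3145 J mol^-1 K^-1, T = 293 K.
#'
#' The quantity that actually enters every Nernstian expression is
#' `F/(R*T)`, about 39.6 V^-1 at 293 K; `thermal_voltage()` returns its
#' reciprocal, `RT/F` (about 25.25 mV).
#'
#' @param temperature Working temperature in kelvin.
#' @param faraday Faraday constant in J V^-1 mol^-1.
#' @param gas_constant Ideal gas constant in J mol^-1 K^-1.
#' @return An object of class `redox_constants`.
#' @examples
#' k <- redox_constants()
#' thermal_voltage(k)  # RT/F in volts
#' @export
redox_constants <- function(temperature = 293,
                            faraday = 96485.34,
                            gas_constant = 8.3145) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0,
            is.numeric(faraday), faraday > 0,
            is.numeric(gas_constant), gas_constant > 0)
  structure(list(faraday = faraday,
                 gas_constant = gas_constant,
                 temperature = temperature),
            class = "redox_constants")
}

#' @rdname redox_constants
#' @param constants A `redox_constants` object.
#' @export
thermal_voltage <- function(constants = redox_constants()) {
  stopifnot(inherits(constants, "redox_constants"))
  constants$gas_constant * constants$temperature / constants$faraday
}

#' @export
print.redox_constants <- function(x, ...) {
  cat(sprintf("Redox constants: F = %.2f J/V/mol, R = %.4f J/mol/K, T = %g K\n",
              x$faraday, x$gas_constant, x$temperature))
  cat(sprintf("  RT/F = %.3f mV\n", 1000 * thermal_voltage(x)))
  invisible(x)
}
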