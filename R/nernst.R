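#' Define a set of one-electron redox transitions
#'
#' A transition set is the parameter table of the multi-transition
#' Nernstian model: each row has a midpoint potential (V vs SHE), an
#' amplitude in absorbance units, and the number of electrons transferred
#' (z, 1 unless overridden).
#'
#' @param midpoint Numeric vector of midpoint potentials, V vs SHE.
#' @param amplitude Numeric vector of non-negative amplitudes
#'   (dimensionless absorbance units), recycled against `midpoint`.
#' @param electrons Integer vector of electrons per transition, default 1.
#' @return A data frame of class `transition_set`, sorted ascending by
#'   midpoint.
#' @examples
#' # The two transitions of the as-isolated wild-type protein:
#' transition_set(c(0.353, -0.092), c(0.85, 0.15))
#' @export
transition_set <- function(midpoint, amplitude = 1, electrons = 1L) {
  stopifnot(is.numeric(midpoint), all(is.finite(midpoint)),
            is.numeric(amplitude), all(is.finite(amplitude)),
            all(amplitude >= 0))
  n <- length(midpoint)
  amplitude <- rep_len(amplitude, n)
  electrons <- rep_len(as.integer(electrons), n)
  stopifnot(all(electrons >= 1L))
  out <- data.frame(midpoint = midpoint, amplitude = amplitude,
                    electrons = electrons)
  out <- out[order(out$midpoint), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transition_set", "data.frame")
  out
}

#' Multi-transition Nernstian response
#'
#' Evaluates the reduced-minus-oxidized absorbance signal
#' \deqn{Y(E) = \sum_i \frac{a_i}{\exp[(z_i F / RT)(E - E_{m,i})] + 1}}
#' at applied potential(s) `E`.  Each term is a one-electron (by default)
#' Nernst sigmoid: at `E` far below a midpoint the couple is fully reduced
#' and the term contributes its full amplitude `a_i`; far above, it
#' contributes zero.  `Y` therefore decreases monotonically from
#' `sum(a_i)` to 0 as the potential is raised.
#'
#' @param potential Numeric vector of potentials, V vs SHE.
#' @param transitions A [transition_set()].
#' @param constants A [redox_constants()] object.
#' @return Numeric vector of `Y` values, same length as `potential`.
#' @examples
#' tr <- transition_set(0.0, 1)
#' nernst_response(0.0, tr)   # 0.5 at the midpoint
#' @export
nernst_response <- function(potential, transitions,
                            constants = redox_constants()) {
  stopifnot(is.numeric(potential), inherits(constants, "redox_constants"))
  if (!all(is.finite(potential)))
    stop("non-finite potential values", call. = FALSE)
  if (!inherits(transitions, "transition_set"))
    transitions <- as_transition_set(transitions)
  f <- 1 / thermal_voltage(constants)   # F/(RT), V^-1
  y <- numeric(length(potential))
  for (i in seq_len(nrow(transitions))) {
    zi <- transitions$electrons[i]
    y <- y + transitions$amplitude[i] /
      (exp(zi * f * (potential - transitions$midpoint[i])) + 1)
  }
  y
}

as_transition_set <- function(x) {
  if (inherits(x, "transition_set")) return(x)
  if (is.data.frame(x) && all(c("midpoint", "amplitude") %in% names(x))) {
    el <- if ("electrons" %in% names(x)) x$electrons else 1L
    return(transition_set(x$midpoint, x$amplitude, el))
  }
  stop("cannot interpret object as a transition set", call. = FALSE)
}

#' Paired four-transition model
#'
#' Parameterization used for titrations of partially calcium-loaded
#' protein: four one-electron transitions arranged as two closely spaced
#' pairs.  The high-potential pair corresponds to the calcium-loaded hemes
#' and the low-potential pair to the calcium-free hemes.  Both pairs share
#' the same within-pair spacing, members sit at `center +/- spacing/2`,
#' and the two members of a pair have identical amplitude.
#'
#' The defaults are the fitted values for the wild-type protein titrated
#' in the presence of 10 mM calcium: pair centers at -130.5 and +370 mV
#' vs SHE, 30 mV within-pair spacing, per-member amplitudes 0.06 (low)
#' and 0.44 (high), which expand to individual transitions near -145,
#' -116, +355 and +385 mV and a calcium-site occupancy of 88%.
#'
#' @param low_center,high_center Pair centers, V vs SHE.
#' @param spacing Shared within-pair spacing, V (>= 0).
#' @param a_low,a_high Per-member amplitudes (>= 0) of the low- and
#'   high-potential pairs.
#' @return An object of class `paired_model`.
#' @seealso [expand_pairs()], [pair_occupancy()]
#' @export
paired_model <- function(low_center = -0.1305, high_center = 0.370,
                         spacing = 0.030, a_low = 0.06, a_high = 0.44) {
  stopifnot(is.numeric(low_center), is.numeric(high_center),
            is.numeric(spacing), spacing >= 0,
            a_low >= 0, a_high >= 0)
  structure(list(low_center = low_center, high_center = high_center,
                 spacing = spacing, a_low = a_low, a_high = a_high),
            class = "paired_model")
}

#' Expand a paired model to its four individual transitions
#'
#' @param model A [paired_model()].
#' @return A [transition_set()] with four rows (members at
#'   `center +/- spacing/2`, pair members sharing one amplitude).
#' @export
expand_pairs <- function(model) {
  stopifnot(inherits(model, "paired_model"))
  h <- model$spacing / 2
  transition_set(
    midpoint = c(model$low_center - h, model$low_center + h,
                 model$high_center - h, model$high_center + h),
    amplitude = c(model$a_low, model$a_low, model$a_high, model$a_high))
}

#' Calcium-site occupancy implied by a paired model
#'
#' The fractional amplitude of the high-potential (calcium-loaded) pair:
#' `2*a_high / (2*a_high + 2*a_low)`.  Two member amplitudes of 0.44
#' against two of 0.06 give 88% occupancy.
#'
#' @param model A [paired_model()].
#' @return Occupancy as a fraction in \[0, 1\].
#' @export
pair_occupancy <- function(model) {
  stopifnot(inherits(model, "paired_model"))
  tot <- 2 * model$a_high + 2 * model$a_low
  if (tot <= 0) return(NA_real_)
  2 * model$a_high / tot
}

#' @export
print.paired_model <- function(x, ...) {
  cat("Paired four-transition Nernst model\n")
  cat(sprintf("  pair centers: %+.1f / %+.1f mV vs SHE (separation %.1f mV)\n",
              1000 * x$low_center, 1000 * x$high_center,
              1000 * (x$high_center - x$low_center)))
  cat(sprintf("  within-pair spacing: %.1f mV\n", 1000 * x$spacing))
  cat(sprintf("  member amplitudes: low %.3f, high %.3f (occupancy %.1f%%)\n",
              x$a_low, x$a_high, 100 * pair_occupancy(x)))
  invisible(x)
}
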