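#' Spectroelectrochemical titration curve
#'
#' A titration curve records the optical response (typically absorbance
#' at the Soret band, 417 nm) at a series of applied potentials within
#' one titration branch.  Potentials are tagged with their reference
#' frame: `"raw"` for the instrument's reference electrode scale and
#' `"SHE"` after correction to the standard hydrogen electrode (see
#' [she_correct()]).
#'
#' @param potential Numeric vector of potentials (V), strictly monotone
#'   within the branch.
#' @param absorbance Numeric vector, same length as `potential`.
#' @param branch One of `"oxidative"`, `"reductive"`, `"averaged"`.
#' @param frame Reference frame of the potentials: `"raw"` or `"SHE"`.
#' @param errors Optional non-negative per-point standard deviations.
#' @return An object of class `titration_curve` (a data frame with
#'   attributes `branch` and `frame`).
#' @export
titration_curve <- function(potential, absorbance,
                            branch = c("oxidative", "reductive", "averaged"),
                            frame = c("raw", "SHE"),
                            errors = NULL) {
  branch <- match.arg(branch)
  frame <- match.arg(frame)
  stopifnot(is.numeric(potential), is.numeric(absorbance),
            length(potential) == length(absorbance),
            all(is.finite(potential)), all(is.finite(absorbance)))
  if (length(potential) >= 2) {
    d <- diff(potential)
    if (!(all(d > 0) || all(d < 0)))
      stop("potentials must be strictly monotone within a branch",
           call. = FALSE)
  }
  if (!is.null(errors)) {
    stopifnot(is.numeric(errors), length(errors) == length(potential),
              all(errors >= 0 | is.na(errors)))
  }
  out <- data.frame(potential = potential, absorbance = absorbance)
  if (!is.null(errors)) out$errors <- errors
  structure(out, branch = branch, frame = frame,
            class = c("titration_curve", "data.frame"))
}

curve_frame <- function(curve) attr(curve, "frame")
curve_branch <- function(curve) attr(curve, "branch")

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("Titration curve: %d points, %s branch, potentials vs %s\n",
              nrow(x), curve_branch(x),
              if (curve_frame(x) == "SHE") "SHE" else "raw reference"))
  cat(sprintf("  potential range: %+.0f to %+.0f mV\n",
              1000 * min(x$potential), 1000 * max(x$potential)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

#' Stack of UV-Vis spectra indexed by applied potential
#'
#' @param wavelength Numeric wavelength grid in nm.
#' @param potential Numeric vector of applied potentials (V).
#' @param absorbance Matrix, `length(wavelength)` rows by
#'   `length(potential)` columns.
#' @param frame Reference frame of the potentials (`"raw"` or `"SHE"`).
#' @return An object of class `spectra_stack`.
#' @export
spectra_stack <- function(wavelength, potential, absorbance,
                          frame = c("raw", "SHE")) {
  frame <- match.arg(frame)
  absorbance <- as.matrix(absorbance)
  stopifnot(is.numeric(wavelength), is.numeric(potential),
            nrow(absorbance) == length(wavelength),
            ncol(absorbance) == length(potential),
            all(is.finite(absorbance)))
  if (length(wavelength) == 0 || length(potential) == 0)
    stop("empty spectra stack", call. = FALSE)
  structure(list(wavelength = wavelength, potential = potential,
                 absorbance = absorbance, frame = frame),
            class = "spectra_stack")
}

#' @export
print.spectra_stack <- function(x, ...) {
  cat(sprintf("Spectra stack: %d wavelengths (%g-%g nm) x %d potentials\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              length(x$potential)))
  invisible(x)
}

#' Zero each spectrum at a baseline wavelength
#'
#' For every potential column the absorbance at the baseline wavelength
#' (700 nm by default, where the heme chromophore does not absorb) is
#' subtracted from the whole column, so that each spectrum reads zero
#' there.
#'
#' @param stack A [spectra_stack()].
#' @param baseline_wavelength Wavelength (nm) whose absorbance is set to
#'   zero; must lie within the stack's grid.
#' @return A baseline-corrected `spectra_stack`.
#' @export
baseline_correct <- function(stack, baseline_wavelength = 700) {
  stopifnot(inherits(stack, "spectra_stack"))
  if (baseline_wavelength < min(stack$wavelength) ||
      baseline_wavelength > max(stack$wavelength))
    stop(sprintf("baseline wavelength %g nm outside the grid [%g, %g]",
                 baseline_wavelength, min(stack$wavelength),
                 max(stack$wavelength)), call. = FALSE)
  i <- which.min(abs(stack$wavelength - baseline_wavelength))
  offsets <- stack$absorbance[i, ]
  stack$absorbance <- sweep(stack$absorbance, 2, offsets, "-")
  stack
}

#' Extract a single-wavelength titration trace from a spectra stack
#'
#' Selects the wavelength row nearest to the requested monitoring
#' wavelength (417 nm by default, where the largest redox-linked
#' absorbance change occurs) and returns it as a [titration_curve()].
#'
#' @param stack A [spectra_stack()].
#' @param wavelength Monitoring wavelength in nm; the nearest grid point
#'   is used.
#' @param branch Branch label to attach to the resulting curve.
#' @return A `titration_curve` carrying the stack's reference frame.
#' @export
extract_trace <- function(stack, wavelength = 417,
                          branch = c("oxidative", "reductive", "averaged")) {
  stopifnot(inherits(stack, "spectra_stack"))
  branch <- match.arg(branch)
  i <- which.min(abs(stack$wavelength - wavelength))
  titration_curve(stack$potential, stack$absorbance[i, ],
                  branch = branch, frame = stack$frame)
}

#' Correct applied potentials to the SHE scale
#'
#' Adds the reference-electrode offset to every potential and retags the
#' curve as SHE-referenced.  The default offset, +0.200 V, is the
#' potential of the Ag-AgCl-4M-KCl reference electrode used for the
#' titrations.  Applying the correction to a curve already in the SHE
#' frame is an error.
#'
#' @param curve A [titration_curve()] in the raw reference frame.
#' @param reference_offset Reference electrode potential vs SHE, in V.
#' @return The curve with shifted potentials, tagged `"SHE"`.
#' @export
she_correct <- function(curve, reference_offset = 0.200) {
  stopifnot(inherits(curve, "titration_curve"),
            is.numeric(reference_offset), is.finite(reference_offset))
  if (curve_frame(curve) == "SHE")
    stop("curve is already SHE-referenced; refusing to shift twice",
         call. = FALSE)
  out <- titration_curve(curve$potential + reference_offset,
                         curve$absorbance,
                         branch = curve_branch(curve), frame = "SHE",
                         errors = curve[["errors"]])
  out
}

#' Pool oxidative and reductive branches for joint averaging
#'
#' Reorders every curve to ascending potential and relabels it
#' `"averaged"`, so that oxidative and reductive sweeps of the same
#' series can be averaged together with [average_replicates()].  Only
#' appropriate when hysteresis is negligible; with visible hysteresis
#' the branches should be fitted separately instead.
#'
#' @param curves A list of [titration_curve()]s.
#' @return The list with each curve sorted ascending and branch-tagged
#'   `"averaged"`.
#' @export
pool_branches <- function(curves) {
  stopifnot(is.list(curves),
            all(vapply(curves, inherits, TRUE, "titration_curve")))
  lapply(curves, function(cv) {
    ord <- order(cv$potential)
    titration_curve(cv$potential[ord], cv$absorbance[ord],
                    branch = "averaged", frame = curve_frame(cv),
                    errors = cv[["errors"]][ord])
  })
}

#' Average replicate titration curves
#'
#' Pointwise mean over replicate curves measured on the same potential
#' grid and branch, with the pointwise sample standard deviation stored
#' as the per-point error.  A single curve is returned unchanged with a
#' warning (no spread can be estimated).
#'
#' @param curves A list of [titration_curve()] objects sharing the same
#'   potential grid, branch and reference frame.
#' @return A `titration_curve` with `errors` filled in (for >= 2
#'   replicates).
#' @export
average_replicates <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1,
            all(vapply(curves, inherits, TRUE, "titration_curve")))
  ref <- curves[[1]]
  if (length(curves) == 1L) {
    warning("single replicate: returning the curve unchanged, no errors",
            call. = FALSE)
    return(ref)
  }
  for (cv in curves[-1]) {
    if (!isTRUE(all.equal(cv$potential, ref$potential)) ||
        curve_branch(cv) != curve_branch(ref) ||
        curve_frame(cv) != curve_frame(ref))
      stop("replicate curves must share potential grid, branch and frame",
           call. = FALSE)
  }
  mat <- vapply(curves, function(cv) cv$absorbance,
                numeric(nrow(ref)))
  titration_curve(ref$potential, rowMeans(mat),
                  branch = curve_branch(ref), frame = curve_frame(ref),
                  errors = apply(mat, 1, stats::sd))
}
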