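#' Read titration data from a delimited text file
#'
#' Expects a header row with columns `potential_V` and `absorbance`,
#' plus optional `replicate` and `branch` columns.  Returns one
#' [titration_curve()] per (replicate, branch) combination.
#'
#' @param file Path to a CSV (or TSV, `sep = "\t"`) file.
#' @param frame Reference frame declared for the potentials.
#' @param sep Field separator.
#' @return A list of `titration_curve` objects.
#' @export
read_titration_csv <- function(file, frame = c("raw", "SHE"), sep = ",") {
  frame <- match.arg(frame)
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("potential_V", "absorbance")
  if (!all(need %in% names(tab)))
    stop(sprintf("missing required columns: %s",
                 paste(setdiff(need, names(tab)), collapse = ", ")),
         call. = FALSE)
  tab$replicate <- tab[["replicate"]] %||% 1L
  tab$branch <- tab[["branch"]] %||% "oxidative"
  split_by <- interaction(tab$replicate, tab$branch, drop = TRUE)
  lapply(split(tab, split_by), function(d)
    titration_curve(d$potential_V, d$absorbance,
                    branch = d$branch[1], frame = frame))
}

#' Read a spectra stack from a CSV matrix
#'
#' First column `wavelength_nm`; remaining columns are spectra named by
#' their applied potential in volts (a leading "X" or "V" prefix added
#' by spreadsheet tools is tolerated).
#'
#' @param file Path to the CSV file.
#' @param frame Reference frame declared for the potentials.
#' @return A [spectra_stack()].
#' @export
read_spectra_csv <- function(file, frame = c("raw", "SHE")) {
  frame <- match.arg(frame)
  tab <- utils::read.csv(file, check.names = FALSE)
  if (names(tab)[1] != "wavelength_nm")
    stop("first column must be 'wavelength_nm'", call. = FALSE)
  pots <- suppressWarnings(as.numeric(sub("^[XV]", "", names(tab)[-1])))
  if (any(is.na(pots)))
    stop("spectra column names must be numeric potentials (V)",
         call. = FALSE)
  spectra_stack(tab[[1]], pots, as.matrix(tab[, -1, drop = FALSE]),
                frame = frame)
}

#' Write a titration curve to CSV
#'
#' @param curve A [titration_curve()].
#' @param file Output path.
#' @export
write_titration_csv <- function(curve, file) {
  stopifnot(inherits(curve, "titration_curve"))
  d <- as.data.frame(curve)
  names(d)[1:2] <- c("potential_V", "absorbance")
  d$branch <- curve_branch(curve)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Export a Nernst fit as a JSON record plus a fitted-curve CSV
#'
#' The JSON record carries the model tag, the transitions in mV vs SHE
#' with their 1-sigma uncertainties, amplitudes, the oxidized baseline,
#' the residual norm and (for the paired model) the calcium-site
#' occupancy.  The CSV holds the data together with the fitted curve.
#'
#' @param fit A [nernst_fit()] result.
#' @param json_file,csv_file Output paths (`NULL` to skip either).
#' @return Invisibly, the report list that was serialized.
#' @export
write_fit_report <- function(fit, json_file = NULL, csv_file = NULL) {
  stopifnot(inherits(fit, "nernst_fit"))
  tr <- fit$transitions
  rec <- list(
    model = fit$model_tag,
    transitions = data.frame(
      midpoint_mV = 1000 * tr$midpoint,
      se_mV = 1000 * tr$se_midpoint,
      amplitude = tr$amplitude,
      se_amplitude = tr$se_amplitude),
    oxidized_baseline = fit$oxidized_baseline,
    residual_norm = fit$residual_norm,
    constants = unclass(fit$constants))
  if (!is.null(fit$paired)) {
    pm <- fit$paired$model
    rec$paired <- list(
      low_center_mV = 1000 * pm$low_center,
      high_center_mV = 1000 * pm$high_center,
      pair_separation_mV = 1000 * (pm$high_center - pm$low_center),
      spacing_mV = 1000 * pm$spacing,
      occupancy_percent = 100 * fit$paired$occupancy)
  }
  if (!is.null(json_file))
    jsonlite::write_json(rec, json_file, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(csv_file)) {
    d <- data.frame(potential_V = fit$data$potential,
                    absorbance = fit$data$absorbance,
                    fitted = fitted(fit))
    utils::write.csv(d, csv_file, row.names = FALSE)
  }
  invisible(rec)
}

#' Write a distance survey as CSV and JSON summary
#'
#' @param survey A [distance_survey()].
#' @param csv_file,json_file Output paths (`NULL` to skip either).
#' @return Invisibly, the summary list.
#' @export
write_survey <- function(survey, csv_file = NULL, json_file = NULL) {
  stopifnot(inherits(survey, "distance_survey"))
  if (!is.null(csv_file))
    utils::write.csv(survey$distances, csv_file, row.names = FALSE)
  summ <- list(n_structures = survey$n_structures,
               n_structures_with_pairs = survey$n_structures_with_pairs,
               n_distances = survey$n_distances,
               global_min = survey$global_min,
               per_entry_min = survey$per_entry_min)
  if (!is.null(json_file))
    jsonlite::write_json(summ, json_file, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(summ)
}
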