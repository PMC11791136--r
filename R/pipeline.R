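#' End-to-end titration analysis
#'
#' Orchestrates one full titration analysis: (spectra stack ->
#' baseline-correct at 700 nm -> extract the 417 nm trace) or
#' (titration curves directly) -> SHE correction -> replicate averaging
#' -> Nernst fit with the chosen model.  Inputs may be in-memory
#' objects or file paths.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{`curves`}{list of [titration_curve()]s (replicates), or}
#'     \item{`stacks`}{list of [spectra_stack()]s (replicates), or}
#'     \item{`curve_files` / `spectra_files`}{paths read with
#'       [read_titration_csv()] / [read_spectra_csv()];}
#'     \item{`model`}{`"free"`, `"paired4"` or `"mutant3"`;}
#'     \item{`n_transitions`}{for the free model;}
#'     \item{`wavelength`}{monitoring wavelength, default 417 nm;}
#'     \item{`baseline_wavelength`}{default 700 nm;}
#'     \item{`reference_offset`}{V, default 0.200;}
#'     \item{`fix_aox`}{optional fixed oxidized baseline;}
#'     \item{`constants`}{a [redox_constants()], default package values.}
#'   }
#' @return A list of class `calredox_report` with the fit, fitted
#'   quantities in mV vs SHE, occupancy (paired model), the averaged
#'   curve, warnings collected along the way, and the configuration
#'   echoed for provenance.
#' @export
run_titration_pipeline <- function(config) {
  stopifnot(is.list(config))
  constants <- config$constants %||% redox_constants()
  wl <- config$wavelength %||% 417
  bwl <- config$baseline_wavelength %||% 700
  offset <- config$reference_offset %||% 0.200
  model <- config$model %||% "free"
  warnings <- character(0)
  note <- function(w) warnings <<- c(warnings, w)

  curves <- config$curves
  if (is.null(curves) && !is.null(config$curve_files))
    curves <- unlist(lapply(config$curve_files, read_titration_csv),
                     recursive = FALSE)
  if (is.null(curves)) {
    stacks <- config$stacks
    if (is.null(stacks) && !is.null(config$spectra_files))
      stacks <- lapply(config$spectra_files, read_spectra_csv)
    if (is.null(stacks) || length(stacks) == 0)
      stop("config must supply curves, stacks or input files",
           call. = FALSE)
    curves <- lapply(stacks, function(st)
      extract_trace(baseline_correct(st, bwl), wl))
  }
  if (length(curves) == 0) stop("no input curves", call. = FALSE)

  curves <- lapply(curves, function(cv)
    if (curve_frame(cv) == "raw") she_correct(cv, offset) else cv)
  branches <- unique(vapply(curves, curve_branch, character(1)))
  if (length(branches) > 1) curves <- pool_branches(curves)
  averaged <- if (length(curves) > 1)
    average_replicates(curves)
  else withCallingHandlers(average_replicates(curves),
                           warning = function(w) {
                             note(conditionMessage(w))
                             invokeRestart("muffleWarning")
                           })

  fit <- withCallingHandlers(
    nernst_fit(averaged, model = model,
               n_transitions = config$n_transitions,
               fix_aox = config$fix_aox, constants = constants),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  tr <- fit$transitions
  structure(list(
    kind = "titration",
    fit = fit,
    midpoints_mV = 1000 * tr$midpoint,
    se_midpoints_mV = 1000 * tr$se_midpoint,
    amplitudes = tr$amplitude,
    occupancy_percent = if (!is.null(fit$paired))
      100 * occupancy(fit) else NA_real_,
    residual_norm = fit$residual_norm,
    curve = averaged,
    constants = unclass(constants),
    reference_offset = offset,
    warnings = warnings,
    config = config[setdiff(names(config),
                            c("curves", "stacks", "constants"))]),
    class = "calredox_report")
}

#' End-to-end dye-competition Kd estimation
#'
#' Builds the fluorescence calibration from the calibration series,
#' converts the assay signals to Ca-dye complex concentrations,
#' averages replicates, and runs the curve-family comparison to report
#' an upper limit for the protein's apparent calcium Kd.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{`calibration`}{data frame `total_ca` (mol/L), `signal`;}
#'     \item{`assay`}{data frame `protein_conc` (mol/L), `replicate`,
#'       `signal`;}
#'     \item{`egta`, `dye`}{[ligand()]s of the calibration buffer
#'       (defaults: 5 mM EGTA at Kd 1.0e-7 M; 20 uM CalBryte-590 at
#'       Kd 1.4e-6 M);}
#'     \item{`sites_per_protein`}{default 1.6;}
#'     \item{`background_calcium`}{mol/L; estimated from the
#'       protein-free assay wells when absent;}
#'     \item{`kd_grid`}{candidate grid, default 1e-9 to 1e-5 M;}
#'     \item{`level`}{chi-squared consistency level, default 0.95.}
#'   }
#' @return A `calredox_report` list with the calibration model, the
#'   averaged observed series, the [estimate_kd_upper_limit()] result
#'   and the criterion used.
#' @export
run_kd_pipeline <- function(config) {
  stopifnot(is.list(config), is.data.frame(config$calibration),
            is.data.frame(config$assay))
  dye <- config$dye %||% ligand("CalBryte-590", 1.4e-6, 2e-5)
  egta <- config$egta %||% ligand("EGTA", 1.0e-7, 5e-3)
  sites <- config$sites_per_protein %||% 1.6
  kd_grid <- config$kd_grid %||% 10^seq(-9, -5, length.out = 40)
  level <- config$level %||% 0.95
  warnings <- character(0)

  cal <- config$calibration
  systems <- lapply(cal$total_ca, function(ca)
    competition_system(ca, list(egta, dye)))
  calib <- build_calibration(cal$signal, systems, dye_name = dye$name)

  assay <- config$assay
  assay$complex <- apply_calibration(calib, assay$signal)
  # calibration inversion error propagates into every converted point
  cal_rms <- sqrt(mean(calib$residuals^2))
  agg <- stats::aggregate(complex ~ protein_conc, assay, mean)
  nrep <- stats::aggregate(complex ~ protein_conc, assay, length)$complex
  if (any(nrep < 2)) {
    warnings <- c(warnings,
                  "replicate-free input: unweighted criterion (pooled SD)")
    sds <- rep(stats::sd(assay$complex -
                         agg$complex[match(assay$protein_conc,
                                           agg$protein_conc)]) %||% NA,
               nrow(agg))
    if (any(!is.finite(sds)) || any(sds <= 0))
      sds <- rep(0.05 * max(agg$complex), nrow(agg))
  } else {
    # pool replicate SDs (RMS across concentrations): per-point SDs from
    # triplicates are too noisy to weight a chi-squared criterion
    sds <- stats::aggregate(complex ~ protein_conc, assay,
                            stats::sd)$complex
    sds <- rep(sqrt(mean(sds^2)), length(sds))
  }
  sds <- sqrt(sds^2 + cal_rms^2)
  background <- config$background_calcium
  if (is.null(background)) {
    prot_free <- agg$complex[agg$protein_conc == 0]
    if (length(prot_free) != 1)
      stop("supply background_calcium or include protein-free wells",
           call. = FALSE)
    # invert the dye-only equilibrium: total Ca giving this complex
    cplx <- prot_free
    free <- cplx * dye$kd / (dye$total - cplx)
    background <- free + cplx
  }
  est <- estimate_kd_upper_limit(agg$protein_conc, agg$complex, sds,
                                 kd_grid = kd_grid, level = level,
                                 sites_per_protein = sites,
                                 background_calcium = background,
                                 dye = dye)
  structure(list(
    kind = "kd",
    calibration = calib,
    observed = data.frame(protein_conc = agg$protein_conc,
                          complex = agg$complex, sd = sds),
    background_calcium = background,
    estimate = est,
    upper_limit_M = est$upper_limit,
    unbounded = est$unbounded,
    criterion = sprintf("chi-squared <= %.2f (%.0f%% level, df = %d)",
                        est$criterion, 100 * level, nrow(agg)),
    warnings = warnings,
    config = config[setdiff(names(config), c("calibration", "assay"))]),
    class = "calredox_report")
}

#' End-to-end structure survey
#'
#' Parses every structure, finds heme-iron and calcium sites, computes
#' all Fe-Ca distances and aggregates them into a [distance_survey()].
#' Unreadable files are listed in the report and the run continues.
#'
#' @param config A list with `files` (paths) and/or `models` (parsed
#'   [read_structure()] objects), and optionally `heme_residues`.
#' @return A `calredox_report` list with the survey, the global minimum
#'   distance with provenance, and any per-file errors.
#' @export
run_survey_pipeline <- function(config) {
  stopifnot(is.list(config))
  heme <- config$heme_residues %||% c("HEM", "HEC")
  models <- config$models %||% list()
  errors <- character(0)
  for (f in config$files %||% character(0)) {
    m <- tryCatch(read_structure(f), error = function(e)
      conditionMessage(e))
    if (is.character(m)) errors <- c(errors, m)
    else models <- c(models, list(m))
  }
  if (length(models) == 0)
    stop("no readable structures supplied", call. = FALSE)
  sv <- withCallingHandlers(
    distance_survey(models, heme_residues = heme),
    warning = function(w) {
      errors <<- c(errors, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  structure(list(
    kind = "survey",
    survey = sv,
    global_min_A = if (!sv$empty) sv$global_min$distance else NA_real_,
    global_min_entry = if (!sv$empty) sv$global_min$entry else NA_character_,
    n_distances = sv$n_distances,
    errors = errors,
    config = config[setdiff(names(config), "models")]),
    class = "calredox_report")
}

#' @export
print.calredox_report <- function(x, ...) {
  cat(sprintf("calredox %s report\n", x$kind))
  switch(x$kind,
    titration = {
      for (i in seq_along(x$midpoints_mV))
        cat(sprintf("  E_m%d = %+7.1f +/- %.1f mV vs SHE (a = %.3f)\n",
                    i, x$midpoints_mV[i], x$se_midpoints_mV[i],
                    x$amplitudes[i]))
      if (!is.na(x$occupancy_percent))
        cat(sprintf("  calcium-site occupancy = %.1f%%\n",
                    x$occupancy_percent))
    },
    kd = {
      cat(sprintf("  apparent Kd upper limit = %.3g M (%s)\n",
                  x$upper_limit_M, x$criterion))
      if (x$unbounded) cat("  (unbounded: grid maximum consistent)\n")
    },
    survey = {
      cat(sprintf("  %d Fe-Ca distances; global minimum %.2f A (%s)\n",
                  x$n_distances, x$global_min_A, x$global_min_entry))
    })
  if (length(x$warnings %||% character(0)))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Model objects are reduced to their numeric summaries; the
#' configuration echo is carried along for provenance.
#'
#' @param report A `calredox_report`.
#' @param file Output path.
#' @export
write_report_json <- function(report, file) {
  stopifnot(inherits(report, "calredox_report"))
  keep <- !vapply(report, function(el)
    inherits(el, c("nernst_fit", "calibration_model", "kd_estimate",
                   "distance_survey", "titration_curve")), TRUE)
  jsonlite::write_json(report[keep], file, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", force = TRUE)
  invisible(file)
}
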