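#' Define a 1:1 calcium-binding ligand species
#'
#' @param name Species name (unique within a system), e.g. `"EGTA"`,
#'   `"CalBryte-590"` or `"protein"`.
#' @param kd Calcium dissociation constant, mol/L (> 0).
#' @param total Total species concentration, mol/L (>= 0).
#' @return An object of class `ligand`.
#' @export
ligand <- function(name, kd, total) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(kd), kd > 0, is.numeric(total), total >= 0)
  structure(list(name = name, kd = kd, total = total), class = "ligand")
}

#' A competitive calcium-binding system
#'
#' A total calcium pool shared among any number of independent 1:1
#' ligands.  The calibration series of the dye-based affinity assay, for
#' instance, is 0-5 mM total calcium in 5 mM EGTA (Kd 1.0e-7 M) plus
#' 20 uM CalBryte-590 indicator (Kd 1.4e-6 M).
#'
#' @param total_calcium Total calcium, mol/L (>= 0).
#' @param ligands List of [ligand()] objects with unique names (may be
#'   empty).
#' @return An object of class `competition_system`.
#' @examples
#' competition_system(5e-3, list(ligand("EGTA", 1.0e-7, 5e-3),
#'                               ligand("CalBryte-590", 1.4e-6, 2e-5)))
#' @export
competition_system <- function(total_calcium, ligands = list()) {
  stopifnot(is.numeric(total_calcium), total_calcium >= 0,
            is.list(ligands),
            all(vapply(ligands, inherits, TRUE, "ligand")))
  nms <- vapply(ligands, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("ligand names must be unique", call. = FALSE)
  structure(list(total_calcium = total_calcium, ligands = ligands),
            class = "competition_system")
}

#' Solve a competitive calcium-binding equilibrium
#'
#' Finds the unique free-calcium root of the monotone mass-balance
#' function
#' \deqn{f(x) = x + \sum_j \frac{T_j x}{K_{d,j} + x} - Ca_{tot}}
#' by bracketed root finding on `[0, total_calcium]` with Newton
#' polishing, then computes each 1:1 complex as
#' `T_j x / (K_{d,j} + x)`.  Mass balance holds to a relative error
#' below 1e-8.
#'
#' @param system A [competition_system()].
#' @return A list of class `equilibrium_result` with `free_calcium`
#'   (mol/L) and `complexes` (named numeric vector, mol/L).
#' @export
solve_equilibrium <- function(system) {
  stopifnot(inherits(system, "competition_system"))
  tot <- system$total_calcium
  kds <- vapply(system$ligands, `[[`, numeric(1), "kd")
  tls <- vapply(system$ligands, `[[`, numeric(1), "total")
  nms <- vapply(system$ligands, `[[`, character(1), "name")
  complexes_at <- function(x) stats::setNames(tls * x / (kds + x), nms)
  if (tot == 0 || length(kds) == 0) {
    return(structure(list(free_calcium = tot,
                          complexes = complexes_at(tot)),
                     class = "equilibrium_result"))
  }
  g <- function(x) x + sum(tls * x / (kds + x)) - tot
  x <- stats::uniroot(g, lower = 0, upper = tot,
                      tol = max(1e-20, 1e-15 * tot))$root
  for (i in 1:6) {  # Newton polish; g' = 1 + sum(T K/(K+x)^2) >= 1
    slope <- 1 + sum(tls * kds / (kds + x)^2)
    step <- g(x) / slope
    x <- min(max(x - step, 0), tot)
    if (abs(step) < 1e-16 * max(x, tot * 1e-12)) break
  }
  structure(list(free_calcium = x, complexes = complexes_at(x)),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Free Ca2+: %.4g M\n", x$free_calcium))
  for (n in names(x$complexes))
    cat(sprintf("  [Ca.%s] = %.4g M\n", n, x$complexes[[n]]))
  invisible(x)
}

#' Closed-form free calcium for two competing 1:1 ligands
#'
#' With two 1:1 ligands the mass balance reduces to a cubic in free
#' calcium `x`:
#' \deqn{x^3 + b x^2 + c x + d = 0}
#' with `b = K_a + K_b + T_a + T_b - Ca`,
#' `c = K_a K_b + K_b T_a + K_a T_b - Ca (K_a + K_b)`,
#' `d = -Ca K_a K_b`.  The real root on `[0, Ca]` is selected using the
#' trigonometric (three-real-root) or Cardano branch of the depressed
#' cubic, computed on a concentration-rescaled copy of the coefficients
#' for numerical stability, followed by Newton refinement of the
#' polynomial root.
#'
#' @param total_calcium Total calcium, mol/L.
#' @param ligand_a,ligand_b Two [ligand()] objects.
#' @return Free calcium concentration, mol/L.
#' @seealso [solve_equilibrium()], which handles any number of ligands
#'   iteratively and agrees with this closed form to a relative 1e-8.
#' @export
free_calcium_cubic <- function(total_calcium, ligand_a, ligand_b) {
  stopifnot(inherits(ligand_a, "ligand"), inherits(ligand_b, "ligand"),
            is.numeric(total_calcium), total_calcium >= 0)
  ca <- total_calcium
  if (ca == 0) return(0)
  # rescale concentrations so the dominant scale is ~1
  s <- max(ca, ligand_a$total, ligand_b$total, ligand_a$kd, ligand_b$kd)
  ka <- ligand_a$kd / s; kb <- ligand_b$kd / s
  ta <- ligand_a$total / s; tb <- ligand_b$total / s
  cc <- ca / s
  b <- ka + kb + ta + tb - cc
  c2 <- ka * kb + kb * ta + ka * tb - cc * (ka + kb)
  d <- -cc * ka * kb
  # depressed cubic t^3 + p t + q, x = t - b/3
  p <- c2 - b^2 / 3
  q <- 2 * b^3 / 27 - b * c2 / 3 + d
  disc <- (q / 2)^2 + (p / 3)^3
  roots <- if (disc <= 0) {
    # three real roots: trigonometric branch
    m <- 2 * sqrt(-p / 3)
    theta <- acos(pmin(1, pmax(-1, 3 * q / (p * m)))) / 3
    m * cos(theta - 2 * pi * (0:2) / 3) - b / 3
  } else {
    u <- -q / 2 + sqrt(disc)
    v <- -q / 2 - sqrt(disc)
    cbrt <- function(z) sign(z) * abs(z)^(1 / 3)
    cbrt(u) + cbrt(v) - b / 3
  }
  cand <- roots[roots > -1e-12 & roots <= cc * (1 + 1e-9)]
  if (length(cand) == 0)
    stop("no physical root of the competition cubic", call. = FALSE)
  x <- min(pmax(cand, 0))  # unique physical root; guard roundoff
  poly <- function(x) ((x + b) * x + c2) * x + d
  dpoly <- function(x) (3 * x + 2 * b) * x + c2
  for (i in 1:3) {
    dp <- dpoly(x)
    if (!is.finite(dp) || dp == 0) break
    x <- x - poly(x) / dp
  }
  max(0, x) * s
}

#' Calibrate fluorescence signal against Ca-dye complex concentration
#'
#' Given measured fluorescence signals for a calibration series of
#' [competition_system()]s (e.g. 0-5 mM total calcium buffered by 5 mM
#' EGTA with 20 uM indicator dye), computes the Ca-dye complex
#' concentration of each standard with [solve_equilibrium()] and fits a
#' second-order polynomial mapping signal to complex concentration.
#'
#' @param signals Numeric vector of fluorescence signals.
#' @param systems List of `competition_system`s, same length.
#' @param dye_name Name of the dye ligand within each system.
#' @return An object of class `calibration_model` with coefficients
#'   (intercept, linear, quadratic), residuals, the calibration points,
#'   and the signal validity range.
#' @export
build_calibration <- function(signals, systems, dye_name = "CalBryte-590") {
  stopifnot(is.numeric(signals), is.list(systems),
            length(signals) == length(systems), length(signals) >= 3)
  complex <- vapply(systems, function(s) {
    stopifnot(inherits(s, "competition_system"))
    eq <- solve_equilibrium(s)
    if (!dye_name %in% names(eq$complexes))
      stop(sprintf("no ligand named '%s' in calibration system", dye_name),
           call. = FALSE)
    eq$complexes[[dye_name]]
  }, numeric(1))
  X <- cbind(1, signals, signals^2)
  if (qr(X)$rank < 3)
    stop("calibration design is rank-deficient (signals not distinct enough)",
         call. = FALSE)
  fit <- stats::lm.fit(X, complex)
  structure(list(coefficients = stats::setNames(fit$coefficients,
                                                c("c0", "c1", "c2")),
                 residuals = fit$residuals,
                 signals = signals, complex = complex,
                 range = range(signals), dye_name = dye_name),
            class = "calibration_model")
}

#' Convert fluorescence signals to Ca-dye complex concentrations
#'
#' @param model A [build_calibration()] result.
#' @param signals Fluorescence signals; values outside the calibrated
#'   range trigger a warning.
#' @return Complex concentrations, mol/L.
#' @export
apply_calibration <- function(model, signals) {
  stopifnot(inherits(model, "calibration_model"), is.numeric(signals))
  if (any(signals < model$range[1] | signals > model$range[2]))
    warning("signals outside the calibrated range; extrapolating",
            call. = FALSE)
  co <- model$coefficients
  co[["c0"]] + co[["c1"]] * signals + co[["c2"]] * signals^2
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Fluorescence -> [Ca.dye] calibration (order-2 polynomial)\n")
  cat(sprintf("  coefficients: %.4g + %.4g s + %.4g s^2\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  cat(sprintf("  %d points, complex range %.3g-%.3g M, rms residual %.3g M\n",
              length(x$signals), min(x$complex), max(x$complex),
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Predicted dye-complex curve for a protein of given calcium affinity
#'
#' For each protein concentration, solves the three-way competition
#' between the indicator dye and the protein's calcium sites for the
#' background calcium pool, and returns the Ca-dye complex
#' concentration.  Protein sites are modelled as identical independent
#' 1:1 sites, `sites_per_protein` per molecule (the effective
#' stoichiometry from elemental analysis, 1.6 by default).  The curve is
#' non-increasing in protein concentration: a stronger binder strips
#' more calcium from the dye.
#'
#' @param protein_conc Protein concentrations, mol/L.
#' @param kd_protein Apparent protein site Kd, mol/L.
#' @param sites_per_protein Calcium sites per protein molecule.
#' @param background_calcium Total calcium in the protein-free assay
#'   buffer, mol/L (default 2.4e-6, the measured assay background).
#' @param dye The indicator [ligand()] (default 20 uM CalBryte-590 at
#'   Kd 1.4e-6 M).
#' @return Ca-dye complex concentrations, mol/L, one per protein
#'   concentration.
#' @export
predict_assay_curve <- function(protein_conc, kd_protein,
                                sites_per_protein = 1.6,
                                background_calcium = 2.4e-6,
                                dye = ligand("CalBryte-590", 1.4e-6, 2e-5)) {
  stopifnot(is.numeric(protein_conc), all(protein_conc >= 0),
            is.numeric(kd_protein), kd_protein > 0,
            inherits(dye, "ligand"))
  vapply(protein_conc, function(pc) {
    ligs <- list(dye)
    if (pc > 0)
      ligs <- c(ligs, list(ligand("protein", kd_protein,
                                  sites_per_protein * pc)))
    eq <- solve_equilibrium(competition_system(background_calcium, ligs))
    eq$complexes[[dye$name]]
  }, numeric(1))
}

#' Upper limit on the protein's apparent calcium Kd by curve-family
#' comparison
#'
#' Computes the predicted dye-complex-vs-protein curve for every
#' candidate Kd on a grid (1 nM to 10 uM by default) and scores each
#' against the observed replicate-averaged data by chi-squared using the
#' replicate standard deviations.  A candidate is "consistent" when its
#' chi-squared does not exceed the `level` quantile of the chi-squared
#' distribution with one degree of freedom per data point; the reported
#' upper limit is the largest consistent candidate.  When the grid
#' maximum itself is consistent the data do not bound the affinity from
#' above and the estimate is flagged `unbounded`.
#'
#' @param protein_conc Protein concentrations, mol/L (>= 3 values).
#' @param observed Observed Ca-dye complex concentrations, mol/L
#'   (replicate means).
#' @param sd Replicate standard deviations, mol/L (strictly positive).
#' @param kd_grid Candidate Kd grid, mol/L (default 40 log-spaced values
#'   between 1e-9 and 1e-5).
#' @param level Consistency level of the chi-squared criterion
#'   (default 0.95).
#' @inheritParams predict_assay_curve
#' @return An object of class `kd_estimate` with the grid, per-candidate
#'   chi-squared, `upper_limit` (mol/L) and the `unbounded` flag.
#' @export
estimate_kd_upper_limit <- function(protein_conc, observed, sd,
                                    kd_grid = 10^seq(-9, -5, length.out = 40),
                                    level = 0.95,
                                    sites_per_protein = 1.6,
                                    background_calcium = 2.4e-6,
                                    dye = ligand("CalBryte-590", 1.4e-6, 2e-5)) {
  stopifnot(length(protein_conc) >= 3,
            length(observed) == length(protein_conc),
            length(sd) == length(protein_conc),
            all(sd > 0), all(kd_grid > 0))
  kd_grid <- sort(kd_grid)
  chisq <- vapply(kd_grid, function(kd) {
    pred <- predict_assay_curve(protein_conc, kd, sites_per_protein,
                                background_calcium, dye)
    sum(((observed - pred) / sd)^2)
  }, numeric(1))
  crit <- stats::qchisq(level, df = length(protein_conc))
  ok <- chisq <= crit
  # non-binder reference: the flat curve at the protein-free complex.
  # Within the grid even the weakest candidate sequesters some calcium,
  # so flat data can reject every finite Kd while being perfectly
  # consistent with "no binding"; that case is unbounded, not an error.
  flat <- rep(predict_assay_curve(0, dye$kd, sites_per_protein,
                                  background_calcium, dye),
              length(protein_conc))
  chisq_flat <- sum(((observed - flat) / sd)^2)
  flat_ok <- chisq_flat <= crit
  if (!any(ok) && !flat_ok)
    stop(sprintf(paste0("no candidate Kd is consistent with the data ",
                        "(min chi-squared %.2f > criterion %.2f); check ",
                        "stoichiometry, background or noise model"),
                 min(chisq, chisq_flat), crit), call. = FALSE)
  upper <- if (any(ok)) max(kd_grid[ok]) else max(kd_grid)
  structure(list(kd_grid = kd_grid, chisq = chisq,
                 chisq_nonbinder = chisq_flat, criterion = crit,
                 level = level, upper_limit = upper,
                 unbounded = ok[length(ok)] || flat_ok),
            class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat(sprintf("Apparent Kd upper limit: %.3g M (chi-squared criterion %.2f at %.0f%%)\n",
              x$upper_limit, x$criterion, 100 * x$level))
  if (x$unbounded)
    cat("  NOTE: grid maximum is consistent with the data; the affinity is\n",
        "  unbounded from above at this level (non-binder cannot be excluded)\n")
  invisible(x)
}

#' Normalize elemental concentrations to a reference element
#'
#' Divides each element's concentration by that of the reference
#' element (iron by default, since in a c-type cytochrome all iron stems
#' from the covalently bound hemes), yielding per-heme stoichiometries
#' from e.g. ICP-OES concentration tables.
#'
#' @param concentrations Named numeric vector of concentrations (any
#'   single consistent unit, e.g. uM).
#' @param reference Reference element name, present with a positive
#'   concentration.
#' @return Named numeric vector of ratios (reference maps to 1).
#' @examples
#' elemental_ratio(c(Ca = 556.39, Fe = 691.17))  # ~0.80 Ca per heme
#' @export
elemental_ratio <- function(concentrations, reference = "Fe") {
  stopifnot(is.numeric(concentrations), !is.null(names(concentrations)))
  if (!reference %in% names(concentrations))
    stop(sprintf("reference element '%s' missing", reference), call. = FALSE)
  ref <- concentrations[[reference]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference concentration must be positive", call. = FALSE)
  concentrations / ref
}

#' Heme concentration from reduced-minus-oxidized absorbance
#'
#' Beer-Lambert conversion `c = A / (eps * l)` with the pyridine
#' hemochrome extinction coefficient of 62 L/mmol/cm at 550 nm by
#' default.
#'
#' @param absorbance Absorbance at the alpha band (>= 0).
#' @param path_cm Optical path length, cm (> 0).
#' @param extinction_mM Extinction coefficient, L/mmol/cm.
#' @return Concentration in mmol/L.
#' @examples
#' heme_concentration(31)  # the 0.5 mM protein stock
#' @export
heme_concentration <- function(absorbance, path_cm = 1, extinction_mM = 62) {
  stopifnot(is.numeric(absorbance), all(absorbance >= 0))
  if (!is.numeric(path_cm) || path_cm <= 0)
    stop("path length must be positive", call. = FALSE)
  stopifnot(extinction_mM > 0)
  absorbance / (extinction_mM * path_cm)
}
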