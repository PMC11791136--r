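#' Four-state thermodynamic square linking heme redox state and calcium
#'
#' The square couples two equilibria of one heme site: oxidation
#' (midpoint `em_free` with no calcium bound, `em_bound` with calcium
#' bound) and calcium binding (dissociation constant `kd_reduced` in the
#' reduced state, `kd_oxidized` in the oxidized state).  Free-energy
#' closure around the cycle fixes one parameter in terms of the other
#' three:
#' \deqn{F (E_{m,bound} - E_{m,free}) = RT \ln(K_{d,ox}/K_{d,red})}
#' so that a calcium ion that raises the midpoint (stabilizes the
#' reduced\eqn{\times}bound corner relative to oxidized\eqn{\times}bound)
#' necessarily binds the oxidized protein more weakly.
#'
#' Pass `kd_oxidized = "closed"` (the default) to derive it from the
#' other three parameters via [close_cycle()]; an explicit value is
#' checked against closure and rejected if inconsistent.
#'
#' The diheme protein is treated as two independent parallel squares
#' (the heme-heme redox interaction is negligibly small), so
#' `total_protein_sites` in [macroscopic_state()] counts heme sites,
#' not molecules.
#'
#' @param em_bound Midpoint of the calcium-loaded site, V vs SHE.
#' @param em_free Midpoint of the calcium-free site, V vs SHE.
#' @param kd_reduced Calcium dissociation constant of the reduced site,
#'   mol/L.
#' @param kd_oxidized `"closed"` or a positive value in mol/L consistent
#'   with cycle closure.
#' @param constants A [redox_constants()] object.
#' @return An object of class `thermo_square`.
#' @examples
#' sq <- thermo_square(em_bound = 0.370, em_free = -0.130,
#'                     kd_reduced = 1e-7)
#' sq$kd_oxidized / sq$kd_reduced  # huge: oxidation expels calcium
#' @export
thermo_square <- function(em_bound, em_free, kd_reduced,
                          kd_oxidized = "closed",
                          constants = redox_constants()) {
  stopifnot(is.numeric(em_bound), is.numeric(em_free),
            is.numeric(kd_reduced), kd_reduced > 0,
            inherits(constants, "redox_constants"))
  kd_ox_closed <- close_cycle(em_bound, em_free, kd_reduced, constants)
  if (identical(kd_oxidized, "closed")) {
    kd_oxidized <- kd_ox_closed
  } else {
    stopifnot(is.numeric(kd_oxidized), kd_oxidized > 0)
    resid <- abs(constants$faraday * (em_bound - em_free) -
                 constants$gas_constant * constants$temperature *
                 log(kd_oxidized / kd_reduced))
    if (resid > 1e-6)
      stop(sprintf(paste0("kd_oxidized violates cycle closure ",
                          "(residual %.3g J/mol); pass \"closed\" to derive it"),
                   resid), call. = FALSE)
  }
  structure(list(em_bound = em_bound, em_free = em_free,
                 kd_reduced = kd_reduced, kd_oxidized = kd_oxidized,
                 constants = constants),
            class = "thermo_square")
}

#' Close the redox-binding thermodynamic cycle
#'
#' Returns the oxidized-state calcium dissociation constant implied by
#' the two midpoints and the reduced-state Kd:
#' `kd_oxidized = kd_reduced * exp(F (em_bound - em_free) / RT)`.
#'
#' @inheritParams thermo_square
#' @return `kd_oxidized` in mol/L.
#' @export
close_cycle <- function(em_bound, em_free, kd_reduced,
                        constants = redox_constants()) {
  stopifnot(is.numeric(kd_reduced), all(kd_reduced > 0))
  kd_reduced * exp((em_bound - em_free) / thermal_voltage(constants))
}

#' @export
print.thermo_square <- function(x, ...) {
  cat("Redox-calcium thermodynamic square (one heme site)\n")
  cat(sprintf("  Em (Ca-bound) = %+.1f mV, Em (Ca-free) = %+.1f mV vs SHE\n",
              1000 * x$em_bound, 1000 * x$em_free))
  cat(sprintf("  Kd (reduced) = %.3g M, Kd (oxidized) = %.3g M (ratio %.3g)\n",
              x$kd_reduced, x$kd_oxidized, x$kd_oxidized / x$kd_reduced))
  invisible(x)
}

#' Apparent midpoint potential at a given free calcium concentration
#'
#' Macroscopic midpoint of a site in equilibrium with free calcium at
#' concentration `free_calcium`:
#' \deqn{E_{m,app} = E_{m,free} + \frac{RT}{F}
#'   \ln\frac{1 + [Ca]/K_{d,red}}{1 + [Ca]/K_{d,ox}}}
#' It moves from `em_free` at zero calcium to `em_bound` at saturating
#' calcium, and is monotone non-decreasing in calcium whenever
#' `em_bound > em_free`.
#'
#' @param square A [thermo_square()].
#' @param free_calcium Free Ca2+ concentration(s), mol/L (>= 0).
#' @return Apparent midpoint(s), V vs SHE.
#' @export
apparent_midpoint <- function(square, free_calcium) {
  stopifnot(inherits(square, "thermo_square"), is.numeric(free_calcium))
  if (any(free_calcium < 0))
    stop("free calcium concentration must be non-negative", call. = FALSE)
  vt <- thermal_voltage(square$constants)
  square$em_free + vt * log((1 + free_calcium / square$kd_reduced) /
                            (1 + free_calcium / square$kd_oxidized))
}

#' Self-consistent redox/calcium state at fixed potential
#'
#' Solves the coupled mass balance for a pool of independent heme sites
#' equilibrated with an electrode at `potential` and sharing a finite
#' calcium pool.  For free calcium `x`, each site distributes over the
#' four corners of the square with Boltzmann weights
#' `1 : x/Kd_red : exp(phi) : exp(phi) x/Kd_ox` (reduced-free,
#' reduced-bound, oxidized-free, oxidized-bound), where
#' `phi = F (E - em_free)/RT`.  The free concentration is found by
#' monotone root bracketing of
#' `x + sites * f_loaded(x) - total_calcium = 0`.
#'
#' @param square A [thermo_square()].
#' @param potential Electrode potential, V vs SHE.
#' @param total_calcium Total calcium, mol/L.
#' @param total_protein_sites Total heme-site concentration, mol/L.
#' @return A list with `free_calcium`, `fraction_oxidized`,
#'   `fraction_calcium_loaded`.
#' @export
macroscopic_state <- function(square, potential, total_calcium,
                              total_protein_sites) {
  stopifnot(inherits(square, "thermo_square"),
            is.numeric(potential), length(potential) == 1L,
            total_calcium >= 0, total_protein_sites >= 0)
  vt <- thermal_voltage(square$constants)
  phi <- exp((potential - square$em_free) / vt)
  state_at <- function(x) {
    wrf <- 1
    wrb <- x / square$kd_reduced
    wof <- phi
    wob <- phi * x / square$kd_oxidized
    tot <- wrf + wrb + wof + wob
    list(f_ox = (wof + wob) / tot, f_loaded = (wrb + wob) / tot)
  }
  if (total_calcium == 0) {
    st <- state_at(0)
    return(list(free_calcium = 0, fraction_oxidized = st$f_ox,
                fraction_calcium_loaded = st$f_loaded))
  }
  g <- function(x) x + total_protein_sites * state_at(x)$f_loaded -
    total_calcium
  root <- stats::uniroot(g, lower = 0, upper = total_calcium,
                         tol = max(1e-18, 1e-14 * total_calcium))$root
  # Newton polish for tight mass balance
  for (i in 1:4) {
    h <- max(1e-12 * root, 1e-18)
    slope <- (g(root + h) - g(root - h)) / (2 * h)
    if (!is.finite(slope) || slope <= 0) break
    root <- max(0, root - g(root) / slope)
  }
  st <- state_at(root)
  list(free_calcium = root, fraction_oxidized = st$f_ox,
       fraction_calcium_loaded = st$f_loaded)
}

#' Macroscopic redox titration under a finite calcium pool
#'
#' Evaluates [macroscopic_state()] over a potential grid and packages
#' the result as a [titration_curve()] that can be fed straight back
#' into [nernst_fit()].  By default the curve reports the fraction of
#' reduced sites (which, like an absorbance trace at the Soret band,
#' decreases with rising potential); set `response = "oxidized"` for the
#' complementary fraction.
#'
#' The apparent midpoint of the resulting curve moves from `em_free`
#' with no calcium to `em_bound` at saturating calcium, and is
#' non-decreasing in total calcium in between.
#'
#' @param square A [thermo_square()].
#' @param total_calcium Total calcium, mol/L.
#' @param total_protein_sites Total heme-site concentration, mol/L.
#' @param potential_grid Monotone potential grid, V vs SHE.
#' @param response `"reduced"` (default) or `"oxidized"`.
#' @return A `titration_curve` (SHE frame, averaged branch).
#' @export
macroscopic_titration <- function(square, total_calcium,
                                  total_protein_sites, potential_grid,
                                  response = c("reduced", "oxidized")) {
  response <- match.arg(response)
  stopifnot(is.numeric(potential_grid), length(potential_grid) >= 2)
  d <- diff(potential_grid)
  if (!(all(d > 0) || all(d < 0)))
    stop("potential grid must be monotone", call. = FALSE)
  fox <- vapply(potential_grid, function(E)
    macroscopic_state(square, E, total_calcium,
                      total_protein_sites)$fraction_oxidized,
    numeric(1))
  y <- if (response == "reduced") 1 - fox else fox
  titration_curve(potential_grid, y, branch = "averaged", frame = "SHE")
}
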