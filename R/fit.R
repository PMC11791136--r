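#' Fit a multi-transition Nernstian model to a titration curve
#'
#' The workhorse of the package.  Fits the absorbance-vs-potential model
#' \deqn{A(E) = A_{ox} + \sum_i \frac{a_i}{\exp[(z F/RT)(E - E_{m,i})] + 1}}
#' to a SHE-referenced [titration_curve()] by trust-region
#' Levenberg-Marquardt least squares with multi-start initialization
#' (midpoint starting values laid out on a grid over the measured
#' potential window).
#'
#' Three model variants are available:
#' \describe{
#'   \item{`free`}{`n_transitions` independent one-electron transitions,
#'     each with its own midpoint and amplitude.}
#'   \item{`paired4`}{the constrained four-transition model for a
#'     partially calcium-loaded diheme protein: two closely spaced pairs
#'     with a shared within-pair spacing and a single amplitude per pair
#'     (see [paired_model()]).  The calcium-site occupancy is reported as
#'     the fractional amplitude of the high-potential pair.}
#'   \item{`mutant3`}{a free three-transition fit, appropriate for
#'     distal-ligand mutants whose fourth transition (near -450 mV vs
#'     SHE for the calcium-free mutated heme) falls below the applied
#'     potential window and is therefore not modelled.}
#' }
#'
#' The fully oxidized baseline `A_ox` is a free parameter by default;
#' set `fix_aox` to pin it (e.g. to 1.0 when the data are normalized so
#' that the fully oxidized absorbance is 1).  Midpoints are constrained
#' to `midpoint_bounds` (default -0.8 to +0.8 V vs SHE, the applied
#' -0.6 to +0.4 V window plus margin) and amplitudes to be non-negative.
#' Parameter uncertainties are 1-sigma values from the Jacobian-based
#' covariance at the optimum.
#'
#' @param curve A [titration_curve()] in the SHE frame.
#' @param model `"free"`, `"paired4"` or `"mutant3"`.
#' @param n_transitions Number of transitions for the free model
#'   (ignored for `paired4`, forced to 3 for `mutant3`).
#' @param fix_aox Optional fixed value for the oxidized baseline.
#' @param constants A [redox_constants()] object.
#' @param electrons Electrons per transition (z), default 1.
#' @param midpoint_bounds Length-2 numeric, allowed midpoint range in V.
#' @param weights `"none"` (default) for unweighted least squares or
#'   `"errors"` to weight residuals by the curve's per-point standard
#'   deviations (requires strictly positive errors).
#' @return An object of class `nernst_fit`; see [coef.nernst_fit()],
#'   [summary.nernst_fit()], [predict.nernst_fit()], [occupancy()].
#' @examples
#' tr <- transition_set(c(0.353, -0.092), c(0.85, 0.15))
#' E <- seq(-0.6, 0.4, by = 0.05)
#' cv <- titration_curve(E, 0.1 + nernst_response(E, tr), frame = "SHE")
#' fit <- nernst_fit(cv, model = "free", n_transitions = 2)
#' coef(fit)
#' @export
nernst_fit <- function(curve,
                       model = c("free", "paired4", "mutant3"),
                       n_transitions = NULL,
                       fix_aox = NULL,
                       constants = redox_constants(),
                       electrons = 1L,
                       midpoint_bounds = c(-0.8, 0.8),
                       weights = c("none", "errors")) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  stopifnot(inherits(curve, "titration_curve"))
  if (curve_frame(curve) != "SHE")
    stop("curve must be SHE-referenced before fitting (see she_correct())",
         call. = FALSE)
  E <- curve$potential
  A <- curve$absorbance
  w <- rep(1, length(E))
  if (weights == "errors") {
    err <- curve[["errors"]]
    if (is.null(err) || any(!is.finite(err)) || any(err <= 0))
      stop("weighting by errors requires strictly positive per-point errors",
           call. = FALSE)
    w <- 1 / err
  }
  n <- switch(model, free = n_transitions, mutant3 = 3L, paired4 = 4L)
  if (model == "free") {
    if (is.null(n) || n < 1)
      stop("n_transitions must be >= 1 for the free model", call. = FALSE)
    n <- as.integer(n)
  }
  npar <- if (model == "paired4") 5L else 2L * n
  npar <- npar + if (is.null(fix_aox)) 1L else 0L
  if (length(E) < npar + 1L)
    stop(sprintf("need at least %d data points to fit %d parameters",
                 npar + 1L, npar), call. = FALSE)

  fit <- if (model == "paired4") {
    fit_paired_(E, A, w, fix_aox, constants, electrons, midpoint_bounds)
  } else {
    fit_free_(E, A, w, n, fix_aox, constants, electrons, midpoint_bounds)
  }
  fit$model_tag <- model
  fit$data <- curve
  fit$constants <- constants
  fit$weights <- weights
  class(fit) <- "nernst_fit"

  dm <- diff(fit$transitions$midpoint)
  if (length(dm) && any(dm < 1e-3))
    warning("fitted transitions closer than 1 mV; reporting as coincident",
            call. = FALSE)
  if (sum(fit$transitions$amplitude) < 1e-6 * max(1, diff(range(A))) ||
      sum(fit$transitions$amplitude) < 1e-9)
    warning("total fitted amplitude is near zero; the curve may be flat",
            call. = FALSE)
  fit
}

# -- internal: model evaluation for a flat parameter vector ------------------

free_theta_model_ <- function(theta, E, n, fix_aox, f, z) {
  em <- theta[seq_len(n)]
  a <- theta[n + seq_len(n)]
  aox <- if (is.null(fix_aox)) theta[2 * n + 1] else fix_aox
  y <- rep(aox, length(E))
  for (i in seq_len(n)) y <- y + a[i] / (exp(z * f * (E - em[i])) + 1)
  y
}

paired_theta_model_ <- function(theta, E, fix_aox, f, z) {
  h <- theta[3] / 2
  em <- c(theta[1] - h, theta[1] + h, theta[2] - h, theta[2] + h)
  a <- c(theta[4], theta[4], theta[5], theta[5])
  aox <- if (is.null(fix_aox)) theta[6] else fix_aox
  y <- rep(aox, length(E))
  for (i in 1:4) y <- y + a[i] / (exp(z * f * (E - em[i])) + 1)
  y
}

# Run nls.lm over a list of starting vectors, keep the best converged fit.
multistart_lm_ <- function(starts, resid_fn, lower, upper) {
  best <- NULL
  diagnostics <- character(0)
  for (th0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) e)
    if (inherits(res, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(res))
      next
    }
    if (!(res$info %in% 1:4)) {
      diagnostics <- c(diagnostics, res$message)
      next
    }
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    stop(paste0("Nernst fit failed to converge from any start.\n",
                paste(unique(diagnostics), collapse = "\n")), call. = FALSE)
  best
}

# 1-sigma parameter uncertainties from a central-difference Jacobian of the
# residual vector at the optimum.
theta_se_ <- function(theta, resid_fn, nobs) {
  p <- length(theta)
  r0 <- resid_fn(theta)
  J <- matrix(NA_real_, length(r0), p)
  for (j in seq_len(p)) {
    hj <- max(1e-7, 1e-7 * abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + hj
    tm <- theta; tm[j] <- tm[j] - hj
    J[, j] <- (resid_fn(tp) - resid_fn(tm)) / (2 * hj)
  }
  dof <- max(1L, nobs - p)
  sigma2 <- sum(r0^2) / dof
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov)) return(list(se = rep(NA_real_, p), cov = NULL))
  list(se = sqrt(pmax(0, diag(cov))), cov = cov)
}

fit_free_ <- function(E, A, w, n, fix_aox, constants, z, mb) {
  f <- 1 / thermal_voltage(constants)
  resid_fn <- function(th) w * (free_theta_model_(th, E, n, fix_aox, f, z) - A)
  span <- range(E)
  amp0 <- max(diff(range(A)) / n, 1e-3)
  aox0 <- min(A)
  grid <- seq(span[1] + 0.05 * diff(span), span[2] - 0.05 * diff(span),
              length.out = max(n + 2L, 6L))
  # midpoint combinations with repetition, so that starts can place
  # several transitions in one region (closely spaced pairs); repeated
  # values are split by small offsets
  cm <- do.call(expand.grid, rep(list(grid), n))
  combos <- unique(lapply(seq_len(nrow(cm)), function(i)
    sort(as.numeric(cm[i, ]))))
  if (length(combos) > 24)
    combos <- combos[round(seq(1, length(combos), length.out = 24))]
  starts <- lapply(combos, function(ems) {
    dup <- duplicated(ems)
    ems[dup] <- ems[dup] + 0.012 * seq_len(sum(dup))
    c(sort(ems), rep(amp0, n), if (is.null(fix_aox)) aox0)
  })
  lower <- c(rep(mb[1], n), rep(0, n), if (is.null(fix_aox)) -Inf)
  upper <- c(rep(mb[2], n), rep(Inf, n), if (is.null(fix_aox)) Inf)
  best <- multistart_lm_(starts, resid_fn, lower, upper)
  th <- best$par
  unc <- theta_se_(th, resid_fn, length(E))
  em <- th[seq_len(n)]; a <- th[n + seq_len(n)]
  se_em <- unc$se[seq_len(n)]; se_a <- unc$se[n + seq_len(n)]
  ord <- order(em)
  trans <- data.frame(midpoint = em[ord], amplitude = a[ord],
                      electrons = z,
                      se_midpoint = se_em[ord], se_amplitude = se_a[ord])
  aox <- if (is.null(fix_aox)) th[2 * n + 1] else fix_aox
  se_aox <- if (is.null(fix_aox)) unc$se[2 * n + 1] else 0
  list(transitions = trans, oxidized_baseline = aox, se_aox = se_aox,
       residual_norm = sqrt(best$deviance), cov = unc$cov,
       paired = NULL, info = best$info)
}

fit_paired_ <- function(E, A, w, fix_aox, constants, z, mb) {
  f <- 1 / thermal_voltage(constants)
  resid_fn <- function(th) w * (paired_theta_model_(th, E, fix_aox, f, z) - A)
  span <- range(E)
  if (diff(span) < 0.3)
    stop("potential window too narrow to constrain both pair regions",
         call. = FALSE)
  amp0 <- max(diff(range(A)) / 4, 1e-3)
  aox0 <- min(A)
  qs <- function(p) span[1] + p * diff(span)
  starts <- list()
  for (pl in c(0.15, 0.3, 0.45)) for (ph in c(0.6, 0.75, 0.9))
    starts[[length(starts) + 1L]] <-
      c(qs(pl), qs(ph), 0.03, amp0, amp0, if (is.null(fix_aox)) aox0)
  lower <- c(mb[1], mb[1], 0, 0, 0, if (is.null(fix_aox)) -Inf)
  upper <- c(mb[2], mb[2], 0.3, Inf, Inf, if (is.null(fix_aox)) Inf)
  best <- multistart_lm_(starts, resid_fn, lower, upper)
  th <- best$par
  # canonical order: low-potential pair first
  if (th[1] > th[2]) th <- c(th[2], th[1], th[3], th[5], th[4], th[-(1:5)])
  unc <- theta_se_(th, resid_fn, length(E))
  pm <- paired_model(low_center = th[1], high_center = th[2],
                     spacing = th[3], a_low = th[4], a_high = th[5])
  trans <- expand_pairs(pm)
  h2 <- 0.5
  se <- unc$se
  trans$se_midpoint <- sqrt(c(se[1]^2 + (h2 * se[3])^2,
                              se[1]^2 + (h2 * se[3])^2,
                              se[2]^2 + (h2 * se[3])^2,
                              se[2]^2 + (h2 * se[3])^2))
  trans$se_amplitude <- c(se[4], se[4], se[5], se[5])
  aox <- if (is.null(fix_aox)) th[6] else fix_aox
  se_aox <- if (is.null(fix_aox)) se[6] else 0
  # delta-method 1-sigma for occupancy = a_high/(a_high + a_low)
  occ_se <- NA_real_
  if (!is.null(unc$cov)) {
    aL <- th[4]; aH <- th[5]; s <- aL + aH
    g <- c(0, 0, 0, -aH / s^2, aL / s^2, if (is.null(fix_aox)) 0)
    occ_se <- sqrt(max(0, drop(t(g) %*% unc$cov %*% g)))
  }
  list(transitions = trans, oxidized_baseline = aox, se_aox = se_aox,
       residual_norm = sqrt(best$deviance), cov = unc$cov,
       paired = list(model = pm, se = se[1:5], occupancy = pair_occupancy(pm),
                     se_occupancy = occ_se),
       info = best$info)
}

# -- methods -----------------------------------------------------------------

#' Calcium-site occupancy of a fitted titration
#'
#' For a `paired4` fit, the fractional amplitude of the high-potential
#' (calcium-loaded) pair; `NA` for other models.
#'
#' @param object A `nernst_fit`.
#' @return Occupancy fraction in \[0, 1\], or `NA`.
#' @export
occupancy <- function(object) {
  stopifnot(inherits(object, "nernst_fit"))
  if (is.null(object$paired)) return(NA_real_)
  object$paired$occupancy
}

#' @export
coef.nernst_fit <- function(object, ...) {
  tr <- object$transitions
  out <- c(stats::setNames(tr$midpoint,
                           paste0("midpoint", seq_len(nrow(tr)))),
           stats::setNames(tr$amplitude,
                           paste0("amplitude", seq_len(nrow(tr)))),
           oxidized_baseline = object$oxidized_baseline)
  out
}

#' Predicted absorbance from a fitted Nernst model
#'
#' @param object A `nernst_fit`.
#' @param potential Potentials (V vs SHE) at which to evaluate the model;
#'   defaults to the fitted data's potentials.
#' @param ... Unused.
#' @export
predict.nernst_fit <- function(object, potential = NULL, ...) {
  if (is.null(potential)) potential <- object$data$potential
  object$oxidized_baseline +
    nernst_response(potential, object$transitions, object$constants)
}

#' @export
fitted.nernst_fit <- function(object, ...) predict(object)

#' @export
residuals.nernst_fit <- function(object, ...) {
  object$data$absorbance - fitted(object)
}

#' @export
print.nernst_fit <- function(x, ...) {
  cat(sprintf("Multi-transition Nernst fit (%s model)\n", x$model_tag))
  tr <- x$transitions
  for (i in seq_len(nrow(tr)))
    cat(sprintf("  E_m%d = %+7.1f mV vs SHE   a%d = %.4f\n",
                i, 1000 * tr$midpoint[i], i, tr$amplitude[i]))
  cat(sprintf("  A_ox = %.4f, residual norm = %.4g\n",
              x$oxidized_baseline, x$residual_norm))
  if (!is.null(x$paired))
    cat(sprintf("  calcium-site occupancy = %.1f%%\n", 100 * occupancy(x)))
  invisible(x)
}

#' @export
summary.nernst_fit <- function(object, ...) {
  tr <- object$transitions
  tab <- data.frame(
    midpoint_mV = 1000 * tr$midpoint,
    se_mV = 1000 * tr$se_midpoint,
    amplitude = tr$amplitude,
    se_amplitude = tr$se_amplitude)
  out <- list(model_tag = object$model_tag, table = tab,
              oxidized_baseline = object$oxidized_baseline,
              se_aox = object$se_aox,
              residual_norm = object$residual_norm,
              occupancy = occupancy(object),
              se_occupancy = if (!is.null(object$paired))
                object$paired$se_occupancy else NA_real_,
              paired = object$paired)
  class(out) <- "summary.nernst_fit"
  out
}

#' @export
print.summary.nernst_fit <- function(x, ...) {
  cat(sprintf("Multi-transition Nernst fit (%s model)\n", x$model_tag))
  cat("Transitions (mV vs SHE, 1-sigma uncertainties):\n")
  print(round(x$table, 3))
  cat(sprintf("A_ox = %.4f +/- %.4f, residual norm = %.4g\n",
              x$oxidized_baseline, x$se_aox, x$residual_norm))
  if (!is.na(x$occupancy))
    cat(sprintf("Calcium-site occupancy = %.1f%% +/- %.1f%%\n",
                100 * x$occupancy, 100 * x$se_occupancy))
  if (!is.null(x$paired)) {
    pm <- x$paired$model
    cat(sprintf("Pair centers %+.1f / %+.1f mV (separation %.1f mV), spacing %.1f mV\n",
                1000 * pm$low_center, 1000 * pm$high_center,
                1000 * (pm$high_center - pm$low_center), 1000 * pm$spacing))
  }
  invisible(x)
}

#' @export
plot.nernst_fit <- function(x, ...) {
  E <- x$data$potential
  grid <- seq(min(E), max(E), length.out = 200)
  graphics::plot(1000 * E, x$data$absorbance,
                 xlab = "potential (mV vs SHE)", ylab = "absorbance", ...)
  err <- x$data[["errors"]]
  if (!is.null(err))
    graphics::arrows(1000 * E, x$data$absorbance - err,
                     1000 * E, x$data$absorbance + err,
                     length = 0.02, angle = 90, code = 3)
  graphics::lines(1000 * grid, predict(x, grid), col = "red3")
  graphics::abline(v = 1000 * x$transitions$midpoint, lty = 3,
                   col = "grey50")
  invisible(x)
}

#' Simulate replicate titrations from a fitted model
#'
#' Draws new curves from the fitted Nernstian model plus i.i.d. Gaussian
#' noise with standard deviation equal to the fit's residual standard
#' error, the classic parametric-bootstrap companion to [nernst_fit()].
#'
#' @param object A `nernst_fit`.
#' @param nsim Number of replicate curves.
#' @param seed Integer seed (RNG state is restored on exit).
#' @param ... Unused.
#' @return A list of `titration_curve` objects.
#' @export
simulate.nernst_fit <- function(object, nsim = 1, seed = NULL, ...) {
  E <- object$data$potential
  mu <- predict(object)
  p <- length(coef(object))
  sigma <- object$residual_norm / sqrt(max(1, length(E) - p))
  with_seed_(seed, {
    lapply(seq_len(nsim), function(i)
      titration_curve(E, mu + stats::rnorm(length(E), 0, sigma),
                      branch = curve_branch(object$data), frame = "SHE"))
  })
}
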