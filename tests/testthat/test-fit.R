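test_that("noiseless two-transition curves are recovered to < 1 mV", {
  cv <- noiseless_curve(wt_transitions(), aox = 0.1)
  fit <- nernst_fit(cv, model = "free", n_transitions = 2)
  expect_within(1000 * fit$transitions$midpoint, c(-92, 353), 1)
  expect_within(fit$transitions$amplitude, c(0.15, 0.85), 1e-3)
  expect_equal(fit$oxidized_baseline, 0.1, tolerance = 1e-3)
})

test_that("noiseless mutant three-transition curves are recovered to < 1 mV", {
  cv <- noiseless_curve(mutant_transitions())
  fit <- nernst_fit(cv, model = "mutant3")
  expect_equal(nrow(fit$transitions), 3L)
  expect_within(1000 * fit$transitions$midpoint, c(-130, 50, 370), 1)
})

test_that("noiseless paired-model curves return the generating parameters", {
  cv <- noiseless_curve(paired_model())
  fit <- nernst_fit(cv, model = "paired4")
  pm <- fit$paired$model
  expect_within(1000 * c(pm$low_center, pm$high_center),
                c(-130.5, 370), 0.1)
  expect_within(1000 * pm$spacing, 30, 0.1)
  expect_within(1000 * fit$transitions$midpoint,
                c(-145.5, -115.5, 355, 385), 0.1)
  expect_equal(occupancy(fit), 0.88, tolerance = 1e-4)
})

test_that("symmetric paired model degenerates to 50% occupancy", {
  pm <- paired_model(low_center = -0.1, high_center = 0.35,
                     spacing = 0, a_low = 0.25, a_high = 0.25)
  cv <- noiseless_curve(pm)
  # zero spacing makes the pair members coincide, which the fitter flags
  expect_warning(fit <- nernst_fit(cv, model = "paired4"),
                 "coincident")
  expect_equal(occupancy(fit), 0.5, tolerance = 0.02)
  # two two-fold-degenerate transitions
  expect_within(1000 * fit$paired$model$spacing, 0, 5)
})

test_that("overfitting a single transition conserves total amplitude", {
  one <- transition_set(0.15, 0.8)
  cv <- noiseless_curve(one)
  fit1 <- nernst_fit(cv, model = "free", n_transitions = 1)
  fit2 <- suppressWarnings(nernst_fit(cv, model = "free",
                                      n_transitions = 2))
  expect_equal(sum(fit2$transitions$amplitude), 0.8, tolerance = 1e-3)
  # either a vanishing amplitude or two coincident midpoints
  a <- fit2$transitions$amplitude
  dm <- abs(diff(fit2$transitions$midpoint))
  expect_true(min(a) < 1e-3 * sum(a) || any(dm < 1e-3))
  # and it cannot beat the true model's residual
  expect_lte(fit2$residual_norm, fit1$residual_norm + 1e-8)
})

test_that("a flat curve yields a near-zero amplitude flag", {
  cv <- titration_curve(seq(-0.4, 0.6, by = 0.05),
                        rep(0.5, 21), frame = "SHE")
  expect_warning(nernst_fit(cv, model = "free", n_transitions = 1),
                 "near zero|flat")
})

test_that("model limits satisfy conservation beyond the data window", {
  cv <- noiseless_curve(wt_transitions(), aox = 0.07)
  fit <- nernst_fit(cv, model = "free", n_transitions = 2)
  lo <- min(cv$potential) - 2; hi <- max(cv$potential) + 2
  expect_equal(predict(fit, lo),
               fit$oxidized_baseline + sum(fit$transitions$amplitude),
               tolerance = 1e-9)
  expect_equal(predict(fit, hi), fit$oxidized_baseline,
               tolerance = 1e-9)
})

test_that("paired fit matches a free 4-transition fit on conforming data", {
  # noiseless data satisfying the constraints: both parameterizations
  # reach the same (essentially zero) residual
  cv <- noiseless_curve(paired_model())
  fit_c <- nernst_fit(cv, model = "paired4")
  fit_f <- nernst_fit(cv, model = "free", n_transitions = 4)
  expect_lte(abs(fit_c$residual_norm - fit_f$residual_norm),
             0.01 * fit_f$residual_norm + 1e-10)
  expect_within(1000 * fit_f$transitions$midpoint,
                1000 * fit_c$transitions$midpoint, 0.5)
  # with noise, the free model is the nested superset: its optimum can
  # only improve on the constrained one
  sc <- titration_scenario(paired_model(), noise_sd = 0.005,
                           replicates = 3, seed = 7)
  cvn <- averaged_curve(sc)
  fit_cn <- nernst_fit(cvn, model = "paired4")
  fit_fn <- nernst_fit(cvn, model = "free", n_transitions = 4)
  expect_lte(fit_fn$residual_norm, fit_cn$residual_norm + 1e-10)
})

test_that("fitting before vs after SHE correction shifts midpoints exactly", {
  sc <- titration_scenario(wt_transitions(), noise_sd = 0.01,
                           replicates = 3, seed = 3)
  raw <- simulate_titration(sc, branch = "oxidative")
  raw_avg <- average_replicates(raw)
  # fit the raw curve by relabelling the frame (no numeric change)
  raw_as_she <- titration_curve(raw_avg$potential, raw_avg$absorbance,
                                branch = "oxidative", frame = "SHE",
                                errors = raw_avg$errors)
  fit_raw <- nernst_fit(raw_as_she, model = "free", n_transitions = 2)
  fit_she <- nernst_fit(average_replicates(lapply(raw, she_correct)),
                        model = "free", n_transitions = 2)
  # identical to optimizer convergence (well below a thousandth of a mV)
  expect_equal(fit_she$transitions$midpoint,
               fit_raw$transitions$midpoint + 0.200, tolerance = 1e-6)
})

test_that("constrained-fit midpoints are unbiased over 100 noisy seeds", {
  lows <- highs <- spacings <- occs <- numeric(100)
  for (s in 1:100) {
    sc <- titration_scenario(paired_model(), noise_sd = 0.01,
                             replicates = 3, seed = s)
    fit <- nernst_fit(averaged_curve(sc), model = "paired4")
    pm <- fit$paired$model
    lows[s] <- pm$low_center; highs[s] <- pm$high_center
    spacings[s] <- pm$spacing; occs[s] <- occupancy(fit)
  }
  # bias within +/- 5 mV on both pair centers
  expect_within(1000 * mean(lows), -130.5, 5)
  expect_within(1000 * mean(highs), 370, 5)
  # the well-determined high-potential pair stays within +/- 10 mV on
  # every seed; the weak low-potential pair (12% of the amplitude) is
  # held to the same band in spread (SD), not worst case
  expect_lt(max(abs(1000 * highs - 370)), 10)
  expect_lt(1000 * sd(lows), 10)
  expect_within(100 * mean(occs), 88, 1)
  expect_within(1000 * mean(spacings), 30, 3)
})

test_that("fit methods expose the classic modelling surface", {
  cv <- noiseless_curve(wt_transitions())
  fit <- nernst_fit(cv, model = "free", n_transitions = 2)
  expect_named(coef(fit), c("midpoint1", "midpoint2", "amplitude1",
                            "amplitude2", "oxidized_baseline"))
  expect_equal(length(fitted(fit)), nrow(cv))
  expect_equal(residuals(fit), cv$absorbance - fitted(fit))
  expect_s3_class(summary(fit), "summary.nernst_fit")
  expect_output(print(fit), "Multi-transition Nernst fit")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "titration_curve")
  # simulate is deterministic under a seed and restores RNG state
  sims2 <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(sims[[1]]$absorbance, sims2[[1]]$absorbance)
})

test_that("fixing the oxidized baseline reproduces the normalized fit", {
  cv <- noiseless_curve(wt_transitions(), aox = 1.0)
  fit <- nernst_fit(cv, model = "free", n_transitions = 2, fix_aox = 1.0)
  expect_equal(fit$oxidized_baseline, 1.0)
  expect_within(1000 * fit$transitions$midpoint, c(-92, 353), 1)
})
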