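# Shared fixtures: every input is generated in code by the package's own
# forward models.

# wild-type as-isolated transitions: +353 / -92 mV at an 85/15 split
wt_transitions <- function() transition_set(c(0.353, -0.092),
                                            c(0.85, 0.15))

# three-transition pattern of a distal-Met->His mutant (the ~-450 mV
# transition of the mutated calcium-free heme lies below the window)
mutant_transitions <- function() transition_set(c(0.370, 0.050, -0.130),
                                                c(0.44, 0.44, 0.06))

# simulate -> SHE-correct -> pool branches -> average, the standard
# preprocessing chain (both sweeps of each series enter the average)
averaged_curve <- function(scenario, branch = "both") {
  curves <- simulate_titration(scenario, branch = branch)
  curves <- lapply(curves, she_correct, reference_offset =
                     scenario$reference_offset)
  curves <- pool_branches(curves)
  if (length(curves) == 1) return(curves[[1]])
  average_replicates(curves)
}

# noiseless single-replicate curve from a transition set or paired model
noiseless_curve <- function(transitions, aox = 0) {
  sc <- titration_scenario(transitions, noise_sd = 0, replicates = 1,
                           oxidized_baseline = aox)
  averaged_curve(sc)
}

expect_within <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("%s within %g of %s",
                              paste(signif(object, 6), collapse = ", "),
                              tol,
                              paste(signif(expected, 6), collapse = ", ")))
}
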