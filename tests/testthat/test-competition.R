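test_that("equilibrium solver handles degenerate systems exactly", {
  # no ligands: everything stays free
  eq <- solve_equilibrium(competition_system(3e-3))
  expect_equal(eq$free_calcium, 3e-3)
  expect_length(eq$complexes, 0)
  # zero calcium
  eq0 <- solve_equilibrium(
    competition_system(0, list(ligand("EGTA", 1e-7, 5e-3))))
  expect_equal(eq0$free_calcium, 0)
  expect_equal(unname(eq0$complexes), 0)
  # single ligand with total_ca = total_ligand = 2 kd has the
  # closed-form quadratic root x = kd (hand algebra oracle)
  kd <- 3.7e-6
  eq1 <- solve_equilibrium(
    competition_system(2 * kd, list(ligand("L", kd, 2 * kd))))
  expect_equal(eq1$free_calcium, kd, tolerance = 1e-10)
})

test_that("calibration composition yields the published dye-complex range", {
  egta <- ligand("EGTA", 1.0e-7, 5e-3)
  dye <- ligand("CalBryte-590", 1.4e-6, 2e-5)
  cplx <- vapply(seq(0, 5e-3, length.out = 11), function(ca)
    solve_equilibrium(competition_system(ca, list(egta, dye)))$
      complexes[["CalBryte-590"]], numeric(1))
  # complexes run from 0 up to ~18 uM across the 0-5 mM series
  expect_equal(cplx[1], 0)
  expect_equal(round(max(cplx) * 1e6), 18)
  expect_true(all(diff(cplx) > 0))
})

test_that("mass balance and complex bounds hold across random systems", {
  set.seed(21)
  for (i in 1:200) {
    nlig <- sample(1:4, 1)
    ligs <- lapply(seq_len(nlig), function(j)
      ligand(paste0("L", j), 10^runif(1, -9, -3), runif(1, 0, 1e-2)))
    tot <- runif(1, 0, 1e-2)
    eq <- solve_equilibrium(competition_system(tot, ligs))
    bal <- eq$free_calcium + sum(eq$complexes)
    expect_lt(abs(bal - tot), 1e-8 * max(tot, 1e-12))
    for (j in seq_len(nlig))
      expect_lte(eq$complexes[[j]], ligs[[j]]$total + 1e-15)
  }
})

test_that("closed-form cubic agrees with the iterative solver to 1e-8", {
  set.seed(33)
  worst <- 0
  for (i in 1:1000) {
    la <- ligand("A", 10^runif(1, -9, -3), runif(1, 0, 1e-2))
    lb <- ligand("B", 10^runif(1, -9, -3), runif(1, 0, 1e-2))
    tot <- runif(1, 1e-9, 1e-2)
    x_cubic <- free_calcium_cubic(tot, la, lb)
    x_iter <- solve_equilibrium(
      competition_system(tot, list(la, lb)))$free_calcium
    worst <- max(worst, abs(x_cubic - x_iter) / x_iter)
  }
  expect_lt(worst, 1e-8)
  # degenerate reductions
  la <- ligand("A", 1e-6, 2e-6)
  expect_equal(free_calcium_cubic(4e-6, la, ligand("B", 1e-5, 0)),
               solve_equilibrium(
                 competition_system(4e-6, list(la)))$free_calcium,
               tolerance = 1e-10)
  expect_equal(free_calcium_cubic(3e-3, ligand("A", 1e-6, 0),
                                  ligand("B", 1e-5, 0)), 3e-3)
})

test_that("free calcium and complexes respond monotonically to total calcium", {
  egta <- ligand("EGTA", 1.0e-7, 5e-3)
  dye <- ligand("CalBryte-590", 1.4e-6, 2e-5)
  tots <- seq(1e-5, 5e-3, length.out = 40)
  res <- t(vapply(tots, function(ca) {
    eq <- solve_equilibrium(competition_system(ca, list(egta, dye)))
    c(eq$free_calcium, eq$complexes)
  }, numeric(3)))
  expect_true(all(diff(res[, 1]) > 0))
  expect_true(all(diff(res[, 2]) >= 0))
  expect_true(all(diff(res[, 3]) >= 0))
})

test_that("calibration fit recovers exact quadratic coefficients", {
  egta <- ligand("EGTA", 1.0e-7, 5e-3)
  dye <- ligand("CalBryte-590", 1.4e-6, 2e-5)
  cas <- seq(0, 5e-3, length.out = 9)
  systems <- lapply(cas, function(ca)
    competition_system(ca, list(egta, dye)))
  cplx <- vapply(systems, function(s)
    solve_equilibrium(s)$complexes[["CalBryte-590"]], numeric(1))
  # construct signals so that complex = 1e-8 s + 1e-12 s^2 exactly
  # (positive branch of the inverse exists for every complex >= 0)
  truth <- c(0, 1e-8, 1e-12)
  sig <- vapply(cplx, function(cc)
    (-truth[2] + sqrt(truth[2]^2 + 4 * truth[3] * cc)) / (2 * truth[3]),
    numeric(1))
  cal <- build_calibration(sig, systems)
  expect_within(unname(cal$coefficients), truth,
                1e-8 * abs(truth) + 1e-13)
  expect_equal(apply_calibration(cal, sig), cplx, tolerance = 1e-8)
  # constant signals are rank-deficient
  expect_error(build_calibration(rep(1, 9), systems), "rank-deficient")
})

test_that("predicted assay curves fall with protein and with affinity", {
  pc <- seq(0, 3.5e-6, length.out = 8)
  strong <- predict_assay_curve(pc, 1e-7)
  weak <- predict_assay_curve(pc, 1e-5)
  # non-increasing in protein concentration
  expect_true(all(diff(strong) < 0))
  # stronger binder strips more calcium from the dye
  expect_true(all(strong[-1] < weak[-1]))
  # protein-free point equals the dye-only equilibrium
  eq <- solve_equilibrium(
    competition_system(2.4e-6, list(ligand("CalBryte-590", 1.4e-6,
                                           2e-5))))
  expect_equal(strong[1], eq$complexes[["CalBryte-590"]])
  # a non-binder leaves the curve flat at that value
  flat <- predict_assay_curve(pc, 1e3)
  expect_lt(max(abs(flat - flat[1])), 1e-12)
})

test_that("Kd upper limit brackets the truth and flags non-binders", {
  # strong binder, tiny noise: upper limit below 1 uM
  sc <- assay_scenario(kd_protein = 1e-8, noise_sd = 2e-8, seed = 2)
  a <- simulate_assay(sc)
  agg <- aggregate(complex ~ protein_conc, a, mean)
  sds <- aggregate(complex ~ protein_conc, a, sd)$complex
  sds <- rep(sqrt(mean(sds^2)), length(sds))  # pooled replicate SD
  est <- estimate_kd_upper_limit(agg$protein_conc, agg$complex, sds)
  expect_lt(est$upper_limit, 1e-6)
  expect_false(est$unbounded)
  # non-binder: grid maximum is consistent, flagged unbounded
  scn <- assay_scenario(kd_protein = 1e3, noise_sd = 1e-7, seed = 4)
  an <- simulate_assay(scn)
  aggn <- aggregate(complex ~ protein_conc, an, mean)
  sdsn <- aggregate(complex ~ protein_conc, an, sd)$complex
  sdsn <- rep(sqrt(mean(sdsn^2)), length(sdsn))
  estn <- estimate_kd_upper_limit(aggn$protein_conc, aggn$complex, sdsn)
  expect_true(estn$unbounded)
})

test_that("upper limit covers the generating Kd in >= 95% of seeds", {
  hits <- 0L
  nseeds <- 50L
  for (s in seq_len(nseeds)) {
    sc <- assay_scenario(kd_protein = 5e-7, noise_sd = 0.11e-6, seed = s)
    a <- simulate_assay(sc)
    agg <- aggregate(complex ~ protein_conc, a, mean)
    sds <- aggregate(complex ~ protein_conc, a, sd)$complex
    sds <- rep(sqrt(mean(sds^2)), length(sds))
    est <- tryCatch(
      estimate_kd_upper_limit(agg$protein_conc, agg$complex, sds),
      error = function(e) NULL)
    if (!is.null(est) && est$upper_limit >= 5e-7) hits <- hits + 1L
  }
  expect_gte(hits / nseeds, 0.95)
})

test_that("elemental ratios normalize concentrations to iron", {
  as_iso_1 <- c(Ba = 0.12, Ca = 556.39, Cu = 3.89, Fe = 691.17,
                K = 53.71, Na = 6312.38, Ni = 24.02, Sr = 1.09,
                Zn = 100.05)
  r <- elemental_ratio(as_iso_1)
  expect_equal(round(r[["Ca"]], 2), 0.80)
  expect_equal(r[["Fe"]], 1)
  # EGTA treatment strips calcium by an order of magnitude
  egta_1 <- c(Ca = 18.46, Fe = 533.60)
  expect_equal(round(elemental_ratio(egta_1)[["Ca"]], 3), 0.035)
  expect_equal(elemental_ratio(c(Ca = 7, Fe = 7))[["Ca"]], 1)
  expect_error(elemental_ratio(c(Ca = 1)), "missing")
  expect_error(elemental_ratio(c(Ca = 1, Fe = 0)), "positive")
})

test_that("heme concentration follows Beer-Lambert with epsilon 62", {
  expect_equal(heme_concentration(0.62), 0.01)
  expect_equal(heme_concentration(0), 0)
  # the 0.5 mM protein stock from A550 = 31
  expect_equal(heme_concentration(31), 0.5)
  expect_equal(heme_concentration(0.62, path_cm = 0.2), 0.05)
  expect_error(heme_concentration(0.5, path_cm = 0), "positive")
})
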