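#' Scenario for simulating a spectroelectrochemical titration
#'
#' Describes the forward model of one titration experiment: the true
#' transition parameters, the applied-potential program (-600 to
#' +400 mV vs the reference electrode in 50 mV steps by default), the
#' reference-electrode offset, replicate count and the additive Gaussian
#' noise level.  The default noise, 0.01 of the total amplitude, and the
#' three replicates mirror the replicate structure of the measured
#' titrations.
#'
#' @param transitions A [transition_set()] or [paired_model()] (V vs
#'   SHE).  Defaults to the two wild-type as-isolated transitions
#'   (+353 and -92 mV at an 85/15 amplitude split).
#' @param potential_grid Applied potentials in the raw reference frame,
#'   V.
#' @param reference_offset Reference electrode potential vs SHE, V.
#' @param oxidized_baseline True fully-oxidized absorbance.
#' @param noise_sd Gaussian noise standard deviation, absorbance units.
#' @param replicates Number of replicate series.
#' @param hysteresis_offset Constant potential lag (V) applied to the
#'   reductive branch.
#' @param seed Integer seed; mandatory when `noise_sd > 0`.
#' @return An object of class `titration_scenario`.
#' @export
titration_scenario <- function(transitions = transition_set(
                                 c(0.353, -0.092), c(0.85, 0.15)),
                               potential_grid = seq(-0.600, 0.400,
                                                    by = 0.050),
                               reference_offset = 0.200,
                               oxidized_baseline = 0.0,
                               noise_sd = 0.01,
                               replicates = 3L,
                               hysteresis_offset = 0,
                               seed = NULL) {
  if (inherits(transitions, "paired_model"))
    transitions <- expand_pairs(transitions)
  transitions <- as_transition_set(transitions)
  stopifnot(is.numeric(potential_grid), length(potential_grid) >= 2,
            noise_sd >= 0, replicates >= 1)
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is mandatory for stochastic simulation", call. = FALSE)
  structure(list(transitions = transitions,
                 potential_grid = potential_grid,
                 reference_offset = reference_offset,
                 oxidized_baseline = oxidized_baseline,
                 noise_sd = noise_sd,
                 replicates = as.integer(replicates),
                 hysteresis_offset = hysteresis_offset,
                 seed = seed),
            class = "titration_scenario")
}

#' Simulate replicate titration curves
#'
#' Forward model of the titration analysis: the multi-transition
#' Nernstian response is evaluated at the SHE-corrected potentials
#' (applied grid plus reference offset), i.i.d. Gaussian noise is added,
#' and the curves are returned in the raw reference frame, exactly as
#' the instrument would report them (pass through [she_correct()]
#' before fitting).  Each simulated series covers, like the measured
#' ones, an oxidative sweep followed by a reductive sweep back
#' (`branch = "both"`, the default), so `replicates = 3` yields six
#' traces; single branches can be requested instead.  The reductive
#' branch lags the oxidative one by the scenario's hysteresis offset.
#' Output is deterministic for a fixed scenario seed.
#'
#' @param scenario A [titration_scenario()].
#' @param branch `"both"` (default), `"oxidative"` (ascending
#'   potentials) or `"reductive"`.
#' @return A list of [titration_curve()]s in the raw frame
#'   (`replicates` curves per requested branch).
#' @export
simulate_titration <- function(scenario,
                               branch = c("both", "oxidative",
                                          "reductive")) {
  stopifnot(inherits(scenario, "titration_scenario"))
  branch <- match.arg(branch)
  branches <- if (branch == "both") c("oxidative", "reductive")
              else branch
  base <- lapply(branches, function(br) {
    grid <- sort(scenario$potential_grid)
    if (br == "reductive") grid <- rev(grid)
    she <- grid + scenario$reference_offset
    if (br == "reductive") she <- she - scenario$hysteresis_offset
    list(branch = br, grid = grid,
         mu = scenario$oxidized_baseline +
           nernst_response(she, scenario$transitions))
  })
  with_seed_(scenario$seed, {
    out <- list()
    for (r in seq_len(scenario$replicates)) for (b in base) {
      noise <- if (scenario$noise_sd > 0)
        stats::rnorm(length(b$grid), 0, scenario$noise_sd) else 0
      out[[length(out) + 1L]] <-
        titration_curve(b$grid, b$mu + noise, branch = b$branch,
                        frame = "raw")
    }
    out
  })
}

#' Default reduced/oxidized basis spectra
#'
#' Synthetic UV-Vis basis spectra emulating the redox difference
#' spectrum of a c-type cytochrome: the reduced basis has a Soret band
#' at 415 nm with alpha and beta bands at 550 and 521 nm; the oxidized
#' basis has a weaker, broader Soret band at 408 nm.  Both vanish at
#' 700 nm, the baseline wavelength.
#'
#' @param wavelength Wavelength grid, nm (must cover 417 and 700 nm).
#' @return A list with `reduced` and `oxidized` numeric vectors on the
#'   grid.
#' @export
default_basis_spectra <- function(wavelength = seq(350, 700, by = 1)) {
  stopifnot(min(wavelength) <= 417, max(wavelength) >= 700)
  band <- function(center, height, width)
    height * exp(-0.5 * ((wavelength - center) / width)^2)
  list(reduced = band(415, 1.00, 10) + band(550, 0.12, 6) +
         band(521, 0.08, 6),
       oxidized = band(408, 0.70, 13))
}

#' Simulate a potential-indexed stack of UV-Vis spectra
#'
#' Each potential column is the mixture
#' `f_red * basis_reduced + (1 - f_red) * basis_oxidized + offset + noise`
#' where `f_red` is the scenario's Nernstian reduced fraction at that
#' (SHE-corrected) potential.  A constant baseline offset can be added
#' to every column to exercise [baseline_correct()].
#'
#' @param scenario A [titration_scenario()].
#' @param basis List with `reduced` and `oxidized` spectra on
#'   `wavelength`; defaults to [default_basis_spectra()].
#' @param wavelength Wavelength grid, nm.
#' @param baseline_offset Constant absorbance added to all columns.
#' @return A [spectra_stack()] in the raw reference frame.
#' @export
simulate_spectra_stack <- function(scenario,
                                   basis = NULL,
                                   wavelength = seq(350, 700, by = 1),
                                   baseline_offset = 0) {
  stopifnot(inherits(scenario, "titration_scenario"))
  basis <- basis %||% default_basis_spectra(wavelength)
  stopifnot(length(basis$reduced) == length(wavelength),
            length(basis$oxidized) == length(wavelength))
  grid <- sort(scenario$potential_grid)
  she <- grid + scenario$reference_offset
  total <- sum(scenario$transitions$amplitude)
  f_red <- nernst_response(she, scenario$transitions) / total
  mat <- vapply(f_red, function(f)
    f * basis$reduced + (1 - f) * basis$oxidized + baseline_offset,
    numeric(length(wavelength)))
  if (scenario$noise_sd > 0)
    mat <- with_seed_(scenario$seed,
                      mat + stats::rnorm(length(mat), 0,
                                         scenario$noise_sd))
  spectra_stack(wavelength, grid, mat, frame = "raw")
}

#' Scenario for simulating the dye-competition calcium assay
#'
#' Protein concentrations 0-3.5 uM against 20 uM indicator dye
#' (Kd 1.4e-6 M) on a 2.4 uM background calcium pool, 1.6 sites per
#' protein molecule, in triplicate -- the composition of the measured
#' competition assay.
#'
#' @param protein_grid Protein concentrations, mol/L.
#' @param kd_protein True apparent protein Kd, mol/L.
#' @param sites_per_protein Calcium sites per molecule.
#' @param background_calcium Total calcium in the assay buffer, mol/L.
#' @param dye Indicator dye [ligand()].
#' @param noise_sd Gaussian noise on the complex concentration, mol/L
#'   (default 0.1 uM, about 5% of the protein-free complex).
#' @param replicates Replicates per concentration.
#' @param seed Integer seed; mandatory when `noise_sd > 0`.
#' @return An object of class `assay_scenario`.
#' @export
assay_scenario <- function(protein_grid = seq(0, 3.5e-6,
                                              length.out = 8),
                           kd_protein = 1e-6,
                           sites_per_protein = 1.6,
                           background_calcium = 2.4e-6,
                           dye = ligand("CalBryte-590", 1.4e-6, 2e-5),
                           noise_sd = 0.1e-6,
                           replicates = 3L,
                           seed = NULL) {
  stopifnot(all(protein_grid >= 0), kd_protein > 0, noise_sd >= 0,
            replicates >= 1, inherits(dye, "ligand"))
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is mandatory for stochastic simulation", call. = FALSE)
  structure(list(protein_grid = protein_grid, kd_protein = kd_protein,
                 sites_per_protein = sites_per_protein,
                 background_calcium = background_calcium, dye = dye,
                 noise_sd = noise_sd, replicates = as.integer(replicates),
                 seed = seed),
            class = "assay_scenario")
}

#' Simulate a dye-competition assay table
#'
#' For every protein concentration the true Ca-dye complex is computed
#' with [solve_equilibrium()] (via [predict_assay_curve()]) and Gaussian
#' noise is added per replicate.  Deterministic for a fixed seed.
#'
#' @param scenario An [assay_scenario()].
#' @return A data frame with columns `protein_conc` (mol/L),
#'   `replicate` and `complex` (observed Ca-dye complex, mol/L).
#' @export
simulate_assay <- function(scenario) {
  stopifnot(inherits(scenario, "assay_scenario"))
  truth <- predict_assay_curve(scenario$protein_grid,
                               scenario$kd_protein,
                               scenario$sites_per_protein,
                               scenario$background_calcium,
                               scenario$dye)
  out <- expand.grid(replicate = seq_len(scenario$replicates),
                     idx = seq_along(scenario$protein_grid))
  out <- data.frame(protein_conc = scenario$protein_grid[out$idx],
                    replicate = out$replicate,
                    complex = truth[out$idx])
  if (scenario$noise_sd > 0)
    out$complex <- with_seed_(scenario$seed,
                              out$complex + stats::rnorm(nrow(out), 0,
                                                         scenario$noise_sd))
  out
}

#' Simulate raw fluorescence tables for the full Kd pipeline
#'
#' Emits what the plate reader would deliver: a calibration series
#' (total calcium in EGTA buffer plus dye, with fluorescence signals)
#' and a protein assay series, both passed through the same synthetic
#' instrument response `signal = s0 + s1*c + s2*c^2` applied to the true
#' Ca-dye complex concentration `c`.
#'
#' @param scenario An [assay_scenario()].
#' @param instrument Numeric length-3: instrument response polynomial
#'   coefficients (intercept; per mol/L; per (mol/L)^2).  The default is
#'   mildly nonlinear and strictly increasing over the assay's complex
#'   range.
#' @param calibration_ca Total-calcium grid of the calibration series,
#'   mol/L.
#' @param egta EGTA [ligand()] used in the calibration buffer.
#' @return A list with `calibration` (data frame: `total_ca`, `signal`)
#'   and `assay` (data frame: `protein_conc`, `replicate`, `signal`).
#' @export
simulate_fluorescence_assay <- function(scenario,
                                        instrument = c(100, 5e7, -4e11),
                                        calibration_ca = seq(0, 5e-3,
                                                             length.out = 11),
                                        egta = ligand("EGTA", 1.0e-7,
                                                      5e-3)) {
  stopifnot(inherits(scenario, "assay_scenario"),
            length(instrument) == 3)
  respond <- function(cplx)
    instrument[1] + instrument[2] * cplx + instrument[3] * cplx^2
  cal_complex <- vapply(calibration_ca, function(ca) {
    eq <- solve_equilibrium(competition_system(ca, list(egta,
                                                        scenario$dye)))
    eq$complexes[[scenario$dye$name]]
  }, numeric(1))
  assay <- simulate_assay(scenario)
  list(calibration = data.frame(total_ca = calibration_ca,
                                signal = respond(cal_complex)),
       assay = data.frame(protein_conc = assay$protein_conc,
                          replicate = assay$replicate,
                          signal = respond(pmax(assay$complex, 0))))
}

# ---------------------------------------------------------------------------
# coordinate-file fixtures

#' Write a synthetic coordinate fixture with heme irons and calcium ions
#'
#' Builds a minimal, well-formed coordinate file around the supplied
#' metal positions: each iron position becomes the FE atom of a HEC
#' (heme c) residue, padded with its four pyrrole nitrogens so that
#' heme-atom superposition has enough atoms to work with; each calcium
#' position becomes a CA ion record.  Optional decoy atoms (e.g. an
#' iron-sulfur-cluster FE, or a zinc mislabeled with atom name "CA")
#' exercise the site filters.  Both PDB and mmCIF dialects can be
#' written and parse to identical site lists.
#'
#' @param fe_positions Numeric n-by-3 matrix of heme iron positions, A.
#' @param ca_positions Numeric m-by-3 matrix of calcium positions, A
#'   (may have zero rows).
#' @param decoys Optional data frame with columns `element`, `name`,
#'   `resid`, `x`, `y`, `z` and optionally `altloc`/`occupancy`.
#' @param file Optional output path; the dialect text is also returned.
#' @param format `"pdb"` or `"mmcif"`.
#' @param entry_id Identifier written into the file header.
#' @return Invisibly, the file text (character vector of lines).
#' @export
make_fixture_structure <- function(fe_positions,
                                   ca_positions = NULL,
                                   decoys = NULL,
                                   file = NULL,
                                   format = c("pdb", "mmcif"),
                                   entry_id = "SYNT") {
  format <- match.arg(format)
  fe_positions <- matrix(as.numeric(fe_positions), ncol = 3)
  if (!is.null(ca_positions) && length(ca_positions))
    ca_positions <- matrix(as.numeric(ca_positions), ncol = 3)
  else ca_positions <- matrix(numeric(0), ncol = 3)
  stopifnot(all(is.finite(fe_positions)), all(is.finite(ca_positions)))

  atoms <- NULL
  resno <- 0L
  # pyrrole nitrogen offsets around each iron (A)
  ring <- rbind(c(2.0, 0, 0), c(0, 2.0, 0), c(-2.0, 0, 0), c(0, -2.0, 0))
  for (i in seq_len(nrow(fe_positions))) {
    resno <- resno + 1L
    p <- fe_positions[i, ]
    atoms <- rbind(atoms,
      data.frame(element = c("FE", "N", "N", "N", "N"),
                 name = c("FE", "NA", "NB", "NC", "ND"),
                 resid = "HEC", chain = "A", resno = resno,
                 altloc = "", occupancy = 1,
                 x = c(p[1], p[1] + ring[, 1]),
                 y = c(p[2], p[2] + ring[, 2]),
                 z = c(p[3], p[3] + ring[, 3])))
  }
  for (i in seq_len(nrow(ca_positions))) {
    resno <- resno + 1L
    atoms <- rbind(atoms,
      data.frame(element = "CA", name = "CA", resid = "CA", chain = "A",
                 resno = resno, altloc = "", occupancy = 1,
                 x = ca_positions[i, 1], y = ca_positions[i, 2],
                 z = ca_positions[i, 3]))
  }
  if (!is.null(decoys) && nrow(decoys)) {
    for (col in c("altloc", "occupancy"))
      if (is.null(decoys[[col]]))
        decoys[[col]] <- if (col == "altloc") "" else 1
    if (is.null(decoys$chain)) decoys$chain <- "A"
    if (is.null(decoys$resno))
      decoys$resno <- resno + seq_len(nrow(decoys))
    atoms <- rbind(atoms, decoys[, names(atoms)])
  }
  text <- if (format == "pdb") fixture_pdb_text_(atoms, entry_id)
          else fixture_cif_text_(atoms, entry_id)
  if (!is.null(file)) writeLines(text, file)
  invisible(text)
}

fixture_pdb_text_ <- function(atoms, entry_id) {
  lines <- sprintf("HEADER    SYNTHETIC FIXTURE                       %s",
                   entry_id)
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    nm <- if (nchar(a$name) >= 4) substr(a$name, 1, 4)
          else if (nchar(a$element) == 2) sprintf("%-4s", a$name)
          else sprintf(" %-3s", a$name)
    lines <- c(lines, sprintf(
      "HETATM%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, nm, a$altloc, a$resid, a$chain, a$resno,
      a$x, a$y, a$z, a$occupancy, 0, a$element))
  }
  c(lines, "END")
}

fixture_cif_text_ <- function(atoms, entry_id) {
  lines <- c(sprintf("data_%s", entry_id),
             "#",
             "loop_",
             "_atom_site.group_PDB",
             "_atom_site.id",
             "_atom_site.type_symbol",
             "_atom_site.label_atom_id",
             "_atom_site.label_alt_id",
             "_atom_site.label_comp_id",
             "_atom_site.label_asym_id",
             "_atom_site.label_entity_id",
             "_atom_site.label_seq_id",
             "_atom_site.pdbx_PDB_ins_code",
             "_atom_site.Cartn_x",
             "_atom_site.Cartn_y",
             "_atom_site.Cartn_z",
             "_atom_site.occupancy",
             "_atom_site.B_iso_or_equiv",
             "_atom_site.pdbx_formal_charge",
             "_atom_site.auth_seq_id",
             "_atom_site.auth_comp_id",
             "_atom_site.auth_asym_id",
             "_atom_site.auth_atom_id",
             "_atom_site.pdbx_PDB_model_num")
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    alt <- if (a$altloc == "") "." else a$altloc
    lines <- c(lines, sprintf(
      "HETATM %d %s %s %s %s %s 1 . ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
      i, a$element, a$name, alt, a$resid, a$chain,
      a$x, a$y, a$z, a$occupancy, 0, a$resno, a$resid, a$chain, a$name))
  }
  c(lines, "#")
}
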