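write_fix <- function(..., format = "pdb") {
  f <- tempfile(fileext = if (format == "pdb") ".pdb" else ".cif")
  make_fixture_structure(..., file = f, format = format)
  f
}

test_that("fixture files parse with exact coordinates in both dialects", {
  fe <- rbind(c(1.234, -2.5, 3.75))
  ca <- rbind(c(8.134, -2.5, 3.75))
  for (fmt in c("pdb", "mmcif")) {
    f <- write_fix(fe, ca, format = fmt)
    m <- read_structure(f)
    expect_equal(nrow(m), 6)  # FE + 4 pyrrole N + CA
    feat <- m[m$name == "FE", ]
    expect_equal(c(feat$x, feat$y, feat$z), c(1.234, -2.5, 3.75),
                 tolerance = 1e-3)
    unlink(f)
  }
})

test_that("PDB and mmCIF renderings give identical site lists", {
  fe <- rbind(c(0, 0, 0), c(20, 0, 0))
  ca <- rbind(c(6.9, 0, 0), c(28.6, 0, 0))
  mp <- read_structure(write_fix(fe, ca, format = "pdb"))
  mc <- read_structure(write_fix(fe, ca, format = "mmcif"))
  sp <- find_metal_sites(mp); sc <- find_metal_sites(mc)
  expect_equal(sp$kind, sc$kind)
  expect_equal(sp[, c("x", "y", "z")], sc[, c("x", "y", "z")],
               tolerance = 1e-3)
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  decoys <- data.frame(
    element = c("CA", "CA"), name = c("CA", "CA"), resid = c("CA", "CA"),
    chain = "B", resno = 50L, altloc = c("A", "B"),
    occupancy = c(0.4, 0.6),
    x = c(5, 6), y = 0, z = 0)
  f <- write_fix(rbind(c(0, 0, 0)), NULL, decoys = decoys)
  m <- read_structure(f)
  site <- find_metal_sites(m)
  ca <- site[site$kind == "calcium", ]
  expect_equal(nrow(ca), 1)           # one conformer retained
  expect_equal(ca$x, 6)               # the 0.6-occupancy one
  # occupancy tie breaks by altloc letter
  decoys$occupancy <- c(0.5, 0.5)
  m2 <- read_structure(write_fix(rbind(c(0, 0, 0)), NULL,
                                 decoys = decoys))
  ca2 <- find_metal_sites(m2)
  expect_equal(ca2[ca2$kind == "calcium", "x"], 5)  # altloc A wins
})

test_that("site finding filters by residue vocabulary and element", {
  decoys <- data.frame(
    element = c("FE", "ZN"), name = c("FE1", "CA"),
    resid = c("SF4", "DEC"), x = c(50, 60), y = 0, z = 0)
  f <- write_fix(rbind(c(0, 0, 0)), rbind(c(6.9, 0, 0)),
                 decoys = decoys)
  sites <- find_metal_sites(read_structure(f))
  # the iron-sulfur iron is not a heme iron; the Zn with atom name CA
  # is not calcium
  expect_equal(sum(sites$kind == "heme_iron"), 1)
  expect_equal(sum(sites$kind == "calcium"), 1)
  expect_false(any(sites$resid %in% c("SF4", "DEC")))
  # a protein C-alpha (element C, ATOM record) can never match calcium
})

test_that("distances form the full Fe x Ca cross product", {
  fe <- rbind(c(0, 0, 0), c(30, 0, 0))
  ca <- rbind(c(6.9, 0, 0), c(0, 8, 0), c(30, 0, 5))
  m <- read_structure(write_fix(fe, ca))
  d <- fe_ca_distances(m)
  expect_equal(nrow(d), 6)
  expect_equal(min(d$distance), 5)
  expect_equal(sort(d$distance)[2], 6.9)
  # empty cross product when no calcium is present
  m2 <- read_structure(write_fix(fe, NULL))
  expect_equal(nrow(fe_ca_distances(m2)), 0)
})

test_that("survey aggregates minima and is permutation invariant", {
  # two entries built to mirror the published geometry: the diheme
  # protein with 6.9 A in each domain, and a runner-up at 8.6 A
  f1 <- write_fix(rbind(c(0, 0, 0), c(25, 0, 0)),
                  rbind(c(6.9, 0, 0), c(25 + 6.9, 0, 0)))
  f2 <- write_fix(rbind(c(0, 0, 0)), rbind(c(8.6, 0, 0)))
  sv <- distance_survey(c(f1, f2))
  expect_equal(sv$global_min$distance, 6.9, tolerance = 1e-9)
  expect_equal(sv$per_entry_min$distance, c(6.9, 8.6),
               tolerance = 1e-9)
  expect_equal(sv$n_structures, 2)
  expect_equal(sv$n_distances, 5)
  # per-domain minima of the diheme entry are both 6.9 A
  d1 <- fe_ca_distances(read_structure(f1))
  per_fe <- tapply(d1$distance, d1$fe_id, min)
  expect_equal(as.numeric(per_fe), c(6.9, 6.9), tolerance = 1e-9)
  # shuffled input order yields identical sorted output
  sv2 <- distance_survey(c(f2, f1))
  expect_equal(sv2$distances$distance, sv$distances$distance)
  expect_equal(sv2$global_min$distance, sv$global_min$distance)
  # a survey of one entry is just its distance list
  sv1 <- distance_survey(c(f2))
  expect_equal(sv1$distances$distance, 8.6, tolerance = 1e-9)
  # structures without sites are flagged
  f3 <- write_fix(rbind(c(0, 0, 0)), NULL)
  expect_warning(distance_survey(c(f3)), "empty")
})

test_that("distances are invariant under rigid transformation", {
  fe <- rbind(c(0, 0, 0), c(20, 5, -3))
  ca <- rbind(c(6.9, 0, 0), c(15, 5, 4))
  m <- read_structure(write_fix(fe, ca))
  d0 <- fe_ca_distances(m)$distance
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xyz <- as.matrix(m[, c("x", "y", "z")]) %*% t(R)
  m2 <- m
  m2$x <- xyz[, 1] + 11.3; m2$y <- xyz[, 2] - 4; m2$z <- xyz[, 3] + 2
  expect_lt(max(abs(fe_ca_distances(m2)$distance - d0)), 1e-9)
})

test_that("Kabsch superposition recovers known transforms", {
  set.seed(9)
  A <- matrix(rnorm(30), 10, 3)
  # identity
  s0 <- superpose_coords(A, A)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-8)
  # known 30-degree rotation plus translation
  th <- pi / 6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  B <- A %*% t(R) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  s <- superpose_coords(A, B)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, R, tolerance = 1e-8)
  expect_error(superpose_coords(A[1:2, ], A[1:2, ]), "at least 3")
})

test_that("superposition is optimal and matches an independent package", {
  set.seed(10)
  A <- matrix(rnorm(24), 8, 3)
  B <- A + matrix(rnorm(24, 0, 0.3), 8, 3)
  s <- superpose_coords(A, B)
  # no random rigid transform of A does better (optimality spot check)
  for (i in 1:100) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- rbind(
      c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
        2 * (q[2] * q[4] + q[1] * q[3])),
      c(2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
        2 * (q[3] * q[4] - q[1] * q[2])),
      c(2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
        1 - 2 * (q[2]^2 + q[3]^2)))
    t <- rnorm(3, 0, 0.5)
    trial <- sweep(A %*% t(R), 2, t, "+")
    rmsd_trial <- sqrt(mean(rowSums((trial - B)^2)))
    expect_gte(rmsd_trial, s$rmsd - 1e-12)
  }
  # independent oracle: bio3d's fitting reports the same minimum RMSD
  # (bio3d rounds its value to three decimals)
  rmsd_bio3d <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)),
                            fit = TRUE)
  expect_equal(s$rmsd, rmsd_bio3d, tolerance = 2e-3)
})

test_that("within-structure heme superposition pairs atoms by name", {
  # two HEC groups related by a rigid transform: RMSD must vanish
  fe <- rbind(c(0, 0, 0), c(25, 3, -1))
  m <- read_structure(write_fix(fe, NULL))
  s <- superpose_hemes(m, list(chain = "A", resno = 1),
                       list(chain = "A", resno = 2))
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(s$n_atoms, 5)
})
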