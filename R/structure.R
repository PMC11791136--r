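#' Read a macromolecular structure into a flat atom table
#'
#' Parses a PDB or mmCIF coordinate file (via bio3d) into a
#' `structure_model`: a data frame of atoms with element, atom name,
#' residue name, chain, residue number, altloc, occupancy and Cartesian
#' coordinates in angstroms.
#'
#' Alternate locations are resolved by keeping, for each
#' (chain, residue, atom-name) group, the conformer with the highest
#' occupancy, ties broken by altloc letter.  For multi-model (NMR-style)
#' files only the first model is read.
#'
#' @param file Path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param entry_id Identifier stored with the model; defaults to the
#'   file name without extension.
#' @return An object of class `structure_model` (a data frame with
#'   attribute `entry_id`).
#' @export
read_structure <- function(file, format = c("auto", "pdb", "mmcif"),
                           entry_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(file))
    stop(sprintf("file not found: %s", file), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", file, ignore.case = TRUE)) "mmcif"
    else "pdb"
  }
  pdb <- tryCatch(
    suppressWarnings(
      if (format == "mmcif")
        bio3d::read.cif(file, rm.alt = FALSE, verbose = FALSE)
      else bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                           verbose = FALSE)),
    error = function(e)
      stop(sprintf("failed to parse %s as %s: %s", file, format,
                   conditionMessage(e)), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop(sprintf("no atom records found in %s", file), call. = FALSE)
  elem <- toupper(trimws(at$elesy %||% ""))
  # infer missing element symbols from the atom name, as PDB readers do
  noel <- is.na(elem) | elem == ""
  if (any(noel))
    elem[noel] <- toupper(substr(trimws(gsub("[0-9']", "",
                                             at$elety[noel])), 1, 2))
  atoms <- data.frame(
    element = elem,
    name = toupper(trimws(at$elety)),
    resid = toupper(trimws(at$resid)),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    hetero = at$type == "HETATM",
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop(sprintf("non-finite coordinates in %s", file), call. = FALSE)
  atoms <- resolve_altloc_(atoms)
  structure(atoms,
            entry_id = entry_id %||% sub("\\.[^.]+$", "", basename(file)),
            class = c("structure_model", "data.frame"))
}

# keep one conformer per (chain, resno, resid, atom name):
# highest occupancy, ties by altloc letter
resolve_altloc_ <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$name, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$resid,
                                   atoms$name, sep = "|")), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure %s: %d atoms, %d chains\n",
              attr(x, "entry_id"), nrow(x),
              length(unique(x$chain))))
  invisible(x)
}

#' Locate heme iron atoms and calcium ions in a structure
#'
#' Heme irons are Fe atoms belonging to residues named HEM or HEC (the
#' b- and c-type heme residue codes; configurable).  Calcium sites are
#' atoms whose element is Ca; in PDB-derived models a hetero-record
#' context is additionally required, so that a (carbon) C-alpha atom
#' named "CA" can never slip through on the atom-name fallback.
#'
#' @param model A [read_structure()] result.
#' @param heme_residues Residue names treated as hemes.
#' @return A data frame of class `metal_sites` with columns `kind`
#'   (`"heme_iron"` or `"calcium"`), `resid`, `chain`, `resno`, `x`,
#'   `y`, `z`; zero rows when nothing is found.
#' @export
find_metal_sites <- function(model, heme_residues = c("HEM", "HEC")) {
  stopifnot(inherits(model, "structure_model"))
  fe <- model$element == "FE" & model$resid %in% toupper(heme_residues)
  ca <- model$element == "CA" & model$hetero
  pick <- function(mask, kind) {
    m <- model[mask, c("resid", "chain", "resno", "x", "y", "z"),
               drop = FALSE]
    if (nrow(m)) m <- cbind(kind = kind, m)
    else m <- cbind(kind = character(0), m)
    m
  }
  out <- rbind(pick(fe, "heme_iron"), pick(ca, "calcium"))
  rownames(out) <- NULL
  structure(out, entry_id = attr(model, "entry_id"),
            class = c("metal_sites", "data.frame"))
}

#' All heme-iron to calcium distances in a structure
#'
#' Full cross product of heme iron atoms and calcium ions with their
#' Euclidean distances in angstroms.
#'
#' @inheritParams find_metal_sites
#' @return A data frame with one row per (Fe, Ca) pair: `fe_id`,
#'   `ca_id` (chain:resno labels) and `distance` (angstrom); zero rows
#'   if either site list is empty.
#' @export
fe_ca_distances <- function(model, heme_residues = c("HEM", "HEC")) {
  sites <- find_metal_sites(model, heme_residues)
  fe <- sites[sites$kind == "heme_iron", , drop = FALSE]
  ca <- sites[sites$kind == "calcium", , drop = FALSE]
  lab <- function(s) sprintf("%s:%s%d", s$resid, s$chain, s$resno)
  out <- expand.grid(i = seq_len(nrow(fe)), j = seq_len(nrow(ca)))
  d <- if (nrow(out)) sqrt((fe$x[out$i] - ca$x[out$j])^2 +
                           (fe$y[out$i] - ca$y[out$j])^2 +
                           (fe$z[out$i] - ca$z[out$j])^2) else numeric(0)
  data.frame(entry = rep(attr(sites, "entry_id"), nrow(out)),
             fe_id = if (nrow(out)) lab(fe)[out$i] else character(0),
             ca_id = if (nrow(out)) lab(ca)[out$j] else character(0),
             distance = d, stringsAsFactors = FALSE)
}

#' Aggregate a heme-iron/calcium distance survey over many structures
#'
#' Computes all Fe-Ca distances per entry, the per-entry minima, the
#' globally sorted distance list, and histogram-ready counts.  Entry
#' order does not affect the (sorted) outputs.  Structure and distance
#' counts depend on the structure set surveyed and are reported, never
#' asserted against any external database snapshot.
#'
#' @param models A list of [read_structure()] models (or a character
#'   vector of file paths, which are read first).
#' @param heme_residues Residue names treated as hemes.
#' @return An object of class `distance_survey` with elements
#'   `distances` (all pairs, sorted ascending), `per_entry_min`,
#'   `n_structures`, `n_structures_with_pairs`, `n_distances`,
#'   `global_min` (row with provenance) and `empty` flag.
#' @export
distance_survey <- function(models, heme_residues = c("HEM", "HEC")) {
  if (is.character(models))
    models <- lapply(models, read_structure)
  stopifnot(is.list(models), length(models) >= 1,
            all(vapply(models, inherits, TRUE, "structure_model")))
  per <- lapply(models, fe_ca_distances, heme_residues = heme_residues)
  all_d <- do.call(rbind, per)
  all_d <- all_d[order(all_d$distance), , drop = FALSE]
  rownames(all_d) <- NULL
  withp <- vapply(per, nrow, integer(1)) > 0
  per_min <- do.call(rbind, lapply(per[withp], function(d)
    d[which.min(d$distance), , drop = FALSE]))
  if (!is.null(per_min)) {
    per_min <- per_min[order(per_min$distance), , drop = FALSE]
    rownames(per_min) <- NULL
  }
  empty <- nrow(all_d) == 0
  if (empty)
    warning("no Fe-Ca pairs found in any structure; empty survey",
            call. = FALSE)
  structure(list(distances = all_d,
                 per_entry_min = per_min,
                 n_structures = length(models),
                 n_structures_with_pairs = sum(withp),
                 n_distances = nrow(all_d),
                 global_min = if (!empty) all_d[1, , drop = FALSE] else NULL,
                 empty = empty),
            class = "distance_survey")
}

#' @export
print.distance_survey <- function(x, ...) {
  cat(sprintf("Fe-Ca distance survey: %d structures (%d with pairs), %d distances\n",
              x$n_structures, x$n_structures_with_pairs, x$n_distances))
  if (!x$empty) {
    gm <- x$global_min
    cat(sprintf("  global minimum: %.2f A (%s, %s - %s)\n",
                gm$distance, gm$entry, gm$fe_id, gm$ca_id))
  }
  invisible(x)
}

#' Optimal rigid-body superposition of paired coordinate sets
#'
#' Least-squares superposition of two paired coordinate sets (Kabsch
#' algorithm): both sets are centered, the optimal rotation is obtained
#' from the SVD of the covariance matrix with a determinant correction
#' that excludes improper rotations (reflections), and the RMSD is
#' computed after applying the transform to the first set.
#'
#' @param coords_a,coords_b Numeric n-by-3 matrices (n >= 3) with rows
#'   in 1:1 correspondence, angstrom units.
#' @return A list with `rotation` (3x3, applied to centered `coords_a`),
#'   `translation` (length 3), `rmsd` (angstrom) and `transformed`
#'   (coords_a after superposition onto coords_b).
#' @export
superpose_coords <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  stopifnot(ncol(coords_a) == 3, ncol(coords_b) == 3,
            nrow(coords_a) == nrow(coords_b))
  if (nrow(coords_a) < 3)
    stop("need at least 3 paired atoms for a rigid superposition",
         call. = FALSE)
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  if (any(svd(A)$d < 1e-9 * max(svd(A)$d)) && nrow(A) == 3)
    stop("degenerate (collinear) coordinates", call. = FALSE)
  H <- crossprod(A, B)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  transformed <- sweep(A %*% t(R), 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((transformed - coords_b)^2)))
  list(rotation = R, translation = cb - as.vector(R %*% ca),
       rmsd = rmsd, transformed = transformed)
}

#' Superpose the heme groups of two residues within one structure
#'
#' Convenience wrapper: extracts the atoms of two heme residues, pairs
#' them by atom name, and calls [superpose_coords()].
#'
#' @param model A `structure_model`.
#' @param res_a,res_b Lists with `chain` and `resno` identifying the two
#'   heme residues.
#' @param heme_residues Residue names treated as hemes.
#' @return As [superpose_coords()], plus `n_atoms` matched.
#' @export
superpose_hemes <- function(model, res_a, res_b,
                            heme_residues = c("HEM", "HEC")) {
  stopifnot(inherits(model, "structure_model"))
  get_res <- function(r) {
    m <- model[model$resid %in% toupper(heme_residues) &
               model$chain == r$chain & model$resno == r$resno, ,
               drop = FALSE]
    if (nrow(m) == 0)
      stop(sprintf("no heme residue at %s%d", r$chain, r$resno),
           call. = FALSE)
    m
  }
  a <- get_res(res_a); b <- get_res(res_b)
  common <- intersect(a$name, b$name)
  if (length(common) < 3)
    stop("fewer than 3 atom names shared between the two hemes",
         call. = FALSE)
  a <- a[match(common, a$name), ]; b <- b[match(common, b$name), ]
  out <- superpose_coords(as.matrix(a[, c("x", "y", "z")]),
                          as.matrix(b[, c("x", "y", "z")]))
  out$n_atoms <- length(common)
  out
}

#' Fetch a structure file from the RCSB PDB (network required)
#'
#' Downloads a coordinate file by accession for optional accession-based
#' checks.  All package tests run on locally generated fixtures; this
#' helper is the only operation that touches the network.
#'
#' @param id Four-character PDB accession, e.g. `"7ZS0"`.
#' @param dir Download directory.
#' @param format `"pdb"` or `"mmcif"`.
#' @return Invisibly, the path to the downloaded file.
#' @export
fetch_structure <- function(id, dir = tempdir(),
                            format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", id))
  ext <- if (format == "pdb") "pdb" else "cif"
  dest <- file.path(dir, sprintf("%s.%s", tolower(id), ext))
  url <- sprintf("https://files.rcsb.org/download/%s.%s",
                 toupper(id), ext)
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  invisible(dest)
}
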