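# Rigid 7TM superposition (Kabsch) and voxel-grid consensus ligand volumes.
#
# Voxels live on a global lattice anchored at the origin: voxel (i,j,k)
# has its centre at ((i,j,k) + 0.5) * spacing, so grids with equal spacing
# are automatically commensurate and set operations are exact.

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinate sets, e.g. shared-BW-position 7TM C-alpha atoms of two
#' receptors.
#'
#' @param mobile,reference n x 3 coordinate matrices with matched rows
#'   (n >= 3, non-degenerate).
#' @return Object of class `rigid_transform`: list with `rotation` (3x3,
#'   `det = +1`), `translation` (length 3) and `rmsd` over the paired set.
#'   Apply with [apply_transform()]: `x %*% t(rotation) + translation`.
#' @export
superpose_kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3 ||
      nrow(mobile) != nrow(reference) || nrow(mobile) < 3)
    stop("need matched n x 3 coordinate sets with n >= 3")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  A <- sweep(mobile, 2, mc); B <- sweep(reference, 2, rc)
  s <- svd(t(A) %*% B)
  if (min(s$d) < 1e-12 && sum(s$d > 1e-12) < 2)
    stop("degenerate (collinear) coordinates; superposition undefined")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  rot <- s$v %*% D %*% t(s$u)
  trans <- rc - as.vector(rot %*% mc)
  fitted <- A %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform, RMSD %.4g A\n", x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param coords n x 3 matrix.
#' @param transform a `rigid_transform` (identity if `NULL`).
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  if (is.null(transform)) return(as.matrix(coords))
  stopifnot(inherits(transform, "rigid_transform"))
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        -transform$translation)
}

#' Superpose two structures on shared 7TM C-alpha positions
#'
#' Pairs C-alpha atoms across receptors via shared BW labels and runs
#' [superpose_kabsch()].
#'
#' @param mobile,reference structures (`toy_bundle`, atom data frame or PDB
#'   path).
#' @param mobile_bw,reference_bw BW maps ([assign_bw_numbers()]); taken from
#'   the bundles when omitted.
#' @return A `rigid_transform` (with `rmsd` over the paired C-alpha set).
#' @export
superpose_7tm <- function(mobile, reference, mobile_bw = NULL,
                          reference_bw = NULL) {
  get_bw <- function(s, bw) {
    if (!is.null(bw)) return(bw)
    if (inherits(s, "toy_bundle")) return(s$bw_map)
    stop("a BW map is required for plain structures")
  }
  mb <- get_bw(mobile, mobile_bw); rb <- get_bw(reference, reference_bw)
  shared <- intersect(mb$bw, rb$bw)
  if (length(shared) < 3) stop("fewer than 3 shared BW positions")
  ca_coords <- function(s, map, labels) {
    at <- as_atom_table(s)
    ca <- at[at$elety == "CA" & at$type == "ATOM", ]
    resno <- map$resno[match(labels, map$bw)]
    idx <- match(resno, ca$resno)
    if (anyNA(idx)) stop("missing C-alpha for a shared BW position")
    as.matrix(ca[idx, c("x", "y", "z")])
  }
  superpose_kabsch(ca_coords(mobile, mb, shared),
                   ca_coords(reference, rb, shared))
}

# --- voxel grids ---------------------------------------------------------

voxel_grid <- function(indices, spacing) {
  indices <- unique_rows(indices)
  structure(list(origin = c(0, 0, 0), spacing = spacing, indices = indices),
            class = "voxel_grid")
}

unique_rows <- function(m) {
  if (is.null(m) || nrow(m) == 0)
    return(matrix(integer(0), 0, 3))
  m[!duplicated(paste(m[, 1], m[, 2], m[, 3])), , drop = FALSE]
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel grid: %d occupied voxels, spacing %.3g A, volume %.4g A^3\n",
              nrow(x$indices), x$spacing, grid_volume(x)))
  invisible(x)
}

#' Total volume of a voxel grid
#' @param grid a `voxel_grid`.
#' @return Occupied-voxel count times spacing cubed, in cubic Angstrom.
#' @export
grid_volume <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  nrow(grid$indices) * grid$spacing^3
}

# voxels whose centres lie within radius of any point (n x 3)
voxels_near_points <- function(points, radius, spacing) {
  points <- as.matrix(points)
  out <- vector("list", nrow(points))
  r_vox <- ceiling(radius / spacing) + 1L
  for (p in seq_len(nrow(points))) {
    ctr <- floor(points[p, ] / spacing)
    rng <- lapply(1:3, function(k) (ctr[k] - r_vox):(ctr[k] + r_vox))
    cand <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
    centres <- (cand + 0.5) * spacing
    keep <- rowSums(sweep(centres, 2, points[p, ])^2) <= radius^2
    out[[p]] <- cand[keep, , drop = FALSE]
  }
  unique_rows(do.call(rbind, out))
}

#' Consensus ligand-accessible volume on a voxel grid
#'
#' Transforms each structure's ligand heavy atoms into the common frame and
#' marks every voxel whose centre lies within `atom_radius` of any atom;
#' the result is the union over structures.
#'
#' @param structures list of structures (`toy_bundle`, atom table or path).
#' @param transforms list of `rigid_transform`s (or `NULL` entries for the
#'   identity), one per structure.
#' @param ligand_resid ligand residue name(s) selecting the probe atoms.
#' @param atom_radius sphere radius per atom in Angstrom (default 1.7, the
#'   carbon van der Waals radius).
#' @param spacing voxel edge length in Angstrom (default 0.5).
#' @return A `voxel_grid`.
#' @export
ligand_volume <- function(structures, transforms = NULL,
                          ligand_resid = "LIG", atom_radius = 1.7,
                          spacing = 0.5) {
  stopifnot(length(structures) >= 1, spacing > 0, atom_radius > 0)
  if (is.null(transforms)) transforms <- vector("list", length(structures))
  pts <- NULL
  for (i in seq_along(structures)) {
    at <- as_atom_table(structures[[i]])
    lig <- at[at$resid %in% ligand_resid & !grepl("^H", at$elety), ]
    if (nrow(lig) == 0) next
    xyz <- apply_transform(as.matrix(lig[, c("x", "y", "z")]),
                           transforms[[i]])
    pts <- rbind(pts, xyz)
  }
  if (is.null(pts) || nrow(pts) == 0) stop("empty ligand selection")
  voxel_grid(voxels_near_points(pts, atom_radius, spacing), spacing)
}

#' Intersection of two voxel grids
#'
#' @param a,b `voxel_grid`s with equal spacing (grids share the global
#'   lattice, so equal spacing implies commensurate voxels).
#' @return List with `grid` (the intersection `voxel_grid`) and `volume`
#'   in cubic Angstrom.
#' @export
overlap_region <- function(a, b) {
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  if (abs(a$spacing - b$spacing) > 1e-12)
    stop("incompatible grids: spacings differ")
  ka <- paste(a$indices[, 1], a$indices[, 2], a$indices[, 3])
  kb <- paste(b$indices[, 1], b$indices[, 2], b$indices[, 3])
  g <- voxel_grid(a$indices[ka %in% kb, , drop = FALSE], a$spacing)
  list(grid = g, volume = grid_volume(g))
}

#' Fraction of a residue range's atoms inside a target volume
#'
#' Transforms the heavy atoms of a residue range (e.g. extracellular loop 2)
#' into the grid frame and reports the fraction falling in occupied voxels.
#'
#' @param structure structure containing the residues.
#' @param resno_range integer residue numbers of the range (non-empty).
#' @param grid target `voxel_grid`.
#' @param transform optional `rigid_transform` into the grid frame.
#' @return Fraction in `[0, 1]`.
#' @export
el2_occupancy <- function(structure, resno_range, grid, transform = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!length(resno_range)) stop("empty residue range")
  at <- as_atom_table(structure)
  sel <- at[at$type == "ATOM" & at$resno %in% resno_range &
              !grepl("^H", at$elety), ]
  if (nrow(sel) == 0) stop("no atoms in the residue range")
  xyz <- apply_transform(as.matrix(sel[, c("x", "y", "z")]), transform)
  vox <- floor(xyz / grid$spacing)
  keys <- paste(vox[, 1], vox[, 2], vox[, 3])
  occ <- paste(grid$indices[, 1], grid$indices[, 2], grid$indices[, 3])
  mean(keys %in% occ)
}
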