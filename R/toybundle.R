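# Toy seven-helix receptor bundles with planted ligand / sodium-water sites.
#
# Geometry is idealised: seven straight alpha-helices (3.6 residues/turn =
# 100 degrees twist, 1.5 A rise, 2.3 A helix radius) placed on a circle,
# alternating up/down, with C-beta pseudo-atoms extending radially so that
# anchor-facing side chains point into the bundle lumen. This is artifact
# plumbing for testing coordinate-based stages, not protein physics.

HELIX_BG_AA <- c("A", "L", "V", "I", "M", "G", "S")
HELIX_ANCHOR_AA <- c("N", "D", "R", "W", "P", "F", "Y")
LOOP_BASE_AA <- c("G", "E", "S", "T", "K", "Q")

#' Specification of a toy 7-helix receptor
#'
#' @param n_res residues per helix (length-7 integer vector).
#' @param loop_len lengths of the six connecting loops (il1, el1, il2, el2,
#'   il3, el3).
#' @param anchor_local anchor (x.50) position within each helix, 1-based
#'   local index; defaults to the middle residue.
#' @param bundle_radius distance of each helix axis from the bundle axis, in
#'   Angstrom.
#' @return A `toy_receptor_spec` list.
#' @export
toy_receptor_spec <- function(n_res = rep(24L, 7), loop_len = c(4, 4, 4, 8, 4, 4),
                              anchor_local = pmax(1L, n_res %/% 2L),
                              bundle_radius = 11) {
  stopifnot(length(n_res) == 7, all(n_res >= 3), length(loop_len) == 6,
            all(loop_len >= 0), length(anchor_local) == 7)
  if (any(anchor_local < 1 | anchor_local > n_res))
    stop("anchor index outside helix span")
  structure(list(n_res = as.integer(n_res), loop_len = as.integer(loop_len),
                 anchor_local = as.integer(anchor_local),
                 bundle_radius = bundle_radius),
            class = "toy_receptor_spec")
}

#' Build a toy receptor structure with planted binding sites
#'
#' Constructs idealised coordinates for the spec, assigns the toy sequence
#' (a distinctive anchor motif per helix on a uniform background), computes
#' helix spans and the true BW map, and optionally plants a ligand site
#' and/or a sodium/water site: one pseudo-atom is placed at exactly
#' `pocket_distance` Angstrom from each chosen residue's C-beta, towards the
#' bundle axis. The generator verifies by construction that no unplanted
#' residue comes within `pocket_distance + margin` of any planted probe
#' atom, so the planted residue sets are exactly recoverable by contact
#' extraction at any cutoff in `[pocket_distance, pocket_distance + margin)`.
#'
#' @param spec a [toy_receptor_spec()].
#' @param seed integer seed for optional coordinate jitter.
#' @param name receptor name.
#' @param pocket_resnos residue numbers (global) to plant ligand contacts on.
#' @param ion_resnos residue numbers to plant the sodium/water site on; the
#'   first gets the ion probe, the remainder get water probes.
#' @param pocket_distance probe placement distance (default 3.5 A).
#' @param margin guaranteed clearance beyond `pocket_distance` for all other
#'   residues (default 0.4 A).
#' @param jitter_sd standard deviation of isotropic coordinate noise
#'   (default 0: exact geometry).
#' @return Object of class `toy_bundle`: list with `name`, `atoms` (data
#'   frame: type, chain, resno, resid, elety, x, y, z), `sequence`,
#'   `helix_spans`, `anchors` (global resno per helix), `bw_map`, and
#'   `planted` (list `pocket`, `ion_site` of residue numbers).
#' @export
make_toy_bundle <- function(spec = toy_receptor_spec(), seed = 1,
                            name = "toy", pocket_resnos = NULL,
                            ion_resnos = NULL, pocket_distance = 3.5,
                            margin = 0.4, jitter_sd = 0) {
  stopifnot(inherits(spec, "toy_receptor_spec"))
  n_res <- spec$n_res; loop_len <- spec$loop_len
  R <- spec$bundle_radius
  # global numbering: helices and loops in topological order
  seg_len <- integer(13); seg_len[seq(1, 13, 2)] <- n_res
  seg_len[seq(2, 12, 2)] <- loop_len
  seg_end <- cumsum(seg_len); seg_start <- seg_end - seg_len + 1L
  helix_spans <- data.frame(helix = 1:7, start = seg_start[seq(1, 13, 2)],
                            end = seg_end[seq(1, 13, 2)])
  anchors <- stats::setNames(helix_spans$start + spec$anchor_local - 1L,
                             as.character(1:7))
  total <- seg_end[13]
  seqv <- character(total)
  zmax <- 1.5 * (max(n_res) - 1)

  coords <- matrix(NA_real_, total, 3)  # CA
  cb <- matrix(NA_real_, total, 3)
  for (h in 1:7) {
    th <- 2 * pi * (h - 1) / 7
    axis <- R * c(cos(th), sin(th))
    up <- h %% 2 == 1
    idx <- helix_spans$start[h]:helix_spans$end[h]
    seqv[idx] <- HELIX_BG_AA[h]
    seqv[anchors[h]] <- HELIX_ANCHOR_AA[h]
    for (i in seq_along(idx)) {
      local <- i
      phase <- (local - spec$anchor_local[h]) * 100 * pi / 180 + th + pi
      ca_xy <- axis + 2.3 * c(cos(phase), sin(phase))
      z <- if (up) 1.5 * (local - 1) else 1.5 * (n_res[h] - local)
      coords[idx[i], ] <- c(ca_xy, z)
      cb_xy <- axis + 3.8 * c(cos(phase), sin(phase))
      cb[idx[i], ] <- c(cb_xy, z)
    }
  }
  # loops: linear interpolation between flanking helix ends, bulged in z
  for (k in 1:6) {
    li <- seg_start[2 * k]:seg_end[2 * k]
    if (seg_len[2 * k] == 0) next
    a <- coords[seg_end[2 * k - 1], ]; b <- coords[seg_start[2 * k + 1], ]
    extra <- k %% 2 == 0  # el loops on the extracellular (high-z) side
    bump <- if (extra) 4 else -4
    for (i in seq_along(li)) {
      f <- i / (length(li) + 1)
      p <- (1 - f) * a + f * b
      p[3] <- p[3] + bump * sin(pi * f)
      coords[li[i], ] <- p
      cb[li[i], ] <- p + c(0, 0, sign(bump) * 1.0)
    }
    seqv[li] <- LOOP_BASE_AA[k]
  }

  if (jitter_sd > 0) {
    with_seed(seed, {
      coords <- coords + matrix(stats::rnorm(3 * total, 0, jitter_sd), total)
      cb <- cb + matrix(stats::rnorm(3 * total, 0, jitter_sd), total)
    })
  }

  # probe placement: towards the bundle axis at exactly pocket_distance
  place_probe <- function(resno) {
    p <- cb[resno, ]
    u <- c(-p[1], -p[2], 0)
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) u <- c(1, 0, 0) else u <- u / nu
    p + pocket_distance * u
  }
  lig <- NULL
  if (length(pocket_resnos)) {
    stopifnot(all(pocket_resnos >= 1 & pocket_resnos <= total))
    lig <- t(vapply(pocket_resnos, place_probe, numeric(3)))
  }
  ion <- NULL; waters <- NULL
  if (length(ion_resnos)) {
    stopifnot(all(ion_resnos >= 1 & ion_resnos <= total))
    pts <- t(vapply(ion_resnos, place_probe, numeric(3)))
    ion <- pts[1, , drop = FALSE]
    if (nrow(pts) > 1) waters <- pts[-1, , drop = FALSE]
  }

  atoms <- data.frame(
    type = "ATOM", chain = "A",
    resno = rep(seq_len(total), each = 2),
    resid = rep(vapply(seqv, aa_three, character(1)), each = 2),
    elety = rep(c("CA", "CB"), total),
    x = as.vector(rbind(coords[, 1], cb[, 1])),
    y = as.vector(rbind(coords[, 2], cb[, 2])),
    z = as.vector(rbind(coords[, 3], cb[, 3])),
    stringsAsFactors = FALSE)
  het <- NULL
  if (!is.null(lig))
    het <- rbind(het, data.frame(type = "HETATM", chain = "A",
                                 resno = 900L, resid = "LIG",
                                 elety = paste0("C", seq_len(nrow(lig))),
                                 x = lig[, 1], y = lig[, 2], z = lig[, 3],
                                 stringsAsFactors = FALSE))
  if (!is.null(ion))
    het <- rbind(het, data.frame(type = "HETATM", chain = "A", resno = 801L,
                                 resid = "NA", elety = "NA",
                                 x = ion[1], y = ion[2], z = ion[3],
                                 stringsAsFactors = FALSE))
  if (!is.null(waters))
    het <- rbind(het, data.frame(type = "HETATM", chain = "A",
                                 resno = 850L + seq_len(nrow(waters)),
                                 resid = "HOH", elety = "O",
                                 x = waters[, 1], y = waters[, 2],
                                 z = waters[, 3], stringsAsFactors = FALSE))
  atoms <- rbind(atoms, het)

  bundle <- structure(list(
    name = name, atoms = atoms,
    sequence = paste0(seqv, collapse = ""),
    helix_spans = helix_spans, anchors = anchors,
    bw_map = assign_bw_numbers(seqv, helix_spans, anchors),
    planted = list(pocket = sort(unique(pocket_resnos)),
                   ion_site = sort(unique(ion_resnos)))),
    class = "toy_bundle")

  # construction guarantee: planted sets exactly recoverable at the cutoff
  check_probe_margins(bundle, pocket_distance, margin)
  bundle
}

#' Lumen-facing residues of a toy bundle spec
#'
#' Residues whose C-beta direction points towards the bundle axis within
#' `max_angle` degrees — the geometrically sensible targets for planting
#' pocket or ion sites with [make_toy_bundle()].
#'
#' @param spec a [toy_receptor_spec()].
#' @param max_angle maximal deviation from axis-facing, in degrees.
#' @return Integer vector of global residue numbers.
#' @export
lumen_facing_residues <- function(spec = toy_receptor_spec(),
                                  max_angle = 25) {
  seg_len <- integer(13); seg_len[seq(1, 13, 2)] <- spec$n_res
  seg_len[seq(2, 12, 2)] <- spec$loop_len
  seg_end <- cumsum(seg_len); seg_start <- seg_end - seg_len + 1L
  out <- integer(0)
  for (h in 1:7) {
    local <- seq_len(spec$n_res[h])
    ang <- ((local - spec$anchor_local[h]) * 100) %% 360
    ang <- pmin(ang, 360 - ang)
    out <- c(out, seg_start[2 * h - 1] + local[ang <= max_angle] - 1L)
  }
  sort(out)
}

aa_three <- function(a) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  unname(map[a])
}

check_probe_margins <- function(bundle, pocket_distance, margin) {
  at <- bundle$atoms
  prot <- at[at$type == "ATOM", ]
  for (site in c("pocket", "ion_site")) {
    planted <- bundle$planted[[site]]
    if (!length(planted)) next
    probes <- if (site == "pocket") at[at$resid == "LIG", ]
              else at[at$resid %in% c("NA", "HOH"), ]
    pr <- as.matrix(probes[, c("x", "y", "z")])
    dmin <- vapply(split(seq_len(nrow(prot)), prot$resno), function(ii) {
      pm <- as.matrix(prot[ii, c("x", "y", "z")])
      min(sqrt(outer(rowSums(pm^2), rowSums(pr^2), "+") -
                 2 * pm %*% t(pr)))
    }, numeric(1))
    resnos <- as.integer(names(dmin))
    inside <- resnos[dmin <= pocket_distance + 1e-6]
    if (!setequal(inside, planted) ||
        any(dmin[!resnos %in% planted] < pocket_distance + margin))
      stop("toy bundle geometry violates the planted-site margin; ",
           "choose less crowded residues for the ", site)
  }
  invisible(bundle)
}

#' Write a toy bundle (or atom table) to a PDB file
#'
#' @param bundle a `toy_bundle` or an atom data frame with columns
#'   `type, chain, resno, resid, elety, x, y, z`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_toy_pdb <- function(bundle, path) {
  at <- if (inherits(bundle, "toy_bundle")) bundle$atoms else bundle
  bio3d::write.pdb(file = path,
                   type = at$type,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   elety = at$elety, eleno = seq_len(nrow(at)))
  invisible(path)
}

#' Read a PDB file into the atom-table representation
#'
#' @param path PDB file.
#' @return Data frame with columns `type, chain, resno, resid, elety,
#'   x, y, z`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  data.frame(type = at$type, chain = at$chain, resno = at$resno,
             resid = at$resid, elety = at$elety,
             x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
}
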