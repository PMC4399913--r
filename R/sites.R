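# Ligand-contact and sodium/water-site extraction, BW-indexed pocket
# profiles, and the position-removal robustness utilities.

# coerce structure input to the atom table
as_atom_table <- function(structure) {
  if (inherits(structure, "toy_bundle")) return(structure$atoms)
  if (is.character(structure) && length(structure) == 1L)
    return(read_structure(structure))
  if (is.data.frame(structure)) return(structure)
  stop("structure must be a toy_bundle, atom data frame, or PDB path")
}

pairwise_min_dist <- function(A, B) {
  # A, B: n x 3 coordinate matrices; returns n_A vector of min distances
  cross <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(cross, 0))
}

THREE_TO_ONE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# contact extraction against an arbitrary probe atom set
contacts_to_probes <- function(structure, probes, cutoff, bw_map = NULL,
                               helix_spans = NULL) {
  at <- as_atom_table(structure)
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  if (nrow(probes) == 0) stop("empty probe selection")
  prot <- at[at$type == "ATOM" & !grepl("^H", at$elety), , drop = FALSE]
  pm <- as.matrix(prot[, c("x", "y", "z")])
  pr <- as.matrix(probes[, c("x", "y", "z")])
  dm <- pairwise_min_dist(pm, pr)
  mind <- apply(dm, 1L, min)
  hit <- unique(prot$resno[mind <= cutoff])
  hit <- sort(hit)
  aa <- vapply(hit, function(r) {
    rid <- prot$resid[prot$resno == r][1]
    out <- THREE_TO_ONE[rid]
    if (is.na(out)) "X" else unname(out)
  }, character(1))
  bw <- rep(NA_character_, length(hit))
  if (!is.null(bw_map)) bw <- bw_map$bw[match(hit, bw_map$resno)]
  if (!is.null(helix_spans)) {
    loop <- is.na(bw)
    bw[loop] <- vapply(hit[loop], loop_tag_for, character(1),
                       helix_spans = helix_spans)
  }
  data.frame(resno = hit, aa = aa, bw = bw, stringsAsFactors = FALSE)
}

# loop tag (il1..el3) for a residue between helix spans, NA outside 7TM
loop_tag_for <- function(resno, helix_spans) {
  spans <- as.data.frame(helix_spans)
  spans <- spans[order(spans$helix), ]
  for (k in 1:6) {
    if (resno > spans$end[k] && resno < spans$start[k + 1])
      return(LOOP_IDS[k])
  }
  NA_character_
}

#' Extract ligand-contact residues from a structure
#'
#' All protein residues with at least one heavy atom within `cutoff`
#' Angstrom of any heavy atom of the ligand selection. Waters are never part
#' of the ligand probe set.
#'
#' @param structure a `toy_bundle`, atom data frame or PDB path.
#' @param ligand_resid residue name(s) of the ligand (default `"LIG"`).
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.0; the
#'   criterion is recorded with the result).
#' @param bw_map optional BW map (from [assign_bw_numbers()]) to label
#'   contacts; residues outside helices get loop tags when `helix_spans`
#'   is given.
#' @param helix_spans optional helix span table for loop tagging.
#' @return Data frame of pocket residues: `resno`, `aa`, `bw`; the cutoff
#'   is attached as attribute `cutoff`.
#' @export
extract_ligand_contacts <- function(structure, ligand_resid = "LIG",
                                    cutoff = 4.0, bw_map = NULL,
                                    helix_spans = NULL) {
  at <- as_atom_table(structure)
  probes <- at[at$resid %in% ligand_resid & at$resid != "HOH" &
                 !grepl("^H", at$elety), , drop = FALSE]
  if (nrow(probes) == 0) stop("empty ligand selection: ",
                              paste(ligand_resid, collapse = ","))
  out <- contacts_to_probes(at, probes, cutoff, bw_map, helix_spans)
  attr(out, "cutoff") <- cutoff
  out
}

#' Extract the sodium/water-site residues from a structure
#'
#' Like [extract_ligand_contacts()], but the probe set is the sodium ion
#' plus its bound water molecules, so a residue contacting only a water is
#' included.
#'
#' @param structure a `toy_bundle`, atom data frame or PDB path.
#' @param ion_resid residue name of the ion (default `"NA"`).
#' @param water_resid residue name of waters (default `"HOH"`).
#' @param cutoff distance cutoff in Angstrom.
#' @param bw_map,helix_spans as in [extract_ligand_contacts()].
#' @return Data frame of site residues (possibly empty): `resno`, `aa`,
#'   `bw`.
#' @export
extract_sodium_site <- function(structure, ion_resid = "NA",
                                water_resid = "HOH", cutoff = 4.0,
                                bw_map = NULL, helix_spans = NULL) {
  at <- as_atom_table(structure)
  probes <- at[at$resid %in% c(ion_resid, water_resid), , drop = FALSE]
  if (nrow(probes) == 0) stop("empty ion/water selection")
  out <- tryCatch(contacts_to_probes(at, probes, cutoff, bw_map, helix_spans),
                  error = function(e) stop(e))
  attr(out, "cutoff") <- cutoff
  out
}

#' Build BW-indexed pocket profiles across receptors
#'
#' The position index is the ordered union of the BW positions (helix
#' positions sorted by helix then position, loop tags last) over all
#' receptors' pocket residue sets; each receptor's profile carries its
#' residue letter at occupied positions and a gap elsewhere.
#'
#' @param sets named list of pocket residue data frames (`aa`, `bw`).
#' @return Object of class `pocket_profiles`: list with `positions`
#'   (character vector) and `profiles` (named character vector, all of
#'   length `length(positions)`).
#' @export
build_pocket_profiles <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  all_bw <- unique(unlist(lapply(sets, `[[`, "bw")))
  if (any(is.na(all_bw)))
    stop("every pocket residue needs a BW label or loop tag")
  is_helix <- grepl("^[1-7]\\.", all_bw)
  hx <- all_bw[is_helix]
  hx <- hx[order(as.numeric(sub("\\..*", "", hx)),
                 as.numeric(sub(".*\\.", "", hx)))]
  lp <- sort(all_bw[!is_helix])
  positions <- c(hx, lp)
  profiles <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    if (anyDuplicated(s$bw))
      stop("duplicate position ", s$bw[duplicated(s$bw)][1],
           " in receptor ", nm)
    ch <- rep("-", length(positions))
    ch[match(s$bw, positions)] <- s$aa
    paste0(ch, collapse = "")
  }, character(1))
  structure(list(positions = positions, profiles = profiles),
            class = "pocket_profiles")
}

#' @export
print.pocket_profiles <- function(x, ...) {
  cat(sprintf("pocket profiles: %d receptors x %d positions\n",
              length(x$profiles), length(x$positions)))
  invisible(x)
}

#' Remove named positions from pocket profiles
#'
#' @param profiles a `pocket_profiles`.
#' @param positions_to_drop position labels to remove (must exist).
#' @return A `pocket_profiles` without those columns.
#' @export
variant_without_positions <- function(profiles, positions_to_drop) {
  stopifnot(inherits(profiles, "pocket_profiles"))
  missing <- setdiff(positions_to_drop, profiles$positions)
  if (length(missing))
    stop("unknown position(s): ", paste(missing, collapse = ", "))
  keep <- !profiles$positions %in% positions_to_drop
  m <- seq_chars(profiles$profiles)[, keep, drop = FALSE]
  structure(list(positions = profiles$positions[keep],
                 profiles = chars_to_seq(m)),
            class = "pocket_profiles")
}

#' Positions shared between two sites' profiles
#'
#' @param a,b `pocket_profiles` objects (or plain position vectors).
#' @return Character vector: intersection of the position sets, in `a`'s
#'   order.
#' @export
shared_positions <- function(a, b) {
  pa <- if (inherits(a, "pocket_profiles")) a$positions else a
  pb <- if (inherits(b, "pocket_profiles")) b$positions else b
  pa[pa %in% pb]
}

#' Distance matrix between pocket profiles
#'
#' @param profiles a `pocket_profiles`.
#' @param method as in [dist_matrix()]; the field standard for dissimilar
#'   short pocket sequences is `"p"` (uncorrected P distance).
#' @param ... passed to [dist_matrix()].
#' @return Symmetric distance matrix.
#' @export
pocket_dist <- function(profiles, method = "p", ...) {
  stopifnot(inherits(profiles, "pocket_profiles"))
  dist_matrix(profiles$profiles, method = method, ...)
}

#' Write pocket profiles and their position index
#' @param profiles a `pocket_profiles`.
#' @param fasta_path FASTA-like matrix output path.
#' @param positions_path TSV path for the position index (optional).
#' @return `fasta_path`, invisibly.
#' @export
write_pocket_profiles <- function(profiles, fasta_path,
                                  positions_path = NULL) {
  write_fasta(profiles$profiles, fasta_path)
  if (!is.null(positions_path))
    utils::write.table(
      data.frame(index = seq_along(profiles$positions),
                 position = profiles$positions),
      positions_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}
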