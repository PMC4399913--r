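# Hierarchical repertoire handling: length filter, iterative farthest-leaf
# group extraction against crystal-structure sequences, per-group template
# assignment, 7TM trimming, and merged-set construction.

#' Remove over-long sequences
#'
#' Sequences strictly longer than `max_len` residues are removed and logged,
#' mirroring the practice of excluding very long receptors whose alignment
#' and tree inference dominate runtime.
#'
#' @param sequences named character vector.
#' @param max_len maximum length kept (strictly greater is removed).
#' @return List with `kept` (named character vector) and `removed`
#'   (data frame `name`, `length`).
#' @export
length_filter <- function(sequences, max_len = 1500) {
  stopifnot(is.character(sequences), max_len >= 1)
  len <- nchar(sequences)
  drop <- len > max_len
  list(kept = sequences[!drop],
       removed = data.frame(name = names(sequences)[drop],
                            length = unname(len[drop]),
                            stringsAsFactors = FALSE))
}

# distance matrix for unaligned sequences: progressive alignment first
# (realign = TRUE) or direct comparison when already of equal length
repertoire_distances <- function(sequences, distance = c("p", "blosum62"),
                                 realign = TRUE) {
  distance <- match.arg(distance)
  if (realign || length(unique(nchar(sequences))) > 1)
    sequences <- progressive_align(sequences)
  dist_matrix(sequences, method = distance)
}

#' Extract the group farthest from the crystal-structure sequences
#'
#' Builds an NJ tree on the current sequence set, finds the non-crystal
#' leaf with the largest tree path distance to its nearest crystal-bearing
#' leaf, and extracts the maximal crystal-free subtree containing it. Ties
#' are broken lexicographically by leaf name.
#'
#' @param sequences named character vector (aligned or not).
#' @param crystal_names names of the crystal-structure sequences present.
#' @param distance `"p"` or `"blosum62"` (the distance feeding NJ).
#' @param realign realign the current set before computing distances
#'   (the default mirrors full re-alignment between iterations; set FALSE
#'   to reuse the existing alignment for speed).
#' @return `NULL` when no non-crystal sequences remain (completion);
#'   otherwise a list with `group` (named character vector),
#'   `remainder` (named character vector) and `score` (path distance of
#'   the extracted leaf to its nearest crystal leaf).
#' @export
extract_farthest_group <- function(sequences, crystal_names,
                                   distance = "p", realign = TRUE) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  crystal <- intersect(names(sequences), crystal_names)
  if (!length(crystal)) stop("no crystal sequence present in the set")
  noncrystal <- setdiff(names(sequences), crystal)
  if (!length(noncrystal)) return(NULL)
  if (length(sequences) < 3) {
    # too small for a tree: extract the non-crystal leaves directly
    return(list(group = sequences[noncrystal],
                remainder = sequences[crystal], score = NA_real_))
  }
  d <- repertoire_distances(sequences, distance, realign)
  tree <- neighbor_joining(d)
  pd <- stats::cophenetic(tree)
  near <- apply(pd[noncrystal, crystal, drop = FALSE], 1L, min)
  far <- names(near)[order(-near, names(near))][1]
  # maximal crystal-free edge side containing the farthest leaf
  ut <- phylo_to_utree(tree)
  adj <- utree_adjacency(ut)
  best_side <- far
  for (k in seq_len(nrow(ut$edges))) {
    for (dir in 1:2) {
      side <- if (dir == 1) utree_edge_side(ut, k, adj)
              else setdiff(ut$tips, utree_edge_side(ut, k, adj))
      if (far %in% side && !any(side %in% crystal) &&
          length(side) > length(best_side))
        best_side <- side
    }
  }
  list(group = sequences[sort(best_side)],
       remainder = sequences[setdiff(names(sequences), best_side)],
       score = unname(near[far]))
}

#' Choose the template crystal structure for a group
#'
#' The template is the crystal sequence minimising the median distance to
#' the group members ("closest to the majority"); ties are broken
#' lexicographically.
#'
#' @param group named character vector of group member sequences.
#' @param crystal_sequences named character vector of crystal sequences.
#' @param distance `"p"` or `"blosum62"`, computed on pairwise global
#'   alignments.
#' @return Template name (character scalar).
#' @export
assign_template <- function(group, crystal_sequences, distance = "p") {
  stopifnot(length(group) >= 1, length(crystal_sequences) >= 1)
  med <- vapply(sort(names(crystal_sequences)), function(cn) {
    ds <- vapply(names(group), function(gn) {
      pa <- pairwise_global(group[gn], crystal_sequences[cn])
      rows <- pa$rows
      switch(distance,
             p = tryCatch(p_distance(rows[[1]], rows[[2]]),
                          error = function(e) 1),
             blosum62 = blosum62_distance(rows[[1]], rows[[2]]))
    }, numeric(1))
    stats::median(ds)
  }, numeric(1))
  names(med)[which.min(med)]  # names pre-sorted: ties lexicographic
}

#' Trim a sequence to the 7TM span of its template
#'
#' Globally aligns the query to the template (BLOSUM62, affine gaps), maps
#' the template's TM1-start and TM7-end columns onto the query, and returns
#' the query substring between the mapped positions (inclusive). Terminal
#' extensions are removed; internal insertions inside the span are kept.
#'
#' @param sequence query sequence (string).
#' @param template list with `sequence` and `span = c(start, end)` (1-based
#'   TM1 start and TM7 end in the template).
#' @param open,extend affine gap parameters.
#' @return Trimmed query substring.
#' @export
trim_to_7tm <- function(sequence, template, open = 10, extend = 1) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is.list(template), length(template$span) == 2L)
  span <- as.integer(template$span)
  tlen <- nchar(template$sequence)
  if (span[1] >= span[2] || span[1] < 1 || span[2] > tlen)
    stop("invalid template span")
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  pa <- Biostrings::pairwiseAlignment(
    sequence, template$sequence, type = "global",
    substitutionMatrix = env$BLOSUM62,
    gapOpening = open, gapExtension = extend)
  q <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  t <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  tpos <- cumsum(t != "-")
  qpos <- cumsum(q != "-")
  inside <- which(tpos >= span[1] & tpos <= span[2] & q != "-")
  if (!length(inside)) stop("no query residues map inside the template span")
  substr(sequence, qpos[min(inside)], qpos[max(inside)])
}

#' Merge trimmed groups into the two cross-seeded class sets
#'
#' Builds the rhodopsin-like and non-rhodopsin-like 7TM sequence sets; each
#' set additionally receives the cross-class crystal 7TM sequences so the
#' connecting node between the classes can be located in either tree.
#'
#' @param groups list of groups; each a list with `members` (named character
#'   vector of trimmed sequences) and `group_id`.
#' @param class_labels named character vector mapping `group_id` to
#'   `"rhodopsin"` or `"non_rhodopsin"`.
#' @param crystal_7tm named character vector of crystal 7TM sequences.
#' @param crystal_classes named character vector mapping crystal names to
#'   classes.
#' @return List with `rhodopsin` and `non_rhodopsin` named character
#'   vectors.
#' @export
build_merged_sets <- function(groups, class_labels, crystal_7tm,
                              crystal_classes) {
  stopifnot(is.list(groups), length(groups) >= 1)
  sets <- list(rhodopsin = character(0), non_rhodopsin = character(0))
  for (g in groups) {
    lab <- unlist(class_labels)[g$group_id]
    if (is.null(lab) || is.na(lab))
      stop("group ", g$group_id, " has no class label")
    if (!lab %in% names(sets)) stop("unknown class label: ", lab)
    clash <- intersect(names(g$members), names(sets[[lab]]))
    if (length(clash))
      stop("duplicate sequence name(s) across groups: ",
           paste(clash, collapse = ", "))
    sets[[lab]] <- c(sets[[lab]], g$members)
  }
  for (cls in names(sets)) {
    other <- setdiff(names(sets), cls)
    cross <- crystal_7tm[names(crystal_7tm) %in%
                           names(crystal_classes)[crystal_classes == other]]
    add <- cross[!names(cross) %in% names(sets[[cls]])]
    sets[[cls]] <- c(sets[[cls]], add)
  }
  sets
}

#' Run the full iterative repertoire grouping
#'
#' Length-filters the input, then repeatedly extracts the farthest
#' crystal-free group (up to `max_groups` extractions), assigns each group
#' its template, and partitions any remaining non-crystal sequences by
#' nearest template. Every input sequence ends in exactly one group or in
#' the removal log.
#'
#' @param sequences named character vector (the repertoire including the
#'   crystal sequences).
#' @param crystal_names names of the crystal-structure sequences.
#' @param max_len length filter threshold.
#' @param max_groups extraction cap before nearest-template partitioning.
#' @param distance `"p"` or `"blosum62"`.
#' @param realign realign between iterations (see
#'   [extract_farthest_group()]).
#' @return List with `groups` (list of `group_id`, `members`, `template`),
#'   `removed` (removal log), and `table` (data frame `name`, `group_id`,
#'   `template`).
#' @export
run_repertoire <- function(sequences, crystal_names, max_len = 1500,
                           max_groups = 7, distance = "p", realign = TRUE) {
  lf <- length_filter(sequences, max_len)
  work <- lf$kept
  crystal <- work[intersect(names(work), crystal_names)]
  if (!length(crystal)) stop("no crystal sequence passed the length filter")
  groups <- list()
  gid <- 0
  while (gid < max_groups) {
    ex <- extract_farthest_group(work, names(crystal), distance, realign)
    if (is.null(ex)) break
    gid <- gid + 1
    groups[[gid]] <- list(group_id = sprintf("group%02d", gid),
                          members = ex$group[setdiff(names(ex$group),
                                                     names(crystal))])
    work <- ex$remainder
  }
  rest <- work[setdiff(names(work), names(crystal))]
  if (length(rest)) {
    nearest <- vapply(names(rest), function(nm) {
      assign_template(rest[nm], crystal, distance = distance)
    }, character(1))
    for (tmpl in sort(unique(nearest))) {
      gid <- gid + 1
      groups[[gid]] <- list(group_id = sprintf("group%02d", gid),
                            members = rest[nearest == tmpl])
    }
  }
  for (i in seq_along(groups))
    groups[[i]]$template <- assign_template(groups[[i]]$members, crystal,
                                            distance = distance)
  tab <- do.call(rbind, lapply(groups, function(g)
    data.frame(name = names(g$members), group_id = g$group_id,
               template = g$template, stringsAsFactors = FALSE)))
  list(groups = groups, removed = lf$removed, table = tab)
}
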