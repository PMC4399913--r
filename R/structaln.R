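# Structure-anchored composite alignment of the 7TM domain:
# gapless helix blocks indexed by Ballesteros-Weinstein (BW) labels,
# interleaved with progressively aligned loop blocks.
#
# BW labels use the x.yy notation: the most conserved residue of helix x is
# x.50, a residue k positions C-terminal of it is x.(50+k), N-terminal
# x.(50-k), bounded by the helix span.

BLOCK_ORDER <- c("TM1", "il1", "TM2", "el1", "TM3", "il2", "TM4",
                 "el2", "TM5", "il3", "TM6", "el3", "TM7")
LOOP_IDS <- c("il1", "el1", "il2", "el2", "il3", "el3")

#' Assign Ballesteros-Weinstein numbers from helix spans and anchors
#'
#' The residue at each helix's anchor position receives label `x.50`;
#' residues `k` positions C-terminal of the anchor get `x.(50+k)` and
#' N-terminal `x.(50-k)`, bounded by the helix span.
#'
#' @param sequence receptor sequence (string or character vector).
#' @param helix_spans data frame with columns `helix` (1-7), `start`, `end`
#'   (1-based residue indices, inclusive).
#' @param anchors named integer vector: anchor residue index per helix
#'   (names `"1"`..`"7"` or `"TM1"`..`"TM7"`).
#' @return Data frame (`bw_map`): `resno`, `helix`, `pos`, `bw` (label
#'   string), `aa`.
#' @export
assign_bw_numbers <- function(sequence, helix_spans, anchors) {
  seqv <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  spans <- as.data.frame(helix_spans)
  stopifnot(all(c("helix", "start", "end") %in% names(spans)))
  anames <- sub("^TM", "", names(anchors))
  out <- NULL
  for (r in seq_len(nrow(spans))) {
    h <- spans$helix[r]
    a <- anchors[match(as.character(h), anames)]
    if (is.na(a))
      stop("missing anchor for helix ", h)
    if (a < spans$start[r] || a > spans$end[r])
      stop("anchor for helix ", h, " lies outside its span")
    resno <- spans$start[r]:spans$end[r]
    pos <- 50L + (resno - as.integer(a))
    out <- rbind(out, data.frame(
      resno = resno, helix = h, pos = pos,
      bw = sprintf("%d.%02d", h, pos),
      aa = seqv[resno], stringsAsFactors = FALSE))
  }
  if (anyDuplicated(out$bw)) stop("duplicate BW label within a receptor")
  out
}

#' Structure-anchored alignment block for one helix
#'
#' One column per BW label occurring in any receptor for the given helix,
#' ordered by position; a receptor lacking a label carries a gap there, and
#' no other gaps are introduced.
#'
#' @param receptors named list; each element a list with `sequence` (string)
#'   and `bw_map` (from [assign_bw_numbers()]).
#' @param helix helix number 1-7.
#' @return An `alignment_block` (list: `kind`, `block_id`, `rows`, `labels`).
#' @export
align_helix_blocks <- function(receptors, helix) {
  stopifnot(length(receptors) >= 2, !is.null(names(receptors)))
  maps <- lapply(receptors, function(r) r$bw_map[r$bw_map$helix == helix, ])
  pos_union <- sort(unique(unlist(lapply(maps, `[[`, "pos"))))
  if (!length(pos_union))
    stop("no BW-labelled residues in helix ", helix, " for any receptor")
  rows <- vapply(names(receptors), function(nm) {
    m <- maps[[nm]]
    ch <- rep("-", length(pos_union))
    hit <- match(m$pos, pos_union)
    ch[hit] <- m$aa
    paste0(ch, collapse = "")
  }, character(1))
  structure(list(kind = "helix", block_id = paste0("TM", helix),
                 rows = rows,
                 labels = sprintf("%d.%02d", helix, pos_union)),
            class = "alignment_block")
}

#' Progressive alignment block for one loop
#'
#' Aligns the extracted loop sequences with the deterministic progressive
#' aligner ([progressive_align()]; NJ guide on P distances of pairwise
#' global alignments, BLOSUM62, affine gaps). Empty loops become all-gap
#' rows.
#'
#' @param loops named character vector of (possibly empty) loop sequences.
#' @param block_id one of `il1`, `el1`, `il2`, `el2`, `il3`, `el3`.
#' @param open,extend affine gap parameters (default 10 / 1).
#' @return An `alignment_block`.
#' @export
align_loop <- function(loops, block_id = "el2", open = 10, extend = 1) {
  stopifnot(is.character(loops), !is.null(names(loops)))
  nonempty <- loops[nchar(loops) > 0]
  aligned <- if (length(nonempty) == 0) {
    stats::setNames(character(0), character(0))
  } else if (length(nonempty) == 1) {
    nonempty
  } else {
    progressive_align(nonempty, open = open, extend = extend)
  }
  W <- if (length(aligned)) nchar(aligned[[1]]) else 0L
  rows <- vapply(names(loops), function(nm) {
    if (nm %in% names(aligned)) aligned[[nm]]
    else paste0(rep("-", W), collapse = "")
  }, character(1))
  structure(list(kind = "loop", block_id = block_id, rows = rows,
                 labels = NULL),
            class = "alignment_block")
}

#' Concatenate helix and loop blocks into the composite alignment
#'
#' Blocks are interleaved in membrane topology order TM1, il1, TM2, el1,
#' TM3, il2, TM4, el2, TM5, il3, TM6, el3, TM7.
#'
#' @param helix_blocks list of 7 helix `alignment_block`s (TM1..TM7).
#' @param loop_blocks list of 6 loop `alignment_block`s (il1..el3).
#' @return Object of class `composite_alignment`: list with `taxa`,
#'   `blocks` (named, in order) and `rows` (named character vector of the
#'   concatenated alignment).
#' @export
build_composite <- function(helix_blocks, loop_blocks) {
  blocks <- c(helix_blocks, loop_blocks)
  names(blocks) <- vapply(blocks, `[[`, character(1), "block_id")
  if (!setequal(names(blocks), BLOCK_ORDER))
    stop("expected the 13 blocks ", paste(BLOCK_ORDER, collapse = ", "))
  blocks <- blocks[BLOCK_ORDER]
  taxa <- sort(names(blocks[[1]]$rows))
  for (b in blocks)
    if (!setequal(names(b$rows), taxa))
      stop("taxon mismatch in block ", b$block_id, ": ",
           paste(symdiff_chr(names(b$rows), taxa), collapse = ", "))
  rows <- vapply(taxa, function(tx)
    paste0(vapply(blocks, function(b) b$rows[[tx]], character(1)),
           collapse = ""), character(1))
  structure(list(taxa = taxa, blocks = blocks, rows = rows),
            class = "composite_alignment")
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' @export
print.composite_alignment <- function(x, ...) {
  cat(sprintf("composite 7TM alignment: %d receptors, %d columns (%s)\n",
              length(x$taxa), nchar(x$rows[[1]]),
              paste(sprintf("%s:%d", names(x$blocks),
                            vapply(x$blocks, function(b) nchar(b$rows[[1]]),
                                   integer(1))), collapse = " ")))
  invisible(x)
}

#' Composite 7TM alignment from annotated receptors
#'
#' End-to-end builder: assigns BW numbers, builds the seven anchored helix
#' blocks, extracts and aligns the six loops, and concatenates everything.
#' Loop boundaries are `(end of helix k) + 1 .. (start of helix k+1) - 1`.
#'
#' @param receptors named list; each element a list with `sequence`,
#'   `helix_spans`, `anchors` (see [assign_bw_numbers()]).
#' @param open,extend affine gap parameters for loop alignment.
#' @return A `composite_alignment`.
#' @export
composite_alignment <- function(receptors, open = 10, extend = 1) {
  stopifnot(length(receptors) >= 2, !is.null(names(receptors)))
  ann <- lapply(receptors, function(r) {
    r$bw_map <- assign_bw_numbers(r$sequence, r$helix_spans, r$anchors)
    r
  })
  helix_blocks <- lapply(1:7, function(h) align_helix_blocks(ann, h))
  loop_blocks <- lapply(seq_along(LOOP_IDS), function(k) {
    loops <- vapply(ann, function(r) {
      spans <- as.data.frame(r$helix_spans)
      spans <- spans[order(spans$helix), ]
      from <- spans$end[k] + 1L
      to <- spans$start[k + 1] - 1L
      if (from > to) "" else substr(r$sequence, from, to)
    }, character(1))
    align_loop(loops, block_id = LOOP_IDS[k], open = open, extend = extend)
  })
  build_composite(helix_blocks, loop_blocks)
}

#' Write a composite alignment (or any alignment) as multi-FASTA
#' @param x `composite_alignment` or named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_composite_fasta <- function(x, path) {
  rows <- if (inherits(x, "composite_alignment")) x$rows else x
  write_fasta(rows, path)
}

#' Write BW maps for a receptor set as TSV
#' @param receptors named list with `bw_map` entries or lists accepted by
#'   [composite_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bw_tsv <- function(receptors, path) {
  tab <- do.call(rbind, lapply(names(receptors), function(nm) {
    r <- receptors[[nm]]
    m <- if (!is.null(r$bw_map)) r$bw_map
    else assign_bw_numbers(r$sequence, r$helix_spans, r$anchors)
    cbind(receptor = nm, m)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
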