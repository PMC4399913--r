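# Canonical split (bipartition) handling.
#
# A split is stored as the sorted side NOT containing the lexicographically
# first taxon of the full set, keyed as a comma-joined string. This makes
# split sets directly comparable across trees and networks over the same
# taxa.

split_key <- function(side, taxa) {
  first <- min(taxa)
  if (first %in% side) side <- setdiff(taxa, side)
  paste(sort(side), collapse = ",")
}

split_side <- function(key) strsplit(key, ",", fixed = TRUE)[[1]]

is_trivial_split <- function(key, taxa) {
  k <- length(split_side(key))
  k <= 1 || k >= length(taxa) - 1
}

# internal unrooted tree structure: tips 1..ntip labelled, edges matrix, len
utree_new <- function(tips, edges, len) {
  structure(list(tips = tips, edges = edges, len = len), class = "utree")
}

phylo_to_utree <- function(phy) {
  utree_new(phy$tip.label, phy$edge,
            if (is.null(phy$edge.length)) rep(0, nrow(phy$edge))
            else phy$edge.length)
}

utree_adjacency <- function(ut) {
  nn <- max(ut$edges)
  adj <- vector("list", nn)
  for (k in seq_len(nrow(ut$edges))) {
    u <- ut$edges[k, 1]; v <- ut$edges[k, 2]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

# tips on the v-side of edge k (u,v), as label vector
utree_edge_side <- function(ut, k, adj = utree_adjacency(ut)) {
  ntip <- length(ut$tips)
  u <- ut$edges[k, 1]; v <- ut$edges[k, 2]
  seen <- logical(length(adj)); seen[u] <- TRUE
  stack <- v; out <- integer(0)
  while (length(stack)) {
    x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (seen[x]) next
    seen[x] <- TRUE
    if (x <= ntip) out <- c(out, x)
    stack <- c(stack, adj[[x]][!seen[adj[[x]]]])
  }
  ut$tips[out]
}

utree_splits <- function(ut, include_trivial = FALSE) {
  adj <- utree_adjacency(ut)
  taxa <- ut$tips
  keys <- vapply(seq_len(nrow(ut$edges)), function(k)
    split_key(utree_edge_side(ut, k, adj), taxa), character(1))
  if (!include_trivial) keys <- keys[!vapply(keys, is_trivial_split,
                                             logical(1), taxa = taxa)]
  unique(keys)
}

utree_to_phylo <- function(ut) {
  adj <- utree_adjacency(ut)
  elen <- new.env()
  for (k in seq_len(nrow(ut$edges))) {
    key <- paste(sort(ut$edges[k, ]), collapse = "-")
    assign(key, ut$len[k], envir = elen)
  }
  ntip <- length(ut$tips)
  deg <- lengths(adj)
  root <- which(deg >= 3)[1]
  if (is.na(root)) root <- ntip + 1  # 2-tip edge case not expected
  rec <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (node <= ntip && !length(kids)) return(ut$tips[node])
    inner <- paste(vapply(kids, function(k) {
      bl <- get(paste(sort(c(node, k)), collapse = "-"), envir = elen)
      sprintf("%s:%.12g", rec(k, node), bl)
    }, character(1)), collapse = ",")
    sprintf("(%s)", inner)
  }
  ape::read.tree(text = paste0(rec(root, 0L), ";"))
}

#' Non-trivial splits (bipartitions) induced by a tree
#'
#' Each internal edge of an unrooted tree induces one bipartition of the
#' taxa. Splits are canonicalised as the sorted side not containing the
#' lexicographically first taxon, serialised as comma-joined strings.
#'
#' @param tree an [ape::phylo] tree.
#' @param include_trivial also return the leaf (single-taxon) splits.
#' @return Character vector of canonical split keys.
#' @export
tree_splits <- function(tree, include_trivial = FALSE) {
  utree_splits(phylo_to_utree(as_phylo_tree(tree)), include_trivial)
}
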