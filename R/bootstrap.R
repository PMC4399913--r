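#' Nonparametric bootstrap with split-support counting
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' pseudo-replicate with the chosen builder, and counts for every internal
#' split of the original tree how many replicate trees contain it.
#'
#' @param aln named character vector of aligned sequences.
#' @param n_replicates number of bootstrap replicates (`>= 0`).
#' @param seed integer seed; identical seeds reproduce identical support.
#' @param builder `"nj"` (fast, distance-based) or `"ml"` (full
#'   [ml_tree()] per replicate; expensive).
#' @param distance distance used by the NJ builder: `"p"`, `"ml"` or
#'   `"blosum62"`.
#' @param model substitution model for ML distances/likelihood.
#' @param tree optional original tree whose splits are scored; defaults to
#'   the builder's tree on the original alignment.
#' @param schedule passed to [ml_tree()] when `builder = "ml"`.
#' @return Object of class `bootstrap_result`: list with `tree`,
#'   `n_replicates`, `seed` and `support` (data frame `split`, `count`).
#' @export
bootstrap_support <- function(aln, n_replicates, seed, builder = c("nj", "ml"),
                              distance = "p", model = jtt_model(),
                              tree = NULL, schedule = "nni_spr") {
  builder <- match.arg(builder)
  aln <- check_alignment(aln)
  if (!is.numeric(n_replicates) || n_replicates < 0 ||
      n_replicates != round(n_replicates))
    stop("n_replicates must be a non-negative integer")
  build <- function(a) {
    if (builder == "nj")
      neighbor_joining(dist_matrix(a, method = distance, model = model))
    else
      ml_tree(a, model = model, schedule = schedule)$tree
  }
  if (is.null(tree)) tree <- build(aln)
  orig <- tree_splits(tree)
  counts <- stats::setNames(rep(0L, length(orig)), orig)
  L <- nchar(aln[[1]])
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      idx <- sample.int(L, L, replace = TRUE)
      rep_aln <- resample_columns(aln, idx)
      rep_tree <- tryCatch(build(rep_aln), error = function(e) NULL)
      if (is.null(rep_tree)) next
      hits <- orig %in% tree_splits(rep_tree)
      counts[hits] <- counts[hits] + 1L
    }
  })
  structure(list(tree = tree, n_replicates = as.integer(n_replicates),
                 seed = seed,
                 support = data.frame(split = orig, count = unname(counts),
                                      stringsAsFactors = FALSE)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap: %d replicates, %d internal splits (seed %s)\n",
              x$n_replicates, nrow(x$support), format(x$seed)))
  print(x$support)
  invisible(x)
}

#' Attach bootstrap counts to a tree as internal node labels
#'
#' @param result a `bootstrap_result` from [bootstrap_support()].
#' @return The original tree with `node.label` set to the support count of
#'   the split below each internal node (empty where not applicable),
#'   matching the conventional Newick support-as-node-label style.
#' @export
annotate_support <- function(result) {
  stopifnot(inherits(result, "bootstrap_result"))
  phy <- result$tree
  ntip <- length(phy$tip.label)
  taxa <- phy$tip.label
  labs <- character(phy$Nnode)
  sup <- stats::setNames(result$support$count, result$support$split)
  for (node in (ntip + 1):(ntip + phy$Nnode)) {
    tips <- tips_under(phy, node)
    key <- split_key(tips, taxa)
    if (!is_trivial_split(key, taxa) && key %in% names(sup))
      labs[node - ntip] <- as.character(sup[[key]])
  }
  phy$node.label <- labs
  phy
}

tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  out <- character(0)
  for (ch in phy$edge[phy$edge[, 1] == node, 2])
    out <- c(out, tips_under(phy, ch))
  out
}
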