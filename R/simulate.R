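#' Simulate amino-acid sequence evolution along a tree
#'
#' Evolves sequences under a reversible empirical substitution model
#' (default JTT) along a tree with branch lengths in expected substitutions
#' per site. The root sequence is drawn from the model's equilibrium
#' frequencies and each branch applies `P(t) = exp(Qt)` site-independently.
#'
#' @param tree an [ape::phylo] object or a Newick string with branch lengths.
#' @param length number of sites (columns) to simulate; `>= 1`.
#' @param seed integer seed; identical seeds give identical output.
#' @param model a [subst_model()]; defaults to [jtt_model()].
#' @return Named character vector of simulated sequences, one per leaf.
#' @examples
#' aln <- simulate_alignment("(A:0.1,B:0.1);", length = 50, seed = 1)
#' nchar(aln)
#' @export
simulate_alignment <- function(tree, length, seed, model = jtt_model()) {
  tree <- as_phylo_tree(tree)
  if (!is.numeric(length) || length(length) != 1L || length < 1 ||
      length != round(length))
    stop("length must be a positive integer site count")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("all branch lengths must be finite and >= 0")
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("tree must have at least 2 leaves")
  if (anyDuplicated(tree$tip.label)) stop("leaf labels must be unique")
  L <- as.integer(length)

  with_seed(seed, {
    tree <- stats::reorder(tree, "cladewise")  # parents before children
    nnode <- ntip + tree$Nnode
    states <- matrix(NA_integer_, nnode, L)
    root <- ntip + 1L
    states[root, ] <- sample.int(20L, L, replace = TRUE, prob = model$pi)
    for (k in seq_len(nrow(tree$edge))) {
      par <- tree$edge[k, 1]; chi <- tree$edge[k, 2]
      t <- tree$edge.length[k]
      ps <- states[par, ]
      if (t == 0) { states[chi, ] <- ps; next }
      P <- transition_matrix(model, t)
      cs <- integer(L)
      for (s in unique(ps)) {
        w <- which(ps == s)
        cs[w] <- sample.int(20L, length(w), replace = TRUE, prob = P[s, ])
      }
      states[chi, ] <- cs
    }
    out <- vapply(seq_len(ntip), function(i)
      paste0(AA_STATES[states[i, ]], collapse = ""), character(1))
    names(out) <- tree$tip.label
    out
  })
}

# accept phylo or newick string
as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    out <- tryCatch(suppressWarnings(ape::read.tree(text = tree)),
                    error = function(e) NULL)
    if (is.null(out)) stop("malformed Newick tree string")
    return(out)
  }
  stop("tree must be a 'phylo' object or a Newick string")
}

#' Simulate a multi-family sequence repertoire with designated templates
#'
#' Emulates a grouped receptor repertoire: `n_families` families descend from
#' a common ancestor; within each family one member is the designated
#' template (emulating a receptor with a known crystal structure) and the
#' remaining members evolve from it at the given intra-family divergence.
#' Family ancestors are separated by `inter_divergence` expected
#' substitutions per site, so members are closer (in expected P distance) to
#' their own template than to any other family's template whenever
#' `divergence` is well below `inter_divergence`.
#'
#' @param n_families number of families; `>= 1`.
#' @param members_per_family members per family (including the template).
#' @param divergence intra-family branch length from template to member
#'   (expected substitutions/site).
#' @param inter_divergence separation between family ancestors (expected
#'   substitutions/site between any two templates).
#' @param length sequence length in residues.
#' @param seed integer seed.
#' @param model a [subst_model()].
#' @return List with `sequences` (named character vector) and `info`
#'   (data frame: `name`, `family`, `is_template`).
#' @export
make_family_set <- function(n_families, members_per_family,
                            divergence = 0.1, inter_divergence = 1.0,
                            length = 300, seed = 1, model = jtt_model()) {
  stopifnot(n_families >= 1, members_per_family >= 1,
            divergence >= 0, inter_divergence >= 0, length >= 1)
  with_seed(seed, {
    root <- sample.int(20L, length, replace = TRUE, prob = model$pi)
    evolve <- function(states, t) {
      if (t == 0) return(states)
      P <- transition_matrix(model, t)
      out <- integer(base::length(states))
      for (s in unique(states)) {
        w <- which(states == s)
        out[w] <- sample.int(20L, base::length(w), replace = TRUE, prob = P[s, ])
      }
      out
    }
    seqs <- character(0); info <- NULL
    for (f in seq_len(n_families)) {
      fam <- sprintf("fam%02d", f)
      template <- evolve(root, inter_divergence / 2)
      tname <- paste0(fam, "_t01")
      seqs[[tname]] <- paste0(AA_STATES[template], collapse = "")
      info <- rbind(info, data.frame(name = tname, family = fam,
                                     is_template = TRUE))
      if (members_per_family > 1) {
        for (m in 2:members_per_family) {
          mem <- evolve(template, divergence)
          mname <- sprintf("%s_m%02d", fam, m)
          seqs[[mname]] <- paste0(AA_STATES[mem], collapse = "")
          info <- rbind(info, data.frame(name = mname, family = fam,
                                         is_template = FALSE))
        }
      }
    }
    rownames(info) <- NULL
    list(sequences = seqs, info = info)
  })
}
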