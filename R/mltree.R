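# Maximum-likelihood tree search: hill climbing over NNI and SPR
# rearrangements with per-move local branch re-optimisation and full
# re-optimisation after each accepted move.

# --- rearrangement generators (on utree) ---------------------------------

# list of candidate utrees from NNI moves; each with touched edge indices
nni_candidates <- function(ut) {
  adj <- utree_adjacency(ut)
  ntip <- length(ut$tips)
  out <- list()
  for (k in seq_len(nrow(ut$edges))) {
    u <- ut$edges[k, 1]; v <- ut$edges[k, 2]
    if (u <= ntip || v <= ntip) next
    nu <- sort(setdiff(adj[[u]], v)); nv <- sort(setdiff(adj[[v]], u))
    if (length(nu) != 2 || length(nv) != 2) next
    B <- nu[2]
    for (C in nv) {
      e2 <- ut$edges; l2 <- ut$len
      iB <- which((e2[, 1] == u & e2[, 2] == B) | (e2[, 1] == B & e2[, 2] == u))
      iC <- which((e2[, 1] == v & e2[, 2] == C) | (e2[, 1] == C & e2[, 2] == v))
      e2[iB, ] <- c(u, C); e2[iC, ] <- c(v, B)
      out[[length(out) + 1]] <- list(tree = utree_new(ut$tips, e2, l2),
                                     touched = c(k, iB, iC))
    }
  }
  out
}

# SPR: cut an edge, suppress the degree-2 node left behind, regraft the
# pruned component onto every other edge of the remaining tree
spr_candidates <- function(ut) {
  adj <- utree_adjacency(ut)
  ntip <- length(ut$tips)
  out <- list()
  ne <- nrow(ut$edges)
  for (k in seq_len(ne)) for (dir in 1:2) {
    u <- ut$edges[k, dir]; v <- ut$edges[k, 3 - dir]
    # prune the component containing v; u must be internal (degree 3)
    if (u <= ntip) next
    pq <- setdiff(adj[[u]], v)
    if (length(pq) != 2) next
    # nodes of the pruned component
    side_nodes <- local({
      seen <- logical(length(adj)); seen[u] <- TRUE
      stack <- v; res <- integer(0)
      while (length(stack)) {
        x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
        if (seen[x]) next
        seen[x] <- TRUE; res <- c(res, x)
        stack <- c(stack, adj[[x]][!seen[adj[[x]]]])
      }
      res
    })
    # remaining edges: drop (u,v), (u,p), (u,q); add merged (p,q)
    drop_idx <- c(k,
                  which((ut$edges[, 1] == u & ut$edges[, 2] == pq[1]) |
                        (ut$edges[, 2] == u & ut$edges[, 1] == pq[1])),
                  which((ut$edges[, 1] == u & ut$edges[, 2] == pq[2]) |
                        (ut$edges[, 2] == u & ut$edges[, 1] == pq[2])))
    keep <- setdiff(seq_len(ne), drop_idx)
    merged_len <- sum(ut$len[setdiff(drop_idx, k)])
    base_edges <- rbind(ut$edges[keep, , drop = FALSE], c(pq[1], pq[2]))
    base_len <- c(ut$len[keep], merged_len)
    nb <- nrow(base_edges)
    for (t in seq_len(nb - 1)) {   # exclude the merged edge itself (last)
      x <- base_edges[t, 1]; y <- base_edges[t, 2]
      if (x %in% side_nodes || y %in% side_nodes) next
      e2 <- base_edges; l2 <- base_len
      e2[t, ] <- c(x, u); l2[t] <- base_len[t] / 2
      e2 <- rbind(e2, c(u, y), c(u, v))
      l2 <- c(l2, base_len[t] / 2, ut$len[k])
      out[[length(out) + 1]] <- list(
        tree = utree_new(ut$tips, e2, l2),
        touched = c(t, nrow(e2) - 1L, nrow(e2), which(e2[, 1] == pq[1] &
                                                        e2[, 2] == pq[2])))
    }
  }
  out
}

topology_key <- function(ut) paste(sort(utree_splits(ut)), collapse = ";")

# one hill-climbing phase over a move neighbourhood.
# Candidates are first screened cheaply at their inherited branch lengths;
# the best-screened candidates then get the two-sweep local branch
# re-optimisation (in screening order) until one improves the current
# likelihood, which is accepted and followed by a full re-optimisation.
climb_phase <- function(ut, pat, model, moves = c("nni", "spr"),
                        cur_ll = NULL, local_sweeps = 2, eps = 1e-8,
                        screen_k = 5L) {
  moves <- match.arg(moves)
  if (is.null(cur_ll)) cur_ll <- utree_loglik(ut, pat, model)
  repeat {
    cands <- if (moves == "nni") nni_candidates(ut) else spr_candidates(ut)
    seen <- topology_key(ut)
    keep <- screened <- list()
    for (cand in cands) {
      key <- topology_key(cand$tree)
      if (key %in% seen) next
      seen <- c(seen, key)
      cand$screen_ll <- utree_loglik(cand$tree, pat, model)
      keep[[length(keep) + 1]] <- cand
    }
    if (!length(keep)) return(list(tree = ut, logL = cur_ll))
    ord <- order(-vapply(keep, `[[`, numeric(1), "screen_ll"))
    accepted <- NULL
    for (idx in ord[seq_len(min(screen_k, length(ord)))]) {
      cand <- keep[[idx]]
      t2 <- opt_branches(cand$tree, pat, model, cand$touched,
                         sweeps = local_sweeps)
      ll <- utree_loglik(t2, pat, model)
      if (ll > cur_ll + eps) { accepted <- t2; break }
    }
    if (is.null(accepted)) return(list(tree = ut, logL = cur_ll))
    ut <- opt_branches(accepted, pat, model, sweeps = 2)
    cur_ll <- utree_loglik(ut, pat, model)
  }
}

#' Maximum-likelihood tree inference with NNI/SPR topology search
#'
#' Hill-climbing search over tree topologies under a reversible amino-acid
#' model. The search starts from a Neighbor-Joining tree on ML distances
#' (or a user-supplied tree), optimises branch lengths (bounded 1-D Brent
#' per branch), and explores NNI and SPR rearrangements; candidate moves
#' re-optimise the branches adjacent to the rearrangement (two sweeps) and
#' an accepted move triggers a full two-sweep re-optimisation. The schedule
#' `"both"` runs NNI-then-SPR and SPR-then-NNI and returns the better
#' result, mirroring the practice of keeping the higher-likelihood tree of
#' the two optimisation orders.
#'
#' @param aln named character vector of aligned sequences (>= 4 taxa).
#' @param model a [subst_model()]; default JTT.
#' @param start `"nj"` or a starting [ape::phylo] tree.
#' @param schedule `"both"`, `"nni_spr"` or `"spr_nni"`.
#' @return List with `tree` (phylo, optimised branch lengths) and `logL`.
#' @export
ml_tree <- function(aln, model = jtt_model(), start = "nj",
                    schedule = c("both", "nni_spr", "spr_nni")) {
  schedule <- match.arg(schedule)
  aln <- check_alignment(aln)
  if (length(aln) < 4) stop("ML tree search requires at least 4 taxa")
  pat <- compress_patterns(aln)
  if (identical(start, "nj")) {
    D <- dist_matrix(aln, method = "ml", model = model)
    start_tree <- neighbor_joining(D)
  } else {
    start_tree <- as_phylo_tree(start)
    if (!setequal(start_tree$tip.label, names(aln)))
      stop("start tree leaves must match alignment taxa")
  }
  ut0 <- opt_branches(phylo_to_utree(start_tree), pat, model, sweeps = 2)
  ll0 <- utree_loglik(ut0, pat, model)
  run <- function(order) {
    res <- list(tree = ut0, logL = ll0)
    for (mv in order)
      res <- climb_phase(res$tree, pat, model, mv, cur_ll = res$logL)
    res
  }
  plans <- switch(schedule,
                  nni_spr = list(c("nni", "spr")),
                  spr_nni = list(c("spr", "nni")),
                  both = list(c("nni", "spr"), c("spr", "nni")))
  results <- lapply(plans, run)
  best <- results[[which.max(vapply(results, `[[`, numeric(1), "logL"))]]
  # final polish: tight branch-length convergence on the winning topology
  ut <- opt_branches(best$tree, pat, model, sweeps = 3, tol = 1e-7)
  list(tree = utree_to_phylo(ut), logL = utree_loglik(ut, pat, model))
}
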