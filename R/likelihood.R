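# Felsenstein pruning log-likelihood on unrooted trees, with site-pattern
# compression and per-node scaling. Gaps/ambiguities are missing data
# (conditional vector of ones).

compress_patterns <- function(aln) {
  aln <- check_alignment(aln)
  m <- seq_chars(aln)
  idx <- aa_index(m); dim(idx) <- dim(m)
  keys <- apply(idx, 2L, paste, collapse = ".")
  first <- !duplicated(keys)
  w <- as.vector(table(factor(keys, levels = keys[first])))
  list(idx = idx[, first, drop = FALSE], weights = w, taxa = rownames(m))
}

# log-likelihood of an utree given compressed patterns
utree_loglik <- function(ut, pat, model) {
  ntip <- length(ut$tips)
  tipid <- match(pat$taxa, ut$tips)
  if (anyNA(tipid) || length(pat$taxa) != ntip)
    stop("tree leaves and alignment taxa must match")
  adj <- utree_adjacency(ut)
  npat <- ncol(pat$idx)
  deg <- lengths(adj)
  root <- which(deg >= 3)[1]
  if (is.na(root)) root <- 1L
  lenv <- new.env()
  for (k in seq_len(nrow(ut$edges)))
    assign(paste(sort(ut$edges[k, ]), collapse = "-"), ut$len[k], envir = lenv)
  logscale <- numeric(npat)
  tip_indicator <- function(node) {
    L <- matrix(0, 20, npat)
    states <- pat$idx[match(ut$tips[node], pat$taxa), ]
    miss <- is.na(states)
    if (any(miss)) L[, miss] <- 1
    if (any(!miss)) L[cbind(states[!miss], which(!miss))] <- 1
    L
  }
  ntip_local <- length(ut$tips)
  rec <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    L <- if (node <= ntip_local) tip_indicator(node)
         else matrix(1, 20, npat)
    if (!length(kids)) return(L)
    for (k in kids) {
      bl <- get(paste(sort(c(node, k)), collapse = "-"), envir = lenv)
      P <- transition_matrix(model, max(bl, 0))
      L <- L * (P %*% rec(k, node))
    }
    s <- apply(L, 2L, max)
    s[s <= 0] <- 1
    logscale <<- logscale + log(s)
    L / rep(s, each = 20)
  }
  Lr <- rec(root, 0L)
  site_ll <- log(as.vector(model$pi %*% Lr)) + logscale
  sum(pat$weights * site_ll)
}

#' Felsenstein pruning log-likelihood
#'
#' Computes the log-likelihood of an alignment on an unrooted tree under a
#' reversible amino-acid substitution model by the pruning algorithm, with
#' site-pattern compression and numeric scaling. Gap and ambiguity
#' characters are treated as missing data.
#'
#' @param tree [ape::phylo] tree (leaf set equal to the alignment taxa).
#' @param aln named character vector of aligned sequences.
#' @param model a [subst_model()].
#' @return Total log-likelihood (sum over sites).
#' @export
felsenstein_loglik <- function(tree, aln, model = jtt_model()) {
  ut <- phylo_to_utree(as_phylo_tree(tree))
  utree_loglik(ut, compress_patterns(aln), model)
}

# conditional likelihood of the subtree behind `node`, seen from
# neighbour `from` (i.e. excluding the edge node-from); returns the 20 x
# npat matrix plus per-pattern log scaling
conditional_toward <- function(ut, node, from, pat, model, adj, lenv) {
  npat <- ncol(pat$idx)
  kids <- setdiff(adj[[node]], from)
  if (node <= length(ut$tips)) {
    L <- matrix(0, 20, npat)
    states <- pat$idx[match(ut$tips[node], pat$taxa), ]
    miss <- is.na(states)
    if (any(miss)) L[, miss] <- 1
    if (any(!miss)) L[cbind(states[!miss], which(!miss))] <- 1
  } else L <- matrix(1, 20, npat)
  logscale <- numeric(npat)
  if (!length(kids)) return(list(L = L, logscale = logscale))
  for (k in kids) {
    sub <- conditional_toward(ut, k, node, pat, model, adj, lenv)
    bl <- get(paste(sort(c(node, k)), collapse = "-"), envir = lenv)
    P <- transition_matrix(model, max(bl, 0))
    L <- L * (P %*% sub$L)
    logscale <- logscale + sub$logscale
  }
  s <- apply(L, 2L, max); s[s <= 0] <- 1
  list(L = L / rep(s, each = 20), logscale = logscale + log(s))
}

len_env <- function(ut) {
  lenv <- new.env()
  for (k in seq_len(nrow(ut$edges)))
    assign(paste(sort(ut$edges[k, ]), collapse = "-"), ut$len[k], envir = lenv)
  lenv
}

# optimise branch lengths in place; edges_idx defaults to all edges.
# Per edge the conditionals of both incident subtrees are computed once,
# so each 1-D likelihood evaluation costs a single matrix product.
opt_branches <- function(ut, pat, model, edges_idx = seq_len(nrow(ut$edges)),
                         sweeps = 2, tol = 1e-4,
                         bounds = c(1e-8, 10)) {
  adj <- utree_adjacency(ut)
  for (s in seq_len(sweeps)) {
    for (k in edges_idx) {
      lenv <- len_env(ut)
      u <- ut$edges[k, 1]; v <- ut$edges[k, 2]
      cu <- conditional_toward(ut, u, v, pat, model, adj, lenv)
      cv <- conditional_toward(ut, v, u, pat, model, adj, lenv)
      base <- cu$logscale + cv$logscale
      piLu <- model$pi * cu$L
      f <- function(x) {
        P <- transition_matrix(model, x)
        site <- colSums(piLu * (P %*% cv$L))
        sum(pat$weights * (log(site) + base))
      }
      opt <- stats::optimize(f, bounds, maximum = TRUE, tol = tol)
      ut$len[k] <- opt$maximum
    }
  }
  ut
}
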