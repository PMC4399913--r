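# shared fixtures, all generated in code

# random binary unrooted tree with branch lengths in [lo, hi]
random_tree <- function(n, seed, lo = 0.05, hi = 0.5) {
  gpcrnet:::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE,
                     tip.label = sprintf("t%02d", seq_len(n)))
    tr$edge.length <- stats::runif(nrow(tr$edge), lo, hi)
    tr
  })
}

# additive (path-length) distance matrix of a tree
tree_metric <- function(tr) {
  d <- stats::cophenetic(tr)
  d[sort(rownames(d)), sort(rownames(d))]
}

# canonical form of a circular ordering (rotation/reflection invariant)
canonical_cycle <- function(ord) {
  n <- length(ord)
  rots <- lapply(seq_len(n) - 1, function(k) ord[((seq_len(n) - 1 + k) %% n) + 1])
  rots <- c(rots, lapply(rots, rev))
  keys <- vapply(rots, paste, character(1), collapse = ",")
  min(keys)
}

# independent brute-force affine-gap global alignment score (exponential
# enumeration via recursion with memo on (i, j, state))
oracle_align_score <- function(a, b, open = 10, extend = 1,
                               smat = gpcrnet:::blosum62_matrix()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ai <- match(av, gpcrnet:::AA_STATES); bi <- match(bv, gpcrnet:::AA_STATES)
  memo <- new.env()
  rec <- function(i, j, state) {
    if (i == 0 && j == 0)
      return(if (state == 0) 0 else -Inf)
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (state == 0 && i > 0 && j > 0) {
      s <- smat[ai[i], bi[j]]
      best <- max(best, rec(i - 1, j - 1, 0) + s,
                  rec(i - 1, j - 1, 1) + s, rec(i - 1, j - 1, 2) + s)
    }
    if (state == 1 && i > 0) {   # gap in b, consuming a
      best <- max(best, rec(i - 1, j, 0) - open - extend,
                  rec(i - 1, j, 1) - extend)
    }
    if (state == 2 && j > 0) {   # gap in a, consuming b
      best <- max(best, rec(i, j - 1, 0) - open - extend,
                  rec(i, j - 1, 2) - extend)
    }
    memo[[key]] <- best
    best
  }
  max(rec(length(av), length(bv), 0), rec(length(av), length(bv), 1),
      rec(length(av), length(bv), 2))
}

# two planted pocket classes with redundant signal: class identity is
# encoded at several variable positions; the "shared" ligand/sodium
# positions are fully conserved, so removing them rescales all P distances
# uniformly and cannot change the network topology
two_class_profiles <- function() {
  classA <- c("D", "R", "W", "Y")      # letters at 4 informative positions
  classB <- c("E", "K", "F", "S")
  conserved <- c("N", "P")             # the shared ligand/sodium positions
  pos <- c(sprintf("3.%02d", 28:31), c("2.50", "7.49"))
  mk <- function(letters, wobble_at, wobble) {
    aa <- c(letters, conserved)
    aa[wobble_at] <- wobble
    data.frame(resno = seq_along(pos), aa = aa, bw = pos)
  }
  sets <- list(
    a1 = mk(classA, 1, "D"), a2 = mk(classA, 2, "H"), a3 = mk(classA, 3, "V"),
    b1 = mk(classB, 1, "E"), b2 = mk(classB, 2, "T"), b3 = mk(classB, 3, "I"))
  build_pocket_profiles(sets)
}

# toy receptor helper: annotated receptor list entry from a bundle
toy_receptor <- function(name, loop4 = 8, n_res = rep(24L, 7), ...) {
  b <- make_toy_bundle(toy_receptor_spec(n_res = n_res,
                                         loop_len = c(4, 4, 4, loop4, 4, 4)),
                       name = name, ...)
  list(sequence = b$sequence, helix_spans = b$helix_spans,
       anchors = b$anchors, bundle = b)
}
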