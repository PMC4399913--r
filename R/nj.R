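# Neighbor-Joining with deterministic lexicographic tie-breaks.
#
# The engine records the cluster join order so the progressive aligner can
# reuse NJ agglomeration as its guide. Each active cluster is represented by
# its lexicographically smallest member label; ties in the Q criterion are
# broken by the sorted pair of representative labels.

nj_engine <- function(D) {
  d <- check_dist(D)
  n <- nrow(d)
  if (n < 3) stop("Neighbor-Joining requires at least 3 taxa")
  labels <- rownames(d)
  reps <- labels               # representative label per active node
  sub <- labels                # Newick subtree string per active node
  joins <- list()

  pick_pair <- function(score) {
    m <- nrow(score)
    best <- NULL; best_q <- Inf; best_key <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      q <- score[i, j]
      key <- paste(sort(c(reps[i], reps[j])), collapse = "\r")
      if (q < best_q - 1e-12 ||
          (abs(q - best_q) <= 1e-12 && key < best_key)) {
        best <- c(i, j); best_q <- q; best_key <- key
      }
    }
    best
  }

  while (n > 3) {
    r <- rowSums(d)
    Qm <- (n - 2) * d - outer(r, r, "+")
    ij <- pick_pair(Qm)
    i <- ij[1]; j <- ij[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    li <- max(0, li); lj <- max(0, lj)
    joins[[length(joins) + 1]] <- c(reps[i], reps[j])
    newsub <- sprintf("(%s:%.10g,%s:%.10g)", sub[i], li, sub[j], lj)
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    reps <- c(reps[keep], min(reps[c(i, j)]))
    sub <- c(sub[keep], newsub)
    rownames(d2) <- colnames(d2) <- reps
    d <- d2
    n <- n - 1
  }

  # terminal 3-node star: three-point branch lengths
  l1 <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  l2 <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  l3 <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  # join order among the last three: closest pair first, ties lexicographic
  pr <- pick_pair(d)
  k3 <- setdiff(1:3, pr)
  joins[[length(joins) + 1]] <- c(reps[pr[1]], reps[pr[2]])
  joins[[length(joins) + 1]] <- c(min(reps[pr]), reps[k3])
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    sub[1], l1, sub[2], l2, sub[3], l3)
  list(tree = ape::read.tree(text = newick), joins = joins)
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Standard Saitou--Nei Neighbor-Joining: repeatedly joins the pair of
#' active nodes minimising the Q criterion
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch lengths
#' from the NJ formulas (negative estimates clamped to zero) and ties broken
#' lexicographically by the joined clusters' smallest member labels. Exact on
#' additive (tree) metrics.
#'
#' @param D symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return Unrooted [ape::phylo] tree (trifurcating root node).
#' @examples
#' d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' neighbor_joining(d)$edge.length
#' @export
neighbor_joining <- function(D) {
  nj_engine(D)$tree
}
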