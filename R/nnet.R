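# NeighborNet circular split networks: agglomerative circular ordering
# (Bryant-Moulton scheme with the published selection criteria and the
# 2/3-1/3 chain reduction) followed by non-negative least-squares split
# weights over all circular splits.

#' Circular taxon ordering by NeighborNet agglomeration
#'
#' Implements the NeighborNet agglomerative scheme: clusters (chains of one
#' or two active nodes) are repeatedly selected with the net-divergence
#' corrected criterion `d(A,B) - r(A) - r(B)`; within the selected cluster
#' pair the closest node pair is chosen with the analogous criterion over
#' the expanded cluster list, and three-node chains are reduced to two
#' composite nodes with weights 2/3 and 1/3. Ties are broken
#' lexicographically by taxon label, so the ordering is deterministic.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @return Character vector: the circular ordering of the taxa (a rotation/
#'   reflection-equivalent representative). Sets of fewer than 4 taxa are
#'   returned in input order.
#' @export
neighbornet_ordering <- function(D) {
  d <- check_dist(D)
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 4) return(labels)
  rownames(d) <- colnames(d) <- NULL

  # active node bookkeeping; composite nodes reuse slots of old ones
  active <- seq_len(n)
  CL <- as.list(seq_len(n))          # clusters: active node ids (1 or 2)
  ORD <- as.list(seq_len(n))         # per-cluster chain of original taxa
  rep_of <- function(cl) min(labels[unlist(ORD[cl])])

  avg_d <- function(a, b) mean(d[a, b])

  reduce3 <- function(x, y, z) {
    # replace chain x-y-z by composites u (in slot x) and v (in slot z)
    u <- 2 / 3 * d[x, ] + d[y, ] / 3
    v <- 2 / 3 * d[z, ] + d[y, ] / 3
    uv <- (d[x, y] + d[x, z] + d[y, z]) / 3
    d[x, ] <<- u; d[, x] <<- u
    d[z, ] <<- v; d[, z] <<- v
    d[x, z] <<- uv; d[z, x] <<- uv
    d[x, x] <<- 0; d[z, z] <<- 0
    d[y, ] <<- 0; d[, y] <<- 0
  }

  while (length(CL) > 1) {
    m <- length(CL)
    # cluster-level average distances
    DM <- matrix(0, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m)
      DM[i, j] <- DM[j, i] <- avg_d(CL[[i]], CL[[j]])
    if (m > 2) {
      r <- rowSums(DM) / (m - 2)
      crit <- DM - outer(r, r, "+")
    } else crit <- DM
    diag(crit) <- Inf
    best <- NULL; bq <- Inf; bkey <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      key <- paste(sort(c(rep_of(i), rep_of(j))), collapse = "\r")
      if (crit[i, j] < bq - 1e-12 ||
          (abs(crit[i, j] - bq) <= 1e-12 && key < bkey)) {
        best <- c(i, j); bq <- crit[i, j]; bkey <- key
      }
    }
    e1 <- best[1]; e2 <- best[2]
    n1 <- length(CL[[e1]]); n2 <- length(CL[[e2]])

    if (n1 == 1 && n2 == 1) {
      CL[[e1]] <- c(CL[[e1]], CL[[e2]])
      ORD[[e1]] <- c(ORD[[e1]], ORD[[e2]])
      CL <- CL[-e2]; ORD <- ORD[-e2]
      next
    }

    # node-level selection: nodes of the two clusters as singletons plus
    # the other clusters
    nodes <- c(CL[[e1]], CL[[e2]])
    others <- CL[-c(e1, e2)]
    mm <- length(nodes) + length(others)
    rnode <- vapply(seq_along(nodes), function(i) {
      xi <- nodes[i]
      s <- sum(vapply(seq_along(nodes)[-i], function(j) d[xi, nodes[j]],
                      numeric(1)))
      if (length(others))
        s <- s + sum(vapply(others, function(C) mean(d[xi, C]), numeric(1)))
      s
    }, numeric(1))
    if (mm > 2) rnode <- rnode / (mm - 2)
    sc <- matrix(Inf, n1, n2)
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      x <- nodes[i]; y <- nodes[n1 + j]
      sc[i, j] <- d[x, y] - rnode[i] - rnode[n1 + j]
    }
    # deterministic argmin: smallest value, ties by (i, j)
    bij <- which(sc == min(sc), arr.ind = TRUE)[1, ]
    i <- bij[1]; j <- bij[2]

    if (n1 == 2 && n2 == 1) {
      if (i == 2) { # chain a1-a2-b
        newCL <- c(CL[[e1]][1], CL[[e2]])
        newORD <- c(ORD[[e1]], ORD[[e2]])
        reduce3(CL[[e1]][1], CL[[e1]][2], CL[[e2]])
      } else {      # chain b-a1-a2
        newCL <- c(CL[[e2]], CL[[e1]][2])
        newORD <- c(ORD[[e2]], ORD[[e1]])
        reduce3(CL[[e2]], CL[[e1]][1], CL[[e1]][2])
      }
    } else if (n1 == 1 && n2 == 2) {
      if (j == 1) { # chain a-b1-b2
        newCL <- c(CL[[e1]], CL[[e2]][2])
        newORD <- c(ORD[[e1]], ORD[[e2]])
        reduce3(CL[[e1]], CL[[e2]][1], CL[[e2]][2])
      } else {      # chain b1-b2-a -> reversed
        newCL <- c(CL[[e2]][1], CL[[e1]])
        newORD <- c(ORD[[e2]], ORD[[e1]])
        reduce3(CL[[e2]][1], CL[[e2]][2], CL[[e1]])
      }
    } else { # 2 and 2: join x and y, two successive reductions
      a <- CL[[e1]]; b <- CL[[e2]]
      if (i == 1 && j == 1) {
        newCL <- c(a[2], b[2]); newORD <- c(rev(ORD[[e1]]), ORD[[e2]])
        reduce3(a[2], a[1], b[1]); reduce3(a[2], b[1], b[2])
      } else if (i == 2 && j == 1) {
        newCL <- c(a[1], b[2]); newORD <- c(ORD[[e1]], ORD[[e2]])
        reduce3(a[1], a[2], b[1]); reduce3(a[1], b[1], b[2])
      } else if (i == 1 && j == 2) {
        newCL <- c(a[2], b[1]); newORD <- c(rev(ORD[[e1]]), rev(ORD[[e2]]))
        reduce3(a[2], a[1], b[2]); reduce3(a[2], b[2], b[1])
      } else {
        newCL <- c(a[1], b[1]); newORD <- c(ORD[[e1]], rev(ORD[[e2]]))
        reduce3(a[1], a[2], b[2]); reduce3(a[1], b[2], b[1])
      }
    }
    CL[[e1]] <- newCL; ORD[[e1]] <- newORD
    CL <- CL[-e2]; ORD <- ORD[-e2]
  }
  labels[ORD[[1]]]
}

# all distinct circular splits of an ordering, as canonical keys
circular_splits <- function(ordering) {
  n <- length(ordering)
  keys <- character(0)
  for (s in seq_len(n)) for (len in seq_len(n - 1)) {
    side <- ordering[((s - 1 + seq_len(len) - 1) %% n) + 1]
    keys <- c(keys, split_key(side, ordering))
  }
  unique(keys)
}

#' NeighborNet split weights by non-negative least squares
#'
#' Given a circular ordering, fits non-negative weights for all
#' `n(n-1)/2` circular splits by least squares against the input
#' distances (Lawson--Hanson active-set NNLS), and drops splits whose
#' weight falls below a pruning threshold. On an additive (tree) metric
#' the retained splits are exactly the tree's splits with weights equal
#' to branch lengths.
#'
#' @param D symmetric distance matrix.
#' @param ordering circular taxon ordering, e.g. from
#'   [neighbornet_ordering()]; defaults to computing it from `D`.
#' @param eps weight-pruning threshold (default `1e-9`).
#' @return Object of class `split_system`: list with `taxa`, `ordering`,
#'   and `splits` (data frame `split` key, `weight`).
#' @export
nnls_split_weights <- function(D, ordering = neighbornet_ordering(D),
                               eps = 1e-9) {
  d <- check_dist(D)
  taxa <- rownames(d)
  if (!setequal(ordering, taxa) || length(ordering) != length(taxa))
    stop("ordering must be a permutation of the distance matrix taxa")
  n <- length(taxa)
  keys <- circular_splits(ordering)
  pairs <- utils::combn(taxa, 2)
  np <- ncol(pairs)
  A <- matrix(0, np, length(keys))
  for (sidx in seq_along(keys)) {
    side <- split_side(keys[sidx])
    in_side <- pairs[1, ] %in% side
    in_side2 <- pairs[2, ] %in% side
    A[, sidx] <- as.numeric(xor(in_side, in_side2))
  }
  dv <- d[cbind(pairs[1, ], pairs[2, ])]
  w <- pracma::lsqnonneg(A, dv)$x
  keep <- w > eps
  new_split_system(taxa, ordering,
                   data.frame(split = keys[keep], weight = w[keep],
                              stringsAsFactors = FALSE))
}

new_split_system <- function(taxa, ordering, splits) {
  stopifnot(all(splits$weight >= 0))
  structure(list(taxa = sort(taxa), ordering = ordering, splits = splits),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  nt <- sum(!vapply(x$splits$split, is_trivial_split, logical(1),
                    taxa = x$taxa))
  cat(sprintf("circular split system: %d taxa, %d splits (%d non-trivial)\n",
              length(x$taxa), nrow(x$splits), nt))
  invisible(x)
}

#' Build a NeighborNet split network from a distance matrix
#'
#' Convenience wrapper: [neighbornet_ordering()] then
#' [nnls_split_weights()].
#'
#' @param D symmetric distance matrix (asymmetric or negative input is
#'   rejected).
#' @param eps weight-pruning threshold.
#' @return A `split_system`; see [nnls_split_weights()].
#' @export
neighbor_net <- function(D, eps = 1e-9) {
  nnls_split_weights(D, eps = eps)
}

# distances implied by a weighted split system
split_system_distances <- function(ss) {
  taxa <- ss$taxa
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (k in seq_len(nrow(ss$splits))) {
    side <- split_side(ss$splits$split[k])
    inA <- taxa %in% side
    w <- ss$splits$weight[k]
    d[inA, !inA] <- d[inA, !inA] + w
    d[!inA, inA] <- d[!inA, inA] + w
  }
  d
}

#' Compare two split systems
#'
#' Set-wise comparison of bipartitions (weights ignored): shared and unique
#' non-trivial splits and the Jaccard index over non-trivial splits.
#'
#' @param s1,s2 `split_system` objects over the same taxa.
#' @return List with `shared`, `only1`, `only2` (split keys) and `jaccard`
#'   (1 when both systems have no non-trivial splits).
#' @export
compare_split_systems <- function(s1, s2) {
  stopifnot(inherits(s1, "split_system"), inherits(s2, "split_system"))
  if (!setequal(s1$taxa, s2$taxa))
    stop("split systems must share the same taxon set")
  nt <- function(s) s$splits$split[!vapply(s$splits$split, is_trivial_split,
                                           logical(1), taxa = s$taxa)]
  a <- nt(s1); b <- nt(s2)
  shared <- intersect(a, b)
  uni <- union(a, b)
  list(shared = shared, only1 = setdiff(a, b), only2 = setdiff(b, a),
       jaccard = if (length(uni) == 0) 1 else length(shared) / length(uni))
}

#' Write a split system as a NEXUS SPLITS block
#'
#' Produces a minimal SplitsTree-compatible NEXUS file with TAXA and SPLITS
#' blocks (cycle plus weighted splits).
#'
#' @param ss a `split_system`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nexus_splits <- function(ss, path) {
  stopifnot(inherits(ss, "split_system"))
  taxa <- ss$ordering
  n <- length(taxa)
  idx <- function(lbl) match(lbl, taxa)
  lines <- c("#NEXUS", "",
             "BEGIN TAXA;",
             sprintf("DIMENSIONS ntax=%d;", n),
             "TAXLABELS",
             sprintf("  [%d] '%s'", seq_len(n), taxa),
             ";", "END;", "",
             "BEGIN SPLITS;",
             sprintf("DIMENSIONS ntax=%d nsplits=%d;", n, nrow(ss$splits)),
             "FORMAT labels=no weights=yes;",
             sprintf("CYCLE %s;", paste(seq_len(n), collapse = " ")),
             "MATRIX")
  for (k in seq_len(nrow(ss$splits))) {
    side <- split_side(ss$splits$split[k])
    lines <- c(lines, sprintf("[%d] %.10g : %s,", k, ss$splits$weight[k],
                              paste(sort(idx(side)), collapse = " ")))
  }
  lines <- c(lines, ";", "END;")
  writeLines(lines, path)
  invisible(path)
}
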