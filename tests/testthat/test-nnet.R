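test_that("caterpillar metrics give the path circular order", {
  tr <- ape::read.tree(
    text = "(A:1,(B:1,(C:1,(D:1,E:1):1):1):1);")
  d <- tree_metric(tr)
  ord <- neighbornet_ordering(d)
  # the ordering must be tree-compatible: every split of the caterpillar is
  # a contiguous arc of the cycle (enumerating the valid circular orders)
  expect_true(all(tree_splits(tr) %in% gpcrnet:::circular_splits(ord)))
  # cherries are adjacent in the cycle
  adjacent <- function(x, y) {
    i <- match(x, ord); j <- match(y, ord)
    abs(i - j) == 1 || abs(i - j) == length(ord) - 1
  }
  expect_true(adjacent("D", "E"))
  expect_true(adjacent("A", "B"))
})

test_that("small taxon sets are returned in input order", {
  taxa <- c("Z", "Q", "M")
  d <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, dimnames = list(taxa, taxa))
  expect_identical(neighbornet_ordering(d), taxa)
})

test_that("the ordering is invariant to input taxon permutation", {
  tr <- random_tree(7, seed = 61)
  d <- tree_metric(tr)
  ord1 <- neighbornet_ordering(d)
  perm <- sample(seq_len(nrow(d)))
  ord2 <- neighbornet_ordering(d[perm, perm])
  expect_equal(canonical_cycle(ord1), canonical_cycle(ord2))
})

test_that("asymmetric or negative distances are rejected", {
  taxa <- LETTERS[1:4]
  d <- matrix(1, 4, 4, dimnames = list(taxa, taxa)); diag(d) <- 0
  d[1, 2] <- 2                       # asymmetric
  expect_error(nnls_split_weights(d, taxa), "symmetric")
  d2 <- matrix(1, 4, 4, dimnames = list(taxa, taxa)); diag(d2) <- 0
  d2[1, 2] <- d2[2, 1] <- -1
  expect_error(neighbornet_ordering(d2), "non-negative|symmetric")
})

test_that("tree metrics reduce the network to the tree (perfect phylogeny)", {
  for (seed in 1:3) {
    tr <- random_tree(8, seed = 70 + seed)
    d <- tree_metric(tr)
    ss <- neighbor_net(d)
    nontrivial <- ss$splits$split[!vapply(ss$splits$split,
                                          gpcrnet:::is_trivial_split,
                                          logical(1), taxa = ss$taxa)]
    expect_setequal(nontrivial, tree_splits(tr))
    # weights equal branch lengths; fitted distances reproduce the metric
    fitted <- gpcrnet:::split_system_distances(ss)
    expect_lt(max(abs(fitted[rownames(d), colnames(d)] - d)), 1e-6)
  }
})

test_that("NNLS weights match a brute-force oracle on 4-taxon metrics", {
  taxa <- c("A", "B", "C", "D")
  brute_nnls <- function(d, ordering) {
    keys <- gpcrnet:::circular_splits(ordering)
    pairs <- utils::combn(taxa, 2)
    A <- 1 * sapply(keys, function(k) {
      side <- gpcrnet:::split_side(k)
      xor(pairs[1, ] %in% side, pairs[2, ] %in% side)
    })
    dv <- d[cbind(pairs[1, ], pairs[2, ])]
    best <- NULL
    for (sub in seq_len(2^length(keys)) - 1) {      # all active sets
      on <- which(bitwAnd(sub, 2^(seq_along(keys) - 1)) > 0)
      if (!length(on)) { w <- numeric(0); res <- sum(dv^2) }
      else {
        fit <- stats::lm.fit(A[, on, drop = FALSE], dv)
        if (any(is.na(fit$coefficients)) || any(fit$coefficients < -1e-12))
          next
        w <- fit$coefficients; res <- sum(fit$residuals^2)
      }
      if (is.null(best) || res < best$res - 1e-12)
        best <- list(res = res, keys = keys[on], w = w)
    }
    best
  }
  # (a) the metric that looks conflicting but is additive: tree AB|CD
  d1 <- matrix(3, 4, 4, dimnames = list(taxa, taxa)); diag(d1) <- 0
  d1["A", "B"] <- d1["B", "A"] <- 2; d1["C", "D"] <- d1["D", "C"] <- 2
  ss1 <- neighbor_net(d1)
  oracle1 <- brute_nnls(d1, ss1$ordering)
  expect_setequal(ss1$splits$split, oracle1$keys)
  expect_equal(ss1$splits$weight[match(oracle1$keys, ss1$splits$split)],
               unname(oracle1$w), tolerance = 1e-8)
  nt1 <- ss1$splits$split[!vapply(ss1$splits$split,
                                  gpcrnet:::is_trivial_split,
                                  logical(1), taxa = taxa)]
  expect_identical(nt1, "C,D")    # the single tree split AB|CD
  # (b) a genuinely circular conflicting metric: two incompatible splits
  d2 <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  d2["A", "B"] <- d2["C", "D"] <- 1.5
  d2["B", "C"] <- d2["A", "D"] <- 2
  d2["A", "C"] <- d2["B", "D"] <- 2.5
  d2 <- d2 + t(d2)
  ss2 <- neighbor_net(d2)
  nt2 <- ss2$splits$split[!vapply(ss2$splits$split,
                                  gpcrnet:::is_trivial_split,
                                  logical(1), taxa = taxa)]
  expect_setequal(nt2, c("C,D", "B,C"))  # AB|CD and AD|BC, both positive
  oracle2 <- brute_nnls(d2, ss2$ordering)
  expect_setequal(ss2$splits$split, oracle2$keys)
  expect_equal(ss2$splits$weight[match(oracle2$keys, ss2$splits$split)],
               unname(oracle2$w), tolerance = 1e-8)
})

test_that("network splits equal NJ splits on tree metrics (cross-module)", {
  for (seed in 1:2) {
    tr <- random_tree(7, seed = 80 + seed)
    d <- tree_metric(tr)
    ss <- neighbor_net(d)
    nt <- ss$splits$split[!vapply(ss$splits$split,
                                  gpcrnet:::is_trivial_split,
                                  logical(1), taxa = ss$taxa)]
    expect_setequal(nt, tree_splits(neighbor_joining(d)))
  }
})

test_that("split systems match phangorn's NeighborNet on tree metrics", {
  tr <- random_tree(8, seed = 91)
  d <- tree_metric(tr)
  ss <- neighbor_net(d)
  nn <- phangorn::neighborNet(d)
  ph_splits <- vapply(nn$splits, function(ii)
    gpcrnet:::split_key(attr(nn$splits, "labels")[ii], rownames(d)),
    character(1))
  keep <- attr(nn$splits, "weights") > 1e-9
  expect_setequal(ss$splits$split, unique(ph_splits[keep]))
})

test_that("split-system comparison reports shared, unique and Jaccard", {
  taxa <- sprintf("t%d", 1:6)
  mk <- function(keys) gpcrnet:::new_split_system(
    taxa, taxa, data.frame(split = keys, weight = 1))
  s_id <- mk(c("t2,t3", "t4,t5"))
  expect_equal(compare_split_systems(s_id, s_id)$jaccard, 1.0)
  s_disj <- mk(c("t3,t4", "t5,t6"))
  expect_equal(compare_split_systems(s_id, s_disj)$jaccard, 0.0)
  a <- mk(c("t2,t3", "t4,t5", "t2,t3,t4", "t5,t6", "t3,t4"))
  b <- mk(c("t2,t3", "t4,t5", "t2,t3,t4", "t5,t6", "t4,t5,t6"))
  cmp <- compare_split_systems(a, b)
  expect_equal(cmp$jaccard, 4 / 6)
  expect_setequal(cmp$only1, "t3,t4")
  expect_setequal(cmp$only2, "t4,t5,t6")
  other <- gpcrnet:::new_split_system(
    c("x1", "x2", "x3", "x4"), c("x1", "x2", "x3", "x4"),
    data.frame(split = "x1,x2", weight = 1))
  expect_error(compare_split_systems(a, other), "taxon set")
})

test_that("NEXUS splits output contains taxa, cycle and weighted splits", {
  tr <- random_tree(5, seed = 95)
  ss <- neighbor_net(tree_metric(tr))
  f <- withr::local_tempfile(fileext = ".nex")
  write_nexus_splits(ss, f)
  txt <- readLines(f)
  expect_true(any(grepl("BEGIN SPLITS;", txt)))
  expect_true(any(grepl(sprintf("nsplits=%d", nrow(ss$splits)), txt)))
  expect_true(any(grepl("CYCLE", txt)))
})
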