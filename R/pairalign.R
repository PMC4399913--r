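# Profile-profile global alignment (Gotoh, affine gaps) and progressive
# multiple alignment with an NJ guide built from pairwise global alignments.
#
# Gap cost convention: a gap of length L costs open + extend * L (matching
# Biostrings::pairwiseAlignment with the same parameters). Column score
# between profiles is the average-of-pairs substitution score over non-gap
# residues. Ties in the dynamic program are resolved match > gap-in-B >
# gap-in-A, so results are deterministic.

profile_counts <- function(rows) {
  m <- seq_chars(rows)
  L <- ncol(m)
  cnt <- matrix(0, 20, L)
  idx <- aa_index(m)
  dim(idx) <- dim(m)
  for (j in seq_len(L)) {
    tab <- tabulate(idx[, j][!is.na(idx[, j])], nbins = 20)
    cnt[, j] <- tab
  }
  cnt
}

# align two profiles (named character vectors of equal-length rows)
align_profiles <- function(rows_a, rows_b, open = 10, extend = 1,
                           smat = blosum62_matrix()) {
  ca <- profile_counts(rows_a); cb <- profile_counts(rows_b)
  La <- ncol(ca); Lb <- ncol(cb)
  na <- pmax(colSums(ca), 1); nb <- pmax(colSums(cb), 1)
  S <- t(ca) %*% smat %*% cb / outer(na, nb)   # La x Lb column scores
  NEG <- -1e12
  M <- X <- Y <- matrix(NEG, La + 1, Lb + 1)
  M[1, 1] <- 0
  if (La > 0) X[2:(La + 1), 1] <- -(open + extend * seq_len(La))
  if (Lb > 0) Y[1, 2:(Lb + 1)] <- -(open + extend * seq_len(Lb))
  tbM <- tbX <- tbY <- matrix(0L, La + 1, Lb + 1)  # 1 = from M, 2 = X, 3 = Y
  for (i in seq_len(La)) {
    Mi1 <- M[i, ]; Xi1 <- X[i, ]; Yi1 <- Y[i, ]
    Mi <- M[i + 1, ]; Xi <- X[i + 1, ]; Yi <- Y[i + 1, ]
    for (j in seq_len(Lb)) {
      # match state
      best <- Mi1[j]; src <- 1L
      if (Xi1[j] > best) { best <- Xi1[j]; src <- 2L }
      if (Yi1[j] > best) { best <- Yi1[j]; src <- 3L }
      Mi[j + 1] <- best + S[i, j]; tbM[i + 1, j + 1] <- src
      # gap in B (consume profile A)
      vm <- Mi1[j + 1] - open - extend; vx <- Xi1[j + 1] - extend
      if (vm >= vx) { Xi[j + 1] <- vm; tbX[i + 1, j + 1] <- 1L }
      else          { Xi[j + 1] <- vx; tbX[i + 1, j + 1] <- 2L }
      # gap in A (consume profile B)
      wm <- Mi[j] - open - extend; wy <- Yi[j] - extend
      if (wm >= wy) { Yi[j + 1] <- wm; tbY[i + 1, j + 1] <- 1L }
      else          { Yi[j + 1] <- wy; tbY[i + 1, j + 1] <- 3L }
    }
    M[i + 1, ] <- Mi; X[i + 1, ] <- Xi; Y[i + 1, ] <- Yi
  }
  ends <- c(M[La + 1, Lb + 1], X[La + 1, Lb + 1], Y[La + 1, Lb + 1])
  state <- which.max(ends)           # prefers M on ties
  score <- ends[state]
  # traceback
  ops <- integer(0)                  # 1 = both, 2 = A only, 3 = B only
  i <- La; j <- Lb
  while (i > 0 || j > 0) {
    if (state == 1L) {
      ops <- c(1L, ops); prev <- tbM[i + 1, j + 1]; i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      ops <- c(2L, ops); prev <- tbX[i + 1, j + 1]; i <- i - 1
    } else {
      ops <- c(3L, ops); prev <- tbY[i + 1, j + 1]; j <- j - 1
    }
    if (i == 0 && j == 0) break
    if (prev == 0L) prev <- if (i == 0) 3L else if (j == 0) 2L else 1L
    state <- prev
  }
  ma <- seq_chars(rows_a); mb <- seq_chars(rows_b)
  W <- length(ops)
  out <- matrix("-", length(rows_a) + length(rows_b), W)
  ia <- 0; jb <- 0
  for (k in seq_len(W)) {
    if (ops[k] != 3L) { ia <- ia + 1; out[seq_along(rows_a), k] <- ma[, ia] }
    if (ops[k] != 2L) { jb <- jb + 1
      out[length(rows_a) + seq_along(rows_b), k] <- mb[, jb] }
  }
  rownames(out) <- c(names(rows_a), names(rows_b))
  list(rows = chars_to_seq(out), score = score)
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman--Wunsch/Gotoh global alignment of two ungapped sequences under
#' a substitution matrix (default BLOSUM62) with gap cost
#' `open + extend * length`.
#'
#' @param a,b sequence strings.
#' @param open,extend affine gap parameters (positive penalties).
#' @param smat substitution matrix over the 20 amino acids.
#' @return List with `rows` (the two aligned strings, named as the inputs
#'   or `a`/`b`) and `score`.
#' @export
pairwise_global <- function(a, b, open = 10, extend = 1,
                            smat = blosum62_matrix()) {
  rows_a <- stats::setNames(a, if (is.null(names(a))) "a" else names(a))
  rows_b <- stats::setNames(b, if (is.null(names(b))) "b" else names(b))
  align_profiles(rows_a, rows_b, open = open, extend = extend, smat = smat)
}

#' Progressive multiple sequence alignment
#'
#' Deterministic progressive alignment: P distances are computed from
#' pairwise global alignments ([Biostrings::pairwiseAlignment()], BLOSUM62,
#' affine gaps), an NJ guide determines the agglomeration order (ties broken
#' lexicographically by taxon name), and profiles are merged by
#' profile-profile Gotoh alignment with average-of-pairs column scores.
#'
#' @param seqs named character vector of ungapped sequences (>= 1).
#' @param open,extend affine gap parameters.
#' @return Named character vector of aligned rows (input order preserved).
#' @export
progressive_align <- function(seqs, open = 10, extend = 1) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names")
  if (length(seqs) == 1L) return(seqs)
  if (length(seqs) == 2L) {
    o <- order(names(seqs))
    return(align_profiles(seqs[o[1]], seqs[o[2]], open,
                          extend)$rows[names(seqs)])
  }
  d <- guide_p_distances(seqs, open, extend)
  joins <- nj_engine(d)$joins
  profiles <- lapply(names(seqs), function(nm) seqs[nm])
  names(profiles) <- names(seqs)
  key <- function(p) min(names(p))
  for (jn in joins) {
    ka <- vapply(profiles, function(p) jn[1] %in% names(p), logical(1))
    kb <- vapply(profiles, function(p) jn[2] %in% names(p), logical(1))
    ia <- which(ka); ib <- which(kb)
    if (length(ia) != 1 || length(ib) != 1 || ia == ib) next
    # canonical orientation so the result is invariant to input order
    if (min(names(profiles[[ib]])) < min(names(profiles[[ia]]))) {
      tmp <- ia; ia <- ib; ib <- tmp
    }
    merged <- align_profiles(profiles[[ia]], profiles[[ib]], open, extend)$rows
    profiles[[ia]] <- merged
    profiles <- profiles[-ib]
  }
  while (length(profiles) > 1) {  # safety: complete any remaining merges
    profiles[[1]] <- align_profiles(profiles[[1]], profiles[[2]],
                                    open, extend)$rows
    profiles <- profiles[-2]
  }
  profiles[[1]][names(seqs)]
}

# P distances from Biostrings pairwise global alignments
guide_p_distances <- function(seqs, open = 10, extend = 1) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pa <- Biostrings::pairwiseAlignment(
      seqs[[i]], seqs[[j]], type = "global",
      substitutionMatrix = env$BLOSUM62,
      gapOpening = open, gapExtension = extend, scoreOnly = FALSE)
    ai <- as.character(Biostrings::alignedPattern(pa))
    aj <- as.character(Biostrings::alignedSubject(pa))
    d[i, j] <- d[j, i] <- tryCatch(p_distance(ai, aj), error = function(e) 1)
  }
  d
}
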