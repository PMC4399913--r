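#' Uncorrected P distance between two aligned sequences
#'
#' Proportion of mismatching residues over comparable sites, using strict
#' pairwise deletion: only columns where both sequences carry one of the 20
#' standard amino acids are compared (gaps and ambiguity codes are skipped).
#'
#' @param a,b aligned sequence strings of equal length.
#' @return Mismatch proportion in `[0, 1]`.
#' @examples
#' p_distance("AAAA", "AAAT")
#' @export
p_distance <- function(a, b) {
  cmp <- comparable_sites(a, b)
  if (cmp$n == 0) stop("no comparable (gap-free) sites; P distance undefined")
  sum(cmp$ia != cmp$ib) / cmp$n
}

comparable_sites <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length")
  ia <- aa_index(strsplit(a, "")[[1]])
  ib <- aa_index(strsplit(b, "")[[1]])
  keep <- !is.na(ia) & !is.na(ib)
  list(ia = ia[keep], ib = ib[keep], n = sum(keep))
}

#' Maximum-likelihood distance under a reversible amino-acid model
#'
#' Finds the branch length `t` maximising the likelihood
#' `sum(log(pi[a] * P[a,b](t)))` over pairwise-deletion sites, by bounded
#' 1-D optimisation (Brent) on `[0, cap]`. Pairs so dissimilar that the
#' likelihood is still increasing at the bound are reported as saturated:
#' the distance is capped with a warning.
#'
#' @param a,b aligned sequence strings.
#' @param model a [subst_model()]; default JTT.
#' @param cap saturation cap for the distance (default 10).
#' @param tol optimisation tolerance (default 1e-6).
#' @return Estimated distance in expected substitutions per site.
#' @export
ml_distance <- function(a, b, model = jtt_model(), cap = 10, tol = 1e-6) {
  cmp <- comparable_sites(a, b)
  if (cmp$n == 0) stop("no comparable (gap-free) sites; ML distance undefined")
  if (all(cmp$ia == cmp$ib)) return(0)
  # sufficient statistic: 20x20 pair count matrix
  N <- matrix(0, 20, 20)
  tab <- table(cmp$ia, cmp$ib)
  N[cbind(as.integer(rownames(tab))[row(tab)],
          as.integer(colnames(tab))[col(tab)])] <- as.vector(tab)
  ll <- function(t) {
    P <- transition_matrix(model, t)
    sum(N * log(pmax(P, 1e-300)))
  }
  opt <- stats::optimize(ll, c(0, cap), maximum = TRUE, tol = tol)
  t_hat <- opt$maximum
  if (t_hat > cap - 1e-3 && ll(cap) >= ll(t_hat) - 1e-9) {
    warning("saturated pair: ML distance capped at ", cap)
    return(cap)
  }
  t_hat
}

#' BLOSUM62 score-based distance
#'
#' `1 - S(a,b) / min(S(a,a), S(b,b))` where `S` is the summed BLOSUM62 score
#' over pairwise-deletion comparable columns; clamped to be non-negative.
#'
#' @param a,b aligned sequence strings.
#' @return Non-negative distance (0 for identical sequences).
#' @export
blosum62_distance <- function(a, b) {
  cmp <- comparable_sites(a, b)
  if (cmp$n == 0) stop("no comparable (gap-free) sites")
  B <- blosum62_matrix()
  sab <- sum(B[cbind(cmp$ia, cmp$ib)])
  saa <- sum(B[cbind(cmp$ia, cmp$ia)])
  sbb <- sum(B[cbind(cmp$ib, cmp$ib)])
  max(0, 1 - sab / min(saa, sbb))
}

# BLOSUM62 restricted to the 20 standard states, indexed like AA_STATES
blosum62_matrix <- function() {
  cached <- .gpcrnet_env$blosum62
  if (!is.null(cached)) return(cached)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  B <- env$BLOSUM62[AA_STATES, AA_STATES]
  .gpcrnet_env$blosum62 <- B
  B
}

#' Pairwise distance matrix from an alignment
#'
#' @param aln named character vector of aligned sequences.
#' @param method `"p"`, `"ml"` or `"blosum62"`.
#' @param model substitution model for `method = "ml"`.
#' @param ... passed to the per-pair distance function.
#' @return Symmetric matrix with zero diagonal, taxa as dimnames.
#' @export
dist_matrix <- function(aln, method = c("p", "ml", "blosum62"),
                        model = jtt_model(), ...) {
  aln <- check_alignment(aln)
  method <- match.arg(method)
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- switch(method,
      p = p_distance(aln[[i]], aln[[j]]),
      ml = ml_distance(aln[[i]], aln[[j]], model = model, ...),
      blosum62 = blosum62_distance(aln[[i]], aln[[j]]))
  }
  stopifnot(max(abs(d - t(d))) == 0, all(diag(d) == 0))
  d
}

#' Write a distance matrix as square TSV with a taxa header row
#' @param d distance matrix. @param path output file.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(d, path) {
  d <- check_dist(d)
  utils::write.table(format(d, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a distance matrix written by [write_dist_tsv()]
#' @param path TSV file.
#' @return Distance matrix.
#' @export
read_dist_tsv <- function(path) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  check_dist(as.matrix(tab))
}
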