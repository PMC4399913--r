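#' Amino-acid substitution model under the JTT rate matrix
#'
#' Constructs the Jones--Taylor--Thornton (JTT) empirical amino-acid
#' replacement model from the exchangeabilities and equilibrium frequencies
#' packaged with `gpcrnet` (the published values distributed with standard
#' phylogenetics software). The instantaneous rate matrix `Q` is
#' `Q[i,j] = R[i,j] * pi[j]` with rows summing to zero, normalised so the
#' expected number of substitutions per site per unit time equals one, i.e.
#' `-sum(pi * diag(Q)) == 1`. Branch lengths are therefore in expected
#' substitutions per site.
#'
#' The model is time-reversible, so `P(t) = exp(Q t)` is computed through the
#' symmetric similarity transform `diag(sqrt(pi)) %*% Q %*% diag(1/sqrt(pi))`,
#' whose eigendecomposition is cached in the returned object.
#'
#' @return An object of class `subst_model`: a list with elements
#'   `states` (20 amino acids), `R` (symmetric exchangeability matrix),
#'   `pi` (equilibrium frequencies, summing to 1), `Q` (normalised rate
#'   matrix) and the cached eigensystem used by [transition_matrix()].
#' @examples
#' m <- jtt_model()
#' sum(m$pi)
#' range(rowSums(m$Q))
#' @export
jtt_model <- function() {
  cached <- .gpcrnet_env$jtt
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "jtt_model.tsv", package = "gpcrnet",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  R <- as.matrix(tab[AA_STATES, AA_STATES])
  pi <- tab[AA_STATES, "pi"]
  names(pi) <- AA_STATES
  m <- subst_model(R, pi, name = "JTT")
  .gpcrnet_env$jtt <- m
  m
}

#' Build a normalised reversible substitution model
#'
#' @param R symmetric 20x20 exchangeability matrix (zero diagonal).
#' @param pi equilibrium frequencies; normalised to sum to one.
#' @param name model label.
#' @return A `subst_model` object; see [jtt_model()].
#' @export
subst_model <- function(R, pi, name = "custom") {
  stopifnot(is.matrix(R), nrow(R) == 20, ncol(R) == 20,
            length(pi) == 20, all(pi > 0))
  if (max(abs(R - t(R))) > 1e-10) stop("exchangeability matrix must be symmetric")
  pi <- pi / sum(pi)
  Q <- R %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))     # expected substitutions per unit time
  Q <- Q / mu
  dimnames(Q) <- list(AA_STATES, AA_STATES)
  # symmetric form B = Pi^{1/2} Q Pi^{-1/2}; exact symmetry by averaging
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  structure(list(states = AA_STATES, R = R, pi = pi, Q = Q, name = name,
                 eig_values = e$values,
                 U = diag(1 / sp) %*% e$vectors,     # right transform
                 Uinv = t(e$vectors) %*% diag(sp)),  # left transform
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("substitution model %s (20 states, 1 expected subst/site/unit)\n",
              x$name))
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [subst_model()].
#' @param t branch length in expected substitutions per site; `t >= 0`.
#' @return Row-stochastic 20x20 matrix of transition probabilities.
#' @examples
#' P <- transition_matrix(jtt_model(), 0.5)
#' rowSums(P)
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "subst_model"), is.numeric(t), length(t) == 1L)
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0")
  P <- model$U %*% (exp(model$eig_values * t) * model$Uinv)
  # numerical cleanup: clamp tiny negatives, renormalise rows
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(model$states, model$states)
  P
}
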