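# internal helpers shared across modules

#' @keywords internal
"_PACKAGE"

# The 20 canonical amino-acid one-letter codes, in the order used by the
# packaged substitution-model tables.
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Split sequence strings into a character matrix (rows = taxa).
seq_chars <- function(x) {
  stopifnot(is.character(x))
  n <- nchar(x)
  if (length(unique(n)) > 1L)
    stop("sequences differ in length")
  m <- matrix("", length(x), n[1])
  for (i in seq_along(x)) m[i, ] <- strsplit(x[[i]], "")[[1]]
  rownames(m) <- names(x)
  m
}

chars_to_seq <- function(m) {
  out <- apply(m, 1L, paste0, collapse = "")
  names(out) <- rownames(m)
  out
}

# Indices 1..20 for amino acids, NA for gaps/ambiguity codes.
aa_index <- function(chars) {
  match(toupper(chars), AA_STATES)
}

is_square_dist <- function(d) {
  is.matrix(d) && nrow(d) == ncol(d) &&
    !is.null(rownames(d)) && identical(rownames(d), colnames(d)) &&
    all(is.finite(d)) && max(abs(d - t(d))) < 1e-8 && all(diag(d) == 0) &&
    all(d >= 0)
}

check_dist <- function(d) {
  d <- as.matrix(d)
  if (!is_square_dist(d))
    stop("expected a symmetric non-negative distance matrix with zero ",
         "diagonal and matching row/column names")
  d
}
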