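#' @keywords internal
"_PACKAGE"

# Rank ladder used throughout; collapse targets exclude kingdom.
TAXONOMY_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                    "genus", "species")

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so stochastic helpers do not
#' perturb the global random stream. A `NULL` seed leaves the stream alone.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

#' All permutations of 1..n
#'
#' Plain recursive enumeration, used for exhaustive permutation inference on
#' small samples. Size is guarded because n! grows fast.
#'
#' @param n number of elements (n! must be at most 50,000).
#' @return matrix with n! rows, each a permutation of `seq_len(n)`.
#' @keywords internal
all_permutations <- function(n) {
  if (factorial(n) > 50000) stop("refusing to enumerate ", n, "! permutations")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

# Distinct rearrangements of a label vector (multinomial coefficient).
n_label_arrangements <- function(labels) {
  tab <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'", name, "' must be a single probability in [0, 1]")
}
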