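## Small shared helpers.

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Circular rank correlation between two angular variables
#'
#' Fisher-Lee circular correlation applied to the circular ranks of the
#' two inputs (each mapped to `2 * pi * rank / n`). Invariant to rotations
#' of either variable; a reflection flips the sign, so the absolute value
#' is the natural measure of circular ordering agreement (e.g. between
#' embedding angle and preferred stimulus direction on a ring).
#'
#' @param a,b Numeric vectors of angles (radians; any values - only ranks
#'   are used).
#' @param rank Use circular ranks (default) or the raw angles.
#' @return Correlation in `[-1, 1]`.
#' @export
circular_rank_correlation <- function(a, b, rank = TRUE) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (rank) {
    a <- 2 * pi * base::rank(a, ties.method = "average") / n
    b <- 2 * pi * base::rank(b, ties.method = "average") / n
  }
  da <- outer(a, a, `-`); db <- outer(b, b, `-`)
  num <- sum(sin(da) * sin(db))
  den <- sqrt(sum(sin(da)^2) * sum(sin(db)^2))
  if (den == 0) return(0)
  num / den
}
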