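## Idealized winner-take-all oracle.
##
## The exact, noiseless argmax transformation that the circuit is meant to
## approximate: the option with the largest norm drives the output, every
## other option is set to exactly 0. Used throughout as ground truth when
## scoring circuit behaviour.

#' Idealized winner-take-all transformation
#'
#' Applies the hard winner-take-all operation to a vector of option norms:
#' `y[i] = f(x[i])` for the option(s) with the maximal norm and `y[i] = 0`
#' otherwise. Ties are reported as a tie set rather than silently broken.
#'
#' @param norms numeric vector of option norms (finite), one per option.
#' @param f monotone non-decreasing output map applied to the winning norm;
#'   defaults to the identity, which is all the winner-selection logic needs.
#' @return an object of class `wta_result`: a list with elements
#'   \describe{
#'     \item{winner}{index of the unique winner, or `NA_integer_` on a tie.}
#'     \item{tie_set}{integer vector of all argmax indices (length 1 when the
#'       winner is unique).}
#'     \item{x_star}{the winning norm `max(norms)`.}
#'     \item{y}{output vector: `f(x)` at the winner(s), 0 elsewhere.}
#'     \item{flexible_boundary}{`max(norms)`: the category boundary that
#'       exactly the winner's norm meets.}
#'   }
#' @examples
#' ideal_wta(c(10, 2))$x_star    # 10
#' ideal_wta(c(20, 13))$winner   # 1
#' ideal_wta(c(5, 5))$tie_set    # 1 2
#' @export
ideal_wta <- function(norms, f = identity) {
  if (length(norms) < 1L) stop("`norms` must contain at least one option")
  norms <- as.numeric(norms)
  if (!all(is.finite(norms))) stop("`norms` must be finite")
  stopifnot(is.function(f))
  x_star <- max(norms)
  tie_set <- which(norms == x_star)
  y <- numeric(length(norms))
  y[tie_set] <- vapply(norms[tie_set], f, numeric(1))
  structure(
    list(
      winner = if (length(tie_set) == 1L) tie_set else NA_integer_,
      tie_set = tie_set,
      x_star = x_star,
      y = y,
      flexible_boundary = x_star
    ),
    class = "wta_result"
  )
}

#' @export
print.wta_result <- function(x, ...) {
  if (is.na(x$winner)) {
    cat("Idealized WTA: tie among options {",
        paste(x$tie_set, collapse = ", "), "}\n", sep = "")
  } else {
    cat("Idealized WTA: winner = option ", x$winner,
        " (x* = ", format(x$x_star), ")\n", sep = "")
  }
  invisible(x)
}

#' Flexible category boundary for a set of option norms
#'
#' The selection boundary that a flexible circuit must realize is not fixed:
#' it equals the largest norm currently on offer, so that exactly the winner
#' meets it. For norms (9, 5) the boundary is 9; for (20, 13) it is 20.
#'
#' @param norms numeric vector of at least two option norms.
#' @return the boundary value `max(norms)`.
#' @export
flexible_boundary <- function(norms) {
  if (length(norms) < 2L) {
    stop("a selection boundary needs at least two competing options")
  }
  ideal_wta(norms)$flexible_boundary
}

#' Discriminability (d') between two noisy response distributions
#'
#' `d' = |mean_a - mean_b| / sqrt((sd_a^2 + sd_b^2) / 2)`: the difference in
#' response means normalized by the root of the average response variance.
#' Uniform gain applied to both means and sds leaves d' unchanged, which is
#' why differential (not uniform) amplification is needed for categorical
#' selection boundaries.
#'
#' @param mean_a,mean_b response means (spikes/s).
#' @param sd_a,sd_b response standard deviations (non-negative; not both 0).
#' @return the scalar d'.
#' @examples
#' discriminability(10, 0.8, 8, 0.6)  # 2 / sqrt(0.5)
#' @export
discriminability <- function(mean_a, sd_a, mean_b, sd_b) {
  stopifnot(sd_a >= 0, sd_b >= 0)
  if (sd_a == 0 && sd_b == 0) {
    stop("d' is undefined when both response distributions have zero variance")
  }
  abs(mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)
}
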