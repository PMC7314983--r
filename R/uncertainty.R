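# The weight-dependent uncertainty of each disease's similarity.
#
# A disease's similarity to AD is treated as the mean of a normal
# distribution whose variance reflects how much of the disease's protein
# complement is still unknown: the mean probability mass sitting on the
# proteins NOT yet annotated to the disease drives a binomial-type standard
# error.  Diseases with many known proteins therefore get a smaller
# variance (their similarity is more dependable) than diseases with few.

#' Mean weight of a disease's unknown proteins
#'
#' For a disease with one-hot membership row `p_row`, returns
#' \eqn{\bar X = \sum_j w_j (1 - p_j) / N}: the total weight carried by
#' proteins not annotated to the disease, averaged over the full universe
#' size \eqn{N}.
#'
#' @param w Numeric weight vector (entries >= 0).
#' @param p_row Binary membership row of the same length.
#' @param n Universe size; defaults to `length(w)` and must match it.
#' @return A single number in \[0, 1\].
#' @export
unknown_mean <- function(w, p_row, n = length(w)) {
  if (length(w) != length(p_row) || length(w) != n) {
    abort("w, p_row and n must agree in length")
  }
  if (any(w < 0)) {
    abort("Weights must be nonnegative")
  }
  sum(w * (1 - p_row)) / n
}

#' Variance of one disease's similarity distribution
#'
#' The binomial-type standard error of the similarity mean:
#' \eqn{\sigma^2 = \bar X (1 - \bar X) / N}, where \eqn{\bar X} is
#' [unknown_mean()].  The more of the universe's weight is already pinned
#' to the disease's known proteins, the smaller \eqn{\bar X} and the
#' smaller the variance.
#'
#' @inheritParams unknown_mean
#' @return A single number in \[0, 0.25 / N\].
#' @export
similarity_variance <- function(w, p_row, n = length(w)) {
  xbar <- unknown_mean(w, p_row, n)
  xbar * (1 - xbar) / n
}

#' Variances of all disease similarity distributions
#'
#' Vectorized [similarity_variance()] over the rows of a membership
#' matrix.  Returns the raw variances; the optimizer and the loss floor
#' them at 1e-12 before dividing by \eqn{\sigma}.
#'
#' @param w Numeric weight vector of length `ncol(membership)`.
#' @param membership Binary disease-by-protein matrix.
#' @return Numeric vector of per-disease variances.
#' @export
all_variances <- function(w, membership) {
  if (length(w) != ncol(membership)) {
    abort("length(w) must equal ncol(membership)")
  }
  if (any(w < 0)) {
    abort("Weights must be nonnegative")
  }
  n <- ncol(membership)
  known_mass <- as.vector(membership %*% w)
  xbar <- (sum(w) - known_mass) / n
  xbar * (1 - xbar) / n
}
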