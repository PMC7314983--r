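# The loss that the iteration minimizes.
#
# Each disease's similarity is standardized against its current
# distribution, Y' = (Y - mu_i) / sigma_i, and the loss is the sum over
# diseases of the integral of Y' from 0 to the model's predicted
# similarity.  The integrand is affine in Y, so the integral has the
# closed form (Yhat^2 / 2 - mu Yhat) / sigma; each term is minimized at
# Yhat = mu with value -mu^2 / (2 sigma), so minimizing the (signed) loss
# drives every predicted similarity toward its observed mean, weighted by
# the current credibility 1 / sigma.

#' Predicted similarity of one disease
#'
#' The model maps protein weights to a disease's similarity as the total
#' weight of the disease's member proteins:
#' \eqn{\hat Y_i = \sum_j w_j p_{ij}}.
#'
#' @param w Numeric weight vector.
#' @param p_row Binary membership row of the same length.
#' @return A single number.
#' @export
predict_similarity <- function(w, p_row) {
  if (length(w) != length(p_row)) {
    abort("w and p_row must agree in length")
  }
  sum(w * p_row)
}

#' One disease's loss term in closed form
#'
#' Evaluates \eqn{\int_0^{\hat Y} (Y - \mu)/\sigma \, dY =
#' (\hat Y^2 / 2 - \mu \hat Y)/\sigma}.  Vectorized over its arguments.
#'
#' @param y_hat Predicted similarity (or vector thereof).
#' @param mu Observed similarity mean(s).
#' @param sigma Standard deviation(s); must be strictly positive.
#' @return Numeric loss term(s); can be negative, with per-term minimum
#'   \eqn{-\mu^2/(2\sigma)} attained at \eqn{\hat Y = \mu}.
#' @export
loss_term <- function(y_hat, mu, sigma) {
  if (any(sigma <= 0)) {
    abort("sigma must be strictly positive")
  }
  (y_hat^2 / 2 - mu * y_hat) / sigma
}

#' Total loss of a weight vector
#'
#' Sums [loss_term()] over all diseases, including the AD row itself.
#' Variances are recomputed from `w` (the objective changes whenever the
#' weights change) and floored at 1e-12 before taking square roots.
#'
#' @param w Numeric weight vector over the protein universe.
#' @param table A [disease_table()] providing the similarity means.
#' @param membership Binary disease-by-protein matrix aligned with `table`.
#' @return A single number.
#' @export
total_loss <- function(w, table, membership) {
  stopifnot(nrow(table) == nrow(membership))
  y_hat <- as.vector(membership %*% w)
  sigma <- sqrt(pmax(all_variances(w, membership), .SIGMA2_FLOOR))
  sum(loss_term(y_hat, table$similarity, sigma))
}

#' Trapezoid-rule check of the loss integral
#'
#' Numerically integrates \eqn{(Y - \mu)/\sigma} from 0 to `y_hat` with
#' `n_grid` trapezoid panels.  The integrand is affine, so the trapezoid
#' rule is exact for any `n_grid >= 1`; the function exists as an
#' independent check of the closed form used in the hot path.
#'
#' @inheritParams loss_term
#' @param n_grid Number of trapezoid panels (>= 1).
#' @return Numeric estimate of the integral.
#' @export
loss_numeric_oracle <- function(y_hat, mu, sigma, n_grid = 128L) {
  stopifnot(length(y_hat) == 1, n_grid >= 1)
  if (sigma <= 0) {
    abort("sigma must be strictly positive")
  }
  if (y_hat == 0) {
    return(0)
  }
  grid <- seq(0, y_hat, length.out = n_grid + 1L)
  vals <- (grid - mu) / sigma
  h <- y_hat / n_grid
  h * (sum(vals) - (vals[1] + vals[n_grid + 1L]) / 2)
}
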