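# Least-angle regression (LAR), used as the sparse "minimum angle
# regression" selector.  The classical algorithm: repeatedly admit the
# predictor most correlated with the current residual and move the
# coefficient vector along the equiangular direction of the active set
# until another predictor ties.  Only the identity of the active set (and
# rough coefficient sizes) matters to the caller, so the implementation is
# a plain dense-algebra version with two pragmatic safeguards for one-hot
# designs: columns are scaled to unit norm (no centering — the model has
# no intercept) and rank-deficient equiangular systems fall back to a
# pseudoinverse.

#' Least-angle regression coefficients
#'
#' Fits a no-intercept least-angle regression path of `y` on `x` and
#' returns the coefficients after at most `max_active` variables have
#' entered.  Exactly the variables admitted to the active set have nonzero
#' coefficients, which is what makes the fit usable as a hard variable
#' selector.
#'
#' @param x Numeric predictor matrix (observations by variables).
#' @param y Numeric response vector.
#' @param max_active Maximum size of the active set; capped at
#'   `min(nrow(x) - 1, ncol(x))`.
#' @return Numeric coefficient vector of length `ncol(x)`.
#' @export
least_angle_regression <- function(x, y, max_active = nrow(x) - 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  n <- nrow(x)
  p <- ncol(x)
  max_active <- min(max_active, n - 1L, p)
  beta <- numeric(p)
  if (max_active < 1L || p == 0L) {
    return(beta)
  }

  norms <- sqrt(colSums(x^2))
  usable <- norms > 1e-12
  if (!any(usable)) {
    return(beta)
  }
  xs <- x
  xs[, usable] <- sweep(x[, usable, drop = FALSE], 2, norms[usable], "/")

  active <- integer(0)
  inactive <- which(usable)
  resid <- as.numeric(y)
  eps <- 1e-10

  solve_or_pinv <- function(a, b) {
    out <- tryCatch(solve(a, b), error = function(e) NULL)
    if (is.null(out) || any(!is.finite(out))) {
      sv <- svd(a)
      pos <- sv$d > max(sv$d[1], 1) * 1e-10
      out <- sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
    }
    drop(out)
  }

  while (length(active) < max_active && length(inactive) > 0) {
    corr <- drop(crossprod(xs, resid))
    j <- inactive[which.max(abs(corr[inactive]))]
    if (abs(corr[j]) < eps) {
      break
    }
    active <- c(active, j)
    inactive <- setdiff(inactive, j)

    s <- sign(corr[active])
    xa <- sweep(xs[, active, drop = FALSE], 2, s, "*")
    g <- crossprod(xa)
    ga1 <- solve_or_pinv(g, rep(1, length(active)))
    denom <- sum(ga1)
    if (!is.finite(denom) || denom <= eps) {
      break
    }
    aa <- 1 / sqrt(denom)
    wa <- aa * ga1
    u <- drop(xa %*% wa)             # unit equiangular vector
    a_corr <- drop(crossprod(xs, u))
    cmax <- max(abs(corr[active]))

    if (length(inactive) == 0 || length(active) == max_active) {
      gamma <- cmax / aa             # full least-squares step on the active set
    } else {
      cand <- c((cmax - corr[inactive]) / (aa - a_corr[inactive]),
                (cmax + corr[inactive]) / (aa + a_corr[inactive]))
      cand <- cand[is.finite(cand) & cand > eps]
      gamma <- if (length(cand) > 0) min(cand, cmax / aa) else cmax / aa
    }

    beta[active] <- beta[active] + gamma * wa * s
    resid <- resid - gamma * u
  }

  beta[usable] <- beta[usable] / norms[usable]   # back to original scale
  beta
}
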