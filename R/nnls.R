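#' Non-negative least squares by the Lawson-Hanson active-set method
#'
#' Solves `min ||A x - y||_2` subject to `x >= 0` exactly (to numerical
#' precision) with the classical active-set algorithm. Deterministic: the same
#' inputs always give the same solution, which is why it is used for the
#' voxel-wise compartment fit rather than an iterative approximate solver.
#'
#' @param A design matrix (m x p).
#' @param y response vector (length m), finite.
#' @param tol dual-feasibility tolerance.
#' @return List with `coef` (length p, >= 0), `residual` (attained 2-norm of
#'   `A coef - y`) and `iterations`.
#' @export
nnls_fit <- function(A, y, tol = 1e-10) {
  A <- as.matrix(A)
  y <- as.numeric(y)
  if (nrow(A) != length(y)) stop("nrow(A) must equal length(y)")
  if (any(!is.finite(A)) || any(!is.finite(y))) stop("non-finite inputs")
  p <- ncol(A)
  x <- numeric(p)
  passive <- rep(FALSE, p)
  w <- crossprod(A, y - A %*% x)  # gradient of -0.5 ||r||^2
  iter <- 0
  max_iter <- 3 * p + 30
  scale <- max(abs(w), 1)
  while (any(!passive) && any(w[!passive] > tol * scale) && iter < max_iter) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(p)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), y)
      s[passive][is.na(s[passive])] <- 0
      if (all(s[passive] > 0)) break
      # step back to the feasible boundary, drop variables hitting zero
      neg <- passive & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- crossprod(A, y - A %*% x)
  }
  list(coef = pmax(x, 0), residual = sqrt(sum((A %*% x - y)^2)),
       iterations = iter)
}

#' Vectorized exact NNLS for many right-hand sides
#'
#' Solves the non-negative least-squares problem for every row of `Y` against
#' one small design matrix by enumerating all supports: the NNLS optimum is
#' the minimum-residual candidate among the feasible unconstrained
#' least-squares solutions restricted to each subset of columns (at the
#' optimum the residual is orthogonal to the active columns, so the optimum
#' itself is such a candidate and no feasible candidate can beat it).
#' Exhaustive over `2^p` supports, so intended for small p (p = 3 here); all
#' voxels are solved with dense matrix algebra.
#'
#' @param A design matrix (m x p), full column rank, small p.
#' @param Y matrix of responses, one row per problem (n x m).
#' @return List with `coef` (n x p, >= 0) and `residual` (length n, 2-norms).
#' @export
nnls_batch <- function(A, Y) {
  A <- as.matrix(A)
  Y <- as.matrix(Y)
  if (ncol(Y) != nrow(A)) stop("ncol(Y) must equal nrow(A)")
  p <- ncol(A)
  if (p > 12) stop("support enumeration is exponential in ncol(A); use nnls_fit")
  n <- nrow(Y)
  best_coef <- matrix(0, n, p)
  best_rss <- rowSums(Y^2)              # empty support: x = 0
  for (code in seq_len(2^p - 1)) {
    S <- which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
    As <- A[, S, drop = FALSE]
    # pinv via QR; As has full column rank when A does
    pinv <- qr.solve(crossprod(As), t(As))
    Cs <- Y %*% t(pinv)                 # n x |S| candidate coefficients
    feas <- rowSums(Cs < -1e-12) == 0
    if (!any(feas)) next
    fitted <- Cs %*% t(As)
    rss <- rowSums((Y - fitted)^2)
    better <- feas & rss < best_rss - 1e-15
    if (any(better)) {
      best_rss[better] <- rss[better]
      best_coef[better, ] <- 0
      best_coef[better, S] <- pmax(Cs[better, , drop = FALSE], 0)
    }
  }
  list(coef = best_coef, residual = sqrt(pmax(best_rss, 0)))
}
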