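# Cubic regression spline basis with an exact curvature penalty.
#
# The basis is parameterized by the function's values at k knots, with
# natural (zero second derivative) end conditions.  Writing the second
# derivatives at the knots as delta = B^-1 D beta, the integrated squared
# second derivative is exactly beta' S beta with S = D' B^-1 D, whose null
# space is the linear functions.  This construction supports any k >= 3 and
# places knots at quantiles of the training covariate.

crs_check_knots <- function(knots) {
  if (length(knots) < 3) stop_params("need at least 3 knots, got %d", length(knots))
  if (any(diff(knots) <= 0)) stop_params("knots must be strictly increasing")
  knots
}

# Quantile-based knot placement over the unique covariate values.
crs_knots <- function(x, basis_dim) {
  ux <- sort(unique(x[is.finite(x)]))
  if (length(ux) < basis_dim) {
    stop_params("covariate has %d unique values; cannot place %d knots",
                length(ux), basis_dim)
  }
  k <- as.numeric(stats::quantile(ux, probs = seq(0, 1, length.out = basis_dim),
                                  type = 7, names = FALSE))
  if (any(diff(k) <= 0)) {
    k <- seq(min(ux), max(ux), length.out = basis_dim)
  }
  k
}

# D ((k-2) x k) and B ((k-2) x (k-2)) of the natural-spline construction.
crs_DB <- function(knots) {
  k <- length(knots)
  h <- diff(knots)
  D <- matrix(0, k - 2, k)
  B <- matrix(0, k - 2, k - 2)
  for (i in seq_len(k - 2)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
    B[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < k - 2) B[i, i + 1] <- B[i + 1, i] <- h[i + 1] / 6
  }
  list(D = D, B = B)
}

# Curvature penalty S = D' B^-1 D (exact integral of squared second
# derivative); annihilates constants and linears.
crs_penalty <- function(knots) {
  crs_check_knots(knots)
  db <- crs_DB(knots)
  S <- t(db$D) %*% solve(db$B, db$D)
  (S + t(S)) / 2
}

# Evaluate the k basis functions (value-at-knot parameterization) at x.
# Values outside the knot span are clamped to the boundary when clamp=TRUE,
# otherwise the spline is continued linearly (natural end conditions).
crs_design <- function(x, knots, clamp = TRUE) {
  crs_check_knots(knots)
  k <- length(knots)
  h <- diff(knots)
  if (clamp) x <- pmin(pmax(x, knots[1]), knots[k])
  db <- crs_DB(knots)
  Fm <- rbind(0, solve(db$B, db$D), 0)  # k x k: beta -> second derivs at knots
  j <- findInterval(x, knots, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), k - 1L)
  hj <- h[j]
  xl <- knots[j]; xr <- knots[j + 1]
  am <- (xr - x) / hj
  ap <- (x - xl) / hj
  cm <- ((xr - x)^3 / hj - hj * (xr - x)) / 6
  cp <- ((x - xl)^3 / hj - hj * (x - xl)) / 6
  n <- length(x)
  A <- matrix(0, n, k)
  A[cbind(seq_len(n), j)] <- am
  A[cbind(seq_len(n), j + 1L)] <- ap
  A + cm * Fm[j, , drop = FALSE] + cp * Fm[j + 1L, , drop = FALSE]
}

#' Build a penalized cubic regression spline basis
#'
#' Constructs a cubic regression spline basis of dimension `basis_dim` for a
#' covariate, with knots at quantiles of the training values (unless given),
#' an exact second-derivative (curvature) penalty whose null space is the
#' linear functions, and a sum-to-zero constraint absorbed by
#' reparameterization so the smooth is identifiable alongside an intercept:
#' the returned design has `basis_dim - 1` columns, each summing to zero over
#' the training values. Evaluation outside the training span clamps the
#' covariate to the span.
#'
#' @param x_values training covariate values.
#' @param basis_dim basis dimension k (>= 3; default 5, i.e. at most five
#'   smoothing terms per parameter).
#' @param knots optional strictly increasing knot vector (length k).
#' @return Object of class `crs_basis`: `knots`, `Z` (k x (k-1) constraint
#'   null-space basis), `X` (constrained design at `x_values`), `S`
#'   (constrained penalty), `S_raw`, `range` (training span), `basis_dim`.
#' @export
build_spline_basis <- function(x_values, basis_dim = 5, knots = NULL) {
  if (basis_dim < 3) {
    stop_params("basis_dim must be >= 3 for a cubic regression spline, got %d",
                basis_dim)
  }
  if (is.null(knots)) knots <- crs_knots(x_values, basis_dim)
  crs_check_knots(knots)
  if (length(knots) != basis_dim) {
    stop_params("knots length (%d) must equal basis_dim (%d)",
                length(knots), basis_dim)
  }
  Xr <- crs_design(x_values, knots)
  S_raw <- crs_penalty(knots)
  cvec <- colSums(Xr)
  qr_c <- qr(matrix(cvec, ncol = 1))
  Z <- qr.Q(qr_c, complete = TRUE)[, -1, drop = FALSE]
  X <- Xr %*% Z
  S <- t(Z) %*% S_raw %*% Z
  S <- (S + t(S)) / 2
  structure(list(knots = knots, Z = Z, X = X, S = S, S_raw = S_raw,
                 range = range(x_values), basis_dim = basis_dim),
            class = "crs_basis")
}

# Evaluate a constrained basis at new covariate values (clamped to the
# training span); returns a matrix with attribute "clamped".
eval_spline_basis <- function(basis, x_new) {
  clamped <- x_new < basis$range[1] | x_new > basis$range[2]
  x_cl <- pmin(pmax(x_new, basis$range[1]), basis$range[2])
  Xn <- crs_design(x_cl, basis$knots) %*% basis$Z
  attr(Xn, "clamped") <- clamped
  Xn
}
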