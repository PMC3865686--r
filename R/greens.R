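#' Random-walk generating function on a finite graph (resolvent route)
#'
#' `G_ij(z) = sum_n p_ij^(n) z^n`, where `p_ij^(n)` is the probability that
#' an n-step random walk following the edge weights ends at `j`. On a finite
#' graph the series sums to entry `(i, j)` of `(I - z W)^{-1}`, which is how
#' this function evaluates it. Evaluated at `z = lambda/(1+lambda)` it gives
#' retention fractions ([phi0_gf()]); at `z = 1 - u` it gives
#' identity-by-descent probabilities ([ibd_probability()]).
#'
#' @param graph a `weighted_graph`.
#' @param i,j node ids (1-based).
#' @param z argument in `[0, 1)`; the series diverges at `z = 1` on finite
#'   graphs.
#' @return `G_ij(z)`.
#' @export
gf_resolvent <- function(graph, i, j, z) {
  if (z < 0 || z >= 1)
    stop("generating function requires 0 <= z < 1 on finite graphs")
  n <- graph$n
  e <- numeric(n)
  e[j] <- 1
  col <- Matrix::solve(Matrix::Diagonal(n) - z * graph$W, e)
  as.numeric(col[i])
}

#' Truncated power-series oracle for the generating function
#'
#' Computes the partial sum `sum_{m <= n_max} p_ij^(m) z^m` by repeated
#' vector-matrix products. Kept as an independent check on
#' [gf_resolvent()]; the resolvent is exact, the series is not.
#'
#' @inheritParams gf_resolvent
#' @param n_max truncation order, `>= 0`.
#' @return the partial sum.
#' @export
gf_series <- function(graph, i, j, z, n_max) {
  if (n_max < 0) stop("n_max must be >= 0")
  v <- numeric(graph$n)
  v[i] <- 1
  total <- if (i == j) 1 else 0       # n = 0 term
  zn <- 1
  for (m in seq_len(n_max)) {
    v <- as.numeric(v %*% graph$W)    # row vector advance: v_k = p_ik^(m)
    zn <- zn * z
    total <- total + v[j] * zn
  }
  total
}

#' Producer retention fraction via the generating function
#'
#' `phi0 = G_ii(lambda/(1+lambda)) / (1+lambda)`: the fraction of its own
#' public good a producer utilizes, expressed through the return-visit
#' generating function of the diffusion random walk. Agrees with the
#' stationary linear solve ([retention_fractions()]) on every finite graph.
#'
#' @param graph a `weighted_graph`.
#' @param lambda diffusion parameter, `>= 0`.
#' @param node node at which to evaluate (any node on a transitive graph).
#' @return `phi0`.
#' @export
phi0_gf <- function(graph, lambda, node = 1L) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (lambda == 0) return(1)
  gf_resolvent(graph, node, node, lambda / (1 + lambda)) / (1 + lambda)
}

#' Arithmetic-geometric mean
#'
#' Iterates `(a, b) -> ((a+b)/2, sqrt(ab))` to convergence (relative
#' tolerance 1e-14). Appears in the closed-form retention fraction of the
#' 2D square lattice.
#'
#' @param a,b positive reals.
#' @return `agm(a, b)`.
#' @export
agm <- function(a, b) {
  if (a <= 0 || b <= 0) stop("agm requires positive arguments")
  while (abs(a - b) > 1e-14 * a) {
    t <- (a + b) / 2
    b <- sqrt(a * b)
    a <- t
  }
  a
}

#' Closed-form producer retention fractions for standard graph families
#'
#' Infinite-population closed forms for the fraction `phi0` of public good
#' retained by its producer:
#' \describe{
#'   \item{complete}{`1/(1+lambda)` (well-mixed).}
#'   \item{lattice_1d}{`1/sqrt(1+2*lambda)`.}
#'   \item{square_2d}{`1/agm(1, 1+2*lambda)`.}
#'   \item{bethe}{degree-k Cayley tree,
#'     `(sqrt((k-2)^2 (1+lambda)^2 + 4 (k-1) (1+2*lambda)) - (k-2)(1+lambda)) / (2 (1+2*lambda))`.}
#' }
#' Every form equals 1 at `lambda = 0` and decreases in `lambda`. The Bethe
#' form is validated in the test suite against the root retention of
#' depth-truncated trees ([bethe_root_retention()]).
#'
#' @param family one of `"complete"`, `"lattice_1d"`, `"square_2d"`,
#'   `"bethe"`.
#' @param lambda diffusion parameter, `>= 0`.
#' @param k tree degree (Bethe family only), `>= 3`.
#' @return `phi0` in `(0, 1]`.
#' @export
phi0_closed_form <- function(family, lambda, k = NULL) {
  if (lambda < 0) stop("lambda must be >= 0")
  switch(match.arg(family, c("complete", "lattice_1d", "square_2d", "bethe")),
    complete   = 1 / (1 + lambda),
    lattice_1d = 1 / sqrt(1 + 2 * lambda),
    square_2d  = 1 / agm(1, 1 + 2 * lambda),
    bethe      = {
      if (is.null(k) || k < 3) stop("bethe family needs degree k >= 3")
      (sqrt((k - 2)^2 * (1 + lambda)^2 + 4 * (k - 1) * (1 + 2 * lambda)) -
         (k - 2) * (1 + lambda)) / (2 * (1 + 2 * lambda))
    })
}

#' Root retention on a depth-truncated Cayley tree
#'
#' Exact stationary solve for the fraction of public good a producer at the
#' root of a depth-truncated degree-`k` tree retains. By radial symmetry the
#' stationary field depends only on the level, so the full linear system
#' reduces to a tridiagonal system in `depth + 1` unknowns — exact at any
#' depth, including depths whose explicit trees would have millions of
#' nodes. Converges to the infinite Bethe-lattice closed form as depth
#' grows.
#'
#' @param k tree degree, `>= 3`.
#' @param depth truncation depth, `>= 1`.
#' @param lambda diffusion parameter, `>= 0`.
#' @return the root node's stationary concentration `phi0`.
#' @export
bethe_root_retention <- function(k, depth, lambda) {
  if (k < 3) stop("k must be >= 3")
  if (depth < 1) stop("depth must be >= 1")
  if (lambda == 0) return(1)
  m <- depth + 1
  A <- matrix(0, m, m)
  rhs <- c(1, numeric(depth))
  A[1, 1] <- 1 + lambda
  A[1, 2] <- -lambda                       # k children, weight 1/k each
  for (lv in 2:depth) {
    A[lv, lv] <- 1 + lambda
    A[lv, lv - 1] <- -lambda / k           # inflow from parent
    A[lv, lv + 1] <- -lambda * (k - 1) / k # inflow from k-1 children
  }
  A[m, m] <- 1 + lambda                    # leaf: parent inflow only
  A[m, m - 1] <- -lambda / k
  solve(A, rhs)[1]
}

#' Producer retention fraction by lattice Green's function integral
#'
#' For an infinite lattice with structure function `chi(y)`,
#' `phi0 = (2*pi)^{-n} \int_{[-pi,pi]^n} dy / (1 + lambda - lambda*chi(y))`.
#' The integrand is smooth and periodic (the denominator is at least 1), so
#' the tensor-product trapezoidal rule converges spectrally; the grid is
#' refined until successive estimates differ by less than `tol`.
#'
#' @param spec a `lattice_spec` with `dim <= 4`.
#' @param lambda diffusion parameter, `>= 0`.
#' @param tol absolute tolerance (default 1e-8).
#' @return `phi0`.
#' @export
phi0_lattice_integral <- function(spec, lambda, tol = 1e-8) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (spec$dim > 4) stop("quadrature supported for dim <= 4")
  if (lambda == 0) return(1)
  est <- function(m) {
    y1 <- seq(-pi, pi, length.out = m + 1)[-(m + 1)]  # periodic grid
    grid <- as.matrix(expand.grid(rep(list(y1), spec$dim)))
    chi <- structure_function(spec, grid)
    mean(1 / (1 + lambda - lambda * chi))
  }
  m <- c(16, 32, 64, 128, 256, 512, 1024)
  m <- m[m^spec$dim <= 2^21]
  prev <- est(m[1])
  for (mm in m[-1]) {
    cur <- est(mm)
    if (abs(cur - prev) < tol) return(cur)
    prev <- cur
  }
  stop(sprintf(
    "lattice quadrature did not reach tol %.1e (last refinement %.3e at m = %d)",
    tol, abs(cur - prev), mm))
}

#' Identity-by-descent probability between two cells
#'
#' With a small per-birth mutation probability `u`, two cells are identical
#' by descent if no mutation separates either from their most recent common
#' ancestor. Coalescing-random-walk theory gives
#' `q_ij = G_ij(1-u) / G_jj(1-u)` in terms of the walk generating function.
#'
#' @param graph a `weighted_graph`.
#' @param i,j node ids.
#' @param u mutation probability in `(0, 1]`; at `u = 0` both generating
#'   functions diverge on a finite graph and the ratio limit is not taken.
#' @return `q_ij` in `[0, 1]`, with `q_jj = 1`.
#' @export
ibd_probability <- function(graph, i, j, u) {
  if (u <= 0 || u > 1)
    stop("u must lie in (0, 1]; the series diverges at u = 0")
  z <- 1 - u
  gf_resolvent(graph, i, j, z) / gf_resolvent(graph, j, j, z)
}
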