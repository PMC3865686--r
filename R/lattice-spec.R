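#' Infinite-lattice specification by step vectors
#'
#' An infinite mathematical lattice is described by a finite set of step
#' vectors `v_1..v_k` in n-space with weights `w_1..w_k` summing to 1. The
#' step set must be closed under negation with matching weights so the
#' structure function is real.
#'
#' @param steps numeric matrix, one step vector per row.
#' @param weights numeric vector of step weights, `sum(weights) == 1`.
#' @return an object of class `lattice_spec` with `dim`, `steps`, `weights`.
#' @seealso [spec_square()], [spec_triangular()], [structure_function()],
#'   [phi0_lattice_integral()]
#' @export
lattice_spec <- function(steps, weights) {
  steps <- as.matrix(steps)
  if (nrow(steps) != length(weights)) stop("one weight per step vector")
  if (any(weights <= 0)) stop("weights must be positive")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  # negation closure: each (v, w) must have a partner (-v, w)
  key <- apply(round(steps, 12), 1, paste, collapse = ",")
  nkey <- apply(round(-steps, 12), 1, paste, collapse = ",")
  m <- match(nkey, key)
  if (any(is.na(m)) || any(abs(weights - weights[m]) > 1e-12))
    stop("step set not closed under negation with matching weights")
  structure(list(dim = ncol(steps), steps = steps, weights = weights),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec: dim %d, %d step vectors>\n", x$dim,
              nrow(x$steps)))
  invisible(x)
}

#' n-dimensional square lattice specification
#' @param dim spatial dimension.
#' @return a `lattice_spec` with steps `±e_i`, each weight `1/(2*dim)`.
#' @export
spec_square <- function(dim = 2) {
  lattice_spec(rbind(diag(1, dim), diag(-1, dim)), rep(1 / (2 * dim), 2 * dim))
}

#' Two-dimensional triangular lattice specification
#'
#' Steps `±(1,0)`, `±(0,1)`, `±(1,1)` with per-direction weights
#' `(a, b, c)`; uniform by default. Matches [graph_triangular()].
#'
#' @param profile per-direction weights `c(a, b, c)` with `2(a+b+c) = 1`.
#' @return a `lattice_spec`.
#' @export
spec_triangular <- function(profile = rep(1 / 6, 3)) {
  if (abs(2 * sum(profile) - 1) > 1e-12)
    stop("profile must satisfy 2(a+b+c) = 1")
  lattice_spec(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1), c(-1, -1)),
               rep(profile, each = 2))
}

#' Structure function of a lattice
#'
#' The Fourier transform of the step distribution,
#' `chi(y) = sum_k w_k exp(i v_k . y)`; real for negation-closed step sets.
#' For the n-dimensional square lattice this is `mean(cos(y_i))`; for the
#' uniform triangular lattice `(cos y1 + cos y2 + cos(y1+y2))/3`.
#'
#' @param spec a `lattice_spec`.
#' @param y numeric vector in n-space (or a matrix of row vectors).
#' @return `chi(y)`, a real value (or vector) in `[-1, 1]`.
#' @export
structure_function <- function(spec, y) {
  y <- if (is.matrix(y)) y else matrix(y, nrow = 1)
  if (ncol(y) != spec$dim) stop("y must have dimension ", spec$dim)
  phase <- y %*% t(spec$steps)            # rows: y points, cols: steps
  val <- exp(1i * phase) %*% spec$weights
  if (max(abs(Im(val))) > 1e-10)
    stop("structure function is complex: step set not negation-closed")
  drop(Re(val))
}
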