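#' Stationary public-goods field on a colony graph
#'
#' Cooperator cells (`state[i] == 1`) each produce one unit of public good
#' per unit utilization time. The good diffuses along edges at relative rate
#' `lambda`, decays at relative rate `decay`, and is utilized in place at
#' rate 1. At stationarity the per-cell concentrations `psi` solve
#'
#' \deqn{(1 + d + \lambda)\,\psi_i = s_i + \lambda \sum_j e_{ji} \psi_j,}
#'
#' a sparse symmetric linear system solved exactly. Alternatively a matrix
#' of arbitrary diffusion fractions `fractions[i, j]` (the share of cell
#' i's production utilized by cell j; rows sum to 1, same symmetry as the
#' graph) can replace the diffusion process entirely, in which case
#' `psi_i = sum_j state[j] * fractions[j, i]` and `lambda`/`decay` must not
#' be supplied.
#'
#' Without decay the total good is conserved: `sum(psi) == sum(state)`;
#' with decay, `sum(psi) == sum(state)/(1 + decay)`.
#'
#' @param graph a `weighted_graph`.
#' @param state integer/numeric vector of production indicators (0 =
#'   defector, 1 = cooperator), one per node.
#' @param lambda diffusion-to-utilization rate ratio, `>= 0`.
#' @param decay decay-to-utilization rate ratio `d >= 0`.
#' @param fractions optional `n x n` matrix of diffusion fractions,
#'   mutually exclusive with `lambda`/`decay`.
#' @return numeric vector `psi` of stationary concentrations (units:
#'   public good per utilization time).
#' @export
stationary_field <- function(graph, state, lambda = NULL, decay = 0,
                             fractions = NULL) {
  state <- check_state(graph, state)
  if (!is.null(fractions)) {
    if (!is.null(lambda) || decay != 0)
      stop("custom diffusion fractions replace the (lambda, decay) process; ",
           "supply one or the other, not both")
    check_fractions(graph, fractions)
    return(as.numeric(state %*% fractions))
  }
  if (is.null(lambda)) stop("supply lambda (or a fractions matrix)")
  check_params(lambda, decay)
  if (lambda == 0) return(state / (1 + decay))
  A <- (1 + decay + lambda) * Matrix::Diagonal(graph$n) -
    lambda * Matrix::t(graph$W)
  as.numeric(Matrix::solve(A, state))
}

check_state <- function(graph, state) {
  if (length(state) != graph$n)
    stop("state must have one entry per node (", graph$n, ")")
  if (!all(state %in% c(0, 1)))
    stop("state entries must be 0 (defector) or 1 (cooperator)")
  as.numeric(state)
}

check_params <- function(lambda, decay) {
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be finite and >= 0")
  if (!is.finite(decay) || decay < 0) stop("decay must be finite and >= 0")
  invisible(TRUE)
}

check_fractions <- function(graph, fractions) {
  if (!all(dim(fractions) == graph$n)) stop("fractions must be n x n")
  if (any(abs(rowSums(fractions) - 1) > 1e-10))
    stop("fraction rows must sum to 1")
  if (max(abs(fractions - t(fractions))) > 1e-10)
    stop("fractions must share the graph's symmetry (phi_ij = phi_ji)")
  invisible(TRUE)
}

#' Influence matrix of the stationary diffusion operator
#'
#' The stationary field is linear in the production state: `psi = M state`
#' with `M = ((1 + d + lambda) I - lambda W')^{-1}`. Column `k` of `M` is
#' the field created by a lone producer at node `k`, so flipping one cell's
#' type updates `psi` by adding or subtracting a single column — an O(n)
#' operation the Death-Birth simulation engine uses between reproductive
#' events.
#'
#' @inheritParams stationary_field
#' @return dense `n x n` matrix `M`. Errors above 3000 nodes (dense
#'   storage).
#' @export
influence_matrix <- function(graph, lambda, decay = 0) {
  check_params(lambda, decay)
  if (graph$n > 3000) stop("influence matrix is dense; n <= 3000 required")
  A <- (1 + decay + lambda) * diag(graph$n) -
    lambda * t(as.matrix(graph$W))
  solve(A)
}

#' Producer and neighbour retention fractions
#'
#' Places a single cooperator on a (vertex-transitive) graph and reads off
#' the two quantities that decide the fate of cooperation: `phi0`, the
#' fraction of its own good the producer utilizes, and `phi1`, the
#' edge-weighted average fraction utilized by each nearest neighbour.
#' Cooperation is favoured under Death-Birth updating iff
#' `b/c > 1/(phi0 + phi1)`. Without decay the identity
#' `(1 + lambda) phi0 = 1 + lambda phi1` holds on every graph.
#'
#' @inheritParams stationary_field
#' @param node producer node (default 1; on a vertex-transitive graph any
#'   node gives the same answer — a warning is issued if the graph's weight
#'   profile is not node-uniform).
#' @return an object of class `sharing_summary`: list with `phi0`, `phi1`,
#'   `kappa` (Simpson degree), `critical_bc = 1/(phi0+phi1)`, `lambda`,
#'   `decay`.
#' @examples
#' retention_fractions(graph_complete(3), lambda = 3)  # phi0 = 5/11
#' @export
retention_fractions <- function(graph, lambda = NULL, decay = 0,
                                fractions = NULL, node = 1L) {
  if (!has_uniform_weight_profile(graph))
    warning("graph is not weight-homogeneous: phi0/phi1 depend on the ",
            "producer node (node = ", node, " used)")
  if (!is.null(fractions)) {
    check_fractions(graph, fractions)
    phi0 <- fractions[node, node]
    phi1 <- sum(graph$W[node, ] * fractions[node, ])
    lambda <- NA_real_
  } else {
    s <- numeric(graph$n)
    s[node] <- 1
    psi <- stationary_field(graph, s, lambda = lambda, decay = decay)
    phi0 <- psi[node]
    phi1 <- sum(graph$W[node, ] * psi)
  }
  structure(list(phi0 = phi0, phi1 = phi1,
                 kappa = simpson_degree(graph, node),
                 critical_bc = 1 / (phi0 + phi1),
                 lambda = lambda, decay = decay),
            class = "sharing_summary")
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf(
    "<sharing_summary: phi0 = %.6g, phi1 = %.6g, kappa = %.4g, critical b/c = %.6g>\n",
    x$phi0, x$phi1, x$kappa, x$critical_bc))
  invisible(x)
}

#' Monte Carlo random-walk estimate of the stationary field
#'
#' Independent oracle for [stationary_field()]: each unit of public good is
#' a particle performing a random walk with step probabilities equal to
#' edge weights. At each cell it is utilized with probability
#' `1/(1 + d + lambda)`, decays with probability `d/(1 + d + lambda)`, and
#' otherwise steps to a neighbour. Utilization counts, normalized per
#' producer, estimate `psi` unbiasedly with standard error shrinking as
#' `1/sqrt(n_particles)`.
#'
#' Uses R's global random number generator; call `set.seed()` for
#' reproducibility.
#'
#' @inheritParams stationary_field
#' @param n_particles particles released per producer, `>= 1`.
#' @return numeric vector of estimated concentrations.
#' @export
random_walk_field <- function(graph, state, lambda, decay = 0,
                              n_particles = 10000L) {
  state <- check_state(graph, state)
  check_params(lambda, decay)
  if (n_particles < 1) stop("n_particles must be >= 1")
  csr <- graph_csr(graph)
  counts <- rw_field_cpp(csr$ptr, csr$idx, csr$cw, which(state == 1) - 1L,
                         lambda, decay, as.integer(n_particles), graph$n)
  counts / n_particles
}

# CSR adjacency (0-based) with raw and normalized-cumulative weights per
# node, for the C++ loops
graph_csr <- function(graph) {
  Wp <- as(Matrix::t(graph$W), "CsparseMatrix")  # column i = neighbours of i
  w <- Wp@x
  cw <- w
  ptr <- Wp@p
  for (i in seq_len(graph$n)) {
    if (ptr[i + 1] > ptr[i]) {
      rng <- (ptr[i] + 1):ptr[i + 1]
      tot <- cumsum(cw[rng])
      cw[rng] <- tot / tot[length(tot)]  # normalized cumulative draw table
    }
  }
  list(ptr = ptr, idx = Wp@i, w = w, cw = cw)
}

#' Effective parameters under public-good decay
#'
#' Decay at relative rate `d` is equivalent to a decay-free model with both
#' the diffusion parameter and the benefit shrunk by `1/(1+d)`:
#' `lambda_eff = lambda/(1+d)`, `b_eff = b/(1+d)` (and the field rescales as
#' `psi = psi_eff/(1+d)`). Because the critical benefit-to-cost ratio grows
#' sublinearly in `lambda`, this shift always hinders cooperation.
#'
#' @param lambda diffusion parameter, `>= 0`.
#' @param b benefit per unit good utilized, `> 0`.
#' @param d decay-to-utilization rate ratio, `>= 0`.
#' @return list with `lambda_eff` and `b_eff`.
#' @export
decay_transform <- function(lambda, b, d) {
  if (lambda < 0 || b < 0 || d < 0) stop("lambda, b, d must be >= 0")
  list(lambda_eff = lambda / (1 + d), b_eff = b / (1 + d))
}
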