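#' Per-cell fecundity under public-goods selection
#'
#' `F_i = 1 + b * psi_i - c * s_i`: baseline fitness 1, plus the benefit of
#' utilized public good, minus the production cost paid by cooperators.
#' Requires `b > 0` and `0 < c < 1` so every fecundity stays positive.
#'
#' @param state production indicator vector (0/1 per node).
#' @param psi stationary public-goods field for `state` (see
#'   [stationary_field()]).
#' @param b benefit per unit public good utilized.
#' @param c production cost.
#' @return numeric vector of fecundities, all `> 0`.
#' @export
fecundity <- function(state, psi, b, c) {
  check_selection(b, c)
  f <- 1 + b * psi - c * state
  if (any(f <= 0)) stop("non-positive fecundity; b, c out of range")
  f
}

# b > 0 and 0 < c < 1 keep fecundities positive; the b = c = 0 boundary is
# admitted for neutral-drift checks
check_selection <- function(b, c) {
  if (!is.finite(b) || b < 0) stop("b must be >= 0")
  if (!is.finite(c) || c < 0 || c >= 1) stop("c must satisfy 0 <= c < 1")
  invisible(TRUE)
}

#' Whether (b, c) lie in the weak-selection regime
#'
#' Several analytic results hold exactly for arbitrary selection only on
#' complete graphs and 1D lattices; elsewhere they hold for weak selection,
#' `b, c << 1/kappa`. This helper applies the working cutoff
#' `b, c < 1/(10*kappa)`.
#'
#' @inheritParams fecundity
#' @param kappa Simpson degree of the graph.
#' @return logical.
#' @export
is_weak_selection <- function(b, c, kappa) {
  b < 1 / (10 * kappa) && c < 1 / (10 * kappa)
}

#' One Death-Birth update step
#'
#' A uniformly random cell dies; the neighbours of the vacancy compete to
#' fill it with probability proportional to fecundity times edge weight,
#' and the winner's offspring (inheriting its type) takes the spot. The
#' public-goods field is at stationarity for the pre-death state, per the
#' separation of diffusion and reproduction timescales.
#'
#' This single-step reference implementation recomputes the stationary
#' field exactly; the trial-level engine behind [estimate_fixation()] does
#' the same update in compiled code with O(n) incremental field updates.
#' Uses R's global RNG.
#'
#' @param graph a `weighted_graph`.
#' @param state 0/1 production vector.
#' @inheritParams fecundity
#' @param lambda,decay diffusion parameters.
#' @return the updated state vector.
#' @export
db_step <- function(graph, state, b, c, lambda, decay = 0) {
  state <- check_state(graph, state)
  psi <- stationary_field(graph, state, lambda = lambda, decay = decay)
  f <- fecundity(state, psi, b, c)
  i <- sample.int(graph$n, 1L)
  wrow <- graph$W[i, ]
  p <- f * wrow
  j <- sample.int(graph$n, 1L, prob = p / sum(p))
  state[i] <- state[j]
  state
}

#' Monte Carlo fixation-probability estimate
#'
#' Runs repeated Death-Birth trials, each starting from a single mutant of
#' the given type placed uniformly at random in a resident population of
#' the opposite type, iterating until one type fixes. The fraction of
#' trials in which the mutant fixes estimates its fixation probability
#' `rho`; cooperation is favoured when `rho_C > rho_D`.
#'
#' The engine precomputes the influence matrix once and updates the
#' stationary field in O(n) per type flip, so the per-step cost is linear
#' in population size. Trials that fail to absorb within `max_steps` are
#' counted and reported in the `overran` field, never silently dropped
#' (they are excluded from the denominator).
#'
#' @param graph a `weighted_graph` (at most 3000 nodes — the influence
#'   matrix is dense).
#' @inheritParams fecundity
#' @param lambda,decay diffusion parameters.
#' @param mutant `"C"` (cooperator invading defectors) or `"D"`.
#' @param trials number of independent trials, `>= 1`.
#' @param seed integer seed (mandatory, for reproducibility).
#' @param max_steps per-trial step cap (default 1e7).
#' @return an object of class `fixation_estimate`: list with
#'   `mutant_type`, `trials`, `fixations`, `overran`, `rho_hat`, `stderr`
#'   (binomial), `mean_steps`, `seed`.
#' @examples
#' est <- estimate_fixation(graph_complete(8), b = 0.2, c = 0.05,
#'                          lambda = 1, mutant = "C", trials = 200, seed = 1)
#' est$rho_hat
#' @export
estimate_fixation <- function(graph, b, c, lambda, mutant = c("C", "D"),
                              trials, seed, decay = 0, max_steps = 1e7) {
  mutant <- match.arg(mutant)
  check_selection(b, c)
  if (missing(seed)) stop("seed is mandatory for simulation runs")
  if (trials < 1) stop("trials must be >= 1")
  M <- influence_matrix(graph, lambda, decay)
  csr <- graph_csr(graph)
  set.seed(seed)
  res <- db_fixation_cpp(csr$ptr, csr$idx, csr$w, M, rowSums(M), b, c,
                         mutant == "C", as.integer(trials), max_steps)
  fix <- res[1]; completed <- res[2]; overran <- res[3]
  rho <- fix / completed
  structure(list(mutant_type = mutant, trials = as.integer(trials),
                 fixations = as.integer(fix), overran = as.integer(overran),
                 rho_hat = rho,
                 stderr = sqrt(rho * (1 - rho) / completed),
                 mean_steps = res[4] / trials, seed = seed),
            class = "fixation_estimate")
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf(
    "<fixation_estimate %s: %d/%d fixed, rho_hat = %.5g (se %.2g)%s>\n",
    x$mutant_type, x$fixations, x$trials, x$rho_hat, x$stderr,
    if (x$overran > 0) sprintf(", %d trials overran max_steps", x$overran)
    else ""))
  invisible(x)
}

#' Exact fixation probabilities on the complete graph
#'
#' On the complete graph the number of cooperators is a sufficient
#' statistic: all cooperators share one stationary concentration and all
#' defectors another (a 2x2 reduction of the stationary system). The
#' Death-Birth process is then a birth-death chain on the cooperator count
#' with absorbing ends, and both fixation probabilities follow from
#' standard first-step analysis, exact to machine precision — an oracle for
#' the Monte Carlo engine at arbitrary selection strength.
#'
#' @param n_nodes population size (2..200; the chain is dense beyond that).
#' @inheritParams fecundity
#' @param lambda diffusion parameter.
#' @return list with `rho_C`, `rho_D`, and the per-count concentrations
#'   `psi_C`, `psi_D` (matrices indexed by cooperator count).
#' @export
exact_fixation_complete <- function(n_nodes, b, c, lambda) {
  check_selection(b, c)
  if (n_nodes < 2 || n_nodes > 200) stop("n_nodes must be in 2..200")
  n <- n_nodes
  # two-class stationary solve for m cooperators among n:
  # (1+L) psi_C = 1 + L[(m-1) psi_C + (n-m) psi_D]/(n-1)
  # (1+L) psi_D =     L[ m    psi_C + (n-m-1) psi_D]/(n-1)
  L <- lambda
  psi_C <- psi_D <- numeric(n - 1)
  for (m in 1:(n - 1)) {
    A <- rbind(c(1 + L - L * (m - 1) / (n - 1), -L * (n - m) / (n - 1)),
               c(-L * m / (n - 1), 1 + L - L * (n - m - 1) / (n - 1)))
    v <- solve(A, c(1, 0))
    psi_C[m] <- v[1]; psi_D[m] <- v[2]
  }
  # transition ratios gamma_m = P(m -> m-1)/P(m -> m+1)
  gam <- numeric(n - 1)
  for (m in 1:(n - 1)) {
    F_C <- 1 + b * psi_C[m] - c
    F_D <- 1 + b * psi_D[m]
    p_up <- ((n - m) / n) * (m * F_C) / (m * F_C + (n - m - 1) * F_D)
    p_dn <- (m / n) * ((n - m) * F_D) / ((m - 1) * F_C + (n - m) * F_D)
    gam[m] <- p_dn / p_up
  }
  cum <- cumprod(gam)
  denom <- 1 + sum(cum)
  rho_C <- 1 / denom
  # defector mutant: chain starts at n-1 cooperators; rho_D = P(hit 0)
  rho_D <- 1 - (1 + sum(cum[1:(n - 2)])) / denom
  if (n == 2) rho_D <- 1 - 1 / denom
  list(rho_C = rho_C, rho_D = rho_D, psi_C = psi_C, psi_D = psi_D)
}

#' Two-proportion pooled z-test between fixation estimates
#'
#' Compares cooperator and defector fixation estimates with the pooled
#' two-proportion z statistic and a two-sided p-value. Verdict `"+"` means
#' cooperation significantly favoured (`rho_C > rho_D`, p < 0.05), `"-"`
#' significantly disfavoured, `"0"` not significant.
#'
#' @param est_C,est_D `fixation_estimate` objects (or lists with
#'   `fixations` and `trials`).
#' @param alpha significance level (default 0.05).
#' @return list with `z`, `p_value`, `verdict`.
#' @export
compare_strategies <- function(est_C, est_D, alpha = 0.05) {
  n1 <- est_C$trials - (est_C$overran %||% 0)
  n2 <- est_D$trials - (est_D$overran %||% 0)
  if (n1 < 1 || n2 < 1) stop("both estimates need at least one trial")
  x1 <- est_C$fixations; x2 <- est_D$fixations
  p_pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (x1 / n1 - x2 / n2) / se
  p <- 2 * stats::pnorm(-abs(z))
  verdict <- if (p < alpha && z > 0) "+" else if (p < alpha && z < 0) "-" else "0"
  list(z = z, p_value = p, verdict = verdict)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
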