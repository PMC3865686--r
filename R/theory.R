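#' Critical benefit-to-cost ratio for cooperation
#'
#' Under Death-Birth updating, public-goods cooperation is favoured
#' (`rho_C > rho_D`) iff `b/c > 1/(phi0 + phi1)`: the benefit the producer
#' keeps plus the average benefit each neighbour receives must outweigh the
#' production cost. Without decay the threshold can equivalently be written
#' `lambda / (phi0 (1 + 2*lambda) - 1)`; both forms are returned and
#' cross-checked through the identity `(1+lambda) phi0 = 1 + lambda phi1`.
#'
#' @param summary a `sharing_summary` from [retention_fractions()] (or any
#'   list with `phi0`, `phi1`, `lambda`, `decay`).
#' @param bc optional benefit-to-cost ratio to test.
#' @return list with `critical_bc`, `critical_bc_alt` (`NA` when `lambda`
#'   is not available or decay is present), and `favored` (logical, `NA`
#'   if `bc` not supplied).
#' @export
critical_ratio <- function(summary, bc = NULL) {
  phi0 <- summary$phi0; phi1 <- summary$phi1
  if (phi0 + phi1 <= 0) stop("phi0 + phi1 must be positive")
  crit <- 1 / (phi0 + phi1)
  lam <- summary$lambda
  alt <- NA_real_
  if (!is.null(lam) && is.finite(lam) && lam > 0 &&
      (summary$decay %||% 0) == 0) {
    if (phi0 * (1 + 2 * lam) <= 1)
      stop("inconsistent summary: phi0 (1 + 2 lambda) <= 1 violates the ",
           "stationarity identity (1+lambda) phi0 = 1 + lambda phi1")
    alt <- lam / (phi0 * (1 + 2 * lam) - 1)
  }
  list(critical_bc = crit, critical_bc_alt = alt,
       favored = if (is.null(bc)) NA else bc > crit)
}

#' Weak-diffusion expansion of the critical ratio
#'
#' For small `lambda` the critical benefit-to-cost ratio expands as
#' `1 + lambda (kappa - 1)/kappa + O(lambda^2)`, showing how cooperation
#' gets harder with both the diffusion parameter and the Simpson degree.
#' As `kappa -> Inf` it approaches the well-mixed line `1 + lambda`.
#'
#' @param kappa Simpson degree, `>= 1`.
#' @param lambda diffusion parameter, `>= 0`.
#' @return the first-order approximation to the critical `b/c`.
#' @export
weak_diffusion_bc <- function(kappa, lambda) {
  if (kappa < 1) stop("kappa must be >= 1")
  if (lambda < 0) stop("lambda must be >= 0")
  1 + lambda * (kappa - 1) / kappa
}

#' Social-multiplier reparameterization
#'
#' In the social-network reading of the model, an action yields its actor a
#' direct benefit `b0` and radiates benefits outward with multiplier `m`
#' (first neighbours `m*b0` combined, second `m^2*b0`, ...). This maps onto
#' the diffusion model via `b = b0/(1-m)`, `lambda = m/(1-m)`.
#'
#' @param b0 direct benefit, `> 0`.
#' @param m multiplier in `[0, 1)`.
#' @return list with `b` and `lambda`.
#' @export
social_multiplier_map <- function(b0, m) {
  if (b0 <= 0) stop("b0 must be > 0")
  if (m < 0 || m >= 1) stop("m must lie in [0, 1); the map diverges at m = 1")
  list(b = b0 / (1 - m), lambda = m / (1 - m))
}

#' Biophysical estimate of the diffusion parameter for budding yeast
#'
#' For invertase-derived monosaccharides in a tightly packed
#' *S. cerevisiae* colony: glucose uptake follows Michaelis-Menten
#' kinetics, linearized at glucose-limited concentrations (`psi << K`) to
#' rate `V_max psi / K`. The mean molecule lifetime before uptake is then
#' `L = K * v / V_max`, where `v` is the water volume per cell — the cell
#' volume `(4/3) pi r^3` scaled by `(1 - packing)/packing` (equal to the
#' cell volume at 50% packing) — and `K` is converted to molecules per
#' cubic micrometre via Avogadro's number. The diffusion length is
#' `sqrt(D * L)`; expressed in cell lengths (one cell length = the diameter
#' `2 r`) and rounded up to an integer it gives the diffusion parameter
#' `lambda` (the rounding convention is reported in the output).
#'
#' @param vmax maximal uptake rate, molecules/second (default 2e7).
#' @param K Michaelis constant, molar (default 1e-3, i.e. 1 mM).
#' @param radius cell radius, micrometres (default 2).
#' @param packing volume fraction occupied by cells, in (0, 1) (default
#'   0.5).
#' @param D diffusion constant, micrometres^2/second (default 100, the
#'   colony-environment estimate).
#' @return an object of class `yeast_estimate`: the inputs plus
#'   `cell_volume` (um^3), `water_volume_per_cell` (um^3), `lifetime`
#'   (seconds), `diffusion_length` (um), `cell_lengths` (raw ratio), and
#'   `lambda` (integer, ceiling of `cell_lengths`).
#' @examples
#' est <- estimate_lambda_yeast()
#' est$lifetime          # ~1 second
#' est$diffusion_length  # ~10 micrometres
#' est$lambda            # 3
#' @export
estimate_lambda_yeast <- function(vmax = 2e7, K = 1e-3, radius = 2,
                                  packing = 0.5, D = 100) {
  if (any(c(vmax, K, radius, D) <= 0)) stop("all inputs must be positive")
  if (packing <= 0 || packing > 1) stop("packing must lie in (0, 1]")
  avogadro <- 6.02214e23
  K_per_um3 <- K * avogadro / 1e15          # molar -> molecules per um^3
  cell_vol <- 4 / 3 * pi * radius^3
  water_vol <- cell_vol * (1 - packing) / packing
  L <- K_per_um3 * water_vol / vmax
  len <- sqrt(D * L)
  ratio <- len / (2 * radius)
  structure(list(vmax = vmax, K = K, radius = radius, packing = packing,
                 D = D, cell_volume = cell_vol,
                 water_volume_per_cell = water_vol, lifetime = L,
                 diffusion_length = len, cell_lengths = ratio,
                 lambda = as.integer(ceiling(ratio)),
                 rounding = "lambda = ceiling(diffusion length / cell diameter)"),
            class = "yeast_estimate")
}

#' @export
print.yeast_estimate <- function(x, ...) {
  cat(sprintf(paste0(
    "<yeast_estimate: lifetime %.3g s, diffusion length %.3g um ",
    "(%.3g cell lengths), lambda = %d>\n"),
    x$lifetime, x$diffusion_length, x$cell_lengths, x$lambda))
  invisible(x)
}
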