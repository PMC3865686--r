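---
title: "Diffusible public goods on colony graphs: model, numerics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusible public goods on colony graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goodsgraph)
```

## The model

Many microbial public goods — hydrolyzed monosaccharides around invertase-
secreting yeast, siderophores, extracellular enzymes — are produced at a
cost by *cooperator* cells and diffuse through the colony, where any cell
can utilize them. `goodsgraph` implements a graph model of this dilemma.
Colony geometry is a finite symmetric weighted graph: nodes are cells, and
the edge weight $e_{ij}$ is the relative frequency with which a diffusing
particle moves from cell $i$ to neighbouring cell $j$. Weights satisfy
$e_{ii} = 0$, $e_{ij} = e_{ji}$ and $\sum_j e_{ij} = 1$, so each row is the
step distribution of a random walk. The model addresses colony interiors —
graphs whose every node has the same weight profile (vertex-transitive
lattices); `validate_graph()` and a homogeneity warning in
`retention_fractions()` flag departures from this regime.

Cooperators produce one unit of good per unit utilization time. Writing
$s_i \in \{0,1\}$ for the type of cell $i$, $\lambda$ for the ratio of the
diffusion rate to the utilization rate, and $d$ for the decay-to-
utilization ratio, the stationary concentrations $\psi_i$ solve the linear
system

$$(1 + d + \lambda)\,\psi_i = s_i + \lambda \sum_j e_{ji}\,\psi_j .$$

Equivalently, each particle performs a random walk with step probabilities
$e_{ij}$ and is utilized at each visited cell with probability
$1/(1+d+\lambda)$ (and decays with probability $d/(1+d+\lambda)$);
$\lambda$ is the expected number of inter-cell steps before utilization
when $d = 0$. `stationary_field()` solves the system exactly (sparse LU;
residuals below $10^{-10}$), and `random_walk_field()` is an independent
Monte Carlo oracle for it.

Two scalars summarize sharing from a single producer: $\phi_0$, the
fraction of its own good the producer utilizes, and $\phi_1$, the
edge-weighted average fraction utilized by each nearest neighbour. Under
Death–Birth updating — a uniformly random cell dies, neighbours compete
for the vacancy in proportion to fecundity $F_i = 1 + b\psi_i - c s_i$
times edge weight — cooperation is favoured ($\rho_C > \rho_D$ for the
two fixation probabilities) exactly when

$$\frac{b}{c} > \frac{1}{\phi_0 + \phi_1},$$

with equality of routes guaranteed by the stationarity identity
$(1+\lambda)\phi_0 = 1 + \lambda\phi_1$ (no decay); the equivalent form
$b/c > \lambda/[\phi_0(1+2\lambda) - 1]$ is returned alongside it by
`critical_ratio()`. The condition holds at arbitrary selection strength on
complete graphs and 1D lattices, and for weak selection
($b, c \ll 1/\kappa$, where $\kappa = 1/\sum_j e_{ij}^2$ is the Simpson
degree) elsewhere.

```{r}
g <- graph_triangular(15)          # hexagonal packing, 225 cells
retention_fractions(g, lambda = 3)
```

## Analytic routes to phi0

Three independent routes to $\phi_0$ are implemented and cross-checked in
the test suite:

1. **Linear solve** of the stationary system with one producer
   (`retention_fractions()`).
2. **Generating functions**: $\phi_0 = G_{ii}(\lambda/(1+\lambda))/(1+\lambda)$
   where $G_{ij}(z) = \sum_n p^{(n)}_{ij} z^n$ is the random-walk
   generating function, evaluated by dense resolvent (`gf_resolvent()`,
   `phi0_gf()`); a truncated power series (`gf_series()`) is kept purely
   as an oracle. At $z = 1 - u$ the same function yields
   identity-by-descent probabilities $q_{ij} = G_{ij}(1-u)/G_{jj}(1-u)$
   (`ibd_probability()`).
3. **Closed forms / lattice integrals** (`phi0_closed_form()`,
   `phi0_lattice_integral()`): $1/(1+\lambda)$ for the complete graph,
   $1/\sqrt{1+2\lambda}$ in 1D, $1/\mathrm{agm}(1, 1+2\lambda)$ on the 2D
   square lattice, and for any mathematical lattice the Brillouin-zone
   integral $(2\pi)^{-n}\int_{[-\pi,\pi]^n} dy\,/(1+\lambda-\lambda\chi(y))$
   with structure function $\chi(y) = \sum_k w_k e^{i v_k\cdot y}$.

### Numerical choices

* **AGM** iterates to relative tolerance $10^{-14}$; double precision
  suffices far beyond any biologically sensible $\lambda$.
* **Lattice quadrature** uses the tensor-product trapezoidal rule on a
  periodic grid, doubled until successive estimates differ by less than
  the requested tolerance (default $10^{-8}$). Because the integrand is
  smooth and periodic — the denominator is bounded below by 1 for finite
  $\lambda$ — the rule converges spectrally, which is why plain trapezoid
  beats adaptive quadrature here.
* **Degree-k Cayley tree (Bethe lattice)**: the closed form

  $$\phi_0 = \frac{\sqrt{(k-2)^2(1+\lambda)^2 + 4(k-1)(1+2\lambda)}
             - (k-2)(1+\lambda)}{2(1+2\lambda)}$$

  equals 1 at $\lambda = 0$, decreases in $\lambda$, and matches the root
  retention of depth-truncated trees to within $10^{-6}$ by depth 12
  (tested for $k \in \{3,4\}$, $\lambda \in \{1,3\}$). Truncated trees keep
  all edge weights at $1/k$ rather than inventing boundary weights, so
  leaf rows deliberately sum to $1/k$ and are flagged; analytic
  comparisons read only the root. For depths whose explicit trees would be
  enormous, `bethe_root_retention()` exploits radial symmetry to reduce
  the solve to a tridiagonal system in depth + 1 unknowns — the same
  linear system, exactly.
* **Lattices are periodic** with minimum side 3 (wraparound on a smaller
  side duplicates edges), realizing homogeneity — "the colony looks the
  same from each cell" — on finite graphs. Finite-size error in $\phi_0$
  decays like $(\lambda/(1+\lambda))^{\text{side}}$, so a 63×63 triangular
  lattice already matches the infinite-lattice integral to $10^{-4}$ at
  $\lambda = 3$.
* The triangular-lattice step convention is $\pm(1,0), \pm(0,1), \pm(1,1)$,
  matching the structure function
  $\chi(y) = [\cos y_1 + \cos y_2 + \cos(y_1{+}y_2)]/3$.
* Coordinates map to node ids row-major; ids are 1-based in the R API,
  while edge-list files use 0-based ids.

## Decay, weak diffusion, social multipliers

Decay at relative rate $d$ folds into effective quantities
$\tilde\lambda = \lambda/(1+d)$, $\tilde b = b/(1+d)$
(`decay_transform()`); since the critical ratio grows sublinearly in
$\lambda$, decay strictly hinders cooperation — a property test scales
just-unfavourable points and asserts they stay unfavourable. For small
$\lambda$ the threshold expands as $1 + \lambda(\kappa-1)/\kappa +
O(\lambda^2)$ (`weak_diffusion_bc()`); the tests assert the quadratic
error order empirically on ring, square and triangular lattices. The
social-network reading maps a behaviour with direct benefit $b_0$ and
multiplier $m$ onto $(b, \lambda) = (b_0/(1-m),\, m/(1-m))$
(`social_multiplier_map()`); on a long 1D lattice the total radiated
benefit is $b_0/(1-m)$ exactly and the combined first-neighbour benefit
approaches $m b_0$ as $m \to 0$, which is the regime in which the
"first neighbours receive $m b_0$" picture is quantitative.

## The yeast estimate of lambda

`estimate_lambda_yeast()` reproduces the biophysical chain for
invertase-derived monosaccharides in *S. cerevisiae*: Michaelis–Menten
uptake ($V_{\max} = 2\times10^7$ molecules/s, $K = 1$ mM) linearized in
the glucose-limited regime $\psi \ll K$; molecule lifetime
$L = K v / V_{\max} \approx 1$ s with $v$ the water volume per cell (equal
to the cell volume $\tfrac43\pi r^3$, $r = 2\,\mu$m, at 50% packing —
generalized as $v = V_{\text{cell}}(1-p)/p$ for packing fraction $p$);
diffusion length $\sqrt{DL} \approx 10\,\mu$m with $D = 100\,\mu$m²/s.
Ten micrometres is 2.51 cell diameters; the function reports
$\lambda = \lceil 2.51 \rceil = 3$ and records the ceiling convention in
its output, making the "∼3 cell lengths, so $\lambda = 3$" chain
deterministic. Avogadro's number is fixed at $6.02214\times10^{23}$/mol;
lengths are in $\mu$m, times in seconds.

```{r}
estimate_lambda_yeast()
```

## Simulation engine

`estimate_fixation()` runs Death–Birth trials from a single mutant placed
uniformly at random, to absorption. Design choices:

* $\psi$ is at stationarity between reproductive events (diffusion and
  utilization are much faster than division). Because the stationary
  system is linear, $\psi = M s$ with
  $M = ((1+d+\lambda)I - \lambda W^{\top})^{-1}$ precomputed once per run;
  a type flip adds or subtracts one column of $M$, so each step costs
  $O(n)$. A test verifies the incremental field equals a full re-solve to
  $10^{-9}$ after every flip.
* Replacement draws use the pre-death fecundities of the vacancy's
  neighbours ($F_j e_{ji}$, normalized); the dying cell's own fecundity
  plays no role.
* The inner loop is compiled (Rcpp) and consumes R's global RNG
  sequentially, so a single `set.seed()` fixes the entire run; every
  randomized entry point requires an explicit seed. No parallelism.
* Trials exceeding `max_steps` ($10^7$ by default) are counted and
  reported, never silently dropped.
* Mutation does not occur during fixation trials; the mutation rate $u$
  enters the theory only through identity-by-descent probabilities.
* On complete graphs the cooperator count is a sufficient statistic, and
  `exact_fixation_complete()` computes both fixation probabilities from
  the absorbing birth–death chain to machine precision — the oracle
  against which the Monte Carlo engine is tested at arbitrary selection
  strength. Whether the finite-$N$ threshold carries corrections beyond
  $1/(\phi_0+\phi_1)$ evaluated with finite-$N$ fractions is left open by
  the theory as stated; the tests therefore bracket the empirical crossing
  (sign change between 0.9× and 1.1× of the finite-$N$ threshold at
  $N = 100$) rather than asserting equality at small $N$.

### Test scale for the threshold sign pattern

The sign-pattern experiment runs on a 6×6 uniform periodic triangular
lattice with $c = 0.05$, $\lambda \in \{1, 3\}$ and $10^5$ trials per
type, with $b/c$ at 1.5× and 0.5× the predicted threshold, compared by a
two-proportion pooled z-test at $p < 0.05$. These sizes are the package's
declared reduced-scale study conditions: they preserve the lattice family,
cost and test statistic of the full 15×15 experiment while keeping the
suite runnable on a laptop. Neutral drift ($b = c = 0$) on the same
lattice is checked against the exact $1/N$ fixation probability.

## What the synthetic graphs do and do not show

All tests run on generated graphs: lattice families, truncated trees, and
randomized circulants (the vertex-transitive family used for property
tests of conservation, the stationarity identity, and route agreement).
These capture the homogeneous-interior assumption of the theory —
symmetric weights, unit row sums, identical local profiles — but not
colony boundaries, disorder in real cell packings, growth, or
time-dependent diffusion. Passing tests therefore validate the
mathematics and the implementation, not the fidelity of any particular
lattice to a particular organism; the E. coli-style rod-packing profile
(`graph_triangular(side, profile = c(0.1, 0.15, 0.25))`) is an idealized
weighting, not a fitted one.

## Known limitations

* Retention fractions on non-homogeneous graphs depend on the producer
  node; the package warns rather than refusing, and reports the chosen
  node's values.
* The generating function is evaluated only for $z < 1$ on finite graphs;
  the $u \to 0$ limit of IBD probabilities (ratio of diverging series) is
  not taken.
* The lattice Green's-function integral is implemented for the origin
  (all that $\phi_0$ requires) and dimensions up to 4.
* Update rules other than Death–Birth, heterotypic (two-species)
  cooperation, and finite-population corrections to the closed forms are
  out of scope.
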