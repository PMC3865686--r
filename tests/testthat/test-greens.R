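test_that("resolvent generating function matches eigen closed forms", {
  g <- triangle_graph()
  # triangle eigenvalues {1, -1/2, -1/2}: G_ii(3/4) = 20/11, G_ij = 12/11
  expect_equal(gf_resolvent(g, 1, 1, 0.75), 20 / 11, tolerance = 1e-12)
  expect_equal(gf_resolvent(g, 1, 2, 0.75), 12 / 11, tolerance = 1e-12)
  expect_equal(gf_resolvent(g, 1, 1, 0), 1)
  expect_equal(gf_resolvent(g, 1, 3, 0), 0)
  expect_error(gf_resolvent(g, 1, 1, 1), "z < 1")
  # symmetry G_ij = G_ji
  gr <- graph_circulant(10, c(`1` = 0.3, `3` = 0.2))
  expect_equal(gf_resolvent(gr, 2, 7, 0.6), gf_resolvent(gr, 7, 2, 0.6),
               tolerance = 1e-12)
})

test_that("series oracle converges to the resolvent", {
  g <- graph_ring(6)
  expect_equal(gf_series(g, 2, 2, 0.5, 0), 1)
  expect_equal(gf_series(g, 1, 2, 0.5, 1), 0.5 * 0.5)
  # 4-ring return term: p_ii^(2) = sum_j e_ij^2 = 1/2
  expect_equal(gf_series(graph_ring(4), 1, 1, 0.5, 2), 1 + 0.5 * 0.25)
  expect_equal(gf_series(g, 1, 1, 0.5, 1e4), gf_resolvent(g, 1, 1, 0.5),
               tolerance = 1e-8)
  # partial sums are monotone on the diagonal
  sums <- sapply(c(0, 2, 4, 8, 16), function(m) gf_series(g, 1, 1, 0.5, m))
  expect_true(all(diff(sums) >= 0))
})

test_that("generating-function and linear-solve phi0 routes agree", {
  expect_equal(phi0_gf(triangle_graph(), 3), 5 / 11, tolerance = 1e-12)
  expect_equal(phi0_gf(graph_ring(1000), 4), 1 / 3, tolerance = 1e-6)
  set.seed(21)
  for (rep in 1:10) {
    g <- random_circulant()
    lam <- stats::runif(1, 0.1, 6)
    expect_equal(phi0_gf(g, lam),
                 retention_fractions(g, lambda = lam)$phi0,
                 tolerance = 1e-9)
  }
})

test_that("closed-form retention fractions evaluate correctly", {
  expect_equal(phi0_closed_form("complete", 3), 0.25)
  expect_equal(phi0_closed_form("lattice_1d", 4), 1 / 3)
  expect_equal(phi0_closed_form("square_2d", 4), 1 / agm(1, 9))
  expect_equal(agm(1, 1), 1)
  expect_equal(agm(1, 9), 3.93623550364956, tolerance = 1e-13)
  # all families: value 1 at lambda = 0, decreasing and convex in lambda
  forms <- list(function(l) phi0_closed_form("complete", l),
                function(l) phi0_closed_form("lattice_1d", l),
                function(l) phi0_closed_form("square_2d", l),
                function(l) phi0_closed_form("bethe", l, k = 3),
                function(l) phi0_closed_form("bethe", l, k = 5))
  lams <- seq(0, 6, by = 0.5)
  for (f in forms) {
    v <- sapply(lams, f)
    expect_equal(v[1], 1)
    expect_true(all(diff(v) < 0))
    expect_true(all(diff(diff(v)) > 0))  # convex
  }
  expect_error(phi0_closed_form("hexagonal", 1), "arg")
  expect_error(phi0_closed_form("bethe", 1), "k >= 3")
})

test_that("structure function matches printed lattice forms", {
  sq <- spec_square(2)
  expect_equal(structure_function(sq, c(0, 0)), 1)
  expect_equal(structure_function(spec_square(1), pi), -1)
  tri <- spec_triangular()
  expect_equal(structure_function(tri, c(pi, pi)), -1 / 3, tolerance = 1e-12)
  y <- c(0.3, -1.2)
  expect_equal(structure_function(tri, y),
               (cos(y[1]) + cos(y[2]) + cos(sum(y))) / 3, tolerance = 1e-12)
  expect_equal(structure_function(sq, y), mean(cos(y)), tolerance = 1e-12)
  expect_error(lattice_spec(rbind(c(1, 0), c(0, 1)), c(0.5, 0.5)),
               "negation")
})

test_that("lattice integral agrees with closed forms and finite solves", {
  expect_equal(phi0_lattice_integral(spec_square(2), 0), 1)
  for (lam in c(1, 4))
    expect_equal(phi0_lattice_integral(spec_square(2), lam),
                 phi0_closed_form("square_2d", lam), tolerance = 1e-7)
  for (lam in c(0.5, 1, 3))
    expect_equal(phi0_lattice_integral(spec_square(1), lam),
                 phi0_closed_form("lattice_1d", lam), tolerance = 1e-8)
  # triangular lattice: integral vs a large periodic finite solve
  expect_equal(phi0_lattice_integral(spec_triangular(), 3),
               retention_fractions(graph_triangular(63), lambda = 3)$phi0,
               tolerance = 1e-4)
})

test_that("Bethe closed form matches truncated-tree root retention", {
  # radial reduction equals the explicit tree solve at small depth
  for (k in c(3, 4)) {
    g <- graph_bethe(k, 5)
    s <- numeric(g$n); s[1] <- 1
    psi_root <- stationary_field(g, s, lambda = 2)[1]
    expect_equal(bethe_root_retention(k, 5, 2), psi_root, tolerance = 1e-12)
  }
  # deep truncation converges to the closed form
  for (k in c(3, 4))
    for (lam in c(1, 3, 5))
      expect_equal(phi0_closed_form("bethe", lam, k = k),
                   bethe_root_retention(k, 12, lam), tolerance = 1e-6)
  expect_equal(bethe_root_retention(3, 12, 0), 1)
})

test_that("IBD probabilities follow the generating-function ratio", {
  g <- triangle_graph()
  expect_equal(ibd_probability(g, 1, 2, u = 1), 0)   # G(0) = identity
  expect_equal(ibd_probability(g, 2, 2, u = 0.3), 1)
  # q_01 = G_01(0.75)/G_11(0.75) = (12/11)/(20/11)
  expect_equal(ibd_probability(g, 1, 2, u = 0.25), 0.6, tolerance = 1e-12)
  expect_error(ibd_probability(g, 1, 2, u = 0), "diverges")
  set.seed(31)
  g2 <- random_circulant()
  for (u in c(0.05, 0.5)) {
    q <- ibd_probability(g2, 1, 3, u)
    expect_true(q >= 0 && q <= 1)
  }
})
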