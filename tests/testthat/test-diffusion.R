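test_that("stationary field solves the diffusion recurrence exactly", {
  # single cooperator on the triangle, lambda = 3: psi = (5/11, 3/11, 3/11)
  g <- triangle_graph()
  psi <- stationary_field(g, c(1, 0, 0), lambda = 3)
  expect_equal(psi, c(5, 3, 3) / 11, tolerance = 1e-12)
  # residual of the recurrence below 1e-10 on an irregular fixture
  set.seed(11)
  gc <- random_circulant()
  s <- as.numeric(stats::runif(gc$n) < 0.4)
  for (d in c(0, 0.7)) {
    psi <- stationary_field(gc, s, lambda = 2.3, decay = d)
    resid <- (1 + d + 2.3) * psi - s -
      2.3 * as.numeric(Matrix::t(gc$W) %*% psi)
    expect_lt(max(abs(resid)), 1e-10)
  }
})

test_that("no diffusion and all-cooperator limits are exact", {
  g <- graph_triangular(5)
  s <- as.numeric(seq_len(g$n) %% 3 == 0)
  expect_equal(stationary_field(g, s, lambda = 0), s)
  expect_equal(stationary_field(g, rep(1, g$n), lambda = 7.5),
               rep(1, g$n), tolerance = 1e-12)
})

test_that("total good is conserved (or scaled by 1/(1+d) under decay)", {
  set.seed(42)
  for (rep in 1:25) {
    g <- random_circulant()
    s <- as.numeric(stats::runif(g$n) < 0.5)
    lam <- stats::runif(1, 0, 8)
    d <- sample(c(0, stats::runif(1, 0, 3)), 1)
    psi <- stationary_field(g, s, lambda = lam, decay = d)
    expect_equal(sum(psi), sum(s) / (1 + d), tolerance = 1e-9)
    expect_true(all(psi >= 0))
  }
})

test_that("the field is linear in the production state", {
  set.seed(7)
  g <- graph_lattice(4, 2)
  s1 <- numeric(g$n); s1[c(1, 6)] <- 1
  s2 <- numeric(g$n); s2[c(11, 16)] <- 1
  expect_equal(stationary_field(g, s1 + s2, lambda = 2),
               stationary_field(g, s1, lambda = 2) +
                 stationary_field(g, s2, lambda = 2),
               tolerance = 1e-12)
})

test_that("single-producer field respects the producer's symmetry", {
  g <- graph_ring(9)
  psi <- stationary_field(g, c(1, numeric(8)), lambda = 4)
  # mirror symmetry around the producer
  expect_equal(psi[2:5], rev(psi[6:9]), tolerance = 1e-12)
})

test_that("(1+lambda) phi0 = 1 + lambda phi1 on every decay-free graph", {
  set.seed(99)
  graphs <- c(builder_gallery(), list(random_circulant(), random_circulant()))
  for (g in graphs) {
    for (lam in c(0.25, 1, 3, 10)) {
      s <- retention_fractions(g, lambda = lam)
      expect_equal((1 + lam) * s$phi0, 1 + lam * s$phi1, tolerance = 1e-9)
      expect_true(s$phi0 > 0 && s$phi0 <= 1)
      expect_true(s$phi1 >= 0 && s$phi0 + s$phi1 <= 1 + 1e-12)
    }
  }
})

test_that("phi0 strictly decreases in lambda", {
  for (g in list(graph_complete(6), graph_triangular(6), graph_ring(11))) {
    lams <- c(0, 0.5, 1, 2, 4, 8)
    phis <- sapply(lams, function(l) retention_fractions(g, lambda = l)$phi0)
    expect_true(all(diff(phis) < 0))
  }
})

test_that("retention fractions warn on weight-inhomogeneous graphs", {
  # a 3-node path: end nodes have a different weight profile
  g <- weighted_graph(rbind(c(0, 1, 0), c(0.5, 0, 0.5), c(0, 1, 0)),
                      validate = FALSE)
  expect_warning(retention_fractions(g, lambda = 1), "producer node")
})

test_that("custom diffusion fractions replace the solver route", {
  g <- triangle_graph()
  phi <- matrix(1 / 3, 3, 3)  # everything shared evenly
  psi <- stationary_field(g, c(1, 0, 0), fractions = phi)
  expect_equal(psi, rep(1 / 3, 3))
  s <- suppressWarnings(retention_fractions(g, fractions = phi))
  expect_equal(s$phi0, 1 / 3)
  expect_equal(s$phi1, sum(g$W[1, ] * phi[1, ]))
  expect_error(stationary_field(g, c(1, 0, 0), lambda = 1, fractions = phi),
               "one or the other")
  bad <- phi; bad[1, 1] <- 0.5
  expect_error(stationary_field(g, c(1, 0, 0), fractions = bad), "sum to 1")
})

test_that("decay is equivalent to rescaled effective parameters", {
  expect_equal(decay_transform(3, 8, 0), list(lambda_eff = 3, b_eff = 8))
  expect_equal(decay_transform(3, 8, 1), list(lambda_eff = 1.5, b_eff = 4))
  g <- graph_triangular(7)
  s <- as.numeric(seq_len(g$n) %% 4 == 0)
  lam <- 3; d <- 1.25
  eff <- decay_transform(lam, 1, d)
  expect_equal(stationary_field(g, s, lambda = lam, decay = d),
               stationary_field(g, s, lambda = eff$lambda_eff) / (1 + d),
               tolerance = 1e-10)
})

test_that("influence-matrix columns reproduce single-flip re-solves", {
  g <- graph_triangular(5)
  lam <- 2; d <- 0.3
  M <- influence_matrix(g, lam, d)
  set.seed(3)
  s <- as.numeric(stats::runif(g$n) < 0.5)
  psi <- as.numeric(M %*% s)
  expect_equal(psi, stationary_field(g, s, lambda = lam, decay = d),
               tolerance = 1e-9)
  for (k in sample(g$n, 8)) {
    s[k] <- 1 - s[k]
    psi <- psi + (2 * s[k] - 1) * M[, k]
    expect_equal(psi, stationary_field(g, s, lambda = lam, decay = d),
                 tolerance = 1e-9)
  }
})

test_that("random-walk Monte Carlo agrees with the exact solve", {
  g <- triangle_graph()
  # lambda = 0: every particle utilized at its source
  set.seed(1)
  expect_equal(random_walk_field(g, c(1, 0, 0), lambda = 0, n_particles = 50),
               c(1, 0, 0))
  # heavy decay kills nearly all mass
  set.seed(2)
  expect_lt(sum(random_walk_field(g, c(1, 1, 1), lambda = 1, decay = 1e6,
                                  n_particles = 200)), 0.01)
  # 3-standard-error agreement with the linear solve
  np <- 2e5
  set.seed(5)
  est <- random_walk_field(g, c(1, 0, 0), lambda = 3, n_particles = np)
  exact <- stationary_field(g, c(1, 0, 0), lambda = 3)
  se <- sqrt(exact * (1 - exact) / np)
  expect_true(all(abs(est - exact) < 3 * se))
})
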