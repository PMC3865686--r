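# Shared fixtures: small exactly-solvable graphs and a randomized family of
# vertex-transitive circulants for property-style tests.

triangle_graph <- function() graph_complete(3)

# random circulant: n in [8, 60], 1-3 offsets with random positive weights
# normalized to 1/2 per direction; offsets resampled until coprime with n
# so the graph is connected
random_circulant <- function() {
  n <- sample(8:60, 1)
  k <- sample(1:3, 1)
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  repeat {
    offs <- sample(setdiff(1:floor((n - 1) / 2), n / 2), k)
    if (Reduce(gcd2, c(offs, n)) == 1) break
  }
  w <- stats::runif(k, 0.1, 1)
  w <- w / (2 * sum(w))
  graph_circulant(n, stats::setNames(w, offs))
}

builder_gallery <- function() {
  list(complete_5 = graph_complete(5),
       ring_9 = graph_ring(9),
       square_5x5 = graph_lattice(5, 2),
       cube_4 = graph_lattice(4, 3),
       triangular_6 = graph_triangular(6),
       triangular_rod = graph_triangular(5, profile = c(0.1, 0.15, 0.25)),
       circulant_12 = graph_circulant(12, c(`1` = 0.3, `2` = 0.2)))
}
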