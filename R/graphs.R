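#' Construct a weighted colony graph
#'
#' A `weighted_graph` describes the interior geometry of a microbial colony:
#' nodes are cells, and the edge weight `e_ij` is the relative frequency with
#' which a diffusing particle of public good steps from cell `i` to cell `j`.
#' Weights are symmetric (`e_ij = e_ji`), have zero diagonal (diffusion is
#' intercellular), and each row sums to one, so each row is the step
#' distribution of a random walk.
#'
#' @param weights a square numeric matrix (dense or `Matrix` sparse) of edge
#'   weights. Symmetrized storage is the caller's responsibility; the
#'   constructor validates, it does not repair.
#' @param coords optional matrix of lattice coordinates, one row per node.
#' @param boundary_truncated logical; `TRUE` for truncated trees whose leaf
#'   rows deliberately do not sum to one (see [graph_bethe()]).
#' @param leaf_nodes integer ids of boundary nodes exempt from the row-sum
#'   check when `boundary_truncated` is `TRUE`.
#' @param validate logical; set `FALSE` only to build deliberately broken
#'   graphs for [validate_graph()] testing.
#' @return an object of class `weighted_graph` with elements `n` (node
#'   count), `W` (sparse `dgCMatrix` of weights), `coords`,
#'   `boundary_truncated`, `leaf_nodes`.
#' @seealso [graph_complete()], [graph_ring()], [graph_lattice()],
#'   [graph_triangular()], [graph_bethe()], [graph_circulant()],
#'   [validate_graph()]
#' @export
weighted_graph <- function(weights, coords = NULL, boundary_truncated = FALSE,
                           leaf_nodes = integer(0), validate = TRUE) {
  W <- methods::as(methods::as(Matrix::Matrix(weights, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  g <- structure(
    list(n = nrow(W), W = W, coords = coords,
         boundary_truncated = isTRUE(boundary_truncated),
         leaf_nodes = as.integer(leaf_nodes)),
    class = "weighted_graph")
  if (validate) {
    v <- validate_graph(g)
    if (length(v) > 0L)
      stop("invalid weighted_graph: ", paste(v, collapse = "; "))
  }
  g
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph: %d nodes, %d edges%s>\n", x$n,
              Matrix::nnzero(x$W) / 2L,
              if (x$boundary_truncated) ", boundary-truncated" else ""))
  invisible(x)
}

#' Validate the invariants of a weighted colony graph
#'
#' Checks non-negativity, zero diagonal, symmetry (`e_ij = e_ji` within
#' 1e-12), unit row sums (within 1e-12; leaf rows of boundary-truncated
#' trees are exempt), and connectivity of the support graph.
#'
#' @param graph a `weighted_graph` (possibly built with `validate = FALSE`).
#' @return character vector of violation messages, empty when all
#'   invariants hold. Each message names the offending node or pair and the
#'   magnitude of the violation.
#' @export
validate_graph <- function(graph) {
  W <- graph$W
  n <- graph$n
  out <- character(0)
  neg <- which(W@x < 0)
  if (length(neg) > 0L)
    out <- c(out, sprintf("negative weight (min %.3g)", min(W@x)))
  dg <- Matrix::diag(W)
  bad <- which(dg != 0)
  if (length(bad) > 0L)
    out <- c(out, sprintf("self-loop at node %d (e_ii = %.3g)",
                          bad[1], dg[bad[1]]))
  asym <- W - Matrix::t(W)
  amax <- if (length(asym@x) > 0) max(abs(asym@x)) else 0
  if (amax > 1e-12) {
    ij <- which(abs(as.matrix(asym)) == amax, arr.ind = TRUE)[1, ]
    out <- c(out, sprintf("asymmetric pair (%d,%d): |e_ij - e_ji| = %.3g",
                          ij[1], ij[2], amax))
  }
  rs <- Matrix::rowSums(W)
  check <- setdiff(seq_len(n),
                   if (graph$boundary_truncated) graph$leaf_nodes else integer(0))
  dev <- abs(rs[check] - 1)
  if (any(dev > 1e-12)) {
    i <- check[which.max(dev)]
    out <- c(out, sprintf("row sum at node %d is %.12g (should be 1)", i, rs[i]))
  }
  # connectivity via BFS on the support
  if (n > 1L) {
    seen <- logical(n)
    seen[1] <- TRUE
    frontier <- 1L
    Wp <- as(W, "TsparseMatrix")
    adj <- split(Wp@j + 1L, Wp@i + 1L)
    while (length(frontier) > 0L) {
      nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    if (!all(seen))
      out <- c(out, sprintf("graph disconnected: %d of %d nodes reachable from node 1",
                            sum(seen), n))
  }
  out
}

#' Complete (well-mixed) colony graph
#'
#' Every cell neighbours every other with weight `1/(n-1)`: the graph model
#' of a well-mixed population.
#'
#' @param n_nodes number of cells, at least 2.
#' @return a `weighted_graph`.
#' @examples
#' g <- graph_complete(10)
#' simpson_degree(g)  # 9
#' @export
graph_complete <- function(n_nodes) {
  if (n_nodes < 2) stop("complete graph needs n_nodes >= 2")
  W <- matrix(1 / (n_nodes - 1), n_nodes, n_nodes)
  diag(W) <- 0
  weighted_graph(W)
}

#' One-dimensional periodic lattice (ring)
#'
#' Each cell is joined to its two cyclic neighbours with weight 1/2.
#'
#' @param n_nodes number of cells, at least 3 (smaller rings would create
#'   parallel edges).
#' @return a `weighted_graph`.
#' @export
graph_ring <- function(n_nodes) {
  if (n_nodes < 3) stop("ring needs n_nodes >= 3")
  i <- seq_len(n_nodes)
  W <- Matrix::sparseMatrix(
    i = c(i, i),
    j = c(i %% n_nodes + 1L, (i - 2L) %% n_nodes + 1L),
    x = 0.5, dims = c(n_nodes, n_nodes))
  weighted_graph(W, coords = matrix(i - 1L, ncol = 1))
}

# shared helper: periodic lattice from step vectors applied with weights,
# row-major coordinate -> id mapping, node (x1,...,xd) -> 1 + sum xk*side^(k-1)
periodic_lattice <- function(side, steps, step_weights) {
  dim <- ncol(steps)
  if (side < 3) stop("periodic lattice needs side >= 3")
  n <- side^dim
  grid <- as.matrix(expand.grid(rep(list(0:(side - 1)), dim)))
  colnames(grid) <- NULL
  id_of <- function(xy) {
    xy <- xy %% side
    as.integer(1 + xy %*% side^(0:(dim - 1)))
  }
  ii <- jj <- integer(0)
  xx <- numeric(0)
  for (k in seq_len(nrow(steps))) {
    tgt <- id_of(sweep(grid, 2, steps[k, ], `+`))
    ii <- c(ii, seq_len(n))
    jj <- c(jj, tgt)
    xx <- c(xx, rep(step_weights[k], n))
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  weighted_graph(W, coords = grid)
}

#' Periodic square lattice in arbitrary dimension
#'
#' Each cell has `2*dim` neighbours (one step along each axis in each
#' direction, with wraparound), each carrying weight `1/(2*dim)`.
#'
#' @param side lattice side length, at least 3.
#' @param dim spatial dimension, at least 1. `dim = 1` reduces to
#'   [graph_ring()].
#' @return a `weighted_graph` with `side^dim` nodes; coordinates map to ids
#'   row-major (node id `1 + x1 + x2*side + ...`).
#' @export
graph_lattice <- function(side, dim = 2) {
  if (dim < 1) stop("dim must be >= 1")
  steps <- rbind(diag(1, dim), diag(-1, dim))
  periodic_lattice(side, steps, rep(1 / (2 * dim), 2 * dim))
}

#' Periodic triangular lattice
#'
#' The hexagonal-packing geometry of spherical cells (e.g., *S. cerevisiae*)
#' in a two-dimensional colony. Node `(x, y)` neighbours `(x±1, y)` with
#' weight `a`, `(x, y±1)` with weight `b`, and `(x±1, y±1)` (same sign) with
#' weight `c`; uniform weights are `a = b = c = 1/6`. Unequal profiles model
#' rod-shaped cells whose shared surface area differs by direction; the
#' profile must satisfy `2(a+b+c) = 1`.
#'
#' @param side lattice side, at least 3; the lattice is periodic with
#'   `side^2` nodes.
#' @param profile either `NULL` (uniform 1/6 weights) or a numeric vector
#'   `c(a, b, c)` of per-direction weights.
#' @return a `weighted_graph`.
#' @examples
#' g <- graph_triangular(15)
#' simpson_degree(g)            # 6
#' g2 <- graph_triangular(9, profile = c(0.1, 0.15, 0.25))
#' simpson_degree(g2)           # ~5.263
#' @export
graph_triangular <- function(side, profile = NULL) {
  if (is.null(profile)) profile <- rep(1 / 6, 3)
  if (length(profile) != 3 || any(profile <= 0))
    stop("profile must be three positive weights (a, b, c)")
  if (abs(2 * sum(profile) - 1) > 1e-12)
    stop(sprintf("profile must satisfy 2(a+b+c) = 1; got 2*sum = %.12g",
                 2 * sum(profile)))
  steps <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1), c(-1, -1))
  periodic_lattice(side, steps, rep(profile, each = 2))
}

#' Depth-truncated Bethe lattice (Cayley tree)
#'
#' Finite rooted truncation of the infinite degree-`k` tree: the root and
#' every interior node have `k` neighbours, all edge weights are `1/k`, and
#' the tree is cut at the given depth. Leaf rows then sum to `1/k` rather
#' than 1; the graph is flagged `boundary_truncated` and leaf rows are
#' exempt from the row-sum invariant. Quantities read at the root converge
#' to the infinite-lattice values as depth grows (see
#' [bethe_root_retention()] for a cheap exact route at large depth).
#'
#' @param k tree degree, at least 3 (`k = 2` is the 1D lattice).
#' @param depth truncation depth, at least 1.
#' @return a `weighted_graph` with `1 + k*((k-1)^depth - 1)/(k-2)` nodes;
#'   node 1 is the root. Errors if the node count exceeds 2e5.
#' @export
graph_bethe <- function(k, depth) {
  if (k < 3) stop("Bethe lattice needs k >= 3 (k = 2 is the 1D lattice)")
  if (depth < 1) stop("depth must be >= 1")
  n <- 1 + k * ((k - 1)^depth - 1) / (k - 2)
  if (n > 2e5) stop("truncation too large (", n,
                    " nodes); use bethe_root_retention() for deep trees")
  n <- as.integer(round(n))
  parent <- integer(n)
  parent[1] <- NA_integer_
  nxt <- 2L
  frontier <- 1L
  for (d in seq_len(depth)) {
    kids_per <- if (d == 1) k else k - 1
    newfrontier <- integer(0)
    for (p in frontier) {
      kids <- seq.int(nxt, length.out = kids_per)
      parent[kids] <- p
      nxt <- nxt + kids_per
      newfrontier <- c(newfrontier, kids)
    }
    frontier <- newfrontier
  }
  ch <- 2:n
  W <- Matrix::sparseMatrix(i = c(ch, parent[ch]), j = c(parent[ch], ch),
                            x = 1 / k, dims = c(n, n))
  weighted_graph(W, boundary_truncated = TRUE, leaf_nodes = frontier)
}

#' Circulant graph fixture
#'
#' Vertex-transitive ring-like graph where node `i` is joined to
#' `i ± o` for each offset `o`, the two directions sharing the offset's
#' weight. Offset weights must sum to 1/2 so rows sum to 1. Used as a
#' randomizable family of vertex-transitive graphs in property tests.
#'
#' @param n_nodes number of nodes.
#' @param offsets named numeric vector: names are integer offsets (1 to
#'   `n_nodes/2` exclusive), values their weights, summing to 1/2.
#' @return a `weighted_graph`.
#' @examples
#' g <- graph_circulant(12, c(`1` = 0.3, `2` = 0.2))
#' simpson_degree(g)  # 1/(2*(0.09 + 0.04)) ~ 3.846
#' @export
graph_circulant <- function(n_nodes, offsets) {
  off <- as.integer(names(offsets))
  w <- as.numeric(offsets)
  if (any(is.na(off))) stop("offsets must have integer names")
  if (any(off %% n_nodes == 0)) stop("offset creates a self-loop")
  if (any(duplicated(off %% n_nodes)) || any((2L * off) %% n_nodes == 0))
    stop("offset creates duplicate edges on ", n_nodes, " nodes")
  if (abs(sum(w) - 0.5) > 1e-12)
    stop("offset weights must sum to 1/2 (applied to both directions)")
  i <- seq_len(n_nodes)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  for (k in seq_along(off)) {
    jp <- (i - 1L + off[k]) %% n_nodes + 1L
    jm <- (i - 1L - off[k]) %% n_nodes + 1L
    ii <- c(ii, i, i)
    jj <- c(jj, jp, jm)
    xx <- c(xx, rep(w[k], 2L * n_nodes))
  }
  weighted_graph(Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                      dims = c(n_nodes, n_nodes)))
}

#' Simpson degree of a colony graph
#'
#' The Simpson diversity of a cell's neighbourhood,
#' `kappa = 1 / sum_j e_ij^2`: an effective neighbour count that equals the
#' ordinary degree on unweighted regular graphs and is smaller when weights
#' are uneven.
#'
#' @param graph a `weighted_graph`.
#' @param node node at which to evaluate (default 1; on vertex-transitive
#'   graphs the value is node-independent, which [retention_fractions()]
#'   relies on).
#' @return the Simpson degree, a real number `>= 1`.
#' @export
simpson_degree <- function(graph, node = 1L) {
  row <- graph$W[node, ]
  s2 <- sum(row^2)
  if (s2 == 0) stop("node ", node, " is isolated (zero row)")
  1 / s2
}

# TRUE iff every node carries the same multiset of incident edge weights
# (a cheap necessary condition for vertex-transitivity used in tests)
has_uniform_weight_profile <- function(graph) {
  Wp <- as(graph$W, "TsparseMatrix")
  rows <- split(Wp@x, Wp@i)
  prof <- vapply(rows, function(v) paste(sort(round(v, 12)), collapse = ","), "")
  length(unique(prof)) == 1L
}
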