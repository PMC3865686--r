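#' Read a weighted graph from an edge-list TSV
#'
#' Expects a tab-separated file with header `i<TAB>j<TAB>weight`, one row
#' per unordered node pair, node ids 0-based (they are shifted to the
#' package's 1-based ids on load). The loader symmetrizes (each listed pair
#' gets the weight in both directions), validates all graph invariants,
#' and attaches a load report.
#'
#' @param path file path.
#' @return a `weighted_graph` with attribute `load_report` (list with
#'   `n_nodes`, `n_edges`, `path`).
#' @export
read_edge_list <- function(path) {
  header <- utils::read.delim(path, nrows = 1, header = TRUE)
  if (!identical(tolower(names(header))[1:3], c("i", "j", "weight")))
    stop("edge list must start with header 'i<TAB>j<TAB>weight'; found: ",
         paste(names(header), collapse = ", "))
  df <- utils::read.delim(path, header = TRUE)
  if (nrow(df) == 0) stop("edge list has no rows")
  if (any(df$i == df$j))
    stop("self-loop in edge list at node ", df$i[which(df$i == df$j)[1]])
  if (any(df$weight < 0)) stop("negative edge weight in file")
  key_f <- paste(df$i, df$j)
  key_r <- paste(df$j, df$i)
  dup <- match(key_r, key_f)
  clash <- which(!is.na(dup) & abs(df$weight - df$weight[dup]) > 1e-12)
  if (length(clash) > 0)
    stop(sprintf("asymmetric duplicate for pair (%d,%d): weights %g and %g",
                 df$i[clash[1]], df$j[clash[1]], df$weight[clash[1]],
                 df$weight[dup[clash[1]]]))
  df <- df[is.na(dup) | key_f < key_r, ]   # keep one row per unordered pair
  n <- max(df$i, df$j) + 1L
  W <- Matrix::sparseMatrix(i = c(df$i, df$j) + 1L, j = c(df$j, df$i) + 1L,
                            x = c(df$weight, df$weight), dims = c(n, n))
  g <- weighted_graph(W)
  attr(g, "load_report") <- list(n_nodes = n, n_edges = nrow(df), path = path)
  g
}

#' Write a weighted graph as an edge-list TSV
#'
#' Inverse of [read_edge_list()]: one row per unordered pair, 0-based ids,
#' full-precision weights so a write/read round trip is bit-compatible.
#'
#' @param graph a `weighted_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  Wp <- as(graph$W, "TsparseMatrix")
  keep <- Wp@i < Wp@j
  df <- data.frame(i = Wp@i[keep], j = Wp@j[keep],
                   weight = sprintf("%.17g", Wp@x[keep]))
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize results to JSON or TSV
#'
#' `sharing_summary`, `fixation_estimate`, `yeast_estimate` and plain
#' lists/data frames serialize to JSON (lossless round trip via
#' [jsonlite]); data frames (e.g. threshold sweeps) can also be written as
#' TSV.
#'
#' @param object the result object.
#' @param path output path.
#' @param format `"json"` or `"tsv"` (TSV for data frames only).
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(object)) stop("tsv format requires a data frame")
    utils::write.table(object, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(unclass(object), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Table of critical benefit-to-cost ratios over a lambda grid
#'
#' Convenience sweep used by the command-line `threshold` subcommand: for a
#' graph (or closed-form family) and a vector of diffusion parameters,
#' tabulate `phi0`, `phi1` and the critical `b/c`.
#'
#' @param graph a `weighted_graph`.
#' @param lambdas numeric vector of diffusion parameters.
#' @param decay decay ratio `d`.
#' @return data frame with columns `lambda`, `decay`, `phi0`, `phi1`,
#'   `kappa`, `critical_bc`.
#' @export
threshold_table <- function(graph, lambdas, decay = 0) {
  rows <- lapply(lambdas, function(l) {
    s <- retention_fractions(graph, lambda = l, decay = decay)
    data.frame(lambda = l, decay = decay, phi0 = s$phi0, phi1 = s$phi1,
               kappa = s$kappa, critical_bc = s$critical_bc)
  })
  do.call(rbind, rows)
}
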