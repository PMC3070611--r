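# Simplified undirected projection used by both centrality measures:
# directions dropped, parallel arcs collapsed, self-loops removed.
.undirected_simple <- function(network) {
  g <- .as_igraph(network)
  g <- igraph::as_undirected(g, mode = "collapse")
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Scaled betweenness centrality
#'
#' For each node i, sums over all node pairs (s, t) the fraction of
#' shortest s-t paths passing through i, scaled by 2 / ((n-1)(n-2)) so the
#' value lies in \[0, 1\] for any network. Computed on the simplified
#' undirected projection; pairs with no connecting path contribute 0.
#' Networks with fewer than 3 nodes have no interior pairs and return all
#' zeros.
#'
#' @param network A `bio_network` or `condensed_network`.
#' @return Named numeric vector (one value per node).
#' @export
scaled_betweenness <- function(network) {
  g <- .undirected_simple(network)
  n <- igraph::vcount(g)
  if (n == 0) stop("network is empty")
  if (n < 3) {
    return(stats::setNames(rep(0, n), igraph::V(g)$name))
  }
  b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE,
                           weights = NA)
  stats::setNames(as.numeric(b), igraph::V(g)$name)
}

#' Degree centrality
#'
#' Node degree on the simplified undirected projection divided by (n - 1);
#' in \[0, 1\] for simple graphs.
#'
#' @param network A `bio_network` or `condensed_network`.
#' @return Named numeric vector.
#' @export
degree_centrality <- function(network) {
  g <- .undirected_simple(network)
  n <- igraph::vcount(g)
  if (n < 2) stop("degree centrality needs at least 2 nodes")
  d <- igraph::degree(g, loops = FALSE) / (n - 1)
  stats::setNames(as.numeric(d), igraph::V(g)$name)
}

#' Centrality report for genes of interest on a reference network
#'
#' Computes scaled betweenness and degree centrality for every node of the
#' reference network, reports the rows for the requested genes, and flags
#' genes exceeding both network-wide means — the signal used to nominate
#' hub-node candidates. Means are arithmetic means over all reference
#' nodes and are recomputed from the network, never cached.
#'
#' @param reference A `bio_network` (e.g. built from a reference
#'   interaction table).
#' @param genes_of_interest Character vector of gene symbols.
#' @param alias_table Optional `alias_table` applied to the genes of
#'   interest.
#' @return A `centrality_report`: list with `rows` (data frame: `gene`,
#'   `betweenness`, `degree_centrality`, `above_both_means`),
#'   `mean_betweenness`, `mean_degree`, `n_nodes`.
#' @export
centrality_report <- function(reference, genes_of_interest,
                              alias_table = NULL) {
  stopifnot(inherits(reference, "bio_network"))
  genes <- unique(resolve_aliases(genes_of_interest, alias_table,
                                  warn = FALSE))
  b <- scaled_betweenness(reference)
  d <- degree_centrality(reference)
  mb <- mean(b)
  md <- mean(d)
  present <- genes[genes %in% names(b)]
  if (length(present) == 0) {
    warning("no gene of interest is present in the reference network",
            call. = FALSE)
  }
  rows <- data.frame(
    gene = present,
    betweenness = unname(b[present]),
    degree_centrality = unname(d[present]),
    above_both_means = unname(b[present] > mb & d[present] > md),
    stringsAsFactors = FALSE)
  structure(list(rows = rows, mean_betweenness = mb, mean_degree = md,
                 n_nodes = length(b)),
            class = "centrality_report")
}

#' Write a centrality report as TSV
#'
#' Columns: gene, betweenness, degree_centrality, above_both_means; the
#' network-wide means and size go into header comment lines.
#'
#' @param report A `centrality_report`.
#' @param path Output path.
#' @export
write_centrality_report <- function(report, path) {
  stopifnot(inherits(report, "centrality_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_nodes=%d mean_betweenness=%.17g mean_degree=%.17g",
                     report$n_nodes, report$mean_betweenness,
                     report$mean_degree), con)
  utils::write.table(report$rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.centrality_report <- function(x, ...) {
  cat("<centrality_report> ", nrow(x$rows), " gene(s) on a ",
      x$n_nodes, "-node reference (mean betweenness ",
      format(x$mean_betweenness, digits = 3), ", mean degree ",
      format(x$mean_degree, digits = 3), ")\n", sep = "")
  invisible(x)
}
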