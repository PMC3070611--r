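# Internal constructor: edges must already be deduplicated arc rows with
# columns source, target, kind, provenance, interaction_id.
.bio_network <- function(edges, vertices = NULL) {
  if (is.null(vertices)) {
    vertices <- sort(unique(c(edges$source, edges$target)), method = "radix")
  } else {
    vertices <- sort(unique(c(vertices, edges$source, edges$target)),
                     method = "radix")
  }
  rownames(edges) <- NULL
  structure(list(vertices = vertices, edges = edges,
                 n_interactions = length(unique(edges$interaction_id))),
            class = "bio_network")
}

.empty_net_edges <- function() {
  data.frame(source = character(), target = character(), kind = character(),
             provenance = character(), interaction_id = character(),
             stringsAsFactors = FALSE)
}

#' Build an integrated biological network from interaction records
#'
#' All mentioned symbols become vertices. Duplicated `(source, target, kind)`
#' arcs are collapsed to one, so the same interaction reported by several
#' databases enters the network once. Undirected records (e.g. protein
#' binding) are expanded to two directed arcs that share one interaction
#' identity, so they count as a single interaction.
#'
#' @param records An `interaction_table` (see [read_interactions()]) or a
#'   data frame with the same columns.
#' @return A `bio_network`: list with `vertices` (sorted character vector),
#'   `edges` (arc data frame) and `n_interactions` (deduplicated count).
#' @export
build_network <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    return(.bio_network(.empty_net_edges()))
  }
  stopifnot(all(c("source", "target", "kind", "directed") %in% names(records)))
  if (is.null(records$provenance)) records$provenance <- "unknown"
  dir <- records[records$directed, , drop = FALSE]
  und <- records[!records$directed, , drop = FALSE]
  # interaction identity: ordered triple for directed arcs, unordered pair
  # for undirected records (so the two expansion arcs share one identity)
  mk <- function(s, t, k, tag) paste(s, t, k, tag, sep = "\x1f")
  rows <- list()
  if (nrow(dir)) {
    rows[[length(rows) + 1L]] <- data.frame(
      source = dir$source, target = dir$target, kind = dir$kind,
      provenance = dir$provenance,
      interaction_id = mk(dir$source, dir$target, dir$kind, "d"),
      stringsAsFactors = FALSE)
  }
  if (nrow(und)) {
    lo <- pmin(und$source, und$target)
    hi <- pmax(und$source, und$target)
    id <- mk(lo, hi, und$kind, "u")
    rows[[length(rows) + 1L]] <- data.frame(
      source = c(und$source, und$target),
      target = c(und$target, und$source),
      kind = c(und$kind, und$kind),
      provenance = c(und$provenance, und$provenance),
      interaction_id = c(id, id), stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, rows)
  edges <- edges[!duplicated(edges[c("source", "target", "kind")]), ,
                 drop = FALSE]
  .bio_network(edges, vertices = unique(c(records$source, records$target)))
}

#' Condense regulatory cycles into supernodes
#'
#' Genes that regulate each other form directed cycles, which break
#' simple-shortest-path semantics; condensation merges each cyclic group
#' into a single supernode whose label joins the member symbols with `+`.
#' Self-loops (auto-regulation) are removed in every mode.
#'
#' Modes:
#' \describe{
#'   \item{`scc` (default)}{merge every strongly connected component with at
#'     least two vertices; the quotient graph is guaranteed acyclic.}
#'   \item{`two_cycle`}{merge maximal groups connected through
#'     mutual-regulation pairs (arcs in both directions), reproducing the
#'     pairwise merging of e.g. AR and DDIT3; longer cycles survive.}
#'   \item{`none`}{only remove self-loops.}
#' }
#'
#' @param network A `bio_network`.
#' @param mode Condensation mode, see above.
#' @return A `condensed_network`: list with `network` (a `bio_network` over
#'   supernode/gene labels), `merge_map` (named list, supernode label ->
#'   member genes; singletons absent) and `mode`.
#' @export
condense <- function(network, mode = c("scc", "two_cycle", "none")) {
  stopifnot(inherits(network, "bio_network"))
  mode <- match.arg(mode)
  edges <- network$edges
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  vertices <- network$vertices

  label_of <- stats::setNames(vertices, vertices)
  merge_map <- list()
  if (mode != "none" && length(vertices) > 1 && nrow(edges) > 0) {
    groups <- switch(mode,
      scc = .scc_groups(edges, vertices),
      two_cycle = .mutual_groups(edges, vertices))
    for (g in groups) {
      lab <- paste(sort(g, method = "radix"), collapse = "+")
      label_of[g] <- lab
      merge_map[[lab]] <- sort(g, method = "radix")
    }
  }
  new_edges <- edges
  if (nrow(new_edges)) {
    new_edges$source <- unname(label_of[new_edges$source])
    new_edges$target <- unname(label_of[new_edges$target])
    new_edges <- new_edges[new_edges$source != new_edges$target, ,
                           drop = FALSE]
    new_edges <- new_edges[!duplicated(new_edges[c("source", "target",
                                                   "kind")]), , drop = FALSE]
  }
  net <- .bio_network(new_edges, vertices = unique(unname(label_of)))
  structure(list(network = net, merge_map = merge_map, mode = mode),
            class = "condensed_network")
}

.scc_groups <- function(edges, vertices) {
  g <- igraph::graph_from_data_frame(
    edges[c("source", "target")], directed = TRUE, vertices = vertices)
  comp <- igraph::components(g, mode = "strong")
  memb <- split(names(comp$membership), comp$membership)
  Filter(function(x) length(x) >= 2, memb)
}

.mutual_groups <- function(edges, vertices) {
  key <- paste(edges$source, edges$target, sep = "\x1f")
  rev_key <- paste(edges$target, edges$source, sep = "\x1f")
  mutual <- edges[key %in% rev_key, c("source", "target"), drop = FALSE]
  if (nrow(mutual) == 0) return(list())
  g <- igraph::graph_from_data_frame(mutual, directed = FALSE,
                                     vertices = vertices)
  comp <- igraph::components(g)
  memb <- split(names(comp$membership), comp$membership)
  Filter(function(x) length(x) >= 2, memb)
}

#' Expand a condensed path to its constituent genes
#'
#' Supernodes on the path expand to all member genes; while scoring, every
#' member contributes its own differential-expression z-score.
#'
#' @param path A `pathway` object or character vector of condensed vertex
#'   labels.
#' @param x A `condensed_network` (vertex membership is then validated) or a
#'   plain merge map (named list, supernode -> members).
#' @return Sorted character vector of gene symbols.
#' @export
expand_path <- function(path, x) {
  labels <- if (inherits(path, "pathway")) path$vertices else path
  if (inherits(x, "condensed_network")) {
    missing <- setdiff(labels, x$network$vertices)
    if (length(missing)) {
      stop("vertex not in condensed network: ",
           paste(missing, collapse = ", "))
    }
    mm <- x$merge_map
  } else {
    mm <- x
  }
  genes <- unlist(lapply(labels, function(l) {
    if (!is.null(mm[[l]])) mm[[l]] else l
  }), use.names = FALSE)
  sort(unique(genes), method = "radix")
}

# igraph view of a network; edge attribute `weight` drives all shortest-path
# queries. `weights` may be NULL (unit), a numeric vector per arc row, or a
# function(edges) -> numeric.
.as_igraph <- function(x, weights = NULL) {
  net <- if (inherits(x, "condensed_network")) x$network else x
  stopifnot(inherits(net, "bio_network"))
  w <- .edge_weights(net$edges, weights)
  df <- net$edges[c("source", "target")]
  df$weight <- w
  igraph::graph_from_data_frame(df, directed = TRUE,
                                vertices = net$vertices)
}

.edge_weights <- function(edges, weights) {
  m <- nrow(edges)
  w <- if (is.null(weights)) {
    rep(1, m)
  } else if (is.function(weights)) {
    as.numeric(weights(edges))
  } else {
    as.numeric(weights)
  }
  if (length(w) == 1L) w <- rep(w, m)
  if (length(w) != m) stop("weights must supply one value per arc")
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("edge weights must be finite and nonnegative")
  }
  w
}

#' @export
print.bio_network <- function(x, ...) {
  cat("<bio_network> ", length(x$vertices), " vertices, ",
      nrow(x$edges), " arcs (", x$n_interactions, " interactions)\n",
      sep = "")
  invisible(x)
}

#' @export
print.condensed_network <- function(x, ...) {
  cat("<condensed_network mode=", x$mode, "> ",
      length(x$network$vertices), " vertices, ", nrow(x$network$edges),
      " arcs, ", length(x$merge_map), " supernode(s)\n", sep = "")
  invisible(x)
}
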