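#' Select seed genes
#'
#' Seeds are the endpoints between which candidate pathways are mined. They
#' come from four sources, each tagged with its provenance: genes of direct
#' user interest (`user_interest`), transcription factors implicated in drug
#' resistance (`resistance`), genes with DNA damage/repair annotations
#' (`dna_damage`), and genes whose differential-expression p-value falls
#' below `p_threshold` (`de_selected`). A gene named by several sources
#' keeps the first tag in that priority order.
#'
#' Seeds absent from the network are reported in the `missing` attribute
#' with a warning rather than failing; if no candidate maps into the
#' network at all, that is an error.
#'
#' @param network A `bio_network` (the uncondensed integrated network).
#' @param user_genes,tf_genes,annotation_genes Character vectors of symbols.
#' @param gene_scores Optional `gene_score_table` used for `de_selected`.
#' @param p_threshold Threshold in (0,1) for differential-expression seeds.
#' @return A `seed_set` data frame (`gene`, `provenance`) with attribute
#'   `missing`.
#' @export
select_seeds <- function(network, user_genes = character(),
                         annotation_genes = character(),
                         tf_genes = character(),
                         gene_scores = NULL, p_threshold = 0.05) {
  stopifnot(inherits(network, "bio_network"))
  if (!is.null(gene_scores)) {
    stopifnot(p_threshold > 0, p_threshold < 1)
  }
  de_genes <- if (!is.null(gene_scores)) {
    gene_scores$gene[gene_scores$p < p_threshold]
  } else {
    character()
  }
  cand <- data.frame(
    gene = c(user_genes, tf_genes, annotation_genes, de_genes),
    provenance = c(rep("user_interest", length(user_genes)),
                   rep("resistance", length(tf_genes)),
                   rep("dna_damage", length(annotation_genes)),
                   rep("de_selected", length(de_genes))),
    stringsAsFactors = FALSE)
  cand <- cand[!duplicated(cand$gene), , drop = FALSE]
  if (nrow(cand) == 0) stop("no seed candidates supplied")
  present <- cand$gene %in% network$vertices
  missing <- cand$gene[!present]
  if (length(missing)) {
    warning(length(missing), " seed(s) not in network: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  seeds <- cand[present, , drop = FALSE]
  if (nrow(seeds) == 0) stop("no seed candidate is present in the network")
  rownames(seeds) <- NULL
  structure(seeds, class = c("seed_set", "data.frame"), missing = missing)
}

# Lexicographically smallest minimum-weight simple path source -> target on
# an igraph with `weight` edge attribute. Returns list(vertices, weight) or
# NULL. Greedy construction: at each step take the smallest-label successor
# that still lies on some minimum-weight completion (checked against
# distances to the target). With positive weights a minimum-weight
# completion can never revisit the prefix, so the walk stays simple.
.lex_shortest <- function(g, source, target) {
  source <- unname(source)
  target <- unname(target)
  vn <- igraph::V(g)$name
  if (!(source %in% vn) || !(target %in% vn)) return(NULL)
  if (source == target) return(list(vertices = source, weight = 0))
  d_t <- igraph::distances(g, v = vn, to = target, mode = "out")[, 1]
  names(d_t) <- vn
  total <- d_t[[source]]
  if (!is.finite(total)) return(NULL)
  path <- character()
  cur <- source
  cum <- 0
  for (step in seq_len(length(vn) + 1L)) {
    path <- c(path, cur)
    if (cur == target) return(list(vertices = path, weight = total))
    es <- igraph::incident(g, cur, mode = "out")
    if (length(es) == 0) return(NULL)
    heads <- igraph::head_of(g, es)$name
    ws <- igraph::edge_attr(g, "weight", es)
    if (is.null(ws)) ws <- rep(1, length(es))
    ok <- !(heads %in% path) & is.finite(d_t[heads]) &
      abs(cum + ws + d_t[heads] - total) < 1e-9
    if (!any(ok)) return(NULL)
    nxt <- sort(unique(heads[ok]), method = "radix")[1]
    cum <- cum + min(ws[ok & heads == nxt])
    cur <- nxt
  }
  stop("shortest-path construction failed to terminate (zero-weight cycle?)")
}

# total weight of a vertex sequence using the minimum parallel-arc weight at
# each step (matches what distance queries see)
.seq_weight <- function(ends, ws, vseq) {
  if (length(vseq) < 2) return(0)
  total <- 0
  for (i in seq_len(length(vseq) - 1L)) {
    sel <- ends[, 1] == vseq[i] & ends[, 2] == vseq[i + 1L]
    if (!any(sel)) stop("vertex sequence uses a missing arc: ",
                        vseq[i], " -> ", vseq[i + 1L])
    total <- total + min(ws[sel])
  }
  total
}

# Reconstruct a pathway object (ordered arcs with kinds) from a condensed
# vertex sequence; among parallel arcs the minimum-weight one wins, ties
# broken by lexicographic kind.
.path_from_vertices <- function(network, vseq, weights = NULL,
                                source_seed = NULL, target_seed = NULL) {
  net <- if (inherits(network, "condensed_network")) network$network else network
  edges <- net$edges
  w <- .edge_weights(edges, weights)
  rows <- integer()
  total <- 0
  if (length(vseq) > 1) {
    for (i in seq_len(length(vseq) - 1L)) {
      sel <- which(edges$source == vseq[i] & edges$target == vseq[i + 1L])
      if (!length(sel)) {
        # undirected projection fallback: accept the reverse arc
        sel <- which(edges$source == vseq[i + 1L] & edges$target == vseq[i])
      }
      if (!length(sel)) stop("no arc ", vseq[i], " -> ", vseq[i + 1L])
      best <- sel[w[sel] == min(w[sel])]
      best <- best[order(edges$kind[best], method = "radix")][1]
      rows <- c(rows, best)
      total <- total + w[best]
    }
  }
  earc <- edges[rows, c("source", "target", "kind"), drop = FALSE]
  rownames(earc) <- NULL
  structure(list(
    vertices = vseq,
    edges = earc,
    length = length(vseq) - 1L,
    weight = total,
    source_seed = if (is.null(source_seed)) vseq[1] else source_seed,
    target_seed = if (is.null(target_seed)) vseq[length(vseq)] else target_seed
  ), class = "pathway")
}

#' Minimum-weight simple path between two vertices
#'
#' Returns the minimum-total-weight simple path, breaking ties by the
#' lexicographic order of the vertex-label sequence so results are
#' reproducible. Unreachable targets give `NULL`. `source == target` yields
#' the degenerate zero-length path of one vertex.
#'
#' @param network A `condensed_network` (or `bio_network`).
#' @param source,target Vertex labels.
#' @param weights `NULL` for unit (hop-count) weights, a numeric vector with
#'   one nonnegative value per arc, or a `function(edges)` returning one.
#' @return A `pathway` or `NULL`.
#' @export
shortest_path <- function(network, source, target, weights = NULL) {
  g <- .as_igraph(network, weights)
  vn <- igraph::V(g)$name
  if (!(source %in% vn)) stop("source vertex not in network: ", source)
  if (!(target %in% vn)) stop("target vertex not in network: ", target)
  res <- .lex_shortest(g, source, target)
  if (is.null(res)) return(NULL)
  .path_from_vertices(network, res$vertices, weights)
}

#' k shortest simple paths (Yen's algorithm)
#'
#' Enumerates up to `k` simple paths from `source` to `target` in
#' nondecreasing total weight, with ties broken by lexicographic order of
#' the vertex sequence; the result is therefore the exact prefix of the
#' full enumeration of simple paths sorted by (weight, label sequence).
#' Spur paths are recomputed on reduced graphs in the classic Yen scheme.
#'
#' @inheritParams shortest_path
#' @param k Maximum number of paths (>= 1).
#' @return List of `pathway` objects (possibly empty).
#' @export
yen_ksp <- function(network, source, target, k, weights = NULL) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    stop("k must be a positive integer")
  }
  k <- as.integer(k)
  g <- .as_igraph(network, weights)
  vn <- igraph::V(g)$name
  if (!(source %in% vn)) stop("source vertex not in network: ", source)
  if (!(target %in% vn)) stop("target vertex not in network: ", target)
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  ws <- igraph::edge_attr(g, "weight")
  if (is.null(ws)) ws <- rep(1, nrow(ends))

  first <- .lex_shortest(g, source, target)
  if (is.null(first)) return(list())
  A <- list(first)
  a_keys <- paste(first$vertices, collapse = "\x1f")
  cand_v <- list()
  cand_w <- numeric()
  cand_keys <- character()

  while (length(A) < k) {
    prev <- A[[length(A)]]$vertices
    if (length(prev) >= 2) {
      for (j in seq_len(length(prev) - 1L)) {
        spur <- prev[j]
        root <- prev[seq_len(j)]
        # arcs to remove: next hops of accepted paths sharing this root
        del <- integer()
        for (p in A) {
          pv <- p$vertices
          if (length(pv) > j && identical(pv[seq_len(j)], root)) {
            del <- c(del, which(ends[, 1] == spur & ends[, 2] == pv[j + 1L]))
          }
        }
        gg <- igraph::delete_edges(g, unique(del))
        if (j > 1) gg <- igraph::delete_vertices(gg, root[seq_len(j - 1L)])
        sp <- .lex_shortest(gg, spur, target)
        if (!is.null(sp)) {
          full <- c(root[seq_len(j - 1L)], sp$vertices)
          key <- paste(full, collapse = "\x1f")
          if (!(key %in% a_keys) && !(key %in% cand_keys)) {
            root_w <- .seq_weight(ends, ws, root)
            cand_v[[length(cand_v) + 1L]] <- full
            cand_w <- c(cand_w, root_w + sp$weight)
            cand_keys <- c(cand_keys, key)
          }
        }
      }
    }
    if (length(cand_v) == 0) break
    ord <- order(cand_w, cand_keys, method = "radix")[1]
    A[[length(A) + 1L]] <- list(vertices = cand_v[[ord]],
                                weight = cand_w[ord])
    a_keys <- c(a_keys, cand_keys[ord])
    cand_v <- cand_v[-ord]
    cand_w <- cand_w[-ord]
    cand_keys <- cand_keys[-ord]
  }
  lapply(A, function(p) .path_from_vertices(network, p$vertices, weights))
}

#' Mine candidate pathways between all seed pairs
#'
#' Runs [yen_ksp()] for every ordered pair of distinct seed vertices on the
#' condensed network and pools the results, removing duplicate vertex
#' sequences. Seeds that fall inside the same supernode are skipped (their
#' connecting cycle was merged away) with a message, as are seeds absent
#' from the network.
#'
#' @param network A `condensed_network`.
#' @param seeds A `seed_set` or character vector of seed gene symbols.
#' @param k Paths per ordered pair (default 5).
#' @param weights Edge weights as in [shortest_path()].
#' @param ordered If `FALSE`, each unordered pair is mined once on the
#'   undirected projection of the network.
#' @param quiet Suppress progress messages.
#' @return List of `pathway` objects sorted by (weight, vertex sequence).
#' @export
mine_pathways <- function(network, seeds, k = 5, weights = NULL,
                          ordered = TRUE, quiet = TRUE) {
  stopifnot(inherits(network, "condensed_network"))
  genes <- if (inherits(seeds, "seed_set")) seeds$gene else as.character(seeds)
  genes <- unique(genes)
  # map each seed gene to its condensed vertex (itself or its supernode)
  vlab <- vapply(genes, function(gn) {
    if (gn %in% network$network$vertices) return(gn)
    for (lab in names(network$merge_map)) {
      if (gn %in% network$merge_map[[lab]]) return(lab)
    }
    NA_character_
  }, character(1))
  absent <- genes[is.na(vlab)]
  if (length(absent) && !quiet) {
    message("seed(s) not in network, skipped: ",
            paste(absent, collapse = ", "))
  }
  genes <- genes[!is.na(vlab)]
  vlab <- vlab[!is.na(vlab)]
  if (length(unique(vlab)) < 2) {
    stop("need at least 2 seeds mapped to distinct network vertices")
  }
  search_net <- network
  if (!ordered) {
    und <- network$network$edges
    flip <- und
    flip$source <- und$target
    flip$target <- und$source
    both <- rbind(und, flip)
    both <- both[!duplicated(both[c("source", "target", "kind")]), ,
                 drop = FALSE]
    search_net <- structure(
      list(network = .bio_network(both, network$network$vertices),
           merge_map = network$merge_map, mode = network$mode),
      class = "condensed_network")
  }
  idx <- seq_along(genes)
  pairs <- expand.grid(i = idx, j = idx)
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  if (!ordered) pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
  out <- list()
  seen <- character()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (vlab[i] == vlab[j]) {
      if (!quiet) message("seeds ", genes[i], " and ", genes[j],
                          " share supernode ", vlab[i], ", pair skipped")
      next
    }
    ps <- yen_ksp(search_net, vlab[i], vlab[j], k, weights)
    for (p in ps) {
      key <- paste(p$vertices, collapse = "\x1f")
      if (key %in% seen) next
      seen <- c(seen, key)
      p$source_seed <- genes[i]
      p$target_seed <- genes[j]
      out[[length(out) + 1L]] <- p
    }
  }
  if (length(out)) {
    keys <- vapply(out, function(p) paste(p$vertices, collapse = "\x1f"),
                   character(1))
    wts <- vapply(out, function(p) p$weight, numeric(1))
    out <- out[order(wts, keys, method = "radix")]
  }
  out
}

#' @export
print.pathway <- function(x, ...) {
  cat("<pathway> ", paste(x$vertices, collapse = " -> "),
      "  (", x$length, " hops, weight ", format(x$weight), ")\n", sep = "")
  invisible(x)
}
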