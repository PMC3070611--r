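# Normalized view of anything comparable: labels, arcs and per-label member
# sets. Supernode labels ("A+B") expand to their member genes; an explicit
# merge map overrides the label-splitting heuristic.
.graph_parts <- function(x, merge_map = NULL) {
  if (inherits(x, "scored_pathway")) x <- x$pathway
  if (inherits(x, "pathway")) {
    labels <- x$vertices
    edges <- x$edges
  } else if (inherits(x, "condensed_network")) {
    labels <- x$network$vertices
    edges <- x$network$edges[c("source", "target", "kind")]
    if (is.null(merge_map)) merge_map <- x$merge_map
  } else if (inherits(x, "bio_network")) {
    labels <- x$vertices
    edges <- x$edges[c("source", "target", "kind")]
  } else {
    stop("cannot compare object of class ", paste(class(x), collapse = "/"))
  }
  members <- lapply(labels, function(l) {
    if (!is.null(merge_map[[l]])) merge_map[[l]] else
      strsplit(l, "+", fixed = TRUE)[[1]]
  })
  names(members) <- labels
  list(labels = labels, edges = edges, members = members)
}

#' Vertex correspondences between two networks
#'
#' Two vertices correspond when they carry the same official gene symbol;
#' supernodes correspond when their member sets share at least one symbol.
#' Correspondences can be many-to-many.
#'
#' @param a,b `bio_network`, `condensed_network`, `pathway` or
#'   `scored_pathway` objects (alias-resolved).
#' @param merge_map_a,merge_map_b Optional explicit merge maps.
#' @return Data frame of class `correspondence` with columns `label_a`,
#'   `label_b`.
#' @export
correspond <- function(a, b, merge_map_a = NULL, merge_map_b = NULL) {
  pa <- .graph_parts(a, merge_map_a)
  pb <- .graph_parts(b, merge_map_b)
  ta <- data.frame(
    member = unlist(pa$members, use.names = FALSE),
    label_a = rep(names(pa$members), lengths(pa$members)),
    stringsAsFactors = FALSE)
  tb <- data.frame(
    member = unlist(pb$members, use.names = FALSE),
    label_b = rep(names(pb$members), lengths(pb$members)),
    stringsAsFactors = FALSE)
  m <- merge(ta, tb, by = "member")
  out <- unique(m[c("label_a", "label_b")])
  out <- out[order(out$label_a, out$label_b, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("correspondence", "data.frame")
  out
}

#' Intersect two pathways or networks by label correspondence
#'
#' The result is reported at the gene-symbol level: its vertices are the
#' symbols present in both inputs (supernode members matched
#' individually). Edge survival depends on the mode:
#' \describe{
#'   \item{`strict` (default)}{an arc survives only if the other input
#'     contains an arc of the same kind between corresponding endpoints,
#'     in the same direction — both vertex labels and edge labels must
#'     agree.}
#'   \item{`relaxed`}{an arc survives whenever both its endpoints have
#'     corresponding vertices in the other input, regardless of that
#'     input's own arcs; qualifying arcs are taken from both inputs so the
#'     operation stays commutative.}
#' }
#' Strict-mode edges are always a subset of relaxed-mode edges.
#'
#' @param a,b Inputs as in [correspond()].
#' @param mode `"strict"` or `"relaxed"`.
#' @return An `intersection_result`: list with `vertices` (sorted symbols),
#'   `edges` (`source`, `target`, `kind`) and `provenance`.
#' @export
intersect_pathways <- function(a, b, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  pa <- .graph_parts(a)
  pb <- .graph_parts(b)
  union_a <- unique(unlist(pa$members, use.names = FALSE))
  union_b <- unique(unlist(pb$members, use.names = FALSE))
  common <- sort(intersect(union_a, union_b), method = "radix")
  edges <- .empty_kind_edges()
  if (length(common)) {
    if (mode == "strict") {
      edges <- rbind(.strict_edges(pa, pb))
    } else {
      edges <- rbind(.relaxed_edges(pa, common),
                     .relaxed_edges(pb, common))
    }
    edges <- edges[!duplicated(edges), , drop = FALSE]
    edges <- edges[order(edges$source, edges$target, edges$kind,
                         method = "radix"), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(vertices = common, edges = edges,
                 provenance = c(a = .input_id(a), b = .input_id(b))),
            class = "intersection_result")
}

.empty_kind_edges <- function() {
  data.frame(source = character(), target = character(),
             kind = character(), stringsAsFactors = FALSE)
}

.input_id <- function(x) {
  if (inherits(x, "scored_pathway")) x <- x$pathway
  if (inherits(x, "pathway")) paste(x$vertices, collapse = ">") else
    paste0("network[", length(.graph_parts(x)$labels), "]")
}

# strict rule: arc of a survives iff b has a same-kind arc between
# corresponding endpoints; surviving arcs are expanded to the shared member
# symbols of the matched endpoint pairs
.strict_edges <- function(pa, pb) {
  ea <- pa$edges; eb <- pb$edges
  out <- list()
  for (i in seq_len(nrow(ea))) {
    ms_a <- pa$members[[ea$source[i]]]
    mt_a <- pa$members[[ea$target[i]]]
    cand <- which(eb$kind == ea$kind[i])
    for (j in cand) {
      ss <- intersect(ms_a, pb$members[[eb$source[j]]])
      tt <- intersect(mt_a, pb$members[[eb$target[j]]])
      if (length(ss) && length(tt)) {
        out[[length(out) + 1L]] <- expand.grid(
          source = ss, target = tt, kind = ea$kind[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(.empty_kind_edges())
  do.call(rbind, out)
}

.relaxed_edges <- function(p, common) {
  e <- p$edges
  out <- list()
  for (i in seq_len(nrow(e))) {
    ss <- intersect(p$members[[e$source[i]]], common)
    tt <- intersect(p$members[[e$target[i]]], common)
    if (length(ss) && length(tt)) {
      out[[length(out) + 1L]] <- expand.grid(
        source = ss, target = tt, kind = e$kind[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_kind_edges())
  do.call(rbind, out)
}

#' Intersect two pathway sets
#'
#' Forms the pairwise intersection over the Cartesian product of the two
#' sets, discards empty results (no shared gene) and collapses duplicates
#' (identical vertex and edge sets). Each surviving result records the
#' indices of the contributing pathway pairs.
#'
#' @param set_a,set_b Non-empty lists of `pathway`/`scored_pathway`.
#' @param mode Passed to [intersect_pathways()].
#' @return List of `intersection_result` objects, each with a `pairs`
#'   attribute (data frame of contributing `a`/`b` indices).
#' @export
intersect_sets <- function(set_a, set_b, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  if (!length(set_a) || !length(set_b)) stop("both sets must be nonempty")
  out <- list()
  keys <- character()
  pairs <- list()
  for (i in seq_along(set_a)) {
    for (j in seq_along(set_b)) {
      r <- intersect_pathways(set_a[[i]], set_b[[j]], mode)
      if (length(r$vertices) == 0) next
      key <- paste(c(r$vertices, "|",
                     paste(r$edges$source, r$edges$target, r$edges$kind,
                           sep = ">")), collapse = "\x1f")
      pos <- match(key, keys)
      if (is.na(pos)) {
        keys <- c(keys, key)
        out[[length(out) + 1L]] <- r
        pairs[[length(pairs) + 1L]] <- data.frame(a = i, b = j)
      } else {
        pairs[[pos]] <- rbind(pairs[[pos]], data.frame(a = i, b = j))
      }
    }
  }
  for (i in seq_along(out)) attr(out[[i]], "pairs") <- pairs[[i]]
  out
}

#' @export
print.intersection_result <- function(x, ...) {
  cat("<intersection> ", length(x$vertices), " shared gene(s), ",
      nrow(x$edges), " edge(s)\n", sep = "")
  invisible(x)
}
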