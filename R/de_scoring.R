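#' Per-gene differential-expression p-values
#'
#' Runs a two-sided two-sample t-test per gene between the sensitive and
#' resistant groups. The default is the classic pooled-variance Student
#' test; `variant = "welch"` drops the equal-variance assumption. The
#' reported statistic is oriented as resistant minus sensitive (positive =
#' up-regulated in resistant samples).
#'
#' Degenerate genes (zero variance in both groups) cannot be tested: equal
#' group means give p = 1, unequal means give the configured p-value floor;
#' both cases are flagged in the `degenerate` column.
#'
#' @param expr An `expression_matrix` (see [read_expression()]).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @param p_floor Lower clamp for p-values of degenerate genes.
#' @return A `gene_score_table` data frame: `gene`, `p`, `z`, `statistic`,
#'   `df`, `degenerate`.
#' @export
gene_pvalues <- function(expr, variant = c("pooled", "welch"),
                         p_floor = 1e-16) {
  stopifnot(inherits(expr, "expression_matrix"))
  variant <- match.arg(variant)
  sens <- expr$values[, expr$groups == "sensitive", drop = FALSE]
  res <- expr$values[, expr$groups == "resistant", drop = FALSE]
  if (ncol(sens) < 2 || ncol(res) < 2) {
    stop("both groups need at least 2 samples")
  }
  genes <- rownames(expr$values)
  n <- length(genes)
  p <- numeric(n); stat <- numeric(n); dfree <- numeric(n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    x <- sens[i, ]; y <- res[i, ]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      degen[i] <- TRUE
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        p[i] <- 1; stat[i] <- 0
      } else {
        p[i] <- p_floor
        stat[i] <- sign(mean(y) - mean(x)) * Inf
      }
      dfree[i] <- NA_real_
    } else {
      tt <- stats::t.test(y, x, var.equal = (variant == "pooled"))
      p[i] <- max(tt$p.value, p_floor)
      stat[i] <- unname(tt$statistic)
      dfree[i] <- unname(tt$parameter)
    }
  }
  out <- data.frame(gene = genes, p = p, z = p_to_z(p), statistic = stat,
                    df = dfree, degenerate = degen, stringsAsFactors = FALSE)
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Convert p-values to z-scores
#'
#' Computes the inverse standard normal CDF of the upper tail,
#' z = qnorm(1 - p), so uniform p-values map to standard-normal z-scores
#' and smaller p-values give larger z-scores. Inputs are clamped to
#' `[eps, 1 - eps]` because the inverse CDF diverges at 0 and 1.
#'
#' @param p Numeric vector of p-values.
#' @param eps Clamping bound (default 1e-16).
#' @return Numeric vector of z-scores, strictly decreasing in p.
#' @export
p_to_z <- function(p, eps = 1e-16) {
  if (!is.numeric(p)) stop("p must be numeric")
  p <- pmin(pmax(p, eps), 1 - eps)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Aggregate gene z-scores into a pathway activity score
#'
#' The default size-corrected form sums the member z-scores and divides by
#' the square root of the gene count, so pathways of all sizes live on a
#' common standard-normal null scale; `normalization = "sum"` returns the
#' raw sum. Genes absent from the score table are excluded from both the
#' sum and the count (their number is reported via a message when any are
#' dropped).
#'
#' @param genes Character vector of gene symbols (non-empty).
#' @param scores A `gene_score_table`.
#' @param normalization `"sqrt_k"` (default) or `"sum"`.
#' @return Aggregate score (scalar); `NA` if no gene is measured.
#' @export
aggregate_score <- function(genes, scores,
                            normalization = c("sqrt_k", "sum")) {
  normalization <- match.arg(normalization)
  if (length(genes) == 0) stop("empty gene set")
  z <- scores$z[match(genes, scores$gene)]
  present <- !is.na(z)
  if (!all(present)) {
    message(sum(!present), " gene(s) without expression scores excluded")
  }
  if (!any(present)) {
    warning("no gene in the set has an expression score", call. = FALSE)
    return(NA_real_)
  }
  s <- sum(z[present])
  if (normalization == "sqrt_k") s / sqrt(sum(present)) else s
}

#' Score mined pathways by differential expression
#'
#' Each pathway is expanded through the merge map (every member of a
#' supernode contributes its own z-score and counts toward the size
#' correction) and scored with [aggregate_score()]. Results are sorted by
#' score, highest first, with the vertex-label sequence as tiebreak.
#'
#' @param pathways List of `pathway` objects from [mine_pathways()].
#' @param merge_map A `condensed_network` or plain merge map matching the
#'   network the pathways were mined on.
#' @param scores A `gene_score_table`.
#' @param normalization Passed to [aggregate_score()].
#' @return List of `scored_pathway` objects.
#' @export
score_pathways <- function(pathways, merge_map, scores,
                           normalization = c("sqrt_k", "sum")) {
  normalization <- match.arg(normalization)
  out <- lapply(pathways, function(p) {
    genes <- expand_path(p, merge_map)
    z <- scores$z[match(genes, scores$gene)]
    names(z) <- genes
    measured <- genes[!is.na(z)]
    sc <- if (length(measured)) {
      suppressMessages(aggregate_score(genes, scores, normalization))
    } else {
      NA_real_
    }
    structure(list(pathway = p, genes = genes,
                   z = z[!is.na(z)], score = sc,
                   k = length(measured)),
              class = "scored_pathway")
  })
  if (length(out)) {
    sc <- vapply(out, function(s) s$score, numeric(1))
    keys <- vapply(out, function(s) paste(s$pathway$vertices,
                                          collapse = "\x1f"), character(1))
    sc[is.na(sc)] <- -Inf
    out <- out[order(-sc, keys, method = "radix")]
  }
  out
}

#' Line graph of a network or pathway
#'
#' Interactions become vertices and two interactions are adjacent when they
#' share an endpoint; the shared gene labels the line-graph edge and, when
#' a score table is supplied, contributes its z-score as the edge weight.
#' This turns vertex-attached expression scores into edge weights.
#'
#' @param x A `bio_network`, `condensed_network` or `pathway` with at least
#'   one arc.
#' @param scores Optional `gene_score_table` for edge weights.
#' @return A `line_graph`: list with `vertices` (one row per source arc)
#'   and `edges` (`a`, `b`, `shared_gene`, `weight`).
#' @export
to_line_graph <- function(x, scores = NULL) {
  arcs <- if (inherits(x, "pathway")) {
    x$edges
  } else if (inherits(x, "condensed_network")) {
    x$network$edges
  } else if (inherits(x, "bio_network")) {
    x$edges
  } else {
    stop("cannot build a line graph from class ",
         paste(class(x), collapse = "/"))
  }
  if (is.null(arcs) || nrow(arcs) == 0) stop("input has no arcs")
  ids <- paste0(arcs$source, "->", arcs$target,
                ifelse(duplicated(arcs[c("source", "target")]) |
                         duplicated(arcs[c("source", "target")],
                                    fromLast = TRUE),
                       paste0(" [", arcs$kind, "]"), ""))
  vertices <- data.frame(id = ids, source = arcs$source,
                         target = arcs$target, kind = arcs$kind,
                         stringsAsFactors = FALSE)
  m <- nrow(arcs)
  ea <- character(); eb <- character(); eg <- character()
  if (m >= 2) {
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        shared <- intersect(c(arcs$source[i], arcs$target[i]),
                            c(arcs$source[j], arcs$target[j]))
        if (length(shared)) {
          ea <- c(ea, ids[i]); eb <- c(eb, ids[j])
          eg <- c(eg, sort(shared, method = "radix")[1])
        }
      }
    }
  }
  w <- if (!is.null(scores)) scores$z[match(eg, scores$gene)] else
    rep(NA_real_, length(eg))
  structure(list(vertices = vertices,
                 edges = data.frame(a = ea, b = eb, shared_gene = eg,
                                    weight = w, stringsAsFactors = FALSE)),
            class = "line_graph")
}

#' Filter scored pathways by threshold and rank
#'
#' Keeps pathways whose aggregate score is at least `threshold` and then
#' truncates to the `top_n` highest, with the lexicographic vertex-sequence
#' order as a stable tiebreak. Pathways without a score (no measured gene)
#' are dropped.
#'
#' @param scored List of `scored_pathway` objects.
#' @param threshold Minimum score (default `-Inf`, no score filter).
#' @param top_n Maximum number of pathways to keep (`NULL` = all).
#' @return Filtered list of `scored_pathway` objects.
#' @export
filter_pathways <- function(scored, threshold = -Inf, top_n = NULL) {
  if (!is.null(top_n) && (!is.numeric(top_n) || top_n < 1)) {
    stop("top_n must be a positive integer")
  }
  sc <- vapply(scored, function(s) s$score, numeric(1))
  keep <- !is.na(sc) & sc >= threshold
  scored <- scored[keep]
  sc <- sc[keep]
  if (length(scored)) {
    keys <- vapply(scored, function(s) paste(s$pathway$vertices,
                                             collapse = "\x1f"),
                   character(1))
    scored <- scored[order(-sc, keys, method = "radix")]
    if (!is.null(top_n)) scored <- utils::head(scored, as.integer(top_n))
  }
  scored
}

#' Benjamini-Hochberg adjusted p-values for a score table
#'
#' Convenience report column; adjusted values are never used in pathway
#' scoring, which follows the raw p < 0.05 convention.
#'
#' @param scores A `gene_score_table`.
#' @return The table with an extra `p_adj` column.
#' @export
add_bh_column <- function(scores) {
  scores$p_adj <- stats::p.adjust(scores$p, method = "BH")
  scores
}

#' @export
print.scored_pathway <- function(x, ...) {
  cat("<scored_pathway> ", paste(x$pathway$vertices, collapse = " -> "),
      "  score ", format(x$score, digits = 4), " (k = ", x$k, ")\n",
      sep = "")
  invisible(x)
}
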