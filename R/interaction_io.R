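# Closed enumeration of interaction kinds recognised in interaction tables.
INTERACTION_KINDS <- c(
  "protein_binding", "regulation_positive", "regulation_negative",
  "metabolic", "unspecified"
)

#' Read a gene alias table
#'
#' Alias tables map alternative gene symbols to official symbols so that
#' interactions parsed from heterogeneous sources can be merged without
#' duplicating vertices. The file is a two-column TSV (`alias`, `official`)
#' with a header row; lines starting with `#` are comments.
#'
#' The returned mapping is single-valued (one official symbol per alias) and
#' official symbols always map to themselves, so applying the table twice is
#' the same as applying it once.
#'
#' @param path Path to the alias TSV.
#' @return A named character vector of class `alias_table`; names are
#'   aliases, values the corresponding official symbols.
#' @export
read_alias_table <- function(path) {
  df <- .read_tsv(path, required = c("alias", "official"))
  if (nrow(df) == 0) {
    return(structure(stats::setNames(character(), character()),
                     class = "alias_table"))
  }
  df$alias <- as.character(df$alias)
  df$official <- as.character(df$official)
  dup <- df$alias[duplicated(df$alias)]
  if (length(dup)) {
    bad <- unique(df$alias[df$alias %in% dup &
                             stats::ave(df$official, df$alias,
                                        FUN = function(x) length(unique(x))) > 1])
    if (length(bad)) {
      stop("alias table is not single-valued for: ",
           paste(bad, collapse = ", "))
    }
    df <- df[!duplicated(df$alias), , drop = FALSE]
  }
  map <- stats::setNames(df$official, df$alias)
  # official symbols map to themselves
  officials <- setdiff(unique(df$official), names(map))
  map <- c(map, stats::setNames(officials, officials))
  structure(map, class = "alias_table")
}

#' Resolve gene symbols through an alias table
#'
#' Symbols absent from the table pass through unchanged (a warning reports
#' how many). Resolution is idempotent.
#'
#' @param symbols Character vector of gene symbols.
#' @param alias_table An `alias_table`, or `NULL` for a no-op.
#' @param warn Emit a warning for unknown symbols? Default `TRUE`.
#' @return Character vector of official symbols.
#' @export
resolve_aliases <- function(symbols, alias_table = NULL, warn = TRUE) {
  if (is.null(alias_table) || length(alias_table) == 0) return(symbols)
  hit <- symbols %in% names(alias_table)
  if (warn && any(!hit)) {
    warning(sum(!hit), " symbol(s) not in alias table passed through unchanged",
            call. = FALSE)
  }
  out <- symbols
  out[hit] <- unname(unclass(alias_table)[symbols[hit]])
  out
}

#' Read an interaction table
#'
#' Interaction tables are the generic flat form of parsed pathway/regulation
#' databases: one row per recorded interaction with columns `source`,
#' `target`, `kind`, `directed`, `provenance`. `kind` must be one of
#' `protein_binding`, `regulation_positive`, `regulation_negative`,
#' `metabolic`, `unspecified`; regulatory interactions are inherently
#' directed and the reader rejects undirected regulation rows. `directed`
#' accepts logicals or the strings `directed`/`undirected`.
#'
#' @param path Path to the TSV (header mandatory, `#` comments allowed).
#' @param alias_table Optional `alias_table` applied to source and target.
#' @return A data frame of class `interaction_table`.
#' @export
read_interactions <- function(path, alias_table = NULL) {
  df <- .read_tsv(path, required = c("source", "target", "kind",
                                     "directed", "provenance"))
  if (nrow(df) > 0) {
    df$source <- as.character(df$source)
    df$target <- as.character(df$target)
    df$kind <- as.character(df$kind)
    df$provenance <- as.character(df$provenance)
    df$directed <- .parse_directed(df$directed)
    if (any(!nzchar(df$source)) || any(!nzchar(df$target))) {
      stop("interaction table has empty source or target symbols")
    }
    bad <- setdiff(unique(df$kind), INTERACTION_KINDS)
    if (length(bad)) {
      stop("unknown interaction kind(s): ", paste(bad, collapse = ", "))
    }
    undirected_reg <- !df$directed & grepl("^regulation_", df$kind)
    if (any(undirected_reg)) {
      stop("regulation interactions must be directed (rows: ",
           paste(which(undirected_reg), collapse = ", "), ")")
    }
    if (!is.null(alias_table)) {
      df$source <- resolve_aliases(df$source, alias_table)
      df$target <- resolve_aliases(df$target, alias_table)
    }
  }
  class(df) <- c("interaction_table", "data.frame")
  df
}

.parse_directed <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "directed")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "undirected")] <- FALSE
  if (anyNA(out)) stop("cannot parse 'directed' column values: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

# Shared TSV reader: header mandatory, '#' comments, empty file -> 0 rows.
.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      quote = ""),
    error = function(e) {
      # completely empty file: treat as an empty table
      if (grepl("no lines available", conditionMessage(e))) {
        stats::setNames(
          as.data.frame(replicate(length(required), character(),
                                  simplify = FALSE)), required)
      } else {
        stop("failed to parse ", path, ": ", conditionMessage(e),
             call. = FALSE)
      }
    })
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Read an expression matrix and its sample-group labels
#'
#' The matrix file is a genes-by-samples TSV whose first column (`gene`)
#' holds gene symbols; the groups file is a two-column TSV (`sample`,
#' `group`) assigning each sample to `sensitive` or `resistant`. Duplicate
#' gene rows (after alias resolution) are collapsed by their mean with a
#' warning. Every sample in the matrix must be labeled, and each group needs
#' at least two samples for the downstream two-sample test.
#'
#' @param matrix_path Path to the expression TSV.
#' @param groups_path Path to the groups TSV.
#' @param alias_table Optional `alias_table` applied to gene symbols.
#' @return An object of class `expression_matrix`: a list with `values`
#'   (numeric matrix, genes in rows) and `groups` (factor with levels
#'   `sensitive`, `resistant`, named by sample).
#' @export
read_expression <- function(matrix_path, groups_path, alias_table = NULL) {
  mdf <- .read_tsv(matrix_path, required = "gene")
  gdf <- .read_tsv(groups_path, required = c("sample", "group"))
  if (nrow(mdf) == 0) stop("expression matrix is empty")
  genes <- resolve_aliases(as.character(mdf$gene), alias_table, warn = FALSE)
  values <- as.matrix(mdf[, setdiff(names(mdf), "gene"), drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  gdf$sample <- as.character(gdf$sample)
  gdf$group <- as.character(gdf$group)
  bad_grp <- setdiff(unique(gdf$group), c("sensitive", "resistant"))
  if (length(bad_grp)) {
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "))
  }
  unlabeled <- setdiff(colnames(values), gdf$sample)
  if (length(unlabeled)) {
    stop("sample(s) missing from groups file: ",
         paste(unlabeled, collapse = ", "))
  }
  groups <- factor(gdf$group[match(colnames(values), gdf$sample)],
                   levels = c("sensitive", "resistant"))
  names(groups) <- colnames(values)
  if (any(table(groups) < 2)) {
    stop("each group needs at least 2 samples (got ",
         paste(table(groups), collapse = " vs "), ")")
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dup),
            " duplicated gene row(s) by mean", call. = FALSE)
    values <- rowsum(values, group = genes) /
      as.vector(table(factor(genes, levels = sort(unique(genes)))))
    values <- values[order(rownames(values)), , drop = FALSE]
  }
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' Read a seed-gene list
#'
#' One symbol per line; blank lines and `#` comments are skipped.
#'
#' @param path Path to the seed file.
#' @param alias_table Optional `alias_table`.
#' @return Character vector of official symbols.
#' @export
read_seeds <- function(path, alias_table = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(resolve_aliases(lines, alias_table, warn = FALSE))
}

#' Write scored pathways to JSON
#'
#' The document stores, per pathway: the ordered (condensed) vertex list,
#' the ordered edge list with kinds, the expanded gene set, per-gene
#' z-scores, the aggregate score and the gene count. `read_pathways()` is
#' the lossless inverse.
#'
#' @param pathways List of `scored_pathway` objects.
#' @param path Output file path.
#' @export
write_pathways <- function(pathways, path) {
  doc <- list(pathways = lapply(pathways, .scored_to_list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.scored_to_list <- function(sp) {
  stopifnot(inherits(sp, "scored_pathway"))
  p <- sp$pathway
  list(
    vertices = as.list(p$vertices),
    edges = .edges_to_list(p$edges),
    source_seed = p$source_seed,
    target_seed = p$target_seed,
    weight = p$weight,
    genes = as.list(sp$genes),
    z = as.list(sp$z),
    score = sp$score,
    k = sp$k
  )
}

.edges_to_list <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) return(list())
  lapply(seq_len(nrow(edges)), function(i) {
    list(source = edges$source[i], target = edges$target[i],
         kind = edges$kind[i])
  })
}

#' Read scored pathways from JSON
#'
#' @param path Path written by [write_pathways()].
#' @return List of `scored_pathway` objects.
#' @export
read_pathways <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(doc$pathways, function(x) {
    edges <- .list_to_edges(x$edges)
    pw <- structure(list(
      vertices = vapply(x$vertices, as.character, character(1)),
      edges = edges,
      length = length(x$vertices) - 1L,
      weight = as.numeric(x$weight),
      source_seed = x$source_seed,
      target_seed = x$target_seed
    ), class = "pathway")
    z <- vapply(x$z, as.numeric, numeric(1))
    structure(list(
      pathway = pw,
      genes = vapply(x$genes, as.character, character(1)),
      z = z,
      score = if (is.null(x$score)) NA_real_ else as.numeric(x$score),
      k = as.integer(x$k)
    ), class = "scored_pathway")
  })
}

.list_to_edges <- function(lst) {
  if (length(lst) == 0) {
    return(data.frame(source = character(), target = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    source = vapply(lst, function(e) as.character(e$source), character(1)),
    target = vapply(lst, function(e) as.character(e$target), character(1)),
    kind = vapply(lst, function(e) as.character(e$kind), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Serialize a network to JSON
#'
#' Works for both `bio_network` and `condensed_network` objects (the latter
#' include their merge map). `read_network()` is the inverse.
#'
#' @param x A `bio_network` or `condensed_network`.
#' @param path Output path.
#' @export
write_network <- function(x, path) {
  if (inherits(x, "condensed_network")) {
    doc <- list(type = "condensed_network", mode = x$mode,
                vertices = as.list(x$network$vertices),
                edges = .net_edges_to_list(x$network$edges),
                merge_map = lapply(x$merge_map, as.list))
  } else if (inherits(x, "bio_network")) {
    doc <- list(type = "bio_network",
                vertices = as.list(x$vertices),
                edges = .net_edges_to_list(x$edges))
  } else {
    stop("cannot serialize object of class ", paste(class(x), collapse = "/"))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.net_edges_to_list <- function(edges) {
  if (nrow(edges) == 0) return(list())
  lapply(seq_len(nrow(edges)), function(i) {
    list(source = edges$source[i], target = edges$target[i],
         kind = edges$kind[i], provenance = edges$provenance[i],
         interaction_id = edges$interaction_id[i])
  })
}

#' Read a network serialized by [write_network()]
#'
#' @param path JSON path.
#' @return A `bio_network` or `condensed_network`.
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  edges <- if (length(doc$edges) == 0) {
    .empty_net_edges()
  } else {
    data.frame(
      source = vapply(doc$edges, function(e) as.character(e$source), character(1)),
      target = vapply(doc$edges, function(e) as.character(e$target), character(1)),
      kind = vapply(doc$edges, function(e) as.character(e$kind), character(1)),
      provenance = vapply(doc$edges, function(e) as.character(e$provenance), character(1)),
      interaction_id = vapply(doc$edges, function(e) as.character(e$interaction_id), character(1)),
      stringsAsFactors = FALSE
    )
  }
  vertices <- vapply(doc$vertices, as.character, character(1))
  net <- .bio_network(edges, vertices)
  if (identical(doc$type, "condensed_network")) {
    mm <- lapply(doc$merge_map, function(m) vapply(m, as.character, character(1)))
    structure(list(network = net, merge_map = mm, mode = doc$mode),
              class = "condensed_network")
  } else {
    net
  }
}

#' Export a network as SIF (simple interaction format)
#'
#' One line per arc: `source TAB kind TAB target`. Supernodes of a condensed
#' network appear under their joined `A+B` label.
#'
#' @param x A `bio_network` or `condensed_network`.
#' @param path Output path.
#' @export
write_sif <- function(x, path) {
  net <- if (inherits(x, "condensed_network")) x$network else x
  stopifnot(inherits(net, "bio_network"))
  lines <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$kind,
                   net$edges$target)
  # isolated vertices are written as bare labels so they are not lost
  isolated <- setdiff(net$vertices, c(net$edges$source, net$edges$target))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Read a precomputed per-gene p-value table
#'
#' Two-column TSV (`gene`, `p`); z-scores are derived with [p_to_z()]. This
#' stands in for expression input when differential-expression tests were
#' run elsewhere.
#'
#' @param path TSV path.
#' @param alias_table Optional `alias_table`.
#' @return A `gene_score_table` data frame.
#' @export
read_gene_pvalues <- function(path, alias_table = NULL) {
  df <- .read_tsv(path, required = c("gene", "p"))
  gene <- resolve_aliases(as.character(df$gene), alias_table, warn = FALSE)
  p <- as.numeric(df$p)
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  out <- data.frame(gene = gene, p = p, z = p_to_z(p),
                    statistic = NA_real_, df = NA_real_,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("gene_score_table", "data.frame")
  out
}
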