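#' Run the full pathway-mining pipeline
#'
#' Executes build -> condense -> seed mapping -> k-shortest-path mining ->
#' differential-expression scoring -> filtering, writing every artifact
#' plus a JSON manifest of the resolved parameters to `out_dir`.
#' Optionally intersects the filtered set with a second pathway set and
#' reports centralities of the filtered genes on a reference network.
#'
#' Either an expression matrix plus group labels or a precomputed per-gene
#' p-value table must be supplied. The run is fully deterministic: the
#' same configuration always produces identical output files.
#'
#' @param interactions Path to the interaction TSV.
#' @param seeds Path to a seed list, or a character vector of symbols.
#' @param out_dir Output directory (created if needed).
#' @param aliases Optional path to an alias TSV.
#' @param expression,groups Paths to the expression matrix and group file.
#' @param pvalues Path to a precomputed p-value TSV (`gene`, `p`),
#'   alternative to `expression`/`groups`.
#' @param condense_mode `"scc"`, `"two_cycle"` or `"none"`.
#' @param k Paths per ordered seed pair.
#' @param test_variant `"pooled"` or `"welch"`.
#' @param normalization `"sqrt_k"` or `"sum"`.
#' @param threshold Minimum aggregate score kept by the filter.
#' @param top_n Number of top pathways kept.
#' @param intersect_with Optional path to a pathway JSON (another
#'   condition) to intersect with.
#' @param intersect_mode `"strict"` or `"relaxed"`.
#' @param reference Optional path to a reference interaction TSV for
#'   centrality reporting.
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a list with every intermediate object and the
#'   output file paths.
#' @export
run_pipeline <- function(interactions, seeds, out_dir,
                         aliases = NULL,
                         expression = NULL, groups = NULL, pvalues = NULL,
                         condense_mode = "scc", k = 5,
                         test_variant = "pooled",
                         normalization = "sqrt_k",
                         threshold = 0, top_n = 20,
                         intersect_with = NULL, intersect_mode = "strict",
                         reference = NULL, quiet = FALSE) {
  has_expr <- !is.null(expression) && !is.null(groups)
  if (!has_expr && is.null(pvalues)) {
    stop("supply either `expression` + `groups` or a `pvalues` table")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pathminer] ", ...)

  alias_table <- if (!is.null(aliases)) read_alias_table(aliases) else NULL

  say("reading interactions: ", interactions)
  records <- read_interactions(interactions, alias_table)
  net <- build_network(records)
  say("network: ", length(net$vertices), " vertices, ", nrow(net$edges),
      " arcs")
  cnet <- condense(net, condense_mode)
  say("condensed (", condense_mode, "): ", length(cnet$merge_map),
      " supernode(s)")

  seed_genes <- if (length(seeds) == 1 && file.exists(seeds)) {
    read_seeds(seeds, alias_table)
  } else {
    resolve_aliases(as.character(seeds), alias_table, warn = FALSE)
  }
  seed_set <- select_seeds(net, user_genes = seed_genes)

  scores <- if (has_expr) {
    expr <- read_expression(expression, groups, alias_table)
    gene_pvalues(expr, variant = test_variant)
  } else {
    read_gene_pvalues(pvalues, alias_table)
  }

  say("mining pathways (k = ", k, ") over ", nrow(seed_set), " seed(s)")
  paths <- mine_pathways(cnet, seed_set, k = k, quiet = quiet)
  say("mined ", length(paths), " candidate pathway(s)")
  scored <- score_pathways(paths, cnet, scores,
                           normalization = normalization)
  filtered <- filter_pathways(scored, threshold = threshold, top_n = top_n)
  say("kept ", length(filtered), " pathway(s) after filtering")

  out <- list(
    network = file.path(out_dir, "network.json"),
    scored = file.path(out_dir, "scored.json"),
    filtered = file.path(out_dir, "filtered.json"),
    manifest = file.path(out_dir, "manifest.json"))
  write_network(cnet, out$network)
  write_pathways(scored, out$scored)
  write_pathways(filtered, out$filtered)

  common <- NULL
  if (!is.null(intersect_with)) {
    other <- read_pathways(intersect_with)
    common <- intersect_sets(filtered, other, mode = intersect_mode)
    out$common <- file.path(out_dir, "common.json")
    .write_intersections(common, out$common)
    say(length(common), " non-empty intersection(s)")
  }

  report <- NULL
  if (!is.null(reference)) {
    ref_net <- build_network(read_interactions(reference, alias_table))
    genes <- sort(unique(unlist(lapply(filtered, function(s) s$genes))))
    report <- centrality_report(ref_net, genes)
    out$centrality <- file.path(out_dir, "centrality.tsv")
    write_centrality_report(report, out$centrality)
  }

  manifest <- list(
    package = "pathminer",
    version = as.character(utils::packageVersion("pathminer")),
    inputs = list(interactions = interactions, aliases = aliases,
                  expression = expression, groups = groups,
                  pvalues = pvalues,
                  seeds = if (is.character(seeds)) seeds else NULL,
                  intersect_with = intersect_with, reference = reference),
    parameters = list(condense_mode = condense_mode, k = k,
                      test_variant = test_variant,
                      normalization = normalization,
                      threshold = threshold, top_n = top_n,
                      intersect_mode = intersect_mode))
  jsonlite::write_json(manifest, out$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  invisible(list(network = net, condensed = cnet, seeds = seed_set,
                 scores = scores, pathways = paths, scored = scored,
                 filtered = filtered, common = common,
                 centrality = report, files = out))
}

.write_intersections <- function(results, path) {
  doc <- lapply(results, function(r) {
    list(vertices = as.list(r$vertices),
         edges = .edges_to_list(r$edges),
         pairs = attr(r, "pairs"))
  })
  jsonlite::write_json(list(intersections = doc), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
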