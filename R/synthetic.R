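#' Specification for a synthetic study
#'
#' Bundles every parameter of the synthetic generator: network size, the
#' planted differential pathway, mutual-regulation cycles that exercise
#' condensation, and the two-group expression model (equal-variance
#' Gaussian, the design a two-sample t-test assumes). One integer seed
#' fixes all randomness end to end.
#'
#' Defaults emulate a small two-group chemosensitivity study: 3 samples per
#' group, a planted path of 5 genes shifted by 2 standard deviations in
#' the resistant group, and two extra competitor seeds so that pathway
#' ranking has non-trivial null alternatives to beat.
#'
#' @param genes Number of genes (network vertices).
#' @param arcs Total number of directed arcs.
#' @param cycle_pairs Number of planted mutual-regulation pairs.
#' @param path_len Number of genes on the planted path.
#' @param effect Expression shift of planted genes in the resistant group,
#'   in units of `sigma`.
#' @param sigma Standard deviation of expression noise.
#' @param n_per_group Samples per group (>= 2).
#' @param baseline Baseline mean expression (log2-scale microarray-like).
#' @param extra_seeds Number of background genes added to the seed list as
#'   competitors.
#' @param seed Integer RNG seed (< 2^31 - 2).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(genes = 20, arcs = 40, cycle_pairs = 2,
                           path_len = 5, effect = 2, sigma = 1,
                           n_per_group = 3, baseline = 8,
                           extra_seeds = 2, seed = 1) {
  stopifnot(genes >= 2, n_per_group >= 2, sigma >= 0, effect >= 0,
            path_len >= 2, cycle_pairs >= 0, extra_seeds >= 0,
            seed == as.integer(seed), abs(seed) < 2^31 - 2)
  if (path_len > genes) {
    stop("planted path longer than the gene count is infeasible")
  }
  if (path_len + 2 * cycle_pairs + extra_seeds > genes) {
    stop("genes cannot host the planted path, cycles and extra seeds disjointly")
  }
  if (arcs < genes - 1) stop("arc count must be at least genes - 1")
  if (arcs < (path_len - 1) + 2 * cycle_pairs) {
    stop("arc count too small for the planted structures")
  }
  structure(list(genes = as.integer(genes), arcs = as.integer(arcs),
                 cycle_pairs = as.integer(cycle_pairs),
                 path_len = as.integer(path_len), effect = effect,
                 sigma = sigma, n_per_group = as.integer(n_per_group),
                 baseline = baseline, extra_seeds = as.integer(extra_seeds),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic interaction network with planted structures
#'
#' Plants (i) a simple directed regulatory path of `path_len` genes whose
#' endpoints are the designated seed genes, and (ii) `cycle_pairs` disjoint
#' mutual-regulation pairs, then fills the remaining arc budget with random
#' directed background arcs (Erdős–Rényi style). Background arcs never
#' touch a planted-path vertex (in either direction) and never create an
#' accidental mutual pair: the planted route is therefore the unique path
#' between its seed endpoints, the planted cycle count is exact, and every
#' competitor pathway mined between the extra seeds is a pure null path —
#' identifiability is guaranteed by construction and all stochasticity
#' enters through the expression data.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `network` (a `bio_network`) and `truth` (planted path,
#'   seed endpoints, cycle pairs, competitor seeds).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  width <- nchar(as.character(spec$genes))
  genes <- sprintf(paste0("G%0", width, "d"), seq_len(spec$genes))
  ord <- sample(genes)
  path <- ord[seq_len(spec$path_len)]
  used <- spec$path_len
  cycles <- list()
  if (spec$cycle_pairs > 0) {
    for (i in seq_len(spec$cycle_pairs)) {
      cycles[[i]] <- ord[used + c(1L, 2L)]
      used <- used + 2L
    }
  }
  extras <- if (spec$extra_seeds > 0) {
    ord[used + seq_len(spec$extra_seeds)]
  } else {
    character()
  }

  rec <- list()
  rec[[1]] <- data.frame(
    source = path[-length(path)], target = path[-1],
    kind = "regulation_positive", directed = TRUE,
    provenance = "synthetic_path", stringsAsFactors = FALSE)
  for (cp in cycles) {
    rec[[length(rec) + 1L]] <- data.frame(
      source = cp, target = rev(cp), kind = "regulation_positive",
      directed = TRUE, provenance = "synthetic_cycle",
      stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, rec)
  n_bg <- spec$arcs - nrow(planted)

  if (n_bg > 0) {
    cand <- expand.grid(source = genes, target = genes,
                        stringsAsFactors = FALSE)
    cand <- cand[cand$source != cand$target, , drop = FALSE]
    cand <- cand[!(cand$source %in% path) & !(cand$target %in% path), ,
                 drop = FALSE]
    taken <- paste(planted$source, planted$target)
    taken <- c(taken, paste(planted$target, planted$source))
    cand <- cand[!(paste(cand$source, cand$target) %in% taken), ,
                 drop = FALSE]
    cand <- cand[sample(nrow(cand)), , drop = FALSE]
    chosen <- logical(nrow(cand))
    seen <- character()
    got <- 0L
    for (i in seq_len(nrow(cand))) {
      fwd <- paste(cand$source[i], cand$target[i])
      rev_ <- paste(cand$target[i], cand$source[i])
      if (fwd %in% seen || rev_ %in% seen) next
      chosen[i] <- TRUE
      seen <- c(seen, fwd)
      got <- got + 1L
      if (got == n_bg) break
    }
    if (got < n_bg) {
      stop("cannot place ", n_bg, " background arcs under the constraints; ",
           "reduce `arcs` or increase `genes`")
    }
    bg <- cand[chosen, , drop = FALSE]
    bg$kind <- "unspecified"
    bg$directed <- TRUE
    bg$provenance <- "synthetic_background"
    planted <- rbind(planted, bg)
  }
  planted$directed <- TRUE
  net <- build_network(planted)
  # every gene is a vertex even if no arc touched it
  net <- .bio_network(net$edges, vertices = genes)
  truth <- list(path = path, seeds = c(path[1], path[length(path)]),
                cycle_pairs = cycles, extra_seeds = extras,
                all_seeds = c(path[1], path[length(path)], extras))
  list(network = net, truth = truth)
}

#' Generate a two-group expression matrix with a planted signal
#'
#' Background genes are Normal(baseline, sigma^2) in both groups;
#' planted-path genes are shifted upward by `effect * sigma` in the
#' resistant group. In the noise-free limit `sigma = 0` the shift is
#' `effect` itself (an absolute offset), so planted genes still separate
#' the groups and exercise the degenerate zero-variance branch of the
#' t-test. Group sizes follow the spec (`S1..Sn` sensitive,
#' `R1..Rn` resistant). Seeded with `spec$seed + 1` so it is reproducible
#' independently of network generation.
#'
#' @param network The `bio_network` from [generate_network()].
#' @param truth The matching truth record.
#' @param spec The `synthetic_spec`.
#' @return An `expression_matrix`.
#' @export
generate_expression <- function(network, truth, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!all(truth$path %in% network$vertices)) {
    stop("truth genes must be network vertices")
  }
  set.seed(spec$seed + 1L)
  genes <- network$vertices
  n <- spec$n_per_group
  samples <- c(paste0("S", seq_len(n)), paste0("R", seq_len(n)))
  values <- matrix(stats::rnorm(length(genes) * 2 * n, mean = spec$baseline,
                                sd = spec$sigma),
                   nrow = length(genes), dimnames = list(genes, samples))
  res_cols <- n + seq_len(n)
  shift <- spec$effect * if (spec$sigma > 0) spec$sigma else 1
  values[truth$path, res_cols] <- values[truth$path, res_cols] + shift
  groups <- factor(rep(c("sensitive", "resistant"), each = n),
                   levels = c("sensitive", "resistant"))
  names(groups) <- samples
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' Write a complete synthetic input set to disk
#'
#' Produces every file the pipeline consumes — interactions, alias table
#' (identity mapping), expression matrix, group labels and seed list — so
#' the full pipeline can run against known ground truth. Identical specs
#' produce byte-identical files.
#'
#' @param spec A `synthetic_spec`.
#' @param dir Output directory (created if needed).
#' @return List with `files` (named paths), `truth` and `spec`.
#' @export
end_to_end_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- generate_network(spec)
  expr <- generate_expression(gen$network, gen$truth, spec)

  files <- list(
    interactions = file.path(dir, "interactions.tsv"),
    aliases = file.path(dir, "aliases.tsv"),
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    seeds = file.path(dir, "seeds.txt"))

  e <- gen$network$edges
  utils::write.table(
    data.frame(source = e$source, target = e$target, kind = e$kind,
               directed = "true", provenance = e$provenance),
    files$interactions, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(alias = gen$network$vertices,
               official = gen$network$vertices),
    files$aliases, sep = "\t", quote = FALSE, row.names = FALSE)
  vals <- expr$values
  utils::write.table(
    data.frame(gene = rownames(vals), vals, check.names = FALSE),
    files$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(expr$groups),
               group = as.character(expr$groups)),
    files$groups, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(gen$truth$all_seeds, files$seeds)

  list(files = files, truth = gen$truth, spec = spec)
}
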