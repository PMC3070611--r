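# In-code fixture builders shared across test files.

# interaction records from "A->B" strings (directed) or "A--B" (undirected)
make_records <- function(..., kind = "unspecified", provenance = "test") {
  specs <- c(...)
  if (!length(specs)) {
    return(data.frame(source = character(), target = character(),
                      kind = character(), directed = logical(),
                      provenance = character(), stringsAsFactors = FALSE))
  }
  src <- character(); tgt <- character(); dir <- logical()
  for (s in specs) {
    if (grepl("->", s, fixed = TRUE)) {
      p <- strsplit(s, "->", fixed = TRUE)[[1]]
      dir <- c(dir, TRUE)
    } else {
      p <- strsplit(s, "--", fixed = TRUE)[[1]]
      dir <- c(dir, FALSE)
    }
    src <- c(src, p[1]); tgt <- c(tgt, p[2])
  }
  data.frame(source = src, target = tgt,
             kind = rep_len(kind, length(src)), directed = dir,
             provenance = provenance, stringsAsFactors = FALSE)
}

make_net <- function(..., kind = "unspecified") {
  build_network(make_records(..., kind = kind))
}

# random simple directed graph as an interaction record frame
random_records <- function(n, m, seed) {
  set.seed(seed)
  v <- LETTERS[seq_len(n)]
  cand <- expand.grid(source = v, target = v, stringsAsFactors = FALSE)
  cand <- cand[cand$source != cand$target, , drop = FALSE]
  m <- min(m, nrow(cand))
  pick <- cand[sample(nrow(cand), m), , drop = FALSE]
  pick$kind <- "unspecified"
  pick$directed <- TRUE
  pick$provenance <- "random"
  rownames(pick) <- NULL
  pick
}

# a plain pathway object from a vertex sequence (chain of arcs)
make_pathway <- function(vseq, kinds = "unspecified") {
  k <- length(vseq) - 1L
  structure(list(
    vertices = vseq,
    edges = data.frame(source = vseq[-length(vseq)], target = vseq[-1],
                       kind = rep_len(kinds, max(k, 0)),
                       stringsAsFactors = FALSE),
    length = k, weight = k,
    source_seed = vseq[1], target_seed = vseq[length(vseq)]
  ), class = "pathway")
}

# gene score table straight from named p-values
make_scores <- function(p) {
  out <- data.frame(gene = names(p), p = unname(p), z = p_to_z(unname(p)),
                    statistic = NA_real_, df = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_score_table", "data.frame")
  out
}

# expression_matrix from a genes x samples matrix and group sizes
make_expr <- function(values, n_sens, n_res) {
  samples <- c(paste0("S", seq_len(n_sens)), paste0("R", seq_len(n_res)))
  colnames(values) <- samples
  groups <- factor(rep(c("sensitive", "resistant"), c(n_sens, n_res)),
                   levels = c("sensitive", "resistant"))
  names(groups) <- samples
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
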