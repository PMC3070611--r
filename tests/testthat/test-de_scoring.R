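test_that("per-gene t-tests match hand-computed values and handle degeneracy", {
  e3 <- make_expr(rbind(same = c(1, 2, 3, 1, 2, 3),
                        flat0 = c(0, 0, 0, 1, 1, 1),
                        flat = c(2, 2, 2, 2, 2, 2)), 3, 3)
  gs <- gene_pvalues(e3)
  # identical groups: t = 0, p = 1, z = qnorm(0) boundary handled
  expect_equal(gs$p[gs$gene == "same"], 1)
  expect_equal(gs$statistic[gs$gene == "same"], 0)
  # zero variance, unequal means: degenerate flag and floored p
  expect_true(gs$degenerate[gs$gene == "flat0"])
  expect_equal(gs$p[gs$gene == "flat0"], 1e-16)
  # both groups constant and equal: p = 1 with the flag set
  expect_true(gs$degenerate[gs$gene == "flat"])
  expect_equal(gs$p[gs$gene == "flat"], 1)

  # pooled-variance example: (1,2,3,4) vs (3,4,5,6).
  # Hand computation: sp^2 = 5/3, t = 2 / sqrt(sp^2 / 2) = 2.19089, df 6;
  # p = 0.070988 frozen from an independent statistics oracle (scipy
  # ttest_ind, equal_var = TRUE, gives 0.07098765).
  e4 <- make_expr(rbind(g = c(1, 2, 3, 4, 3, 4, 5, 6)), 4, 4)
  g4 <- gene_pvalues(e4, variant = "pooled")
  expect_equal(g4$statistic, 2.19089, tolerance = 1e-5)  # resistant - sensitive
  expect_equal(g4$df, 6)
  expect_equal(g4$p, 0.070988, tolerance = 1e-4)

  # welch variant diverges from pooled under unequal variances
  e5 <- make_expr(rbind(g = c(1, 1.1, 0.9, 1, 5, -2, 9, 0)), 4, 4)
  expect_false(isTRUE(all.equal(gene_pvalues(e5, "pooled")$p,
                                gene_pvalues(e5, "welch")$p)))
})

test_that("p-to-z conversion inverts the standard normal upper tail", {
  expect_identical(p_to_z(0.5), 0)
  # cross-checked against bisection inversion of pnorm
  expect_equal(p_to_z(0.05), bisect_inv_norm(0.05), tolerance = 1e-6)
  expect_equal(p_to_z(0.05), 1.6449, tolerance = 1e-4)
  expect_equal(p_to_z(0.975), -1.9600, tolerance = 1e-4)
  # strict monotone decrease over a fine grid
  grid <- seq(1e-6, 1 - 1e-6, length.out = 1000)
  expect_true(all(diff(p_to_z(grid)) < 0))
  # clamping keeps extreme inputs finite
  expect_true(all(is.finite(p_to_z(c(0, 1, -1, 2)))))
  expect_error(p_to_z("a"), "numeric")
})

test_that("aggregate scores follow the size-corrected sum", {
  sc <- make_scores(c(A = 0.5, B = 0.5, C = 0.5))
  expect_equal(aggregate_score(c("A", "B", "C"), sc), 0)
  expect_equal(aggregate_score(c("A", "B", "C"), sc, "sum"), 0)

  one <- make_scores(c(G = stats::pnorm(2, lower.tail = FALSE)))
  expect_equal(aggregate_score("G", one), 2, tolerance = 1e-12)
  expect_equal(aggregate_score("G", one, "sum"), 2, tolerance = 1e-12)

  # four genes with z = 1 each: 4 / sqrt(4) = 2 under sqrt_k
  p1 <- stats::pnorm(1, lower.tail = FALSE)
  four <- make_scores(stats::setNames(rep(p1, 4), c("A", "B", "C", "D")))
  expect_equal(aggregate_score(c("A", "B", "C", "D"), four), 2,
               tolerance = 1e-12)
  expect_equal(aggregate_score(c("A", "B", "C", "D"), four, "sum"), 4,
               tolerance = 1e-12)

  expect_error(aggregate_score(character(), four), "empty gene set")
  # unmeasured genes are excluded from both the sum and the count
  expect_message(s <- aggregate_score(c("A", "B", "ZZ"), four),
                 "excluded")
  expect_equal(s, 2 / sqrt(2), tolerance = 1e-12)
  expect_warning(s2 <- suppressMessages(aggregate_score("ZZ", four)),
                 "no gene")
  expect_true(is.na(s2))
})

test_that("pathway scores decrease in member p-values and expand supernodes", {
  net <- make_net("X->AR", "AR->DDIT3", "DDIT3->AR", "DDIT3->Y",
                  kind = "regulation_positive")
  cn <- condense(net, "scc")
  paths <- mine_pathways(cn, c("X", "Y"), k = 3)
  expect_equal(length(paths), 1)
  sc <- make_scores(c(X = 0.5, AR = 0.1, DDIT3 = 0.1, Y = 0.5))
  scored <- score_pathways(paths, cn, sc)
  # both supernode members contribute and count toward k
  expect_equal(scored[[1]]$k, 4)
  expect_setequal(names(scored[[1]]$z), c("X", "AR", "DDIT3", "Y"))
  # decreasing one gene's p-value never decreases the pathway score
  sc2 <- make_scores(c(X = 0.5, AR = 0.01, DDIT3 = 0.1, Y = 0.5))
  expect_gt(score_pathways(paths, cn, sc2)[[1]]$score,
            scored[[1]]$score)
})

test_that("line graphs follow the shared-endpoint definition", {
  # single arc: one vertex, no edges
  lg1 <- to_line_graph(make_net("A->B"))
  expect_equal(nrow(lg1$vertices), 1)
  expect_equal(nrow(lg1$edges), 0)

  # path A->B->C: two vertices joined through shared gene B
  lg2 <- to_line_graph(make_pathway(c("A", "B", "C")))
  expect_equal(nrow(lg2$vertices), 2)
  expect_equal(nrow(lg2$edges), 1)
  expect_equal(lg2$edges$shared_gene, "B")

  # triangle: line graph is again a 3-cycle
  lg3 <- to_line_graph(make_net("A->B", "B->C", "C->A"))
  expect_equal(nrow(lg3$vertices), 3)
  expect_equal(nrow(lg3$edges), 3)

  # shared genes carry their z-score as edge weight
  sc <- make_scores(c(A = 0.5, B = 0.05, C = 0.5))
  lgw <- to_line_graph(make_pathway(c("A", "B", "C")), scores = sc)
  expect_equal(lgw$edges$weight, p_to_z(0.05))

  expect_error(to_line_graph(build_network(make_records()[0, ])),
               "no arcs")
})

test_that("line-graph size law holds on random oriented simple graphs", {
  for (seed in 1:20) {
    n <- sample(4:10, 1)
    rec <- random_records(n, sample(n:(2 * n), 1), seed = 4000 + seed)
    # orient each unordered pair once so the projection is simple
    key <- paste(pmin(rec$source, rec$target), pmax(rec$source, rec$target))
    rec <- rec[!duplicated(key), , drop = FALSE]
    net <- build_network(rec)
    lg <- to_line_graph(net)
    expect_equal(nrow(lg$vertices), nrow(net$edges))
    deg <- brute_degree_centrality(net$edges, net$vertices) *
      (length(net$vertices) - 1)
    expect_equal(nrow(lg$edges), sum(choose(deg, 2)))
  }
})

test_that("filtering keeps scores above threshold, truncated to top n", {
  ps <- c(3, 2, 2, 1, 0)
  paths <- lapply(seq_along(ps), function(i) {
    make_pathway(c(sprintf("S%d", i), sprintf("T%d", i)))
  })
  scored <- lapply(seq_along(ps), function(i) {
    structure(list(pathway = paths[[i]],
                   genes = paths[[i]]$vertices,
                   z = stats::setNames(rep(ps[i] / 2, 2),
                                       paths[[i]]$vertices),
                   score = ps[i], k = 2L), class = "scored_pathway")
  })
  expect_equal(filter_pathways(scored, -Inf, length(scored)), scored)
  expect_equal(length(filter_pathways(scored, 100)), 0)
  kept <- filter_pathways(scored, threshold = 1.5, top_n = 2)
  expect_equal(vapply(kept, function(s) s$score, numeric(1)), c(3, 2))
  # tie between the two score-2 paths resolved by vertex-sequence order
  expect_equal(kept[[2]]$pathway$vertices, c("S2", "T2"))
  expect_error(filter_pathways(scored, top_n = 0), "positive")
})

test_that("BH adjustment is reported but never alters raw scores", {
  sc <- make_scores(c(A = 0.01, B = 0.02, C = 0.9))
  with_adj <- add_bh_column(sc)
  expect_equal(with_adj$p_adj, stats::p.adjust(sc$p, "BH"))
  expect_identical(with_adj$z, sc$z)
})
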