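test_that("seed selection tags provenance and reports missing genes", {
  net <- make_net("CEBPD->SOD1", "MYC->TP53", "TP53->PCNA", "TP73->ATF4",
                  "PCNA->TP73", kind = "regulation_positive")
  seeds <- select_seeds(net, user_genes = c("CEBPD", "SOD1"),
                        annotation_genes = c("MYC", "TP53", "PCNA",
                                             "TP73", "ATF4"))
  expect_s3_class(seeds, "seed_set")
  expect_equal(seeds$provenance[seeds$gene %in% c("CEBPD", "SOD1")],
               rep("user_interest", 2))
  expect_equal(sum(seeds$provenance == "dna_damage"), 5)

  # differential-expression seeds join via the score table
  sc <- make_scores(c(CEBPD = 0.5, SOD1 = 0.001))
  s2 <- select_seeds(net, user_genes = "MYC", gene_scores = sc,
                     p_threshold = 0.05)
  expect_true("SOD1" %in% s2$gene[s2$provenance == "de_selected"])

  expect_error(select_seeds(net), "no seed candidates")
  expect_warning(s3 <- select_seeds(net, user_genes = c("CEBPD", "NOPE")),
                 "not in network")
  expect_identical(attr(s3, "missing"), "NOPE")
  expect_error(suppressWarnings(select_seeds(net, user_genes = "NOPE")),
               "present in the network")
})

test_that("shortest_path honors weights and degenerate cases", {
  net <- make_net("s->a", "a->t", "s->b", "b->t")
  cn <- condense(net, "none")
  # source == target: zero-length path of one vertex
  p0 <- shortest_path(cn, "s", "s")
  expect_equal(p0$vertices, "s")
  expect_equal(p0$length, 0)
  # disconnected pair -> NULL
  expect_null(shortest_path(cn, "t", "s"))
  # weighted: route of weight 1 beats the two-hop route of weight 2
  w <- function(e) ifelse(e$source == "s" & e$target == "a", 0.4,
                          ifelse(e$source == "a" & e$target == "t", 0.6, 1))
  pw <- shortest_path(cn, "s", "t", weights = w)
  expect_equal(pw$vertices, c("s", "a", "t"))
  expect_equal(pw$weight, 1.0)
  # negative weights are rejected
  expect_error(shortest_path(cn, "s", "t", weights = function(e) -1),
               "nonnegative")
  # equal-weight tie resolved lexicographically
  pt <- shortest_path(cn, "s", "t")
  expect_equal(pt$vertices, c("s", "a", "t"))
})

test_that("yen_ksp returns paths in (weight, lexicographic) order", {
  net <- make_net("s->t", "s->a", "a->t", "s->b", "b->a")
  cn <- condense(net, "none")
  ps <- yen_ksp(cn, "s", "t", k = 3)
  expect_equal(lapply(ps, function(p) p$vertices),
               list("s->t" = c("s", "t"), "s->a->t" = c("s", "a", "t"),
                    "s->b->a->t" = c("s", "b", "a", "t")),
               ignore_attr = TRUE)
  expect_equal(vapply(ps, function(p) p$weight, numeric(1)), c(1, 2, 3))

  # a single-edge graph holds exactly one simple path no matter k
  single <- condense(make_net("s->t"), "none")
  expect_equal(length(yen_ksp(single, "s", "t", k = 5)), 1)

  # unreachable target -> empty list; bad k -> error
  expect_equal(yen_ksp(cn, "t", "s", k = 2), list())
  expect_error(yen_ksp(cn, "s", "t", k = 0), "positive integer")
})

test_that("yen_ksp matches brute-force enumeration on random graphs", {
  for (seed in 1:30) {
    n <- sample(3:8, 1)
    rec <- random_records(n, sample(n:(2 * n), 1), seed = 2000 + seed)
    cn <- condense(build_network(rec), "none")
    v <- cn$network$vertices
    st <- sample(v, 2)
    expected <- enumerate_simple_paths(cn$network$edges, v, st[1], st[2])
    got <- yen_ksp(cn, st[1], st[2], k = 1000)
    expect_equal(lapply(got, function(p) p$vertices), expected,
                 info = paste("seed", seed))
    # k = 1 agrees with the single shortest path
    if (length(expected)) {
      expect_equal(shortest_path(cn, st[1], st[2])$vertices,
                   expected[[1]])
    }
    # determinism: a second run is identical
    again <- yen_ksp(cn, st[1], st[2], k = 1000)
    expect_identical(lapply(got, `[[`, "vertices"),
                     lapply(again, `[[`, "vertices"))
  }
})

test_that("returned paths are simple with nondecreasing weights", {
  for (seed in 1:10) {
    rec <- random_records(7, 18, seed = 3000 + seed)
    cn <- condense(build_network(rec), "none")
    got <- yen_ksp(cn, cn$network$vertices[1],
                   cn$network$vertices[length(cn$network$vertices)],
                   k = 50)
    for (p in got) expect_equal(anyDuplicated(p$vertices), 0)
    w <- vapply(got, function(p) p$weight, numeric(1))
    expect_true(all(diff(w) >= 0))
  }
})

test_that("mine_pathways pools ordered seed pairs and drops duplicates", {
  chain <- condense(make_net("a->b", "b->c"), "none")
  ps <- mine_pathways(chain, c("a", "b", "c"), k = 5)
  expect_setequal(vapply(ps, function(p) paste(p$vertices, collapse = ">"),
                         character(1)),
                  c("a>b", "b>c", "a>b>c"))

  # two mutually reachable seeds give at most 2 paths per direction
  loop <- condense(make_net("u->x", "x->v", "v->y", "y->u"), "none")
  ps2 <- mine_pathways(loop, c("u", "v"), k = 2)
  expect_lte(length(ps2), 4)

  # seeds merged into one supernode are skipped with a message
  merged <- condense(make_net("AR->DDIT3", "DDIT3->AR", "AR->Z", "W->DDIT3",
                              kind = "regulation_positive"), "scc")
  expect_message(
    ps3 <- mine_pathways(merged, c("AR", "DDIT3", "Z"), k = 2,
                         quiet = FALSE),
    "share supernode")
  expect_true(all(vapply(ps3, function(p) "AR+DDIT3" %in% p$vertices ||
                           "Z" %in% p$vertices, logical(1))))
  expect_error(mine_pathways(merged, c("AR", "DDIT3"), k = 2),
               "distinct network vertices")
})
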