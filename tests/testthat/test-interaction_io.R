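test_that("interaction tables round-trip with alias resolution", {
  tsv <- write_tsv(data.frame(
    source = c("AR", "COX2", "GRB2"),
    target = c("DDIT3", "X1", "AKT2"),
    kind = c("regulation_positive", "regulation_positive",
             "protein_binding"),
    directed = c("directed", "true", "undirected"),
    provenance = c("transfac", "pid", "pid")))
  at_path <- write_tsv(data.frame(alias = c("COX2", "AR", "DDIT3"),
                                  official = c("PTGS2", "AR", "DDIT3")))
  at <- read_alias_table(at_path)

  # both the source and the target column trigger a pass-through warning
  expect_warning(expect_warning(rec <- read_interactions(tsv, at),
                                "passed through"))
  expect_s3_class(rec, "interaction_table")
  expect_equal(nrow(rec), 3)
  # AR -> DDIT3 stays a single directed regulation record
  expect_true(rec$directed[1])
  expect_equal(rec$source[1], "AR")
  expect_equal(rec$target[1], "DDIT3")
  # alias COX2 resolved to the official PTGS2 symbol
  expect_equal(rec$source[2], "PTGS2")
})

test_that("interaction reader enforces the format contract", {
  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(read_interactions(empty)), 0)

  header_only <- write_tsv(data.frame(source = character(),
                                      target = character(),
                                      kind = character(),
                                      directed = character(),
                                      provenance = character()))
  expect_equal(nrow(read_interactions(header_only)), 0)

  missing_col <- write_tsv(data.frame(source = "A", target = "B"))
  expect_error(read_interactions(missing_col), "missing required column")

  bad_kind <- write_tsv(data.frame(source = "A", target = "B",
                                   kind = "banana", directed = "true",
                                   provenance = "x"))
  expect_error(read_interactions(bad_kind), "unknown interaction kind")

  undirected_reg <- write_tsv(data.frame(
    source = "A", target = "B", kind = "regulation_negative",
    directed = "false", provenance = "x"))
  expect_error(read_interactions(undirected_reg), "must be directed")
})

test_that("alias resolution is idempotent and single-valued", {
  at <- read_alias_table(write_tsv(data.frame(
    alias = c("COX2", "JMJD2C"), official = c("PTGS2", "KDM4C"))))
  once <- resolve_aliases(c("COX2", "PTGS2", "NOVEL"), at, warn = FALSE)
  twice <- resolve_aliases(once, at, warn = FALSE)
  expect_identical(once, c("PTGS2", "PTGS2", "NOVEL"))
  expect_identical(once, twice)

  conflicting <- write_tsv(data.frame(alias = c("X", "X"),
                                      official = c("A", "B")))
  expect_error(read_alias_table(conflicting), "single-valued")
})

test_that("expression matrices validate groups and collapse duplicates", {
  set.seed(11)
  vals <- matrix(rnorm(60), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  mp <- write_tsv(data.frame(gene = rownames(vals), vals,
                             check.names = FALSE))
  gp <- write_tsv(data.frame(sample = paste0("s", 1:6),
                             group = rep(c("sensitive", "resistant"),
                                         each = 3)))
  expr <- read_expression(mp, gp)
  expect_s3_class(expr, "expression_matrix")
  expect_equal(unname(table(expr$groups)), c(3L, 3L),
               ignore_attr = TRUE)
  expect_equal(dim(expr$values), c(10, 6))

  # identical duplicated rows collapse to one row with unchanged values
  dup <- rbind(vals, vals["g1", , drop = FALSE])
  rownames(dup)[11] <- "g1"
  mp2 <- write_tsv(data.frame(gene = rownames(dup), dup,
                              check.names = FALSE))
  expect_warning(e2 <- read_expression(mp2, gp), "duplicated gene")
  expect_equal(nrow(e2$values), 10)
  expect_equal(e2$values["g1", ], expr$values["g1", ])

  # unlabeled sample and undersized groups are validation errors
  gp_short <- write_tsv(data.frame(sample = paste0("s", 1:5),
                                   group = c(rep("sensitive", 3),
                                             rep("resistant", 2))))
  expect_error(read_expression(mp, gp_short), "missing from groups")
  gp_small <- write_tsv(data.frame(sample = paste0("s", 1:6),
                                   group = c(rep("sensitive", 5),
                                             "resistant")))
  expect_error(read_expression(mp, gp_small), "at least 2 samples")
})

test_that("pathway JSON round-trips losslessly", {
  scores <- make_scores(c(A = 0.01, B = 0.2, C = 0.5))
  paths <- list(make_pathway(c("A", "B", "C"), kinds = "metabolic"),
                make_pathway(c("C", "A")))
  scored <- score_pathways(paths, list(), scores)
  f <- tempfile(fileext = ".json")
  write_pathways(scored, f)
  back <- read_pathways(f)
  expect_equal(length(back), 2)
  # a 3-gene pathway serializes with 3 genes and 2 edges
  expect_equal(length(back[[1]]$genes), 3)
  expect_equal(nrow(back[[1]]$pathway$edges), 2)
  for (i in 1:2) {
    expect_identical(back[[i]]$pathway$vertices,
                     scored[[i]]$pathway$vertices)
    expect_identical(back[[i]]$pathway$edges, scored[[i]]$pathway$edges)
    expect_equal(back[[i]]$z, scored[[i]]$z, tolerance = 1e-12)
    expect_equal(back[[i]]$score, scored[[i]]$score, tolerance = 1e-12)
  }
  # empty set round-trips to an empty array
  f2 <- tempfile(fileext = ".json")
  write_pathways(list(), f2)
  expect_equal(read_pathways(f2), list())
})

test_that("network JSON and SIF exports are consistent", {
  net <- make_net("A->B", "B--C", kind = c("regulation_positive",
                                           "protein_binding"))
  cn <- condense(net, "scc")
  f <- tempfile(fileext = ".json")
  write_network(cn, f)
  back <- read_network(f)
  expect_s3_class(back, "condensed_network")
  expect_identical(back$network$vertices, cn$network$vertices)
  expect_identical(back$network$edges, cn$network$edges)

  sif <- tempfile(fileext = ".sif")
  write_sif(net, sif)
  lines <- readLines(sif)
  expect_true("A\tregulation_positive\tB" %in% lines)
  # the undirected binding appears as both arcs
  expect_true(all(c("B\tprotein_binding\tC",
                    "C\tprotein_binding\tB") %in% lines))
})
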