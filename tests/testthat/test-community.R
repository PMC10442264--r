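test_that("agglomeration follows hand-computed merge order and heights", {
  m <- toy_matrix(c("A", "B", "C"), A_B = 0.8, A_C = 0.2, B_C = 0.2)
  d <- average_linkage(m)
  expect_equal(d$height, c(0.8, 0.2))
  expect_equal(d$merge[1, ], c(-1L, -2L))  # A and B first
  expect_equal(d$merge[2, ], c(-3L, 1L))   # then C joins the pair
})

test_that("two perfect cliques merge internally before joining at zero", {
  ids <- c("A1", "A2", "A3", "B1", "B2", "B3")
  m <- toy_matrix(ids, A1_A2 = 1, A1_A3 = 1, A2_A3 = 1,
                  B1_B2 = 1, B1_B3 = 1, B2_B3 = 1)
  d <- average_linkage(m)
  expect_equal(d$height[5], 0)         # last merge joins the two cliques
  memb <- cut_dendrogram(d, 0.5)
  expect_equal(unname(memb[c("A1", "A2", "A3")]), rep("A1", 3))
  expect_equal(unname(memb[c("B1", "B2", "B3")]), rep("B1", 3))
})

test_that("merge heights are monotone non-increasing", {
  for (seed in 1:5) {
    d <- average_linkage(random_matrix(9, seed))
    expect_true(all(diff(d$height) <= 1e-12))
  }
})

test_that("similarity agglomeration mirrors UPGMA on 1 - HWI", {
  for (seed in 1:10) {
    m <- random_matrix(8, seed)
    d <- average_linkage(m)
    hc <- stats::hclust(stats::as.dist(1 - unclass(m)), method = "average")
    expect_equal(sort(1 - d$height), sort(hc$height), tolerance = 1e-10)
    # cophenetic structure agrees, not just the height multiset
    H <- cophenetic_heights(d)
    Href <- 1 - as.matrix(stats::cophenetic(hc))
    expect_equal(H[rownames(Href), colnames(Href)][upper.tri(Href)],
                 Href[upper.tri(Href)], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("the hclust bridge is a valid monotone tree", {
  m <- random_matrix(7, seed = 21)
  hc <- as.hclust(average_linkage(m))
  expect_s3_class(hc, "hclust")
  expect_true(all(diff(hc$height) >= -1e-12))
  expect_setequal(hc$order, seq_len(7))
})

test_that("cophenetic correlation equals a direct Pearson computation", {
  m <- random_matrix(6, seed = 8)
  d <- average_linkage(m)
  H <- cophenetic_heights(d)
  ut <- upper.tri(H)
  expect_equal(cophenetic_correlation(d, m)$ccc,
               stats::cor(unclass(m)[ut], H[ut]))
})

test_that("an ultrametric matrix reproduces itself with CCC = 1", {
  # matrix generated from a planted two-level ultrametric hierarchy
  ids <- c("A1", "A2", "B1", "B2")
  m <- toy_matrix(ids, A1_A2 = 0.9, B1_B2 = 0.7,
                  A1_B1 = 0.1, A1_B2 = 0.1, A2_B1 = 0.1, A2_B2 = 0.1)
  d <- average_linkage(m)
  expect_equal(cophenetic_heights(d)[upper.tri(diag(4))],
               unclass(m)[upper.tri(diag(4))])
  expect_equal(cophenetic_correlation(d, m)$ccc, 1)
})

test_that("zero-variance input yields an undefined CCC with a warning", {
  ids <- c("A", "B", "C")
  m <- toy_matrix(ids, A_B = 0.5, A_C = 0.5, B_C = 0.5)
  d <- average_linkage(m)
  expect_warning(out <- cophenetic_correlation(d, m), "zero variance")
  expect_true(is.na(out$ccc))
})

test_that("CCC is invariant under affine rescaling of the matrix", {
  m <- random_matrix(7, seed = 13)
  d <- average_linkage(m)
  scaled <- association_matrix(unclass(m) * 0.5 + 0.1 * (1 - diag(7)))
  d2 <- average_linkage(scaled)
  expect_equal(cophenetic_correlation(d2, scaled)$ccc,
               cophenetic_correlation(d, m)$ccc, tolerance = 1e-10)
})

test_that("modularity matches hand values and the igraph oracle", {
  ids <- c("A", "B", "C")
  m1 <- toy_matrix(ids, A_B = 0.4, A_C = 0.3, B_C = 0.2)
  one <- stats::setNames(rep("x", 3), ids)
  expect_equal(modularity_q(m1, one), 0)

  # two disconnected unit-weight triangles split by triangle: Q = 1/2
  ids6 <- c("A1", "A2", "A3", "B1", "B2", "B3")
  tri <- toy_matrix(ids6, A1_A2 = 1, A1_A3 = 1, A2_A3 = 1,
                    B1_B2 = 1, B1_B3 = 1, B2_B3 = 1)
  memb <- stats::setNames(rep(c("a", "b"), each = 3), ids6)
  expect_equal(modularity_q(tri, memb), 0.5)

  for (seed in 1:6) {
    m <- random_matrix(7, seed)
    g <- igraph::graph_from_adjacency_matrix(unclass(m), mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    grp <- sample(1:3, 7, replace = TRUE)
    names(grp) <- rownames(m)
    expect_equal(
      modularity_q(m, grp),
      igraph::modularity(g, grp[igraph::V(g)$name],
                         weights = igraph::E(g)$weight),
      tolerance = 1e-10)
  }
})

test_that("modularity of an all-zero network is undefined", {
  ids <- c("A", "B", "C")
  m <- association_matrix(matrix(0, 3, 3, dimnames = list(ids, ids)))
  expect_warning(q <- modularity_q(m, stats::setNames(1:3, ids)),
                 "all-zero")
  expect_true(is.na(q))
})

test_that("best_partition recovers a planted three-block structure", {
  set.seed(99)
  ids <- sprintf("I%02d", 1:12)
  planted <- rep(c("a", "b", "c"), each = 4)
  base <- ifelse(outer(planted, planted, "=="), 0.6, 0.05)
  noise <- matrix(stats::rnorm(144, sd = 0.02), 12, 12)
  noise <- (noise + t(noise)) / 2
  vals <- pmin(pmax(base + noise, 0), 1)
  diag(vals) <- 0
  dimnames(vals) <- list(ids, ids)
  m <- association_matrix(vals)
  dg <- best_partition(m)
  expect_equal(dg$n_communities, 3)
  expect_equal(mclust::adjustedRandIndex(dg$membership[ids], planted), 1)
  # internal consistency: reported Q is the modularity of the returned cut
  expect_equal(dg$q_max, modularity_q(m, dg$membership))
  # the q_max row exists in the cut curve
  expect_true(any(abs(dg$q_by_cut$q - dg$q_max) < 1e-12))
})

test_that("with two leaves the better of joint/separate partitions wins", {
  m <- toy_matrix(c("A", "B"), A_B = 0.6)
  # a single dyad has no cophenetic variance; only the cut matters here
  dg <- suppressWarnings(best_partition(m))
  q_joint <- modularity_q(m, c(A = "x", B = "x"))
  q_split <- modularity_q(m, c(A = "x", B = "y"))
  expect_equal(dg$q_max, max(q_joint, q_split))
})

test_that("no dendrogram-consistent partition beats the returned cut", {
  # planted two-block society, exhaustive enumeration over all prunings
  ids <- c("A1", "A2", "A3", "B1", "B2", "B3")
  m <- toy_matrix(ids, A1_A2 = 0.7, A1_A3 = 0.65, A2_A3 = 0.6,
                  B1_B2 = 0.72, B1_B3 = 0.66, B2_B3 = 0.61,
                  A1_B1 = 0.08, A1_B2 = 0.05, A1_B3 = 0.04,
                  A2_B1 = 0.06, A2_B2 = 0.07, A2_B3 = 0.03,
                  A3_B1 = 0.02, A3_B2 = 0.05, A3_B3 = 0.06)
  d <- average_linkage(m)
  dg <- best_partition(m, dend = d)
  qs <- vapply(tree_partitions(d), function(parts)
    modularity_q(m, membership_from_parts(parts)), numeric(1))
  expect_gte(dg$q_max, max(qs) - 1e-12)
})

test_that("cluster exports produce readable artifacts", {
  m <- random_matrix(6, seed = 17)
  dg <- best_partition(m)
  dir <- withr::local_tempdir()
  write_diagnostics_json(dg, file.path(dir, "d.json"))
  parsed <- jsonlite::fromJSON(file.path(dir, "d.json"))
  expect_equal(parsed$q_max, dg$q_max)
  export_edgelist(m, file.path(dir, "e.csv"))
  edges <- utils::read.csv(file.path(dir, "e.csv"))
  expect_equal(nrow(edges), 15)
  export_graphml(m, file.path(dir, "g.graphml"),
                 vertex_attrs = data.frame(id = rownames(m),
                                           alliance = rep(c("x", "y"), 3)))
  g <- igraph::read_graph(file.path(dir, "g.graphml"), format = "graphml")
  expect_equal(igraph::gorder(g), 6)
  expect_true("alliance" %in% igraph::vertex_attr_names(g))
  export_newick(dg$dendrogram, file.path(dir, "t.nwk"))
  tree <- ape::read.tree(file.path(dir, "t.nwk"))
  expect_setequal(tree$tip.label, rownames(m))
})
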