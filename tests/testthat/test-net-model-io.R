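test_that("bipartite_layer enforces its invariants", {
  expect_error(bipartite_layer(matrix(numeric(0), 0, 1)), "at least one")
  expect_error(mk_layer(matrix(c(1, NA), 1, 2)), "missing")
  expect_warning(l <- mk_layer(matrix(c(0, 2.5), 1, 2)), "binarized")
  expect_equal(unname(l$incidence), matrix(c(0, 1), 1, 2))
  inc <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("y1", "y2")))
  expect_error(bipartite_layer(inc), "duplicate row")
  inc <- matrix(1, 1, 1, dimnames = list("a", "a"))
  expect_error(bipartite_layer(inc), "bipartite violation")
})

test_that("multilayer_pair aligns by union with zero padding", {
  # species present in one layer only gain an all-zero row/column
  l1 <- mk_layer(matrix(1, 2, 1, dimnames = list(c("x1", "x2"), "y1")))
  l2 <- mk_layer(matrix(1, 1, 2, dimnames = list("x1", c("y1", "y2"))))
  p <- multilayer_pair(l1, l2)
  expect_identical(p$layer1$rows, c("x1", "x2"))
  expect_identical(p$layer1$cols, c("y1", "y2"))
  expect_identical(p$layer1$rows, p$layer2$rows)
  expect_identical(p$layer1$cols, p$layer2$cols)
  expect_equal(p$layer1$incidence["x2", "y2"], 0)
  expect_equal(p$layer2$incidence["x2", "y1"], 0)
  expect_equal(sum(p$layer1$incidence), 2)
  expect_equal(sum(p$layer2$incidence), 2)
})

test_that("edge-list reader collapses duplicates and aligns the union", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "x1\ty1\tL1", "x1\ty1\tL1", "x2\ty2\tL2"), f)
  p <- read_edge_list(f, c("L1", "L2"))
  expect_equal(dim(p$layer1$incidence), c(2L, 2L))
  expect_equal(sum(p$layer1$incidence), 1)            # duplicate collapsed
  expect_equal(p$layer1$incidence["x1", "y1"], 1)
  expect_equal(sum(p$layer1$incidence["x2", ]), 0)    # zero row for x2
  expect_equal(sum(p$layer1$incidence[, "y2"]), 0)    # zero col for y2
  expect_equal(p$layer2$incidence["x2", "y2"], 1)
})

test_that("edge-list reader matches a hand-tabulated 3x3 fixture", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species_a\tspecies_b\tlayer",
               "x1\ty1\tL1", "x2\ty2\tL1", "x3\ty1\tL1",
               "x1\ty2\tL2", "x2\ty3\tL2", "x3\ty3\tL2"), f)
  p <- read_edge_list(f, c("L1", "L2"))
  exp1 <- matrix(c(1, 0, 0,  0, 1, 0,  1, 0, 0), 3, 3, byrow = TRUE,
                 dimnames = list(c("x1", "x2", "x3"), c("y1", "y2", "y3")))
  exp2 <- matrix(c(0, 1, 0,  0, 0, 1,  0, 0, 1), 3, 3, byrow = TRUE,
                 dimnames = list(c("x1", "x2", "x3"), c("y1", "y2", "y3")))
  expect_equal(p$layer1$incidence, exp1)
  expect_equal(p$layer2$incidence, exp2)
})

test_that("edge-list reader rejects bad layers and bipartite violations", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("x1\ty1\tL1", "x1\ty1\tBAD"), f)
  expect_error(read_edge_list(f, c("L1", "L2")), "line 2")
  writeLines(c("x1\ty1\tL1", "y1\tx1\tL2"), f)
  expect_error(read_edge_list(f, c("L1", "L2")), "both guilds")
  writeLines(c("species_a\tspecies_b\tlayer\tweight",
               "x1\ty1\tL1\t3", "x2\ty1\tL2\t0"), f)
  expect_warning(p <- read_edge_list(f, c("L1", "L2")), "binarized")
  expect_equal(sum(p$layer1$incidence), 1)   # weight 3 -> presence
  expect_equal(sum(p$layer2$incidence), 0)   # weight 0 -> absent edge
})

test_that("incidence reader unions label sets and rejects non-binary cells", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sp,y1", "x1,1", "x2,1"), f1)
  writeLines(c("sp,y1,y2", "x1,1,1"), f2)
  p <- read_incidence(f1, f2, c("L1", "L2"))
  expect_equal(dim(p$layer1$incidence), c(2L, 2L))
  expect_equal(p$layer1$incidence["x2", "y2"], 0)
  expect_equal(p$layer2$incidence["x1", "y2"], 1)
  # identical identity matrices give layer1 == layer2
  writeLines(c("sp,y1,y2", "x1,1,0", "x2,0,1"), f1)
  p2 <- read_incidence(f1, f1, c("A", "B"))
  expect_equal(p2$layer1$incidence, p2$layer2$incidence)
  writeLines(c("sp,y1", "x1,2"), f2)
  expect_error(read_incidence(f1, f2, c("A", "B")), "0 or 1")
})

test_that("edge-list round trip preserves incidence and label order", {
  pp <- planted_pair(n_rows = 9, n_cols = 7, k_modules = 2, seed = 11)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(pp$pair, f)
  back <- read_edge_list(f, c("layer1", "layer2"))
  expect_identical(back$layer1$incidence, pp$pair$layer1$incidence)
  expect_identical(back$layer2$incidence, pp$pair$layer2$incidence)
  expect_identical(back$layer1$rows, pp$pair$layer1$rows)
  expect_identical(back$layer1$cols, pp$pair$layer1$cols)
})

test_that("full adjacency has the three-block structure and is symmetric", {
  # m = 1, p = 1 minimal case
  p <- mk_pair(matrix(1, 1, 1), matrix(0, 1, 1))
  A <- full_adjacency(p)
  expect_equal(dim(A), c(3L, 3L))
  expect_equal(A[1, 2], 1); expect_equal(A[2, 1], 1)
  expect_equal(sum(A), 2)
  # m = 2, p = 2 hand-assembled block matrix
  B <- matrix(c(1, 1, 0, 1), 2, 2); C <- matrix(c(0, 1, 1, 0), 2, 2)
  pr <- mk_pair(B, C)
  A6 <- full_adjacency(pr)
  hand <- rbind(cbind(matrix(0, 2, 2), B,               matrix(0, 2, 2)),
                cbind(t(B),            matrix(0, 2, 2), t(C)),
                cbind(matrix(0, 2, 2), C,               matrix(0, 2, 2)))
  expect_equal(unname(A6), hand)
  expect_identical(A6, t(A6))
  # restriction to (layer-1 rows, cols) recovers the layer-1 sub-adjacency
  expect_equal(unname(A6[1:4, 1:4]),
               unname(costructure:::layer_adjacency(pr$layer1)))
})

test_that("layer_summary computes links, connectance and zero-degree counts", {
  z <- mk_layer(matrix(0, 3, 4))
  s <- layer_summary(z)
  expect_equal(s$n_links, 0L)
  expect_equal(s$connectance, 0)
  expect_equal(s$n_zero_degree_rows, 3L)
  expect_equal(s$n_zero_degree_cols, 4L)
  o <- layer_summary(mk_layer(matrix(1, 2, 2)))
  expect_equal(o$n_links, 4L)
  expect_equal(o$connectance, 1)
  # published-scale example: L = 5219 links among 972 x 1123 species
  expect_equal(round(5219 / (972 * 1123), 3), 0.005)
  # degree-sum consistency on a random fixture
  l <- random_layer(7, 5, seed = 4)
  expect_equal(sum(degrees(l, "rows")), layer_summary(l)$n_links)
  expect_equal(sum(degrees(l, "cols")), layer_summary(l)$n_links)
})

test_that("graphml export writes readable graphs", {
  pp <- planted_pair(n_rows = 5, n_cols = 5, k_modules = 2, seed = 2)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(pp$pair$layer1, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gsize(g), layer_summary(pp$pair$layer1)$n_links)
  write_graphml(pp$pair, f)
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g2), 15)  # m + p + m
  expect_equal(igraph::gsize(g2),
               layer_summary(pp$pair$layer1)$n_links +
                 layer_summary(pp$pair$layer2)$n_links)
})
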