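# two disjoint 1-1 interactions: the canonical Q = 0.5 fixture
two_edges <- function() {
  inc <- matrix(0, 2, 2, dimnames = list(c("x1", "x2"), c("y1", "y2")))
  inc[1, 1] <- inc[2, 2] <- 1
  bipartite_layer(inc)
}

test_that("two disjoint edges split into two modules with Q = 0.5", {
  part <- detect_modules(two_edges())
  expect_equal(part$n_modules, 2L)
  expect_equal(part$modularity_q, 0.5)
  expect_equal(unname(part$membership[c("x1", "y1")]),
               rep(part$membership[["x1"]], 2))
  expect_equal(unname(part$membership[c("x2", "y2")]),
               rep(part$membership[["x2"]], 2))
  # brute force over every partition of the 4 nodes confirms the optimum
  A <- costructure:::layer_adjacency(two_edges())
  best <- best_q_bruteforce(A)
  expect_equal(best$q, 0.5)
  expect_equal(part$modularity_q, best$q)
})

test_that("a complete bipartite block stays one module", {
  part <- detect_modules(mk_layer(matrix(1, 2, 2)))
  expect_equal(part$n_modules, 1L)
  expect_equal(part$modularity_q, 0)
})

test_that("isolated species always form singleton modules", {
  inc <- matrix(0, 5, 3, dimnames = list(paste0("x", 1:5), paste0("y", 1:3)))
  inc[1, 1] <- inc[2, 2] <- inc[3, 3] <- 1   # x4, x5 isolated
  part <- detect_modules(mk_layer(inc))
  sizes <- table(part$membership)
  for (sp in c("x4", "x5"))
    expect_equal(sum(part$membership == part$membership[[sp]]), 1L)
  # empty layer errors; all-zero layer is all singletons with Q = 0
  allz <- detect_modules(mk_layer(matrix(0, 3, 2)))
  expect_equal(allz$n_modules, 5L)
  expect_equal(allz$modularity_q, 0)
})

test_that("modularity_q matches the definitional oracle and identities", {
  l <- random_layer(6, 5, density = 0.4, seed = 21)
  part <- detect_modules(l)
  A <- costructure:::layer_adjacency(l)
  expect_equal(part$modularity_q,
               q_oracle(A, part$membership[rownames(A)]))
  # all-in-one partition has Q = 0
  one <- rep(0L, nrow(A)); names(one) <- rownames(A)
  expect_equal(modularity_q(l, one), 0)
  # Q is invariant under module relabelling
  relab <- (part$membership + 3L) %% part$n_modules
  names(relab) <- names(part$membership)
  expect_equal(modularity_q(l, relab), part$modularity_q)
  expect_error(modularity_q(l, one[-1]), "match")
})

test_that("detected Q dominates random partitions and components partition", {
  pp <- planted_pair(n_rows = 12, n_cols = 12, k_modules = 2, seed = 31)
  l <- pp$pair$layer1
  part <- detect_modules(l)
  A <- costructure:::layer_adjacency(l)
  # >= connected-components partition
  g_comp <- costructure:::adjacency_components(A, which(rowSums(A) > 0))
  comp_memb <- integer(nrow(A)); names(comp_memb) <- rownames(A)
  for (i in seq_along(g_comp)) comp_memb[g_comp[[i]]] <- i
  iso <- which(rowSums(A) == 0)
  comp_memb[iso] <- length(g_comp) + seq_along(iso)
  expect_gte(part$modularity_q, modularity_q(l, comp_memb) - 1e-12)
  # >= 100 random partitions
  set.seed(1)
  for (r in 1:100) {
    rnd <- sample.int(4, nrow(A), replace = TRUE)
    names(rnd) <- rownames(A)
    expect_gte(part$modularity_q, modularity_q(l, rnd))
  }
})

test_that("small-graph splits achieve the brute-force optimum when one exists", {
  # all fixtures have <= 8 interacting nodes; enumeration is exact
  fixtures <- list(
    rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1)),
    rbind(c(1, 0, 0), c(0, 1, 1), c(0, 1, 1)),
    rbind(c(1, 1), c(1, 0), c(0, 1)))
  for (inc in fixtures) {
    l <- mk_layer(inc)
    A <- costructure:::layer_adjacency(l)
    best <- best_q_bruteforce(A)
    part <- detect_modules(l)
    if (best$q > 1e-9) expect_gte(part$modularity_q, 0)
    # the refined spectral search reaches the optimum on these tiny graphs
    expect_equal(part$modularity_q, best$q, tolerance = 1e-9)
  }
})

test_that("partitions are canonical and deterministic", {
  pp <- planted_pair(n_rows = 20, n_cols = 20, seed = 13)
  a <- detect_modules(pp$pair$layer1)
  b <- detect_modules(pp$pair$layer1)
  expect_identical(a, b)
  # ids contiguous from 0, ordered by decreasing module size
  ids <- sort(unique(a$membership))
  expect_identical(ids, seq_along(ids) - 1L)
  sizes <- vapply(ids, function(i) sum(a$membership == i), 0L)
  expect_true(all(diff(sizes) <= 0))
  # modules never straddle connected components
  A <- costructure:::layer_adjacency(pp$pair$layer1)
  comps <- costructure:::adjacency_components(A, seq_len(nrow(A))[rowSums(A) > 0])
  comp_id <- integer(nrow(A))
  for (i in seq_along(comps)) comp_id[comps[[i]]] <- i
  for (mod in ids) {
    members <- which(a$membership[rownames(A)] == mod)
    cc <- unique(comp_id[members])
    expect_lte(length(cc[cc > 0]), 1L)
  }
  expect_gte(a$n_modules, length(comps))
})

test_that("eigenvector-only variant reproduces igraph leading-eigen exactly", {
  for (seed in c(1, 5, 9)) {
    pp <- planted_pair(n_rows = 15, n_cols = 15, k_modules = 3, seed = seed)
    l <- pp$pair$layer1
    ours <- detect_modules(l, fine_tune = FALSE)
    g <- igraph::graph_from_adjacency_matrix(
      costructure:::layer_adjacency(l), mode = "undirected")
    ref <- igraph::cluster_leading_eigen(g)
    expect_equal(ours$modularity_q, igraph::modularity(ref), tolerance = 1e-10)
    # identical grouping up to labels
    expect_equal(nmi(confusion(ours$membership,
                               structure(as.integer(igraph::membership(ref)),
                                         names = names(ours$membership)))),
                 1, tolerance = 1e-12)
  }
})

test_that("write_partition exports species/module TSV with JSON sidecar", {
  part <- detect_modules(two_edges())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, f)
  df <- read.delim(f)
  expect_equal(names(df), c("species", "module_id"))
  expect_equal(nrow(df), 4L)
  js <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(js$n_modules, 2L)
  expect_equal(js$modularity_q, 0.5)
})
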