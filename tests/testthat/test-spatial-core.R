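test_that("radius graph uses inclusive same-domain Euclidean threshold", {
  ds <- toy_dataset()
  # cells 1-2 are exactly 5 um apart; threshold is inclusive
  g5 <- build_graph(ds, 5)
  expect_equal(g5$adjacency[1, 2], 1)
  expect_equal(g5$adjacency[2, 1], 1)
  expect_equal(g5$adjacency[1, 1], 0)
  # just below the distance: no edge, degree 0 for both
  g49 <- build_graph(ds, 4.9)
  expect_equal(g49$adjacency[1, 2], 0)
  expect_equal(g49$degree[1:2], c(0L, 0L))
  # a single cell has an empty graph
  one <- spatial_dataset(matrix(1, 1, 1), matrix(0, 1, 2), "A", "img")
  expect_equal(build_graph(one, 10)$degree, 0L)
  expect_error(build_graph(ds, -1), "positive")
})

test_that("graph never links cells across domains and rows of Abar sum to 1", {
  ds <- random_dataset(n = 80, seed = 3)
  g <- build_graph(ds, 40)
  adj <- as.matrix(g$adjacency)
  cross <- outer(ds$domain, ds$domain, "!=")
  expect_true(all(adj[cross] == 0))
  expect_equal(adj, t(adj))
  rs <- Matrix::rowSums(g$normalized_adjacency)
  expect_equal(unname(rs[g$degree > 0]), rep(1, sum(g$degree > 0)),
               tolerance = 1e-12)
  expect_true(all(rs[g$degree == 0] == 0))
})

test_that("edge sets are nested as the resolution grows", {
  ds <- random_dataset(n = 60, seed = 5)
  radii <- c(10, 25, 50, 90)
  prev <- NULL
  for (r in radii) {
    adj <- as.matrix(build_graph(ds, r)$adjacency)
    if (!is.null(prev)) expect_true(all(adj[prev > 0] > 0))
    prev <- adj
  }
})

test_that("resolution grid spans the degree range and includes 10 um", {
  ds <- random_dataset(n = 100, seed = 2)
  grid <- resolution_grid(ds, n_points = 4)
  expect_true(all(diff(grid) > 0))
  expect_true(10 %in% grid)
  degs <- vapply(grid, function(r) mean(build_graph(ds, r)$degree), numeric(1))
  expect_true(all(diff(degs) >= 0))
  # two cells 100 um apart: the largest radius must reach them
  two <- spatial_dataset(matrix(1:4, 2), rbind(c(0, 0), c(100, 0)),
                         c("A", "A"), c("i", "i"))
  expect_gte(max(resolution_grid(two, 2, max_mean_degree = 1)), 100)
  same <- spatial_dataset(matrix(1:4, 2), rbind(c(1, 1), c(1, 1)),
                          c("A", "A"), c("i", "i"))
  expect_error(resolution_grid(same, 3), "degenerate")
})

test_that("node splits have the documented sizes and are seed-deterministic", {
  s <- split_nodes(100, seed = 11)
  expect_length(s$test, 10)
  expect_length(s$validation, 9)
  expect_length(s$train, 81)
  expect_identical(split_nodes(100, 11)$test, s$test)
  expect_false(identical(split_nodes(100, 12)$test, s$test))
  # reference trace of the sampling procedure under the same seed
  ref <- withr::with_seed(42, {
    te <- sample.int(1000, 100)
    re <- setdiff(1:1000, te)
    list(test = sort(te), val = sort(re[sample.int(900, 90)]))
  })
  s2 <- split_nodes(1000, 42)
  expect_identical(s2$test, ref$test)
  expect_identical(sort(s2$validation), ref$val)
  expect_error(split_nodes(9, 1), "at least 10")
})

test_that("split proportions hold for every N from 10 to 200", {
  for (n in 10:200) {
    s <- split_nodes(n, seed = 1)
    expect_length(s$test, floor(0.10 * n + 0.5))
    expect_length(s$validation, floor(0.10 * (n - length(s$test)) + 0.5))
    expect_equal(length(s$train) + length(s$validation) + length(s$test), n)
    expect_setequal(c(s$train, s$validation, s$test), seq_len(n))
  }
})

test_that("size factors follow the total-count formula and average to one", {
  ds <- spatial_dataset(matrix(c(1, 3, 1, 3), 2), matrix(0, 2, 2),
                        c("A", "A"), c("i", "i"))
  expect_equal(size_factors(ds), c(0.5, 1.5))
  dsr <- random_dataset(seed = 8)
  expect_equal(mean(size_factors(dsr)), 1, tolerance = 1e-12)
  same <- spatial_dataset(matrix(2, 3, 2), matrix(0, 3, 2),
                          rep("A", 3), rep("i", 3))
  expect_equal(size_factors(same), rep(1, 3))
  zero <- spatial_dataset(matrix(c(0, 1, 0, 1), 2), matrix(0, 2, 2),
                          c("A", "A"), c("i", "i"))
  expect_error(size_factors(zero), "cell")
})

test_that("variance decomposition reproduces the hand-computed example", {
  ds <- spatial_dataset(matrix(c(0, 2, 4, 6), 4, 1), matrix(0, 4, 2),
                        c("a", "a", "b", "b"), rep("i", 4))
  vd <- variance_decomposition(ds)
  expect_equal(vd$intra_type_ss, 4)
  expect_equal(vd$inter_type_ss, 16)
  expect_equal(vd$gene_ss, 0)
  expect_equal(vd$total_ss, 20)
  expect_equal(sum(vd$fractions), 1)
  # all-identical cells: every term zero
  flat <- spatial_dataset(matrix(3, 4, 2), matrix(0, 4, 2),
                          c("a", "a", "b", "b"), rep("i", 4))
  vdf <- variance_decomposition(flat)
  expect_equal(vdf$total_ss, 0)
  # one cell per type: intra term vanishes
  single <- spatial_dataset(matrix(c(1, 5, 2, 9), 2), matrix(0, 2, 2),
                            c("a", "b"), c("i", "i"))
  expect_equal(variance_decomposition(single)$intra_type_ss, 0)
})

test_that("variance components always sum to the total sum of squares", {
  for (seed in 1:100) {
    ds <- random_dataset(n = 30, j = 4, l = sample(1:4, 1), seed = seed)
    vd <- variance_decomposition(ds)
    expect_equal(vd$intra_type_ss + vd$inter_type_ss + vd$gene_ss,
                 vd$total_ss, tolerance = 1e-9)
  }
})

test_that("log transform is log1p with provenance and rejects negatives", {
  ds <- toy_dataset()
  lt <- log_transform(ds)
  expect_true(lt$log1p)
  expect_equal(lt$expression, log1p(ds$expression))
  expect_equal(expm1(lt$expression), ds$expression, tolerance = 1e-12)
  neg <- ds; neg$expression[1, 1] <- -1
  expect_error(log_transform(neg), "negative")
})

test_that("dataset construction validates shapes, labels and coordinates", {
  expect_error(spatial_dataset(matrix(1, 2, 2), matrix(0, 3, 2),
                               c("A", "B"), c("i", "i")), "cells")
  expect_error(spatial_dataset(matrix(1, 2, 2), matrix(c(0, Inf), 2, 2),
                               c("A", "B"), c("i", "i")), "finite")
  expect_error(spatial_dataset(matrix(1, 2, 2), matrix(0, 2, 2),
                               c("A", "B"), c("i", "i"),
                               gene_names = c("g", "g")), "unique")
})
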