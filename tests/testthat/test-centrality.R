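# Density and the three Freeman centralities, against closed-form cases and
# the igraph implementations as independent oracle.

test_that("density counts off-diagonal ties over n(n-1)", {
  A3 <- matrix(1L, 3, 3) - diag(3L)
  s <- network_density(A3)
  expect_equal(s$m, 6L)
  expect_equal(s$density, 1)
  expect_equal(network_density(matrix(0L, 4, 4))$density, 0)
  # n = 47, m = 413 -> 0.191 at 3 dp (the reported 2020-regime magnitude)
  set.seed(3)
  A <- matrix(0L, 47, 47)
  ones <- sample(which(row(A) != col(A)), 413)
  A[ones] <- 1L
  expect_equal(round(network_density(A)$density, 3), 0.191)
  expect_error(network_density(matrix(0L, 1, 1)), "2 nodes")
})

test_that("star and isolated-node degree cases", {
  A <- star_tie(5)
  d <- degree_centrality(A)
  expect_equal(unname(d[1]), 1)
  expect_equal(unname(d[2]), 0.25)
  A2 <- rbind(cbind(star_tie(4), 0L), 0L)  # add an isolate
  expect_equal(unname(degree_centrality(A2)[5]), 0)
  # in/out modes on a single directed tie
  B <- matrix(0L, 3, 3); B[1, 2] <- 1L
  expect_equal(unname(degree_centrality(B, "out")), c(0.5, 0, 0))
  expect_equal(unname(degree_centrality(B, "in")), c(0, 0.5, 0))
})

test_that("star betweenness and closeness are extremal", {
  A <- star_tie(5)
  b <- betweenness_centrality(A)
  expect_equal(unname(b[1]), 1)
  expect_equal(unname(b[-1]), rep(0, 4))
  cl <- closeness_centrality(A)
  expect_equal(unname(cl$farness[1]), 4)
  expect_equal(unname(cl$closeness[1]), 1)
})

test_that("disconnected pairs use the documented distance convention", {
  # two disjoint dyads, n = 4: farness = 1 + 2 * 4 = 9 per node
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1L
  cl <- closeness_centrality(A)
  expect_equal(unname(cl$farness), rep(9, 4))
  expect_equal(unname(cl$closeness), rep(3 / 9, 4))
  # betweenness: unreachable pairs contribute zero
  expect_equal(unname(betweenness_centrality(A)), rep(0, 4))
})

test_that("centralities match igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(71)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    A <- rand_tie(n, runif(1, 0.15, 0.6))
    sym <- ((A + t(A)) > 0) * 1
    g <- igraph::graph_from_adjacency_matrix(sym, mode = "undirected")
    expect_equal(unname(degree_centrality(A)),
                 unname(igraph::degree(g) / (n - 1)), tolerance = 1e-12)
    expect_equal(unname(betweenness_centrality(A)),
                 unname(igraph::betweenness(g, directed = FALSE,
                                            normalized = TRUE)),
                 tolerance = 1e-10)
    if (igraph::is_connected(g)) {
      expect_equal(unname(closeness_centrality(A)$closeness) / (n - 1),
                   unname(igraph::closeness(g)), tolerance = 1e-10)
    }
  }
})

test_that("betweenness agrees with walk-count path enumeration on tiny graphs", {
  set.seed(81)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    A <- rand_tie(n, 0.4)
    sym <- ((A + t(A)) > 0) * 1
    expect_equal(unname(betweenness_centrality(A)), brute_betweenness(sym),
                 tolerance = 1e-12)
  }
})

test_that("adding a tie never decreases symmetrized degree", {
  set.seed(91)
  A <- rand_tie(10, 0.2)
  zeros <- which(A == 0 & row(A) != col(A))
  d0 <- degree_centrality(A)
  A2 <- A
  A2[zeros[1]] <- 1L
  expect_true(all(degree_centrality(A2) >= d0))
})

test_that("the ranked report is deterministic with lexicographic tie-breaks", {
  A <- star_tie(5)
  rep1 <- centrality_report(A)
  expect_equal(rep1$rank_degree[1], 1L)
  expect_equal(rep1$rank_closeness[1], 1L)
  expect_equal(rep1$rank_betweenness[1], 1L)
  # leaves tie on every measure: ranks follow city id order
  expect_equal(rep1$rank_degree[-1], 2:5)
  m <- attr(rep1, "means")
  expect_true(all(m >= 0) && m[["degree"]] <= 1)
  # a regular all-equal graph ranks purely lexicographically
  K4 <- matrix(1L, 4, 4) - diag(4L)
  dimnames(K4) <- list(letters[1:4], letters[1:4])
  rep2 <- centrality_report(K4)
  expect_equal(rep2$rank_degree, 1:4)
  # percent scale is 100x the fraction scale
  expect_equal(rep2$degree_pct, 100 * rep2$degree)
})

test_that("report writes with a mean row appended", {
  A <- star_tie(5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_centrality(centrality_report(A), f)
  d <- utils::read.csv(f)
  expect_equal(nrow(d), 6L)
  expect_equal(d$city_id[6], "Average")
  expect_equal(d$degree[6], mean(d$degree[1:5]))
})
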