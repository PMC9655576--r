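test_that("network construction counts directed events and keeps isolates", {
  ev <- tibble::tibble(donor = c(1, 1, 1, 2), receiver = c(2, 2, 2, 1))
  net <- build_network(ev, roster = 1:4)
  expect_equal(igraph::vcount(net), 4)
  el <- network_edge_list(net)
  expect_equal(el$weight[el$donor == "1" & el$receiver == "2"], 3)
  expect_equal(el$weight[el$donor == "2" & el$receiver == "1"], 1)

  empty <- build_network(ev[0, ], roster = 1:53)
  expect_equal(igraph::vcount(empty), 53)
  expect_equal(igraph::ecount(empty), 0)
  expect_error(build_network(ev, roster = 3:5), "roster")
})

test_that("a toy log reproduces its hand-counted adjacency", {
  ev <- tibble::tibble(donor = c(1, 2, 1, 3, 1), receiver = c(2, 3, 2, 1, 4))
  net <- build_network(ev, roster = 1:5)
  adj <- igraph::as_adjacency_matrix(net, attr = "weight", sparse = FALSE)
  expected <- matrix(0, 5, 5, dimnames = list(1:5, 1:5))
  expected[1, 2] <- 2; expected[2, 3] <- 1; expected[3, 1] <- 1; expected[1, 4] <- 1
  expect_equal(adj, expected)
})

test_that("global efficiency matches closed forms on simple graphs", {
  two <- build_network(tibble::tibble(donor = 1, receiver = 2), roster = 1:2)
  expect_equal(global_efficiency(two), 1)
  path3 <- build_network(tibble::tibble(donor = c(1, 2), receiver = c(2, 3)),
                         roster = 1:3)
  expect_equal(global_efficiency(path3), 5 / 6)
  edgeless <- build_network(tibble::tibble(donor = integer(), receiver = integer()),
                            roster = 1:5)
  expect_equal(global_efficiency(edgeless), 0)
  expect_error(global_efficiency(build_network(tibble::tibble(donor = integer(),
                                                              receiver = integer()),
                                               roster = 1)), "2 nodes")
})

test_that("centralities match conventions on canonical graphs", {
  # undirected star: the centre lies on every leaf-to-leaf shortest path
  star <- tibble::tibble(donor = rep(1, 5), receiver = 2:6)
  net <- build_network(star, roster = 1:6)
  cent <- node_centralities(net, directed_betweenness = FALSE)
  expect_equal(cent$betweenness[cent$id == "1"], 1)
  expect_equal(cent$betweenness[cent$id != "1"], rep(0, 5))

  triangle <- build_network(tibble::tibble(donor = c(1, 2, 3), receiver = c(2, 3, 1)),
                            roster = 1:3)
  cent_tri <- node_centralities(triangle)
  expect_equal(cent_tri$clustering, rep(1, 3))

  with_iso <- build_network(tibble::tibble(donor = 1, receiver = 2), roster = 1:3)
  cent_iso <- node_centralities(with_iso)
  expect_equal(cent_iso$closeness[cent_iso$id == "3"], 0)
  expect_equal(cent_iso$betweenness[cent_iso$id == "3"], 0)
  expect_equal(cent_iso$clustering[cent_iso$id == "3"], 0)
})

test_that("shortest-path metrics agree with the brute-force oracle", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(3:7, 1)
    adj <- random_adj(n)
    events <- adj_to_events(adj)
    net <- build_network(events, roster = 1:n)
    expect_equal(global_efficiency(net), oracle_efficiency(adj),
                 tolerance = 1e-10)
    cent <- node_centralities(net)
    expect_equal(cent$closeness, oracle_closeness(adj), tolerance = 1e-10)
    expect_equal(cent$betweenness, oracle_betweenness(adj, directed = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("efficiency never decreases when an edge is added", {
  set.seed(32)
  for (rep in 1:8) {
    n <- 6
    adj <- random_adj(n, p = 0.2)
    zeros <- which(adj == 0 & diag(n) == 0, arr.ind = TRUE)
    if (nrow(zeros) == 0) next
    pick <- zeros[sample(nrow(zeros), 1), , drop = FALSE]
    adj2 <- adj
    adj2[pick] <- 1
    e1 <- oracle_efficiency(adj)
    net2 <- build_network(adj_to_events(adj2), roster = 1:n)
    expect_gte(global_efficiency(net2) + 1e-12, e1)
  }
})

test_that("Lorenz curve and Gini match closed forms and invariances", {
  expect_equal(lorenz_gini(c(5, 5, 5, 5))$gini, 0)
  expect_equal(lorenz_gini(c(0, 0, 0, 12))$gini, 0.75)
  set.seed(33)
  x <- rpois(40, 3) + 1
  g <- lorenz_gini(x)$gini
  expect_equal(lorenz_gini(sample(x))$gini, g)       # permutation invariance
  expect_equal(lorenz_gini(7 * x)$gini, g)           # scale invariance
  expect_true(g >= 0 && g <= 1 - 1 / length(x))
  L <- lorenz_gini(x)$lorenz
  expect_true(all(diff(L$L) >= 0))                   # nondecreasing
  expect_true(all(diff(diff(L$L)) >= -1e-12))        # convex
  expect_equal(L$L[c(1, nrow(L))], c(0, 1))
  expect_error(lorenz_gini(c(0, 0)), "all-zero")
  expect_error(lorenz_gini(c(-1, 3)), "nonnegative")
})

test_that("T50 is the first time half the events have started", {
  expect_equal(t50(tibble::tibble(t_start = 1:100)), 50)
  expect_equal(t50(tibble::tibble(t_start = rep(10, 7))), 10)
  expect_equal(t50(tibble::tibble(t_start = c(3, 7, 7, 900))), 7)
  expect_error(t50(tibble::tibble(t_start = numeric())), "empty")
})

test_that("activity profiles tally a toy log and conserve the event count", {
  roster <- tibble::tibble(id = 1:5, caste = c("F", "F", "NF", "NF", "NF"))
  ev <- tibble::tibble(donor = c(1, 1, 2, 3, 1, 4),
                       receiver = c(2, 3, 3, 1, 5, 3))
  prof <- activity_profile(ev, roster)
  expect_equal(prof$given, c(3, 1, 1, 1, 0))
  expect_equal(prof$received, c(1, 1, 3, 0, 1))
  expect_equal(sum(prof$given), nrow(ev))
  expect_equal(sum(prof$received), nrow(ev))

  dist <- activity_distributions(ev, roster)
  all_counts <- dist$count[dist$distribution == "all"]
  expect_equal(sum(all_counts), 2 * nrow(ev))
  expect_equal(sum(dist$count[dist$distribution == "F_given"]) +
                 sum(dist$count[dist$distribution == "NF_given"]), nrow(ev))
  # a single event: donor has given = 1, receiver received = 1, rest zero
  one <- activity_profile(tibble::tibble(donor = 2, receiver = 4), roster)
  expect_equal(one$given, c(0, 1, 0, 0, 0))
  expect_equal(one$received, c(0, 0, 0, 1, 0))
})
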