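toy_bridge_network <- function() {
  nodes <- c("A1", "A2", "B1")
  w <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  w["A1", "A2"] <- w["A2", "A1"] <- 0.5
  w["A2", "B1"] <- w["B1", "A2"] <- 0.5
  part <- c(A1 = "depression", A2 = "depression", B1 = "anxiety")
  symptom_network(w, partition = part)
}

test_that("strength centrality handles isolated nodes and stars", {
  nodes <- c("Anh", "Sdn", "Slp", "Nrv")
  w <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  w["Anh", "Sdn"] <- w["Sdn", "Anh"] <- 0.2
  w["Anh", "Slp"] <- w["Slp", "Anh"] <- 0.3
  net <- symptom_network(w)
  s <- strength_centrality(net)
  expect_equal(unname(s["Anh"]), 0.5)
  expect_equal(unname(s["Nrv"]), 0)
})

test_that("graph distances are reciprocal-weight shortest paths", {
  net <- toy_bridge_network()
  d <- graph_distances(net)
  expect_equal(d["A1", "A2"], 2)     # single edge of weight 0.5
  expect_equal(d["A1", "B1"], 4)     # path through A2
  # unreachable pair
  nodes <- c("A1", "B1")
  w <- matrix(0, 2, 2, dimnames = list(nodes, nodes))
  net2 <- symptom_network(w, partition = c(A1 = "depression",
                                           B1 = "anxiety"))
  expect_true(is.infinite(graph_distances(net2)["A1", "B1"]))
})

test_that("distances match exhaustive path enumeration on random networks", {
  for (s in 1:5) {
    net <- random_symptom_network(p = 6, seed = 40 + s)
    d <- graph_distances(net)
    len <- 1 / abs(net$weights)
    len[net$weights == 0] <- Inf
    diag(len) <- Inf
    expect_equal(d, brute_force_distances(len), ignore_attr = TRUE)
  }
})

test_that("bridge indices reproduce the worked toy example", {
  net <- toy_bridge_network()
  b <- bridge_centrality(net)
  rownames(b) <- b$node
  expect_equal(b[c("A1", "A2", "B1"), "bridge_betweenness"], c(0, 1, 0),
               ignore_attr = TRUE)
  expect_equal(b[c("A1", "A2", "B1"), "bridge_strength"], c(0, 0.5, 0.5),
               ignore_attr = TRUE)
  expect_equal(b[c("A1", "A2", "B1"), "bridge_closeness"],
               c(1 / 4, 1 / 2, 1 / 3), ignore_attr = TRUE)
})

test_that("bridge betweenness and closeness match brute force on random networks", {
  for (s in 1:10) {
    p <- sample(4:7, 1)
    net <- random_symptom_network(p = p, seed = 70 + s)
    b <- bridge_centrality(net)
    expect_equal(b$bridge_betweenness,
                 brute_force_bridge_betweenness(net$weights,
                                                net$partition),
                 tolerance = 1e-9)
    expect_equal(b$bridge_closeness,
                 brute_force_bridge_closeness(net$weights,
                                              net$partition),
                 tolerance = 1e-9)
  }
})

test_that("bridge strength never exceeds strength", {
  for (s in 1:10) {
    net <- random_symptom_network(p = 7, seed = 90 + s)
    b <- bridge_centrality(net)
    expect_true(all(b$bridge_strength <= b$strength + 1e-12))
  }
})

test_that("removing all cross-community edges zeroes every bridge index", {
  net <- random_symptom_network(p = 7, seed = 101)
  w <- net$weights
  cross <- outer(net$partition, net$partition, "!=")
  w[cross] <- 0
  cut_net <- symptom_network(w, partition = net$partition)
  b <- bridge_centrality(cut_net)
  expect_true(all(b$bridge_strength == 0))
  expect_true(all(b$bridge_betweenness == 0))
  expect_true(all(b$bridge_closeness == 0))
  expect_true(all(attr(b, "unreachable")))
})

test_that("integer tie counting counts a node once per crossing pair", {
  # diamond: two equal shortest paths A-B1-D and A-B2-D
  nodes <- c("A", "B1", "B2", "D")
  w <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  for (pr in list(c("A", "B1"), c("A", "B2"), c("B1", "D"),
                  c("B2", "D")))
    w[pr[1], pr[2]] <- w[pr[2], pr[1]] <- 0.5
  part <- c(A = "depression", B1 = "depression", B2 = "depression",
            D = "anxiety")
  net <- symptom_network(w, partition = part)
  frac <- bridge_centrality(net, fractional = TRUE)
  int <- bridge_centrality(net, fractional = FALSE)
  rownames(frac) <- frac$node; rownames(int) <- int$node
  expect_equal(frac["B1", "bridge_betweenness"], 0.5, ignore_attr = TRUE)
  expect_equal(int["B1", "bridge_betweenness"], 1, ignore_attr = TRUE)
})
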