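star_net <- function(k = 4) {
  gene_network(data.frame(a = "center", b = sprintf("leaf%d", seq_len(k)),
                          confidence = 0.9))
}

test_that("star and path closed forms hold exactly", {
  cen <- centralities(star_net(4))
  c_row <- cen[cen$node == "center", ]
  l_row <- cen[cen$node == "leaf1", ]
  expect_equal(c_row$degree, 4)
  expect_equal(l_row$degree, 1)
  expect_equal(c_row$closeness, 1.0)
  expect_equal(l_row$closeness, (1 + 3 * 0.5) / 4)
  expect_equal(c_row$betweenness, 1.0)  # 6 leaf pairs / 6, pair-normalized
  expect_equal(l_row$betweenness, 0)

  path <- gene_network(data.frame(a = c("A", "B"), b = c("B", "C"),
                                  confidence = 1))
  pc <- centralities(path)
  expect_equal(pc$betweenness[pc$node == "B"], 1.0)
  expect_equal(pc$betweenness[pc$node == "A"], 0)
  expect_equal(pc$betweenness[pc$node == "C"], 0)
})

test_that("centralities match the brute-force all-pairs oracle on random graphs", {
  for (i in 1:25) {
    n <- sample(5:50, 1)
    net <- random_network(n, p = runif(1, 0.05, 0.3), seed = 1000 + i)
    got <- centralities(net)
    want <- oracle_centralities(net)
    expect_equal(got$node, want$node)
    expect_equal(got$degree, want$degree, tolerance = 1e-9)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-9)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-9)
  }
})

test_that("isolated nodes and empty graphs are handled", {
  net <- gene_network(data.frame(a = "A", b = "B", confidence = 0.5),
                      nodes = c("A", "B", "loner"))
  cen <- centralities(net)
  lone <- cen[cen$node == "loner", ]
  expect_equal(unlist(lone[c("degree", "closeness", "betweenness")]),
               c(degree = 0, closeness = 0, betweenness = 0))
  empty <- gene_network(data.frame(a = character(), b = character(),
                                   confidence = numeric()))
  expect_equal(nrow(centralities(empty)), 0)
})

test_that("combined ranking is a weighted mean of min-max scaled measures", {
  r <- combined_rank(centralities(star_net(4)))
  expect_equal(r$node[1], "center")
  expect_equal(r$rank[1], 1L)
  expect_equal(r$combined[1], 1.0)     # top of all three scales
  # four symmetric leaves share the same combined score and rank
  leaves <- r[r$node != "center", ]
  expect_equal(length(unique(leaves$combined)), 1L)
  expect_equal(unique(leaves$rank), 2L)
  # ties are broken lexicographically for output order
  expect_equal(leaves$node, sort(leaves$node))
  # constant measures scale to 0.5 each
  two <- gene_network(data.frame(a = "A", b = "B", confidence = 1))
  r2 <- combined_rank(centralities(two))
  expect_equal(r2$combined, c(0.5, 0.5))
  expect_equal(r2$rank, c(1L, 1L))
})

test_that("weights shift the ranking as configured", {
  # center dominates degree; betweenness-only weights still rank it first,
  # while a leaf can never outrank under any weighting of a star
  cen <- centralities(star_net(6))
  for (w in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0.2, 0.3, 0.5))) {
    r <- combined_rank(cen, weights = w)
    expect_equal(r$node[1], "center")
  }
})

test_that("ranking is invariant under node relabeling", {
  net <- random_network(20, 0.2, seed = 77)
  perm <- setNames(sprintf("z%02d", sample(20)), net$nodes)
  relabeled <- gene_network(data.frame(a = unname(perm[net$edges$a]),
                                       b = unname(perm[net$edges$b]),
                                       confidence = net$edges$confidence),
                            nodes = unname(perm))
  r1 <- combined_rank(centralities(net))
  r2 <- combined_rank(centralities(relabeled))
  expect_equal(sort(r1$combined), sort(r2$combined), tolerance = 1e-12)
})

test_that("adding an edge never decreases a node's degree", {
  net <- random_network(15, 0.15, seed = 78)
  cen <- centralities(net)
  new_edge <- data.frame(a = "n01", b = "n15", confidence = 0.9)
  net2 <- gene_network(rbind(net$edges, new_edge), nodes = net$nodes)
  cen2 <- centralities(net2)
  expect_true(all(cen2$degree >= cen$degree))
})

test_that("planted hubs occupy the top ranks in synthetic networks", {
  core <- sprintf("core%02d", 1:30)
  hubs <- c("hub1", "hub2")
  sn <- synth_network(c(core, hubs), n_noise_nodes = 10, hub_ids = hubs,
                      seed = 4)
  r <- combined_rank(centralities(sn$network))
  expect_setequal(r$node[seq_along(hubs)], hubs)
})

test_that("hubless random graphs have no dominant node in most seeds", {
  outliers <- vapply(1:100, function(s) {
    sn <- synth_network(sprintf("g%02d", 1:25), n_noise_nodes = 0,
                        hub_ids = character(), noise_p = 0.15, seed = s)
    r <- combined_rank(centralities(sn$network))
    any(r$combined > mean(r$combined) + 3 * sd(r$combined))
  }, TRUE)
  expect_gte(mean(!outliers), 0.95)
})

test_that("confidence weighting uses edge strengths and lengths", {
  net <- gene_network(data.frame(a = c("A", "A"), b = c("B", "C"),
                                 confidence = c(0.9, 0.5)))
  cen <- centralities(net, use_confidence_weights = TRUE)
  expect_equal(cen$degree[cen$node == "A"], 1.4)
  expect_equal(cen$degree[cen$node == "B"], 0.9)
  # B-C goes through A: length (1-0.9+eps) + (1-0.5+eps) ~ 0.6
  expect_gt(cen$closeness[cen$node == "B"], 0)
})
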