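test_that("cpm_objective matches forced arithmetic and the summation oracle", {
  # unweighted triangle, unit sizes, one community, gamma = 0.5 -> 1.5
  nodes <- tibble::tibble(id = c("a", "b", "c"), is_atlas = FALSE,
                          label = NA_character_, size = 1)
  tri <- similarity_graph(nodes, tibble::tibble(from = c(1L, 1L, 2L),
                                                to = c(2L, 3L, 3L),
                                                weight = 1))
  expect_equal(cpm_objective(tri, c(1, 1, 1), 0.5), 3 - 0.5 * 3)
  # all singletons with unit sizes -> 0
  expect_equal(cpm_objective(tri, 1:3, 0.5), 0)

  for (seed in 1:10) {
    g <- random_constrained_graph(seed, n_labels = 3, n_new = 7)
    memb <- withr::with_seed(seed, sample(1:4, 10, replace = TRUE))
    memb[1:3] <- 1:3
    gamma <- 0.05
    expect_equal(cpm_objective(g, memb, gamma),
                 brute_cpm_objective(g, memb, gamma))
  }
})

test_that("two cliques anchored to distinct atlas nodes inherit their types", {
  # 2 atlas nodes + two 6-cliques of new cells; one cell per clique has an
  # edge to its own atlas node
  nodes <- tibble::tibble(
    id = c("A", "B", paste0("x", 1:6), paste0("y", 1:6)),
    is_atlas = c(TRUE, TRUE, rep(FALSE, 12)),
    label = c("A", "B", rep(NA_character_, 12)),
    size = c(5, 5, rep(1, 12))
  )
  clique <- function(idx) {
    p <- t(combn(idx, 2))
    tibble::tibble(from = as.integer(p[, 1]), to = as.integer(p[, 2]),
                   weight = 1)
  }
  edges <- dplyr::bind_rows(
    clique(3:8), clique(9:14),
    tibble::tibble(from = c(1L, 2L), to = c(3L, 9L), weight = 1))
  g <- similarity_graph(nodes, edges)
  m <- cluster_with_annotations(g, resolution = 0.001, seed = 7)
  lab <- assign_labels(g, m)
  expect_equal(lab$assigned_label[1:6], rep("A", 6))
  expect_equal(lab$assigned_label[7:12], rep("B", 6))
  expect_false(any(lab$is_novel))
})

test_that("disconnected new cells form novel clusters, never atlas labels", {
  nodes <- tibble::tibble(
    id = c("A", paste0("n", 1:5)),
    is_atlas = c(TRUE, rep(FALSE, 5)),
    label = c("A", rep(NA_character_, 5)),
    size = c(10, rep(1, 5))
  )
  # new cells form a path among themselves; no edge to the atlas node
  edges <- tibble::tibble(from = 2:5, to = 3:6, weight = 0.9)
  g <- similarity_graph(nodes, edges)
  m <- cluster_with_annotations(g, resolution = 0.001, seed = 1)
  lab <- assign_labels(g, m)
  expect_true(all(lab$is_novel))
  expect_true(all(startsWith(lab$assigned_label, "novel_")))
})

test_that("a graph of only atlas nodes returns the seed communities", {
  nodes <- tibble::tibble(id = c("A", "B"), is_atlas = TRUE,
                          label = c("A", "B"), size = c(4, 7))
  g <- similarity_graph(nodes, tibble::tibble(from = integer(0),
                                              to = integer(0),
                                              weight = numeric(0)))
  m <- cluster_with_annotations(g, resolution = 0.01, seed = 1)
  expect_equal(m$community, c(1L, 2L))
  expect_equal(m$objective, -0.01 * (4 * 3 / 2 + 7 * 6 / 2))
})

test_that("atlas types never split nor merge across random graphs and seeds", {
  for (seed in 1:40) {
    g <- random_constrained_graph(seed, n_labels = 3, n_new = 10,
                                  edge_prob = 0.5)
    gamma <- c(0.001, 0.01, 0.1)[seed %% 3 + 1]
    m <- cluster_with_annotations(g, resolution = gamma, seed = seed)
    comm <- m$community
    atlas <- which(g$nodes$is_atlas)
    # one community per label and no two labels in one community
    expect_equal(length(unique(comm[atlas])), length(atlas))
    # the objective never decreased across sweeps
    expect_true(all(diff(m$trace) >= -1e-10))
    # no improving single move remains
    expect_lte(audit_node_optimality(g, m, gamma), 1e-9)
  }
})

test_that("clustering is deterministic given the seed", {
  g <- random_constrained_graph(99, n_labels = 4, n_new = 12, edge_prob = 0.5)
  m1 <- cluster_with_annotations(g, resolution = 0.01, seed = 5)
  m2 <- cluster_with_annotations(g, resolution = 0.01, seed = 5)
  expect_identical(m1$community, m2$community)
  expect_identical(m1$objective, m2$objective)
})

test_that("returned objective matches the exhaustive constrained optimum", {
  hits <- 0
  for (seed in 1:25) {
    g <- random_constrained_graph(seed + 1000, n_labels = 3, n_new = 6,
                                  edge_prob = 0.45)
    gamma <- c(0.005, 0.02, 0.05)[seed %% 3 + 1]
    m <- cluster_with_annotations(g, resolution = gamma, seed = seed)
    opt <- exact_constrained_optimum(g, gamma)
    if (opt - m$objective <= 0.01 * abs(opt) + 1e-9) hits <- hits + 1
  }
  # near-optimality is expected in >= 95% of trials (the greedy sweeps can
  # land in a local optimum); the full-size check lives in the acceptance
  # suite
  expect_gte(hits, floor(0.95 * 25))
})

test_that("more resolution means at least as many novel clusters", {
  sim <- small_simulation(seed = 2, n_known = 3, n_novel = 2,
                          new_cells = 80)
  fitg <- function(gamma) {
    fit <- annotate(sim$new_data, sim$atlas, sim$atlas_annotation,
                    n_overdispersed = 150, resolution = gamma, seed = 3)
    glance(fit)$n_novel_clusters
  }
  counts <- vapply(c(1e-4, 1e-3, 1e-2, 5e-2), fitg, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("novel clusters are numbered by decreasing size and filtered by size", {
  nodes <- tibble::tibble(
    id = c("A", paste0("n", 1:13)),
    is_atlas = c(TRUE, rep(FALSE, 13)),
    label = c("A", rep(NA_character_, 13)),
    size = 1
  )
  g <- similarity_graph(nodes, tibble::tibble(from = integer(0),
                                              to = integer(0),
                                              weight = numeric(0)))
  # hand-built membership: one unlabeled community of 10, one of 3
  m <- structure(list(
    community = c(1L, rep(2L, 10), rep(3L, 3)),
    community_label = c(`1` = "A", `2` = NA, `3` = NA),
    objective = 0, trace = numeric(0), n_sweeps = 0L), class = "membership")
  lab <- assign_labels(g, m)
  expect_equal(sum(lab$assigned_label == "novel_1"), 10)
  expect_equal(sum(lab$assigned_label == "novel_2"), 3)
  # label counts match an independent tally
  expect_equal(unname(table(lab$assigned_label)[c("novel_1", "novel_2")]),
               unname(table(m$community[-1])),
               ignore_attr = TRUE)
  lab2 <- assign_labels(g, m, min_novel_cluster_size = 5)
  expect_equal(sum(lab2$assigned_label == "unassigned"), 3)
})

test_that("degenerate graphs are rejected or passed through", {
  expect_error(cluster_with_annotations(
    similarity_graph(tibble::tibble(id = character(0), is_atlas = logical(0),
                                    label = character(0), size = numeric(0)),
                     tibble::tibble(from = integer(0), to = integer(0),
                                    weight = numeric(0))),
    resolution = 0.01), "no nodes")
  g <- random_constrained_graph(1)
  expect_error(cluster_with_annotations(g, resolution = 0), "resolution")
})
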