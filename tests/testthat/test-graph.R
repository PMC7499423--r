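make_merged <- function(n_features = 30, n_atlas = 4, n_new = 20, seed = 17) {
  at <- withr::with_seed(seed, {
    matrix(rexp(n_features * (n_atlas + n_new), 1 / 100),
           n_features, n_atlas + n_new,
           dimnames = list(sprintf("f%03d", seq_len(n_features)),
                           c(if (n_atlas > 0) paste0("A", seq_len(n_atlas)),
                             if (n_new > 0) paste0("n", seq_len(n_new)))))
  })
  lab <- if (n_atlas > 0) paste0("T", seq_len(n_atlas)) else character(0)
  structure(list(
    values = at,
    is_atlas = c(rep(TRUE, n_atlas), rep(FALSE, n_new)),
    label = c(lab, rep(NA_character_, n_new)),
    size = c(rep(20, n_atlas), rep(1, n_new))
  ), class = "merged_matrix")
}

test_that("merge_landmarks does the bookkeeping for both landmark modes", {
  sim <- small_simulation(seed = 6, n_known = 3, atlas_cells = 30,
                          new_cells = 50)
  atlas_cpm <- normalize_cpm(sim$atlas)
  new_cpm <- normalize_cpm(sim$new_data)
  avg <- compute_averages(atlas_cpm, sim$atlas_annotation)
  feats <- gene_ids(new_cpm)[1:40]

  m <- merge_landmarks(avg, new_cpm, feats, atlas_node_size = 20)
  expect_equal(dim(m$values), c(40, 3 + 50))
  expect_equal(sum(m$is_atlas), 3)
  expect_equal(m$size[m$is_atlas], rep(20, 3))
  expect_equal(m$label[1:3], rownames(avg$means))
  expect_true(all(is.na(m$label[!m$is_atlas])))

  sub <- subsample_atlas(atlas_cpm, sim$atlas_annotation, n_per_type = 10,
                         seed = 1)
  m2 <- merge_landmarks(sub, new_cpm, feats)
  expect_equal(ncol(m2$values), 30 + 50)
  expect_equal(sum(m2$is_atlas), 30)
  expect_equal(m2$size, rep(1, 80))

  expect_error(merge_landmarks(avg, new_cpm, c(feats, "NOPE")), "NOPE")
})

test_that("colliding column ids get a deterministic atlas suffix", {
  m <- tiny_counts(c(1e6, 1e6), genes = "G1", cells = c("T1", "x"),
                   normalized = TRUE)
  avg <- structure(list(
    means = matrix(5e5, 1, 1, dimnames = list("T1", "G1")),
    n_cells = c(T1 = 3L)), class = "atlas_averages")
  merged <- merge_landmarks(avg, m, "G1")
  expect_equal(colnames(merged$values), c("T1.atlas", "T1", "x"))
})

test_that("PCA coordinates respect symmetry and rotation invariance", {
  m <- make_merged()
  coords <- standardize_and_pca(m, n_pcs = 5)
  expect_equal(dim(coords), c(ncol(m$values), 5))

  # identical columns get identical coordinates
  dup <- m
  dup$values <- cbind(m$values, m$values[, 10])
  dup$is_atlas <- c(m$is_atlas, FALSE)
  dup$label <- c(m$label, NA)
  dup$size <- c(m$size, 1)
  colnames(dup$values) <- c(colnames(m$values), "dup")
  cd <- standardize_and_pca(dup, n_pcs = 5)
  expect_equal(unname(cd[10, ]), unname(cd[ncol(dup$values), ]), tolerance = 1e-8)

  # at full rank, pairwise distances equal those in standardized space
  full <- standardize_and_pca(m, n_pcs = ncol(m$values) - 1)
  x <- m$values
  z <- (x - rowMeans(x)) / apply(x, 1, sd)
  z[z > 10] <- 10; z[z < -10] <- -10
  expect_equal(unname(as.matrix(dist(full))),
               unname(as.matrix(dist(t(z)))), tolerance = 1e-8)

  expect_warning(standardize_and_pca(m, n_pcs = 999), "clamped")
})

test_that("PCA is deterministic with fixed component signs", {
  m <- make_merged(seed = 23)
  c1 <- standardize_and_pca(m, n_pcs = 4)
  c2 <- standardize_and_pca(m, n_pcs = 4)
  expect_identical(c1, c2)
})

test_that("kNN edges match the exhaustive pairwise-distance oracle", {
  m <- make_merged(n_atlas = 0, n_new = 30, seed = 29)
  coords <- standardize_and_pca(m, n_pcs = 6)
  g <- build_graph(coords, m, k_neighbors = 5, metric = "euclidean")
  oracle_pairs <- unique(do.call(rbind, lapply(seq_len(30), function(i) {
    nb <- brute_knn(coords, i, 5)
    cbind(pmin(i, nb), pmax(i, nb))
  })))
  got <- as.matrix(g$edges[, c("from", "to")])
  expect_equal(nrow(got), nrow(oracle_pairs))
  expect_true(all(paste(got[, 1], got[, 2]) %in%
                  paste(oracle_pairs[, 1], oracle_pairs[, 2])))
  expect_true(all(g$edges$weight == 1))
})

test_that("the graph never contains atlas-atlas edges", {
  for (seed in 1:20) {
    m <- make_merged(n_atlas = 5, n_new = 15, seed = seed)
    coords <- standardize_and_pca(m, n_pcs = 5)
    g <- build_graph(coords, m, k_neighbors = 4, metric = "correlation",
                     edge_threshold = 0)
    expect_false(any(g$nodes$is_atlas[g$edges$from] &
                     g$nodes$is_atlas[g$edges$to]))
  }
  # and the constructor enforces it
  nodes <- tibble::tibble(id = c("a", "b"), is_atlas = c(TRUE, TRUE),
                          label = c("A", "B"), size = c(1, 1))
  expect_error(similarity_graph(nodes, tibble::tibble(from = 1L, to = 2L,
                                                      weight = 0.5)),
               "atlas-atlas")
})

test_that("a graph of only atlas nodes has no edges", {
  m <- make_merged(n_atlas = 6, n_new = 0, seed = 3)
  coords <- standardize_and_pca(m, n_pcs = 3)
  g <- build_graph(coords, m, k_neighbors = 3, metric = "euclidean")
  expect_equal(nrow(g$edges), 0)
})

test_that("graph construction is permutation-equivariant in the new cells", {
  m <- make_merged(n_atlas = 3, n_new = 12, seed = 37)
  colnames(m$values) <- c(paste0("A", 1:3), paste0("n", 1:12))
  coords <- standardize_and_pca(m, n_pcs = 5)
  g1 <- build_graph(coords, m, k_neighbors = 4, metric = "euclidean")

  perm <- withr::with_seed(5, c(1:3, 3 + sample(12)))
  mp <- m
  mp$values <- m$values[, perm]
  mp$is_atlas <- m$is_atlas[perm]
  mp$label <- m$label[perm]
  mp$size <- m$size[perm]
  coordsp <- standardize_and_pca(mp, n_pcs = 5)
  g2 <- build_graph(coordsp, mp, k_neighbors = 4, metric = "euclidean")

  key <- function(g) {
    e <- cbind(g$nodes$id[g$edges$from], g$nodes$id[g$edges$to])
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_equal(key(g1), key(g2))
})

test_that("correlation weights are thresholded and lie in (0, 1]", {
  m <- make_merged(n_atlas = 4, n_new = 16, seed = 41)
  coords <- standardize_and_pca(m, n_pcs = 5)
  g <- build_graph(coords, m, k_neighbors = 5, metric = "correlation",
                   edge_threshold = 0.6)
  expect_true(all(g$edges$weight >= 0.6 & g$edges$weight <= 1))
})

test_that("graph TSV dumps round-trip", {
  m <- make_merged(n_atlas = 3, n_new = 10, seed = 43)
  colnames(m$values) <- c(paste0("A", 1:3), paste0("n", 1:10))
  coords <- standardize_and_pca(m, n_pcs = 4)
  g <- build_graph(coords, m, k_neighbors = 3, metric = "correlation",
                   edge_threshold = 0.5)
  stem <- withr::local_tempfile()
  write_graph(g, stem)
  back <- read_graph(stem)
  expect_equal(back$nodes, g$nodes)
  expect_equal(back$edges, g$edges)
})
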