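# Small programmatic fixtures shared across test files.

tiny_counts <- function(values, genes = NULL, cells = NULL, normalized = FALSE) {
  if (!is.matrix(values)) {
    nr <- if (!is.null(genes)) length(genes) else
      if (!is.null(cells)) length(values) / length(cells) else 2
    values <- matrix(values, nrow = nr)
  }
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(values)))
  if (is.null(cells)) cells <- paste0("C", seq_len(ncol(values)))
  dimnames(values) <- list(genes, cells)
  count_matrix(values, normalized = normalized)
}

random_counts <- function(n_genes, n_cells, seed = 1, normalized = FALSE) {
  withr::with_seed(seed, {
    vals <- matrix(rpois(n_genes * n_cells, lambda = 5), n_genes, n_cells,
                   dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                   sprintf("C%03d", seq_len(n_cells))))
    m <- count_matrix(vals)
    if (normalized) normalize_cpm(m) else m
  })
}

small_simulation <- function(seed = 1, n_genes = 200, n_known = 3,
                             n_novel = 1, atlas_cells = 30, new_cells = 60,
                             markers_per_type = 5, effect = 20) {
  simulate_dataset(
    n_genes = n_genes,
    specs = type_specs(n_known = n_known, n_novel = n_novel,
                       atlas_cells_per_type = atlas_cells,
                       new_cells_total = new_cells,
                       markers_per_type = markers_per_type,
                       marker_effect = effect),
    seed = seed)
}

# A random similarity graph with one atlas node per label; the default
# sizes make atlas nodes behave like small populations.
random_constrained_graph <- function(seed, n_labels = 3, n_new = 6,
                                     edge_prob = 0.4,
                                     atlas_sizes = c(1, 5, 20)) {
  withr::with_seed(seed, {
    n <- n_labels + n_new
    nodes <- tibble::tibble(
      id = c(paste0("L", seq_len(n_labels)), paste0("c", seq_len(n_new))),
      is_atlas = c(rep(TRUE, n_labels), rep(FALSE, n_new)),
      label = c(paste0("L", seq_len(n_labels)), rep(NA_character_, n_new)),
      size = c(sample(atlas_sizes, n_labels, replace = TRUE), rep(1, n_new))
    )
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ok <- !(pairs[, 1] <= n_labels & pairs[, 2] <= n_labels)  # no atlas-atlas
    pairs <- pairs[ok, , drop = FALSE]
    pairs <- pairs[runif(nrow(pairs)) < edge_prob, , drop = FALSE]
    edges <- tibble::tibble(from = as.integer(pairs[, 1]),
                            to = as.integer(pairs[, 2]),
                            weight = runif(nrow(pairs), 0.05, 1))
    similarity_graph(nodes, edges)
  })
}
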