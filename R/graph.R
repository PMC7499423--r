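#' Merge atlas landmarks with the new dataset on the selected features
#'
#' Builds the single joint data table the similarity graph is computed
#' from: atlas columns (type averages or subsampled cells) first, new cells
#' after, restricted to the feature set and log10-transformed (zero
#' preserving, see [log_transform()]).  Atlas-average columns carry a node
#' size so that one average behaves in the clustering objective like a
#' small population rather than a single cell; subsampled atlas cells and
#' new cells have size 1.
#'
#' @param landmarks an `atlas_averages` or `atlas_subsample`.
#' @param new_data CPM-normalized [count_matrix()] of the cells to annotate.
#' @param features feature tibble from [build_feature_set()] (or character
#'   vector of gene ids); every feature must exist on both sides.
#' @param atlas_node_size size given to each atlas-average node (default 20).
#' @param pseudocount shift of the log transform (default 0.1 CPM).
#' @return A `merged_matrix`: list with `values` (features x columns,
#'   log-transformed), `is_atlas`, `label` (NA for new cells), `size`.
#' @export
merge_landmarks <- function(landmarks, new_data, features,
                            atlas_node_size = 20, pseudocount = 0.1) {
  stopifnot(inherits(new_data, "count_matrix"))
  if (!new_data$normalized) stop("new data must be CPM-normalized", call. = FALSE)
  genes <- if (is.data.frame(features)) features$gene else as.character(features)
  if (length(genes) == 0) stop("empty feature set", call. = FALSE)
  if (inherits(landmarks, "atlas_averages")) {
    lm_vals <- t(landmarks$means)            # genes x types
    lm_labels <- rownames(landmarks$means)
    lm_sizes <- rep(as.numeric(atlas_node_size), length(lm_labels))
    lm_ids <- lm_labels
  } else if (inherits(landmarks, "atlas_subsample")) {
    lm_vals <- landmarks$counts$values
    lm_ids <- cell_ids(landmarks$counts)
    lm_labels <- landmarks$annotation$cell_type[match(lm_ids, landmarks$annotation$cell_id)]
    lm_sizes <- rep(1, length(lm_ids))
  } else stop("landmarks must be atlas_averages or atlas_subsample", call. = FALSE)

  miss_lm <- setdiff(genes, rownames(lm_vals))
  miss_new <- setdiff(genes, gene_ids(new_data))
  if (length(miss_lm) > 0 || length(miss_new) > 0) {
    stop("features missing from ",
         if (length(miss_lm) > 0) paste0("landmarks (", paste(utils::head(miss_lm, 5), collapse = ","), ")"),
         if (length(miss_lm) > 0 && length(miss_new) > 0) " and ",
         if (length(miss_new) > 0) paste0("new data (", paste(utils::head(miss_new, 5), collapse = ","), ")"),
         call. = FALSE)
  }
  collide <- lm_ids %in% cell_ids(new_data)
  lm_ids[collide] <- paste0(lm_ids[collide], ".atlas")
  vals <- cbind(lm_vals[genes, , drop = FALSE],
                new_data$values[genes, , drop = FALSE])
  colnames(vals) <- c(lm_ids, cell_ids(new_data))
  vals <- log10(vals + pseudocount) - log10(pseudocount)
  structure(list(
    values = vals,
    is_atlas = c(rep(TRUE, length(lm_ids)), rep(FALSE, ncol(new_data$values))),
    label = c(lm_labels, rep(NA_character_, ncol(new_data$values))),
    size = c(lm_sizes, rep(1, ncol(new_data$values)))
  ), class = "merged_matrix")
}

#' @export
print.merged_matrix <- function(x, ...) {
  cat(sprintf("<merged_matrix> %d features x %d columns (%d atlas, %d new)\n",
              nrow(x$values), ncol(x$values), sum(x$is_atlas), sum(!x$is_atlas)))
  invisible(x)
}

#' Standardize features and reduce by PCA
#'
#' Each feature is z-scored jointly across atlas and new columns,
#' zero-variance features are dropped, values are clipped to \[-10, 10\],
#' and the first `n_pcs` principal component scores are returned.
#' Component signs are fixed by making each loading vector's
#' largest-magnitude entry positive, so results are deterministic.
#'
#' @param m a `merged_matrix` from [merge_landmarks()].
#' @param n_pcs number of components (default 20); clamped with a warning
#'   when the usable rank is smaller.
#' @return A columns x `n_pcs` coordinate matrix (rownames = column ids).
#' @export
standardize_and_pca <- function(m, n_pcs = 20) {
  stopifnot(inherits(m, "merged_matrix"))
  x <- m$values
  if (ncol(x) < 2) stop("PCA needs >= 2 columns", call. = FALSE)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) stop("all features have zero variance", call. = FALSE)
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  z[z > 10] <- 10
  z[z < -10] <- -10
  max_pcs <- min(nrow(z), ncol(z) - 1)
  if (n_pcs > max_pcs) {
    warning("n_pcs clamped to ", max_pcs, call. = FALSE)
    n_pcs <- max_pcs
  }
  zc <- z - rowMeans(z)                 # center across columns for PCA
  sv <- svd(zc, nu = n_pcs, nv = n_pcs)
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  coords <- sv$v %*% diag(sv$d[seq_len(n_pcs)], n_pcs, n_pcs)
  rownames(coords) <- colnames(x)
  colnames(coords) <- paste0("PC", seq_len(n_pcs))
  coords
}

#' Build the kNN similarity graph over atlas nodes and new cells
#'
#' For every *new* cell its `k_neighbors` nearest columns among all other
#' columns (new cells and atlas nodes alike) are found in PC space; the
#' resulting directed lists are symmetrized by union.  Atlas nodes only
#' receive edges through new cells' neighbor lists, so the graph never
#' contains an atlas-atlas edge: each edge connects either two new cells
#' or a new cell with an atlas landmark.
#'
#' @param coords columns x PCs coordinate matrix from
#'   [standardize_and_pca()].
#' @param m the `merged_matrix` the coordinates came from.
#' @param k_neighbors neighbors per new cell (default 10); clamped when the
#'   graph has fewer other columns.
#' @param metric `"correlation"` (default; similarity = Pearson correlation
#'   of coordinate vectors) or `"euclidean"`.
#' @param edge_threshold minimum edge weight kept under the correlation
#'   metric (weight = (1 + r)/2, default threshold 0.6); ignored for
#'   euclidean, where all edges have weight 1.
#' @return A `similarity_graph`: list with `nodes` (tibble `id`,
#'   `is_atlas`, `label`, `size`) and `edges` (tibble `from`, `to`,
#'   `weight`; integer node indices, `from < to`).  Isolated new cells are
#'   reported in attribute `"isolated"`.
#' @export
build_graph <- function(coords, m, k_neighbors = 10,
                        metric = c("correlation", "euclidean"),
                        edge_threshold = 0.6) {
  metric <- match.arg(metric)
  stopifnot(inherits(m, "merged_matrix"))
  n <- ncol(m$values)
  if (nrow(coords) != n) stop("coords rows must align with merged columns", call. = FALSE)
  if (metric == "correlation" && ncol(coords) < 2) {
    stop("correlation metric needs >= 2 PCs; use euclidean", call. = FALSE)
  }
  if (k_neighbors >= n) k_neighbors <- n - 1
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(coords))
    sim <- NULL
  } else {
    sim <- stats::cor(t(coords))
    d <- 1 - sim
  }
  new_idx <- which(!m$is_atlas)
  pairs <- vector("list", length(new_idx))
  for (ii in seq_along(new_idx)) {
    i <- new_idx[ii]
    cand <- setdiff(seq_len(n), i)
    ord <- cand[order(d[i, cand], cand)]   # ties by column index
    nb <- ord[seq_len(k_neighbors)]
    pairs[[ii]] <- cbind(pmin(i, nb), pmax(i, nb))
  }
  ep <- unique(do.call(rbind, pairs))
  if (is.null(ep)) ep <- matrix(integer(0), 0, 2)
  if (nrow(ep) > 0) {
    keep <- !(m$is_atlas[ep[, 1]] & m$is_atlas[ep[, 2]])
    ep <- ep[keep, , drop = FALSE]
  }
  if (metric == "euclidean") {
    w <- rep(1, nrow(ep))
  } else {
    w <- (1 + sim[ep]) / 2
    keep <- w >= edge_threshold
    ep <- ep[keep, , drop = FALSE]
    w <- w[keep]
  }
  ord <- order(ep[, 1], ep[, 2])
  edges <- tibble::tibble(from = as.integer(ep[ord, 1]),
                          to = as.integer(ep[ord, 2]),
                          weight = as.numeric(w[ord]))
  g <- similarity_graph(
    nodes = tibble::tibble(id = colnames(m$values), is_atlas = m$is_atlas,
                           label = m$label, size = m$size),
    edges = edges
  )
  deg <- tabulate(c(edges$from, edges$to), nbins = n)
  iso <- which(deg == 0 & !m$is_atlas)
  if (length(iso) > 0) {
    message("isolated new cells (all similarities below threshold): ",
            paste(utils::head(colnames(m$values)[iso], 5), collapse = ", "))
  }
  attr(g, "isolated") <- colnames(m$values)[iso]
  g
}

#' Construct a similarity graph from node and edge tables
#'
#' Validates the structural invariants: no atlas-atlas edges, no
#' self-loops, weights in (0, 1], every atlas node labeled.
#'
#' @param nodes tibble `id`, `is_atlas`, `label`, `size`.
#' @param edges tibble `from`, `to` (integer node indices), `weight`.
#' @return A `similarity_graph` object.
#' @export
similarity_graph <- function(nodes, edges) {
  stopifnot(all(c("id", "is_atlas", "label", "size") %in% names(nodes)),
            all(c("from", "to", "weight") %in% names(edges)))
  n <- nrow(nodes)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (any(is.na(nodes$label[nodes$is_atlas]))) {
    stop("every atlas node must carry a label", call. = FALSE)
  }
  if (nrow(edges) > 0) {
    if (any(edges$from < 1 | edges$to > n)) stop("edge endpoints out of range", call. = FALSE)
    if (any(edges$from == edges$to)) stop("self-loops are not allowed", call. = FALSE)
    if (any(nodes$is_atlas[edges$from] & nodes$is_atlas[edges$to])) {
      stop("atlas-atlas edges are not allowed", call. = FALSE)
    }
    if (any(edges$weight <= 0 | edges$weight > 1)) {
      stop("edge weights must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d nodes (%d atlas) / %d edges\n",
              nrow(x$nodes), sum(x$nodes$is_atlas), nrow(x$edges)))
  invisible(x)
}

#' Write / read a similarity graph as TSV tables
#'
#' The dump is two files: `<stem>.nodes.tsv` (`id`, `is_atlas`, `label`,
#' `size`) and `<stem>.edges.tsv` (`source`, `target`, `weight`, by node
#' id).  This is the interchange format of the standalone clustering entry
#' point, so a graph built by an external harmonization method can be
#' clustered here.
#'
#' @param g a `similarity_graph`.
#' @param stem path stem for the two files.
#' @return `write_graph()`: the stem, invisibly; `read_graph()`: the graph.
#' @export
write_graph <- function(g, stem) {
  readr::write_tsv(g$nodes, paste0(stem, ".nodes.tsv"))
  readr::write_tsv(tibble::tibble(source = g$nodes$id[g$edges$from],
                                  target = g$nodes$id[g$edges$to],
                                  weight = g$edges$weight),
                   paste0(stem, ".edges.tsv"))
  invisible(stem)
}

#' @rdname write_graph
#' @export
read_graph <- function(stem) {
  nodes <- readr::read_tsv(paste0(stem, ".nodes.tsv"),
                           col_types = readr::cols(
                             id = readr::col_character(),
                             is_atlas = readr::col_logical(),
                             label = readr::col_character(),
                             size = readr::col_double()))
  etab <- readr::read_tsv(paste0(stem, ".edges.tsv"),
                          col_types = readr::cols(
                            source = readr::col_character(),
                            target = readr::col_character(),
                            weight = readr::col_double()))
  from <- match(etab$source, nodes$id)
  to <- match(etab$target, nodes$id)
  if (anyNA(from) || anyNA(to)) stop("edge endpoints missing from node table", call. = FALSE)
  similarity_graph(nodes, tibble::tibble(from = pmin(from, to),
                                         to = pmax(from, to),
                                         weight = etab$weight))
}
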