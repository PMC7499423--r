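#' Annotate new cells against an atlas
#'
#' The end-to-end pipeline: gene intersection, CPM normalization, landmark
#' compression of the atlas (per-type averages or a labeled subsample),
#' joint feature selection (per-type markers plus overdispersed genes of
#' the new dataset), merge, standardization and PCA, kNN similarity graph,
#' constrained Leiden clustering with frozen atlas types, and label
#' assignment.  Every new cell ends up with either a known atlas type or a
#' `novel_<j>` cluster.
#'
#' @param new_data raw [count_matrix()] of cells to annotate.
#' @param atlas raw [count_matrix()] of atlas cells, with `atlas_annotation`
#'   (tibble `cell_id`, `cell_type`); alternatively pass precomputed
#'   `landmarks` and leave `atlas` as `NULL`.
#' @param atlas_annotation annotation tibble for `atlas`.
#' @param landmarks precomputed `atlas_averages`/`atlas_subsample`
#'   (CPM scale), e.g. from [load_landmarks()].
#' @param mode `"average"` or `"subsample"` landmark compression (used when
#'   the atlas is given as counts).
#' @param n_per_type subsample size per type in subsample mode (default 20).
#' @param n_markers_per_type,n_overdispersed feature-selection sizes
#'   (defaults 30 and 500).
#' @param n_pcs,k_neighbors,metric,edge_threshold,atlas_node_size graph
#'   parameters, see [standardize_and_pca()] and [build_graph()].
#' @param resolution CPM resolution of the clustering (default 0.001; keep
#'   below 0.01 to avoid splitting).
#' @param pseudocount shift for log transform and marker scores (0.1 CPM).
#' @param min_total_counts optional raw-count QC threshold on new cells
#'   (0 = off; plate-based tumor data is often filtered at 1e5).
#' @param min_novel_cluster_size minimum size of a reported novel cluster.
#' @param blacklist ambiguous atlas labels to exclude.
#' @param seed integer seed driving subsampling and clustering order.
#' @return An `atlas_fit` object; see [tidy.atlas_fit()] for the
#'   per-cell assignment table and [glance.atlas_fit()] for the run
#'   summary.
#' @examples
#' sim <- simulate_dataset(n_genes = 300,
#'   specs = type_specs(n_known = 3, n_novel = 1, atlas_cells_per_type = 30,
#'                      new_cells_total = 80, markers_per_type = 5),
#'   seed = 1)
#' fit <- annotate(sim$new_data, sim$atlas, sim$atlas_annotation,
#'                 n_overdispersed = 150, seed = 1)
#' tidy(fit)
#' glance(fit)
#' @export
annotate <- function(new_data, atlas = NULL, atlas_annotation = NULL,
                     landmarks = NULL, mode = c("average", "subsample"),
                     n_per_type = 20, n_markers_per_type = 30,
                     n_overdispersed = 500, n_pcs = 20, k_neighbors = 10,
                     metric = c("correlation", "euclidean"),
                     edge_threshold = 0.6, atlas_node_size = 20,
                     resolution = 0.001, pseudocount = 0.1,
                     min_total_counts = 0, min_novel_cluster_size = 0,
                     blacklist = c("unknown", "hybrid"), seed = 0) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  stopifnot(inherits(new_data, "count_matrix"))
  if (ncol(new_data$values) == 0) stop("new dataset has no cells", call. = FALSE)
  config <- list(mode = mode, n_per_type = n_per_type,
                 n_markers_per_type = n_markers_per_type,
                 n_overdispersed = n_overdispersed, n_pcs = n_pcs,
                 k_neighbors = k_neighbors, metric = metric,
                 edge_threshold = edge_threshold,
                 atlas_node_size = atlas_node_size, resolution = resolution,
                 pseudocount = pseudocount, min_total_counts = min_total_counts,
                 min_novel_cluster_size = min_novel_cluster_size,
                 blacklist = blacklist, seed = seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  if (min_total_counts > 0 && !new_data$normalized) {
    new_data <- stage("qc", filter_cells(new_data, min_total_counts))
  }

  if (is.null(landmarks)) {
    if (is.null(atlas) || is.null(atlas_annotation)) {
      stop("provide either (atlas, atlas_annotation) or landmarks", call. = FALSE)
    }
    ann <- stage("annotation", exclude_ambiguous_types(atlas_annotation, blacklist))
    ann <- ann[ann$cell_id %in% cell_ids(atlas), , drop = FALSE]
    atlas <- stage("intersect", {
      atlas <- count_matrix(atlas$values[, ann$cell_id, drop = FALSE],
                            normalized = atlas$normalized)
      both <- intersect_genes(atlas, new_data)
      new_data <<- both$b
      both$a
    })
    atlas_cpm <- stage("normalize", if (atlas$normalized) atlas else normalize_cpm(atlas))
    landmarks <- stage("landmarks", switch(mode,
      average = compute_averages(atlas_cpm, ann, blacklist),
      subsample = subsample_atlas(atlas_cpm, ann, n_per_type, seed, blacklist)))
  } else {
    lm_genes <- if (inherits(landmarks, "atlas_averages")) {
      colnames(landmarks$means)
    } else gene_ids(landmarks$counts)
    shared <- intersect(gene_ids(new_data), lm_genes)
    if (length(shared) == 0) stop("[intersect] empty gene intersection with landmarks", call. = FALSE)
    new_data <- count_matrix(new_data$values[shared, , drop = FALSE],
                             normalized = new_data$normalized)
    if (inherits(landmarks, "atlas_averages")) {
      landmarks$means <- landmarks$means[, shared, drop = FALSE]
    } else {
      landmarks$counts <- count_matrix(landmarks$counts$values[shared, , drop = FALSE],
                                       normalized = TRUE)
    }
  }

  new_cpm <- stage("normalize", {
    nd <- if (new_data$normalized) new_data else normalize_cpm(new_data)
    drop_empty_cells(nd)
  })

  averages <- if (inherits(landmarks, "atlas_averages")) landmarks else {
    compute_averages(landmarks$counts, landmarks$annotation, blacklist)
  }
  markers <- stage("features", select_markers(averages, n_markers_per_type, pseudocount))
  overd <- stage("features", select_overdispersed(new_cpm, min(n_overdispersed, nrow(new_cpm$values))))
  features <- stage("features", build_feature_set(markers, overd))

  merged <- stage("merge", merge_landmarks(landmarks, new_cpm, features,
                                           atlas_node_size, pseudocount))
  coords <- stage("pca", standardize_and_pca(merged, n_pcs))
  graph <- stage("graph", build_graph(coords, merged, k_neighbors, metric,
                                      edge_threshold))
  membership <- stage("cluster", cluster_with_annotations(graph, resolution,
                                                          seed = seed))
  assignments <- stage("labels", assign_labels(graph, membership,
                                               min_novel_cluster_size))

  structure(list(
    assignments = assignments,
    membership = membership,
    graph = graph,
    coords = coords,
    features = features,
    markers = markers,
    landmarks = landmarks,
    config = config,
    config_hash = rlang::hash(config)
  ), class = "atlas_fit")
}

#' @export
print.atlas_fit <- function(x, ...) {
  counts <- table(x$assignments$assigned_label)
  cat(sprintf("<atlas_fit> %d cells annotated against %d atlas types; %d novel cluster(s)\n",
              nrow(x$assignments),
              sum(!is.na(x$membership$community_label)),
              length(unique(x$assignments$assigned_label[x$assignments$is_novel]))))
  print(counts)
  invisible(x)
}

#' Tidy the per-cell assignment table of an annotation fit
#'
#' @param x an `atlas_fit` from [annotate()].
#' @param ... unused.
#' @return A tibble `cell_id`, `assigned_label`, `community_id`,
#'   `is_novel`.
#' @method tidy atlas_fit
#' @export
tidy.atlas_fit <- function(x, ...) x$assignments

#' One-row summary of an annotation fit
#'
#' @param x an `atlas_fit` from [annotate()].
#' @param ... unused.
#' @return A one-row tibble: cells, atlas types, novel clusters, features,
#'   graph edges, CPM objective, sweeps used.
#' @method glance atlas_fit
#' @export
glance.atlas_fit <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$assignments),
    n_atlas_types = sum(!is.na(x$membership$community_label)),
    n_novel_clusters = length(unique(
      x$assignments$assigned_label[x$assignments$is_novel])),
    n_features = nrow(x$features),
    n_edges = nrow(x$graph$edges),
    objective = x$membership$objective,
    n_sweeps = x$membership$n_sweeps
  )
}

#' Plot an annotation fit in PC space
#'
#' New cells are drawn as points in the first two principal components,
#' colored by assigned label; atlas landmark nodes are overplotted as
#' stars.
#'
#' @param object an `atlas_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot atlas_fit
#' @export
autoplot.atlas_fit <- function(object, ...) {
  nodes <- object$graph$nodes
  df <- tibble::tibble(
    PC1 = object$coords[, 1], PC2 = object$coords[, 2],
    is_atlas = nodes$is_atlas,
    label = ifelse(nodes$is_atlas, nodes$label,
                   object$assignments$assigned_label[
                     match(nodes$id, object$assignments$cell_id)])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   color = .data$label)) +
    ggplot2::geom_point(data = df[!df$is_atlas, ], size = 1, alpha = 0.7) +
    ggplot2::geom_point(data = df[df$is_atlas, ], shape = 8, size = 4,
                        stroke = 1.2) +
    ggplot2::labs(color = "assignment",
                  title = "Atlas-guided annotation",
                  subtitle = "stars: atlas landmarks; points: new cells") +
    ggplot2::theme_minimal()
}

#' Write the assignment table and run report
#'
#' Writes `<stem>.assignments.tsv` (cell_id, assigned_label, community_id,
#' is_novel; header comments carry the config hash) and `<stem>.report.json`
#' (resolved parameters, config hash, per-label counts).  The TSV is
#' byte-reproducible for a fixed config and seed.
#'
#' @param fit an `atlas_fit`.
#' @param stem output path stem.
#' @return The stem, invisibly.
#' @export
write_assignments <- function(fit, stem) {
  tsv <- paste0(stem, ".assignments.tsv")
  lines <- c(sprintf("# config_hash=%s", fit$config_hash),
             paste(c("cell_id", "assigned_label", "community_id", "is_novel"),
                   collapse = "\t"),
             sprintf("%s\t%s\t%d\t%s", fit$assignments$cell_id,
                     fit$assignments$assigned_label,
                     fit$assignments$community_id,
                     ifelse(fit$assignments$is_novel, "TRUE", "FALSE")))
  writeLines(lines, tsv)
  counts <- table(fit$assignments$assigned_label)
  jsonlite::write_json(
    list(config = fit$config, config_hash = fit$config_hash,
         n_cells = nrow(fit$assignments),
         label_counts = as.list(counts)),
    paste0(stem, ".report.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
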