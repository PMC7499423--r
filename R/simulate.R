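#' Specify cell types for the count simulator
#'
#' Builds the per-type specification table used by [simulate_dataset()]:
#' known types appear in both atlas and new data; novel types have zero
#' atlas cells.  Marker gene blocks are disjoint across types, assigned in
#' order from the front of the gene list.
#'
#' @param n_known,n_novel numbers of known and novel cell types.
#' @param atlas_cells_per_type atlas cells per known type.
#' @param new_cells_total total new cells, split evenly across all types.
#' @param markers_per_type planted marker genes per type.
#' @param marker_effect multiplicative upregulation of a type's markers.
#' @return A tibble `label`, `n_atlas_cells`, `n_new_cells`, `markers`
#'   (list-column of gene indices), `effect`, `novel`.
#' @export
type_specs <- function(n_known = 5, n_novel = 2, atlas_cells_per_type = 100,
                       new_cells_total = 400, markers_per_type = 10,
                       marker_effect = 20) {
  k <- n_known + n_novel
  if (n_known < 1) stop("at least one known type is required", call. = FALSE)
  if (marker_effect <= 1) stop("marker_effect must be > 1", call. = FALSE)
  per_type <- rep(new_cells_total %/% k, k)
  per_type[seq_len(new_cells_total %% k)] <- per_type[seq_len(new_cells_total %% k)] + 1
  labels <- c(paste0("type_", seq_len(n_known)),
              if (n_novel > 0) paste0("novel_type_", seq_len(n_novel)))
  tibble::tibble(
    label = labels,
    n_atlas_cells = c(rep(atlas_cells_per_type, n_known), rep(0L, n_novel)),
    n_new_cells = per_type,
    markers = lapply(seq_len(k), function(t) {
      (t - 1) * markers_per_type + seq_len(markers_per_type)
    }),
    effect = rep(marker_effect, k),
    novel = c(rep(FALSE, n_known), rep(TRUE, n_novel))
  )
}

#' Simulate a paired (atlas, new dataset) with planted ground truth
#'
#' Negative-binomial counts with type-specific marker genes: every cell of
#' type t draws gene counts from `NB(mean = L * p_t, dispersion)`, where
#' `p_t` is the baseline expression profile with t's marker genes
#' multiplied by the effect size and renormalized to proportions, and `L`
#' is the cell's library size drawn uniformly from `library_size_range`.
#' The baseline profile is shared by all types (housekeeping structure);
#' only markers distinguish them.  Deterministic given `seed`.
#'
#' @param n_genes number of genes.
#' @param specs type specification tibble from [type_specs()].
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   default 0.1, a typical plate-based scRNA-seq value.
#' @param library_size_range min/max of the per-cell total-count draw
#'   (default 5e4-1.5e5 reads, plate-scale depth).
#' @param baseline_scale log-normal sdlog of the baseline gene means
#'   (default 1).
#' @param seed integer seed.
#' @return A list: `atlas` (raw [count_matrix()]), `atlas_annotation`
#'   (tibble `cell_id`, `cell_type`), `new_data` (raw `count_matrix`),
#'   `truth` (tibble `cell_id`, `true_label`, `is_novel`), `specs`.
#' @export
simulate_dataset <- function(n_genes = 2000, specs = type_specs(),
                             dispersion = 0.1,
                             library_size_range = c(5e4, 1.5e5),
                             baseline_scale = 1, seed = 0) {
  all_markers <- unlist(specs$markers)
  if (anyDuplicated(all_markers)) stop("marker sets must be disjoint across types", call. = FALSE)
  if (max(c(0, all_markers)) > n_genes) stop("marker index exceeds n_genes", call. = FALSE)
  if (!any(!specs$novel)) stop("at least one non-novel type is required", call. = FALSE)
  if (any(specs$effect <= 1)) stop("marker effect must be > 1", call. = FALSE)
  genes <- sprintf("G%04d", seq_len(n_genes))
  withr::with_seed(seed, {
    baseline <- stats::rlnorm(n_genes, meanlog = 0, sdlog = baseline_scale)
    profile_of <- function(t) {
      v <- baseline
      v[specs$markers[[t]]] <- v[specs$markers[[t]]] * specs$effect[t]
      v / sum(v)
    }
    draw_cells <- function(n_cells, t) {
      if (n_cells == 0) return(matrix(0, n_genes, 0))
      p <- profile_of(t)
      L <- stats::runif(n_cells, library_size_range[1], library_size_range[2])
      mu <- outer(p, L)
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             n_genes, n_cells)
    }
    atlas_cols <- list(); atlas_types <- character(0)
    new_cols <- list(); new_types <- character(0)
    for (t in seq_len(nrow(specs))) {
      atlas_cols[[t]] <- draw_cells(specs$n_atlas_cells[t], t)
      atlas_types <- c(atlas_types, rep(specs$label[t], specs$n_atlas_cells[t]))
      new_cols[[t]] <- draw_cells(specs$n_new_cells[t], t)
      new_types <- c(new_types, rep(specs$label[t], specs$n_new_cells[t]))
    }
    atlas_vals <- do.call(cbind, atlas_cols)
    new_vals <- do.call(cbind, new_cols)
    colnames(atlas_vals) <- sprintf("atlas_%04d", seq_len(ncol(atlas_vals)))
    colnames(new_vals) <- sprintf("cell_%04d", seq_len(ncol(new_vals)))
    rownames(atlas_vals) <- genes
    rownames(new_vals) <- genes
    list(
      atlas = count_matrix(atlas_vals),
      atlas_annotation = tibble::tibble(cell_id = colnames(atlas_vals),
                                        cell_type = atlas_types),
      new_data = count_matrix(new_vals),
      truth = tibble::tibble(cell_id = colnames(new_vals),
                             true_label = new_types,
                             is_novel = new_types %in% specs$label[specs$novel]),
      specs = specs
    )
  })
}

#' Score a predicted assignment against simulated ground truth
#'
#' Known-type cells are scored by exact label accuracy; cells whose true
#' type is absent from the atlas are scored by the adjusted Rand index
#' between predicted cluster ids and the true novel types (their predicted
#' names are arbitrary, only the grouping matters).
#'
#' @param assignments tibble `cell_id`, `assigned_label` (and optionally
#'   `community_id`).
#' @param truth tibble `cell_id`, `true_label`, `is_novel` from
#'   [simulate_dataset()].
#' @return A one-row tibble: `accuracy_known` (NA when there are no known
#'   cells), `ari_novel` (NA when there are no novel cells), `n_known`,
#'   `n_novel`.
#' @export
score_assignment <- function(assignments, truth) {
  if (nrow(assignments) != nrow(truth)) stop("length mismatch", call. = FALSE)
  idx <- match(truth$cell_id, assignments$cell_id)
  if (anyNA(idx)) stop("assignments and truth disagree on cell ids", call. = FALSE)
  pred <- assignments$assigned_label[idx]
  known <- !truth$is_novel
  acc <- if (any(known)) mean(pred[known] == truth$true_label[known]) else NA_real_
  ari <- if (any(!known)) {
    mclust::adjustedRandIndex(pred[!known], truth$true_label[!known])
  } else NA_real_
  tibble::tibble(accuracy_known = acc, ari_novel = ari,
                 n_known = sum(known), n_novel = sum(!known))
}
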