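#' Per-gene one-vs-rest group means
#'
#' @param data CPM-normalized [count_matrix()].
#' @param cluster_cells,rest_cells character cell ids of the two groups
#'   (both non-empty, disjoint).
#' @return A tibble `gene`, `mean_in`, `mean_out`.
#' @export
one_vs_rest_means <- function(data, cluster_cells, rest_cells) {
  stopifnot(inherits(data, "count_matrix"))
  if (!data$normalized) stop("DE expects CPM-normalized values", call. = FALSE)
  if (length(cluster_cells) == 0 || length(rest_cells) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  missing <- setdiff(c(cluster_cells, rest_cells), cell_ids(data))
  if (length(missing) > 0) {
    stop("unknown cell ids: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    gene = gene_ids(data),
    mean_in = unname(rowMeans(data$values[, cluster_cells, drop = FALSE])),
    mean_out = unname(rowMeans(data$values[, rest_cells, drop = FALSE]))
  )
}

#' Shortlist genes by one-vs-rest fold change
#'
#' Fold change is `(mean_in + pseudocount) / (mean_out + pseudocount)`;
#' the `n_shortlist` genes with the highest fold changes are kept (ties by
#' gene id), the classic pre-filter before the per-cell KS test.
#'
#' @param means tibble from [one_vs_rest_means()].
#' @param n_shortlist genes to keep (default 50); clamped to the number of
#'   genes available.
#' @param pseudocount stabilizer in CPM units (default 0.1).
#' @return The shortlisted rows of `means` with a `fold_change` column,
#'   ordered by decreasing fold change.
#' @export
shortlist_by_fold_change <- function(means, n_shortlist = 50, pseudocount = 0.1) {
  if (n_shortlist < 1) stop("n_shortlist must be >= 1", call. = FALSE)
  fc <- (means$mean_in + pseudocount) / (means$mean_out + pseudocount)
  out <- dplyr::mutate(means, fold_change = fc)
  out <- out[order(-out$fold_change, out$gene), , drop = FALSE]
  utils::head(out, n_shortlist)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The maximum absolute difference between the two empirical CDFs,
#' `D = max over t of |ECDF_x(t) - ECDF_y(t)|`, in \[0, 1\].  No p-value is
#' computed: genes are ranked by the statistic itself.
#'
#' @param x,y non-empty numeric samples.
#' @return The statistic D.
#' @export
ks_statistic <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample", call. = FALSE)
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  ord <- order(pooled)
  steps <- ifelse(ord <= nx, 1 / nx, -1 / ny)
  # cumulative ECDF difference just after each pooled point; ties need the
  # difference evaluated after all equal values are consumed
  z <- cumsum(steps)
  sp <- pooled[ord]
  last_of_run <- c(sp[-1] != sp[-length(sp)], TRUE)
  max(abs(z[last_of_run]))
}

#' Rank differential genes for each novel cluster
#'
#' The one-vs-rest recipe per cluster: group means, shortlist of the
#' `n_shortlist` highest fold changes, then a two-sample KS statistic on
#' the per-cell expression of each shortlisted gene.  Within a cluster,
#' genes are ranked by KS statistic (descending), ties by fold change then
#' gene id.
#'
#' @param data CPM-normalized [count_matrix()] of the new cells.
#' @param assignments tibble with `cell_id` and `assigned_label` (as
#'   returned by [assign_labels()] or [tidy()] of an annotation fit).
#' @param clusters labels to characterize; default all labels starting
#'   with `"novel_"`.
#' @param n_shortlist fold-change shortlist size (default 50).
#' @param pseudocount fold-change stabilizer (default 0.1 CPM).
#' @return A tibble `cluster`, `gene`, `mean_in`, `mean_out`,
#'   `fold_change`, `ks_statistic`, `rank`.
#' @export
rank_de_genes <- function(data, assignments, clusters = NULL,
                          n_shortlist = 50, pseudocount = 0.1) {
  stopifnot(all(c("cell_id", "assigned_label") %in% names(assignments)))
  if (is.null(clusters)) {
    clusters <- sort(unique(assignments$assigned_label[
      startsWith(assignments$assigned_label, "novel_")]))
  }
  if (length(clusters) == 0) stop("no novel clusters to characterize", call. = FALSE)
  purrr::map_dfr(clusters, function(cl) {
    inside <- assignments$cell_id[assignments$assigned_label == cl]
    outside <- setdiff(assignments$cell_id, inside)
    means <- one_vs_rest_means(data, inside, outside)
    short <- shortlist_by_fold_change(means, n_shortlist, pseudocount)
    d <- vapply(short$gene, function(gn) {
      ks_statistic(data$values[gn, inside], data$values[gn, outside])
    }, numeric(1))
    out <- dplyr::mutate(short, cluster = cl, ks_statistic = unname(d))
    out <- out[order(-out$ks_statistic, -out$fold_change, out$gene), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    dplyr::select(out, "cluster", "gene", "mean_in", "mean_out",
                  "fold_change", "ks_statistic", "rank")
  })
}
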