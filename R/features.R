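#' Select upregulated marker genes per atlas cell type
#'
#' A gene's marker score for type t is the log-fold contrast against the
#' *strongest* other type:
#' `log10(mean[t, g] + pseudocount) - log10(max over other types of mean[., g] + pseudocount)`.
#' A marker must therefore beat every other type, not just the average one.
#' The union over types of the top `n_markers_per_type` genes is returned;
#' score ties are broken lexicographically by gene id.
#'
#' @param averages an `atlas_averages` (see [compute_averages()]); at least
#'   two cell types.
#' @param n_markers_per_type markers retained per type (default 30).
#' @param pseudocount fold-change stabilizer in CPM units (default 0.1).
#' @return A tibble with columns `gene`, `cell_type`, `score`, one row per
#'   (type, selected gene); the union gene set is `unique(out$gene)`.
#' @export
select_markers <- function(averages, n_markers_per_type = 30, pseudocount = 0.1) {
  stopifnot(inherits(averages, "atlas_averages"))
  if (n_markers_per_type < 1) stop("n_markers_per_type must be >= 1", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  m <- averages$means
  if (nrow(m) < 2) stop("marker selection needs >= 2 cell types", call. = FALSE)
  lg <- log10(m + pseudocount)
  n <- min(n_markers_per_type, ncol(m))
  per_type <- lapply(seq_len(nrow(m)), function(t) {
    other_max <- apply(lg[-t, , drop = FALSE], 2, max)
    score <- lg[t, ] - other_max
    ord <- order(-score, colnames(m))
    take <- ord[seq_len(n)]
    tibble::tibble(gene = colnames(m)[take], cell_type = rownames(m)[t],
                   score = unname(score[take]))
  })
  dplyr::bind_rows(per_type)
}

#' Select overdispersed genes of the new dataset
#'
#' Ranks genes by their Fano factor (variance / mean) on CPM values; the
#' Fano factor is scale-stable across library sizes and flags genes whose
#' variation exceeds what their mean predicts.  Genes with zero mean score 0.
#'
#' @param new_data a CPM-normalized [count_matrix()] with >= 2 cells.
#' @param n number of genes to return; clamped (with a warning) to the
#'   number of genes available.
#' @return A tibble `gene`, `fano`, ordered by decreasing Fano factor (ties
#'   lexicographic by gene id).
#' @export
select_overdispersed <- function(new_data, n = 500) {
  stopifnot(inherits(new_data, "count_matrix"))
  if (!new_data$normalized) stop("new data must be CPM-normalized", call. = FALSE)
  if (ncol(new_data$values) < 2) stop("overdispersion needs >= 2 cells", call. = FALSE)
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (n > nrow(new_data$values)) {
    warning("requested more overdispersed genes than available; clamping", call. = FALSE)
    n <- nrow(new_data$values)
  }
  mu <- rowMeans(new_data$values)
  v <- apply(new_data$values, 1, stats::var)
  fano <- ifelse(mu == 0, 0, v / mu)
  ord <- order(-fano, gene_ids(new_data))
  take <- ord[seq_len(n)]
  tibble::tibble(gene = gene_ids(new_data)[take], fano = unname(fano[take]))
}

#' Combine marker and overdispersed genes into the joint feature set
#'
#' Deterministic order: marker genes in type order (then score rank), then
#' overdispersed genes by rank; duplicates are kept once with provenance
#' `"both"`.
#'
#' @param markers tibble from [select_markers()] (or a character vector).
#' @param overdispersed tibble from [select_overdispersed()] (or a
#'   character vector).
#' @return A tibble `gene`, `provenance` (`"marker"`, `"overdispersed"` or
#'   `"both"`); no duplicate genes.
#' @export
build_feature_set <- function(markers, overdispersed) {
  mg <- if (is.data.frame(markers)) unique(markers$gene) else unique(as.character(markers))
  og <- if (is.data.frame(overdispersed)) unique(overdispersed$gene) else unique(as.character(overdispersed))
  genes <- c(mg, setdiff(og, mg))
  if (length(genes) == 0) stop("empty feature set", call. = FALSE)
  tibble::tibble(
    gene = genes,
    provenance = dplyr::case_when(
      genes %in% mg & genes %in% og ~ "both",
      genes %in% mg ~ "marker",
      TRUE ~ "overdispersed"
    )
  )
}
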