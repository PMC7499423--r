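#' Construct a genes x cells count matrix
#'
#' The basic expression container: a dense genes x cells matrix of
#' non-negative values with unique gene and cell identifiers.  Raw counts
#' and counts-per-million (CPM) normalized values share the container; the
#' `normalized` flag records which one is stored.
#'
#' @param values numeric matrix, genes in rows and cells in columns.  Row
#'   and column names are used as identifiers when `gene_ids`/`cell_ids`
#'   are not given.
#' @param gene_ids,cell_ids character vectors of unique identifiers; default
#'   to the dimnames of `values`.
#' @param normalized logical; `TRUE` when columns are CPM-normalized
#'   (non-empty cells sum to 1e6).
#' @return A `count_matrix` object.
#' @examples
#' m <- count_matrix(matrix(rpois(12, 5), 3, 4,
#'   dimnames = list(paste0("G", 1:3), paste0("C", 1:4))))
#' dim(m)
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         cell_ids = colnames(values), normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("count_matrix needs gene and cell identifiers (dimnames or arguments)",
         call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) {
    dup <- unique(cell_ids[duplicated(cell_ids)])
    stop("duplicate cell ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) stop("count matrix contains missing values", call. = FALSE)
  if (any(values < 0)) stop("count matrix contains negative values", call. = FALSE)
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, normalized = isTRUE(normalized)),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "CPM-normalized" else "raw counts"))
  invisible(x)
}

#' Gene and cell identifiers of a count matrix
#' @param m a [count_matrix()].
#' @return character vector of identifiers.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(m) colnames(m$values)

#' Restrict two count matrices to their common genes
#'
#' Only genes present in both datasets are retained, in the order of the
#' first matrix.  Cell sets are unchanged.
#'
#' @param a,b [count_matrix()] objects.
#' @return A list with elements `a` and `b`, both restricted to the shared
#'   genes in `a`'s order.
#' @export
intersect_genes <- function(a, b) {
  shared <- intersect(gene_ids(a), gene_ids(b))
  if (length(shared) == 0) {
    stop(sprintf(
      "empty gene intersection: first matrix has %d genes (e.g. %s), second has %d (e.g. %s)",
      nrow(a$values), paste(utils::head(gene_ids(a), 3), collapse = ","),
      nrow(b$values), paste(utils::head(gene_ids(b), 3), collapse = ",")),
      call. = FALSE)
  }
  list(
    a = count_matrix(a$values[shared, , drop = FALSE], normalized = a$normalized),
    b = count_matrix(b$values[shared, , drop = FALSE], normalized = b$normalized)
  )
}

#' Counts-per-million normalization
#'
#' Scales every cell's column so its total is 1e6.  All-zero cells are left
#' all-zero and reported with a warning.
#'
#' @param m a raw [count_matrix()].
#' @return The CPM-normalized `count_matrix`.
#' @export
normalize_cpm <- function(m) {
  if (m$normalized) stop("matrix is already CPM-normalized", call. = FALSE)
  totals <- colSums(m$values)
  zero <- totals == 0
  if (any(zero)) {
    warning("all-zero cells left unnormalized: ",
            paste(cell_ids(m)[zero], collapse = ", "), call. = FALSE)
  }
  scale <- ifelse(zero, 0, 1e6 / totals)
  out <- sweep(m$values, 2, scale, `*`)
  count_matrix(out, normalized = TRUE)
}

#' Discard cells with low total counts
#'
#' Cells whose total raw counts fall below `min_total_counts` are removed
#' (cells exactly at the threshold are kept).  The read-count QC used for
#' plate-based tumor data typically discards cells under 1e5 reads.
#'
#' @param m a raw [count_matrix()].
#' @param min_total_counts non-negative threshold on the column sum.
#' @return The filtered `count_matrix`; gene set and surviving cell order
#'   unchanged.
#' @export
filter_cells <- function(m, min_total_counts) {
  if (m$normalized) stop("filter_cells expects raw counts", call. = FALSE)
  if (min_total_counts < 0) stop("min_total_counts must be >= 0", call. = FALSE)
  keep <- colSums(m$values) >= min_total_counts
  if (!any(keep)) stop("no cells pass QC at threshold ", min_total_counts, call. = FALSE)
  count_matrix(m$values[, keep, drop = FALSE], normalized = FALSE)
}

#' Zero-preserving shifted log10 transform
#'
#' Applies `x -> log10(x + pseudocount) - log10(pseudocount)` elementwise,
#' so zero maps to zero, values stay non-negative, and the transform is
#' monotone.  Used before feature standardization so that distances are not
#' dominated by a few very highly expressed genes.
#'
#' @param m a CPM-normalized [count_matrix()] (or a bare numeric matrix).
#' @param pseudocount positive shift, in CPM units; default 0.1.
#' @return Transformed matrix of the same class as the input.
#' @export
log_transform <- function(m, pseudocount = 0.1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  if (inherits(m, "count_matrix")) {
    if (!m$normalized) stop("log_transform expects CPM-normalized values", call. = FALSE)
    out <- m
    out$values <- log10(m$values + pseudocount) - log10(pseudocount)
    out
  } else {
    log10(m + pseudocount) - log10(pseudocount)
  }
}

#' Drop cells that became all-zero (e.g. after gene intersection)
#' @param m a [count_matrix()].
#' @return `count_matrix` without all-zero cells; warns when any are dropped.
#' @export
drop_empty_cells <- function(m) {
  empty <- colSums(m$values) == 0
  if (any(empty)) {
    warning("dropping all-zero cells: ",
            paste(cell_ids(m)[empty], collapse = ", "), call. = FALSE)
    if (all(empty)) stop("all cells are empty", call. = FALSE)
    m <- count_matrix(m$values[, !empty, drop = FALSE], normalized = m$normalized)
  }
  m
}
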