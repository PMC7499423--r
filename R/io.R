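#' Read a count matrix from CSV/TSV or MatrixMarket files
#'
#' Dense tables are genes x cells: a header row of cell ids and a first
#' column of gene ids (use `transpose = TRUE` for cells-in-rows exports).
#' MatrixMarket triplets (`.mtx`) need sidecar id lists, one id per line:
#' `<stem>.genes.txt` (rows) and `<stem>.cells.txt` (columns), or explicit
#' paths.
#'
#' @param path file path; format inferred from the extension
#'   (`.csv`, `.tsv`/`.txt`, `.mtx`).
#' @param transpose logical; set `TRUE` when a dense table stores cells in
#'   rows.
#' @param genes_path,cells_path sidecar id lists for MTX input.
#' @param normalized logical flag to set on the returned matrix.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, transpose = FALSE, genes_path = NULL,
                        cells_path = NULL, normalized = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    if (is.null(genes_path)) genes_path <- paste0(stem, ".genes.txt")
    if (is.null(cells_path)) cells_path <- paste0(stem, ".cells.txt")
    vals <- as.matrix(Matrix::readMM(path))
    g <- readLines(genes_path)
    cl <- readLines(cells_path)
    return(count_matrix(vals, gene_ids = g, cell_ids = cl,
                        normalized = normalized))
  }
  delim <- if (ext == "csv") "," else "\t"
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- ids
  if (transpose) vals <- t(vals)
  count_matrix(vals, normalized = normalized)
}

#' Write a count matrix
#'
#' Dense output is genes x cells with a `gene_id` first column; `.mtx`
#' output writes the triplet file plus `<stem>.genes.txt` / `<stem>.cells.txt`
#' sidecars.
#'
#' @param m a [count_matrix()].
#' @param path destination; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    writeLines(gene_ids(m), paste0(stem, ".genes.txt"))
    writeLines(cell_ids(m), paste0(stem, ".cells.txt"))
    return(invisible(path))
  }
  delim <- if (ext == "csv") "," else "\t"
  tab <- tibble::as_tibble(m$values, rownames = "gene_id")
  readr::write_delim(tab, path, delim = delim)
  invisible(path)
}

#' Read a cell annotation table
#'
#' Two-column CSV/TSV mapping `cell_id` to `cell_type`, header required.
#'
#' @param path file path (`.csv` or `.tsv`).
#' @return A tibble with columns `cell_id`, `cell_type`.
#' @export
read_cell_annotation <- function(path) {
  delim <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(tab) < 2) stop("annotation needs two columns (cell_id, cell_type)", call. = FALSE)
  ann <- tibble::tibble(cell_id = as.character(tab[[1]]),
                        cell_type = as.character(tab[[2]]))
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  if (anyDuplicated(ann$cell_id)) {
    stop("duplicate cell ids in annotation: ",
         paste(utils::head(unique(ann$cell_id[duplicated(ann$cell_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(ann$cell_type)) || anyNA(ann$cell_type)) {
    stop("empty cell_type labels in annotation", call. = FALSE)
  }
  invisible(ann)
}

#' Remove cells carrying ambiguous type labels
#'
#' Atlas annotations often include placeholder labels ("unknown", "hybrid")
#' that must not seed atlas communities; cells carrying a blacklisted label
#' are dropped and the removal tallied in a message.
#'
#' @param ann annotation tibble (`cell_id`, `cell_type`).
#' @param blacklist character vector of labels to drop (case-insensitive).
#' @return The filtered annotation tibble; attribute `"removed"` holds the
#'   per-label removal counts.
#' @export
exclude_ambiguous_types <- function(ann, blacklist = c("unknown", "hybrid")) {
  validate_annotation(ann)
  bad <- tolower(ann$cell_type) %in% tolower(blacklist)
  removed <- table(ann$cell_type[bad])
  if (all(bad) && length(bad) > 0) {
    warning("all cells carried blacklisted labels; annotation is empty", call. = FALSE)
  }
  out <- ann[!bad, , drop = FALSE]
  attr(out, "removed") <- as.list(removed)
  out
}
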