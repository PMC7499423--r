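#' Compress an atlas into per-type average landmarks
#'
#' For each cell type the arithmetic mean of the CPM-normalized expression
#' profiles of its cells is stored together with the number of cells it
#' summarizes.  Storage grows with (types x genes) only, independent of how
#' many cells the atlas holds — this is what makes landmark atlases scale.
#'
#' @param atlas a CPM-normalized [count_matrix()] of atlas cells.
#' @param ann annotation tibble (`cell_id`, `cell_type`) covering the atlas
#'   cells; ambiguous labels must already be excluded
#'   (see [exclude_ambiguous_types()]).
#' @param blacklist labels rejected as ambiguous (checked, not removed here).
#' @return An `atlas_averages` object: list with `means` (types x genes
#'   matrix), `n_cells` (named per-type cell counts).
#' @export
compute_averages <- function(atlas, ann, blacklist = c("unknown", "hybrid")) {
  stopifnot(inherits(atlas, "count_matrix"))
  if (!atlas$normalized) stop("atlas must be CPM-normalized", call. = FALSE)
  validate_annotation(ann)
  if (any(tolower(ann$cell_type) %in% tolower(blacklist))) {
    stop("annotation still contains ambiguous labels; run exclude_ambiguous_types() first",
         call. = FALSE)
  }
  missing <- setdiff(cell_ids(atlas), ann$cell_id)
  if (length(missing) > 0) {
    stop("atlas cells without annotation: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  labels <- ann$cell_type[match(cell_ids(atlas), ann$cell_id)]
  types <- unique(labels)
  means <- matrix(0, length(types), nrow(atlas$values),
                  dimnames = list(types, gene_ids(atlas)))
  for (t in types) {
    means[t, ] <- rowMeans(atlas$values[, labels == t, drop = FALSE])
  }
  n_cells <- vapply(types, function(t) sum(labels == t), integer(1))
  structure(list(means = means, n_cells = n_cells), class = "atlas_averages")
}

#' @export
print.atlas_averages <- function(x, ...) {
  cat(sprintf("<atlas_averages> %d cell types x %d genes (from %d cells)\n",
              nrow(x$means), ncol(x$means), sum(x$n_cells)))
  invisible(x)
}

#' Compress an atlas into a fixed-size labeled subsample
#'
#' Draws up to `n_per_type` cells per cell type uniformly at random without
#' replacement (types with fewer cells contribute all of them).
#' Deterministic given `seed`.
#'
#' @inheritParams compute_averages
#' @param n_per_type target cells per type (the usual choice is 20).
#' @param seed integer seed for the draw.
#' @return An `atlas_subsample` object: list with `counts`
#'   (CPM [count_matrix()] of selected cells), `annotation` (tibble
#'   restricted to them), `n_per_type`.
#' @export
subsample_atlas <- function(atlas, ann, n_per_type = 20, seed = 0,
                            blacklist = c("unknown", "hybrid")) {
  stopifnot(inherits(atlas, "count_matrix"))
  if (!atlas$normalized) stop("atlas must be CPM-normalized", call. = FALSE)
  if (n_per_type < 1) stop("n_per_type must be >= 1", call. = FALSE)
  validate_annotation(ann)
  if (any(tolower(ann$cell_type) %in% tolower(blacklist))) {
    stop("annotation still contains ambiguous labels; run exclude_ambiguous_types() first",
         call. = FALSE)
  }
  labels <- ann$cell_type[match(cell_ids(atlas), ann$cell_id)]
  if (anyNA(labels)) stop("atlas cells without annotation", call. = FALSE)
  keep <- withr::with_seed(seed, {
    unlist(lapply(unique(labels), function(t) {
      idx <- which(labels == t)
      if (length(idx) <= n_per_type) idx else sort(sample(idx, n_per_type))
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  sub <- count_matrix(atlas$values[, keep, drop = FALSE], normalized = TRUE)
  structure(list(
    counts = sub,
    annotation = tibble::tibble(cell_id = cell_ids(sub), cell_type = labels[keep]),
    n_per_type = as.integer(n_per_type)
  ), class = "atlas_subsample")
}

#' @export
print.atlas_subsample <- function(x, ...) {
  cat(sprintf("<atlas_subsample> %d cells, %d cell types (<= %d per type)\n",
              ncol(x$counts$values), length(unique(x$annotation$cell_type)),
              x$n_per_type))
  invisible(x)
}

# Fixed-width value formatting: file size depends only on matrix shape and
# doubles round-trip exactly through as.numeric().
.fmt_val <- function(x) sprintf("%.17e", x)

#' Save / load an atlas landmark bundle
#'
#' Landmarks are stored as a two-file bundle: `<stem>.landmarks.tsv` (the
#' matrix, types-or-cells x genes) and `<stem>.landmarks.json` (labels,
#' cell counts, format metadata).  Round-trip is lossless.
#'
#' @param l an `atlas_averages` or `atlas_subsample`.
#' @param stem path stem; the two files get `.landmarks.tsv` /
#'   `.landmarks.json` suffixes.
#' @return `save_landmarks()`: the stem, invisibly.  `load_landmarks()`:
#'   the restored landmark object.
#' @export
save_landmarks <- function(l, stem) {
  tsv <- paste0(stem, ".landmarks.tsv")
  json <- paste0(stem, ".landmarks.json")
  if (inherits(l, "atlas_averages")) {
    mat <- l$means
    meta <- list(format = "atlas-landmarks", version = 1L, mode = "average",
                 cell_types = rownames(mat), genes = colnames(mat),
                 n_cells = as.list(stats::setNames(as.integer(l$n_cells),
                                                   names(l$n_cells))))
  } else if (inherits(l, "atlas_subsample")) {
    mat <- t(l$counts$values)
    meta <- list(format = "atlas-landmarks", version = 1L, mode = "subsample",
                 cell_ids = rownames(mat), genes = colnames(mat),
                 cell_types = l$annotation$cell_type,
                 n_per_type = l$n_per_type)
  } else stop("not a landmark object", call. = FALSE)
  lines <- c(paste(c("id", colnames(mat)), collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i) {
               paste(c(rownames(mat)[i], .fmt_val(mat[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, tsv)
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname save_landmarks
#' @export
load_landmarks <- function(stem) {
  tsv <- paste0(stem, ".landmarks.tsv")
  json <- paste0(stem, ".landmarks.json")
  if (!file.exists(tsv) || !file.exists(json)) {
    stop("landmark bundle not found at stem ", stem, call. = FALSE)
  }
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  for (f in c("format", "mode", "genes")) {
    if (is.null(meta[[f]])) stop("landmark metadata missing field: ", f, call. = FALSE)
  }
  lines <- readLines(tsv)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- vapply(body, `[[`, character(1), 1)
  mat <- do.call(rbind, lapply(body, function(r) as.numeric(r[-1])))
  dimnames(mat) <- list(ids, header[-1])
  if (!identical(colnames(mat), as.character(meta$genes))) {
    stop("landmark TSV genes disagree with metadata", call. = FALSE)
  }
  if (meta$mode == "average") {
    if (is.null(meta$n_cells)) stop("landmark metadata missing field: n_cells", call. = FALSE)
    n_cells <- unlist(meta$n_cells)
    structure(list(means = mat, n_cells = n_cells[rownames(mat)]),
              class = "atlas_averages")
  } else if (meta$mode == "subsample") {
    if (is.null(meta$cell_types)) stop("landmark metadata missing field: cell_types", call. = FALSE)
    counts <- count_matrix(t(mat), normalized = TRUE)
    structure(list(
      counts = counts,
      annotation = tibble::tibble(cell_id = rownames(mat),
                                  cell_type = as.character(meta$cell_types)),
      n_per_type = as.integer(meta$n_per_type %||% NA_integer_)
    ), class = "atlas_subsample")
  } else stop("unknown landmark mode: ", meta$mode, call. = FALSE)
}
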