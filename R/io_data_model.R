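# Core containers and readers/writers: UMI count matrices (genes x cells,
# cells are always columns), regulon gene sets (GMT), and bulk matrices.

#' Construct a single-cell UMI count matrix
#'
#' A `CellMatrix` holds a sparse non-negative integer matrix of UMI counts
#' with genes as rows and cells as columns, plus per-cell metadata.
#'
#' @param counts matrix or `Matrix::sparseMatrix` of non-negative integer
#'   counts, genes x cells. Row and column names are used as gene and cell
#'   identifiers unless `gene_ids`/`cell_ids` are given.
#' @param gene_ids,cell_ids optional character identifiers; must be unique.
#' @param cell_meta optional data.frame of per-cell records. Recognised
#'   columns: `sample_id`, `timepoint` ("pre"/"post"), `response`
#'   ("responder"/"nonresponder"), `celltype`, `cluster`; extra columns
#'   (e.g. ground-truth labels) are kept as-is.
#' @return an object of class `CellMatrix` with elements `counts`
#'   (`dgCMatrix`), `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
cell_matrix <- function(counts, gene_ids = rownames(counts),
                        cell_ids = colnames(counts), cell_meta = NULL) {
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stopf("counts must carry gene and cell identifiers")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts)) {
    stopf("length of gene_ids (%d) does not match nrow(counts) (%d)",
          length(gene_ids), nrow(counts))
  }
  if (length(cell_ids) != ncol(counts)) {
    stopf("length of cell_ids (%d) does not match ncol(counts) (%d)",
          length(cell_ids), ncol(counts))
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stopf("duplicate gene_ids: %s", paste(head(dup, 5), collapse = ", "))
  dup <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup)) stopf("duplicate cell_ids: %s", paste(head(dup, 5), collapse = ", "))
  if (!is(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(counts, "generalMatrix"), "CsparseMatrix")
  if (is(counts, "nMatrix") || is(counts, "lMatrix")) {
    counts <- counts * 1
  }
  v <- counts@x
  if (any(v < 0) || any(v != round(v)) || any(!is.finite(v))) {
    stopf("counts must be non-negative integers")
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  meta <- default_cell_meta(cell_ids)
  if (!is.null(cell_meta)) {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != length(cell_ids)) {
      stopf("cell_meta has %d rows for %d cells", nrow(cell_meta), length(cell_ids))
    }
    if (!is.null(cell_meta$cell_id) &&
        !identical(as.character(cell_meta$cell_id), cell_ids)) {
      stopf("cell_meta$cell_id does not match cell_ids")
    }
    for (col in setdiff(names(cell_meta), "cell_id")) meta[[col]] <- cell_meta[[col]]
  }
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = meta),
            class = "CellMatrix")
}

default_cell_meta <- function(cell_ids) {
  n <- length(cell_ids)
  data.frame(cell_id = cell_ids,
             sample_id = rep(NA_character_, n), timepoint = rep(NA_character_, n),
             response = rep(NA_character_, n), celltype = rep(NA_character_, n),
             cluster = rep(NA_integer_, n), stringsAsFactors = FALSE)
}

#' @method print CellMatrix
#' @export
print.CellMatrix <- function(x, ...) {
  cat(sprintf("CellMatrix: %d genes x %d cells (%.0f nonzero UMIs)\n",
              length(x$gene_ids), length(x$cell_ids), length(x$counts@x)))
  invisible(x)
}

#' @export
dim.CellMatrix <- function(x) dim(x$counts)

#' Subset a CellMatrix by cells (and optionally genes)
#'
#' @param m a `CellMatrix`.
#' @param cells,genes logical, integer, or character index vectors.
#' @return the subsetted `CellMatrix`, metadata carried along.
#' @export
subset_cells <- function(m, cells, genes = NULL) {
  stopifnot(inherits(m, "CellMatrix"))
  if (is.character(cells)) cells <- match(cells, m$cell_ids)
  if (is.logical(cells)) cells <- which(cells)
  gi <- if (is.null(genes)) seq_along(m$gene_ids) else genes
  if (is.character(gi)) gi <- match(gi, m$gene_ids)
  if (is.logical(gi)) gi <- which(gi)
  counts <- m$counts[gi, cells, drop = FALSE]
  cell_matrix(counts, gene_ids = m$gene_ids[gi], cell_ids = m$cell_ids[cells],
              cell_meta = m$cell_meta[cells, , drop = FALSE])
}

#' Construct a normalized expression matrix
#'
#' @param values real genes x cells matrix (non-negative, finite).
#' @param transform_tag string describing the applied transform.
#' @return an object of class `NormalizedMatrix`.
#' @export
normalized_matrix <- function(values, transform_tag = "raw") {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("values must carry gene and cell identifiers as dimnames")
  }
  v <- if (is(values, "Matrix")) values@x else values
  if (any(!is.finite(v)) || any(v < 0)) stopf("normalized values must be finite and >= 0")
  structure(list(values = values, gene_ids = rownames(values),
                 cell_ids = colnames(values), transform_tag = transform_tag),
            class = "NormalizedMatrix")
}

#' @method print NormalizedMatrix
#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix [%s]: %d genes x %d cells\n",
              x$transform_tag, length(x$gene_ids), length(x$cell_ids)))
  invisible(x)
}

#' Construct a regulon (a TF with its target gene set)
#'
#' @param tf transcription factor name.
#' @param targets character vector of target gene symbols (non-empty; any
#'   duplicates are dropped with a warning).
#' @param include_tf_in_scoring should the TF's own gene be part of the
#'   scored set? Defaults to `FALSE`: activity is scored on targets only.
#' @return an object of class `Regulon`.
#' @export
regulon <- function(tf, targets, include_tf_in_scoring = FALSE) {
  stopifnot(is.character(tf), length(tf) == 1L, nzchar(tf))
  targets <- as.character(targets)
  if (!length(targets)) stopf("regulon '%s' has no targets", tf)
  if (anyDuplicated(targets)) {
    warnf("regulon '%s': dropping %d duplicated target(s)", tf,
          sum(duplicated(targets)))
    targets <- unique(targets)
  }
  structure(list(tf = tf, targets = targets,
                 include_tf_in_scoring = isTRUE(include_tf_in_scoring)),
            class = "Regulon")
}

#' @method print Regulon
#' @export
print.Regulon <- function(x, ...) {
  cat(sprintf("Regulon %s: %d targets (TF %s in scoring)\n", x$tf,
              length(x$targets), if (x$include_tf_in_scoring) "included" else "excluded"))
  invisible(x)
}

# Gene set actually used for scoring a regulon.
scoring_genes <- function(reg) {
  if (reg$include_tf_in_scoring) unique(c(reg$tf, reg$targets)) else reg$targets
}

#' Construct a bulk expression matrix
#'
#' @param values real genes x samples matrix (finite), dimnames required.
#' @param sample_meta optional data.frame with per-sample `response`,
#'   `time` (months, > 0), `event` (0/1), `immune_score`.
#' @return an object of class `BulkMatrix`.
#' @export
bulk_matrix <- function(values, sample_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("bulk values must carry gene and sample identifiers")
  }
  if (any(!is.finite(values))) stopf("bulk values must be finite")
  if (anyDuplicated(colnames(values))) stopf("duplicate sample_ids")
  meta <- data.frame(sample_id = colnames(values), response = NA_character_,
                     time = NA_real_, event = NA_integer_,
                     immune_score = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (nrow(sample_meta) != ncol(values)) {
      stopf("sample_meta has %d rows for %d samples", nrow(sample_meta), ncol(values))
    }
    for (col in setdiff(names(sample_meta), "sample_id")) meta[[col]] <- sample_meta[[col]]
    if (any(!meta$event[!is.na(meta$event)] %in% c(0L, 1L))) {
      stopf("event indicator must be 0 or 1")
    }
    tt <- meta$time[!is.na(meta$time)]
    if (any(tt <= 0)) stopf("survival times must be positive")
  }
  structure(list(values = values, gene_ids = rownames(values),
                 sample_ids = colnames(values), sample_meta = meta),
            class = "BulkMatrix")
}

read_id_file <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  # 10x-style files may carry extra tab-separated columns; the first is the id
  vapply(strsplit(ids, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Read a single-cell count matrix from disk
#'
#' Accepts Matrix Market triplet files (10x-style, with separate gene and
#' cell id files) or a dense delimited table. Orientation is auto-detected
#' from the id-file lengths and the result is always genes x cells.
#'
#' @param path_matrix path to the `.mtx` file or dense TSV/CSV.
#' @param path_genes,path_cells id files, one identifier per line.
#' @param path_meta optional TSV of per-cell metadata with a `cell_id` column.
#' @return a `CellMatrix`.
#' @export
read_cell_matrix <- function(path_matrix, path_genes, path_cells,
                             path_meta = NULL) {
  genes <- read_id_file(path_genes)
  cells <- read_id_file(path_cells)
  if (grepl("\\.mtx$", path_matrix)) {
    m <- Matrix::readMM(path_matrix)
  } else {
    sep <- if (grepl("\\.csv$", path_matrix)) "," else "\t"
    tab <- read.delim(path_matrix, sep = sep, header = FALSE, check.names = FALSE)
    m <- Matrix::Matrix(as.matrix(tab), sparse = TRUE)
  }
  dims_ok <- function(nr, nc) nr == length(genes) && nc == length(cells)
  if (dims_ok(nrow(m), ncol(m))) {
    # genes x cells already
  } else if (dims_ok(ncol(m), nrow(m))) {
    m <- Matrix::t(m)
  } else {
    stopf(paste0("dimension mismatch: matrix '%s' is %d x %d but '%s' lists ",
                 "%d genes and '%s' lists %d cells"),
          path_matrix, nrow(m), ncol(m), path_genes, length(genes),
          path_cells, length(cells))
  }
  rownames(m) <- genes
  colnames(m) <- cells
  meta <- NULL
  if (!is.null(path_meta)) {
    meta <- read.delim(path_meta, sep = "\t", stringsAsFactors = FALSE)
    if (is.null(meta$cell_id)) stopf("metadata file '%s' lacks a cell_id column", path_meta)
    mi <- match(cells, meta$cell_id)
    if (anyNA(mi)) stopf("metadata file '%s' is missing %d cell id(s)",
                         path_meta, sum(is.na(mi)))
    meta <- meta[mi, , drop = FALSE]
  }
  cell_matrix(m, cell_meta = meta)
}

#' Write a CellMatrix as Matrix Market triplets plus id and metadata files
#'
#' @param m a `CellMatrix`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written (`matrix`, `genes`, `cells`, `meta`).
#' @export
write_cell_matrix <- function(m, dir, prefix = "counts") {
  stopifnot(inherits(m, "CellMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    matrix = file.path(dir, paste0(prefix, ".mtx")),
    genes = file.path(dir, paste0(prefix, ".genes.txt")),
    cells = file.path(dir, paste0(prefix, ".cells.txt")),
    meta = file.path(dir, paste0(prefix, ".meta.tsv")))
  Matrix::writeMM(m$counts, paths$matrix)
  writeLines(m$gene_ids, paths$genes)
  writeLines(m$cell_ids, paths$cells)
  write.table(m$cell_meta, paths$meta, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene symbols.
#' Duplicate genes within a line are dropped with a warning.
#'
#' @param path path to a GMT file.
#' @return a named list of `Regulon` objects (names are the set names).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stopf("GMT line %d of '%s' has %d field(s); expected name, description and >= 1 gene",
            i, path, length(fields))
    }
    out[[fields[[1]]]] <- regulon(fields[[1]], fields[-(1:2)])
  }
  out
}

#' Write regulons to a GMT file
#'
#' @param regulons list of `Regulon` objects.
#' @param path output path.
#' @export
write_gene_sets <- function(regulons, path) {
  lines <- vapply(regulons, function(r) {
    paste(c(r$tf, "regulon", r$targets), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' The packaged 23-gene PPARG regulon
#'
#' The myeloid-cell-specific PPARG regulon used throughout: the PPARG
#' transcription factor with its 23 target genes. The TF itself is excluded
#' from scoring by default (the target list does not contain PPARG).
#'
#' @return a `Regulon` with 23 targets.
#' @export
pparg_regulon <- function() {
  path <- system.file("extdata", "pparg_regulon.gmt", package = "myeloregulon",
                      mustWork = TRUE)
  read_gene_sets(path)[["PPARG"]]
}

#' Packaged default lineage marker signatures
#'
#' Generic canonical marker sets (T, B, myeloid, epithelial) for
#' cluster annotation; a convenience default, not tied to any one tissue.
#'
#' @return a named list of `Regulon` objects, one per lineage.
#' @export
lineage_signatures <- function() {
  path <- system.file("extdata", "lineage_signatures.gmt",
                      package = "myeloregulon", mustWork = TRUE)
  read_gene_sets(path)
}
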