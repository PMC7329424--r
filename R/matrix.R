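#' Assemble the sparse gene-cell count matrix
#'
#' Rows are cells, sorted lexicographically by barcode (a deterministic
#' order); columns are genes in taxonomy order, including genes with zero
#' total counts. One triplet per nonzero (cell, gene); indices are 0-based.
#'
#' @param molecule_counts Tibble with columns `cb`, `gene`, `molecules`
#'   (from [dedup_records()]).
#' @param tax A `tx_taxonomy` supplying the gene order.
#' @return A `gene_cell_matrix`: fields `triplets` (tibble `cell`, `gene`,
#'   `count`, 0-based indices), `cell_ids`, `gene_ids`.
#' @export
assemble_matrix <- function(molecule_counts, tax) {
  gene_ids <- tax$gene_order
  unknown <- setdiff(molecule_counts$gene, gene_ids)
  if (length(unknown) > 0)
    stop("gene id absent from taxonomy: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cell_ids <- sort(unique(molecule_counts$cb))
  triplets <- molecule_counts |>
    dplyr::mutate(
      cell = match(.data$cb, cell_ids) - 1L,
      gene = match(.data$gene, gene_ids) - 1L,
      count = as.integer(.data$molecules)
    ) |>
    dplyr::arrange(.data$cell, .data$gene) |>
    dplyr::select("cell", "gene", "count")
  if (anyDuplicated(triplets[c("cell", "gene")]))
    stop("duplicate (cell, gene) entry", call. = FALSE)
  structure(list(triplets = triplets, cell_ids = cell_ids,
                 gene_ids = gene_ids),
            class = "gene_cell_matrix")
}

#' @export
print.gene_cell_matrix <- function(x, ...) {
  cat(sprintf("<gene_cell_matrix> %d cells x %d genes, %d nonzero entries\n",
              length(x$cell_ids), length(x$gene_ids), nrow(x$triplets)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gene_cell_matrix <- function(x, ...) {
  x$triplets |>
    dplyr::mutate(cb = x$cell_ids[.data$cell + 1L],
                  gene_id = x$gene_ids[.data$gene + 1L])
}

#' @exportS3Method generics::glance
glance.gene_cell_matrix <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$cell_ids),
    n_genes = length(x$gene_ids),
    nnz = nrow(x$triplets),
    total_molecules = sum(x$triplets$count)
  )
}

#' Convert to a Matrix::sparseMatrix (cells x genes)
#'
#' @param x A `gene_cell_matrix`.
#' @return A `dgCMatrix` with dimnames (cell barcodes, gene ids).
#' @export
as_sparse <- function(x) {
  Matrix::sparseMatrix(
    i = x$triplets$cell + 1L, j = x$triplets$gene + 1L,
    x = x$triplets$count,
    dims = c(length(x$cell_ids), length(x$gene_ids)),
    dimnames = list(x$cell_ids, x$gene_ids)
  )
}

#' Write the count matrix and its two index files
#'
#' Three files are written. Native dialect: `matrix.coo.tsv`
#' (tab-separated `cell_index gene_index count`, 0-based), `barcodes.tsv`
#' (one barcode per line, row order), `genes.tsv` (one gene id per line,
#' column order). MatrixMarket dialect: `matrix.mtx`
#' (`coordinate integer general`, 1-based, size line with dims and nnz)
#' plus the same two index files. [read_matrix()] reproduces the matrix
#' exactly.
#'
#' @param x A `gene_cell_matrix`.
#' @param outdir Output directory (created if absent).
#' @param dialect `"native"` or `"matrixmarket"`.
#' @return Invisibly, the paths of the three files.
#' @export
write_matrix <- function(x, outdir, dialect = c("native", "matrixmarket")) {
  dialect <- match.arg(dialect)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bc_path <- file.path(outdir, "barcodes.tsv")
  gn_path <- file.path(outdir, "genes.tsv")
  writeLines(x$cell_ids, bc_path)
  writeLines(x$gene_ids, gn_path)
  if (dialect == "native") {
    m_path <- file.path(outdir, "matrix.coo.tsv")
    readr::write_tsv(x$triplets, m_path, col_names = FALSE)
  } else {
    m_path <- file.path(outdir, "matrix.mtx")
    header <- c(
      "%%MatrixMarket matrix coordinate integer general",
      sprintf("%d %d %d", length(x$cell_ids), length(x$gene_ids),
              nrow(x$triplets)),
      sprintf("%d %d %d", x$triplets$cell + 1L, x$triplets$gene + 1L,
              x$triplets$count)
    )
    writeLines(header, m_path)
  }
  invisible(c(matrix = m_path, barcodes = bc_path, genes = gn_path))
}

#' @rdname write_matrix
#' @param indir Directory holding the three files.
#' @export
read_matrix <- function(indir, dialect = c("native", "matrixmarket")) {
  dialect <- match.arg(dialect)
  cell_ids <- readLines(file.path(indir, "barcodes.tsv"))
  gene_ids <- readLines(file.path(indir, "genes.tsv"))
  if (dialect == "native") {
    triplets <- readr::read_tsv(
      file.path(indir, "matrix.coo.tsv"), col_names = c("cell", "gene", "count"),
      col_types = "iii"
    )
  } else {
    mm <- Matrix::readMM(file.path(indir, "matrix.mtx"))
    mm <- methods::as(mm, "TsparseMatrix")
    triplets <- tibble::tibble(cell = mm@i, gene = mm@j,
                               count = as.integer(mm@x)) |>
      dplyr::arrange(.data$cell, .data$gene)
  }
  structure(list(triplets = tibble::as_tibble(triplets),
                 cell_ids = cell_ids, gene_ids = gene_ids),
            class = "gene_cell_matrix")
}
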