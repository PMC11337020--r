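# Per-cell quality gates and T-cell identification. All four gates are strict
# inequalities exactly as stated for the study design: mito fraction < 0.12,
# UMI count > 500, gene count > 200, expressed housekeeping genes > 40.
# Boundary values fail.

#' Compute per-cell QC metrics and gate decisions
#'
#' @param mat a [count_matrix()].
#' @param housekeeping_genes character vector of housekeeping gene symbols;
#'   a gene counts as expressed with >= 1 UMI. Defaults to the packaged list.
#' @param mito_rule either a symbol prefix (default `"MT-"`, case-insensitive)
#'   or an explicit character vector of mitochondrial gene symbols.
#' @param cd3_genes optional CD3 gene set; when given, an `is_t_cell` column
#'   is added (>= 1 UMI summed over the set, see [identify_t_cells()]).
#' @param mito_max,umi_min,gene_min,housekeeping_min the four gate thresholds.
#' @return data.frame with one row per cell: barcode, umi_count, gene_count,
#'   mito_fraction, housekeeping_expressed, passes_qc (and is_t_cell).
#' @export
compute_cell_qc <- function(mat,
                            housekeeping_genes = default_gene_list("housekeeping"),
                            mito_rule = "MT-",
                            cd3_genes = NULL,
                            mito_max = 0.12, umi_min = 500,
                            gene_min = 200, housekeeping_min = 40) {
  stopifnot(length(housekeeping_genes) > 0)
  counts <- mat$counts
  sym <- mat$gene_symbols
  if (length(mito_rule) == 1 && !mito_rule %in% sym) {
    mito_idx <- which(startsWith(toupper(sym), toupper(mito_rule)))
  } else {
    mito_idx <- which(sym %in% mito_rule)
  }
  umi_count <- Matrix::colSums(counts)
  gene_count <- Matrix::colSums(counts > 0)
  mito_umis <- if (length(mito_idx))
    Matrix::colSums(counts[mito_idx, , drop = FALSE]) else rep(0, ncol(counts))
  mito_fraction <- ifelse(umi_count > 0, mito_umis / umi_count, 0)
  hk_idx <- which(sym %in% housekeeping_genes)
  hk_expressed <- if (length(hk_idx))
    Matrix::colSums(counts[hk_idx, , drop = FALSE] > 0) else rep(0L, ncol(counts))
  qc <- data.frame(
    barcode = mat$cell_barcodes,
    umi_count = as.numeric(umi_count),
    gene_count = as.integer(gene_count),
    mito_fraction = as.numeric(mito_fraction),
    housekeeping_expressed = as.integer(hk_expressed),
    stringsAsFactors = FALSE)
  qc$passes_qc <- qc$mito_fraction < mito_max & qc$umi_count > umi_min &
    qc$gene_count > gene_min & qc$housekeeping_expressed > housekeeping_min
  if (!is.null(cd3_genes)) qc$is_t_cell <- identify_t_cells(mat, cd3_genes)
  qc
}

#' Filter a count matrix to QC-passing cells
#'
#' @param mat a [count_matrix()].
#' @param qc the QC table from [compute_cell_qc()]; must cover every barcode.
#' @return `count_matrix` containing exactly the passing cells, original
#'   order and gene axis preserved, layers sliced congruently.
#' @export
filter_cells <- function(mat, qc) {
  idx <- match(mat$cell_barcodes, qc$barcode)
  if (anyNA(idx))
    stop("filter_cells: QC table does not cover every barcode in the matrix")
  subset_cells(mat, qc$passes_qc[idx])
}

#' Identify T cells by CD3 expression
#'
#' A cell is flagged as a T cell iff it has at least `min_umis` UMIs summed
#' over the CD3 gene set.
#'
#' @param mat a [count_matrix()].
#' @param cd3_genes CD3 gene symbols; default CD3D/CD3E/CD3G.
#' @param min_umis threshold on the summed CD3 UMIs (default 1).
#' @return logical vector, one flag per cell.
#' @export
identify_t_cells <- function(mat, cd3_genes = c("CD3D", "CD3E", "CD3G"),
                             min_umis = 1) {
  idx <- which(mat$gene_symbols %in% cd3_genes)
  if (!length(idx))
    stop("configuration error: none of the CD3 genes (",
         paste(cd3_genes, collapse = ", "), ") are present in the matrix")
  as.vector(Matrix::colSums(mat$counts[idx, , drop = FALSE]) >= min_umis)
}
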