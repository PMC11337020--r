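# I/O for the 10x-style on-disk formats the pipeline touches: MatrixMarket
# count triplets, VDJ contig annotation CSVs, gene-position tables and flat
# result tables. Reading is a pure transcription: no reordering, no collapsing.

#' Construct a count matrix container
#'
#' Genes-by-cells sparse integer UMI counts with optional same-shape layers
#' (e.g. `spliced`/`unspliced`). Gene identifiers must be unique; symbols may
#' repeat (they are display names).
#'
#' @param counts sparse or dense non-negative integer matrix, genes x cells.
#' @param gene_ids unique stable identifiers, one per row.
#' @param gene_symbols display symbols, one per row.
#' @param cell_barcodes unique barcodes, one per column.
#' @param sample_id sample label.
#' @param layers optional named list of matrices congruent with `counts`.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids, gene_symbols, cell_barcodes,
                         sample_id, layers = list()) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(gene_ids) || nrow(counts) != length(gene_symbols))
    stop("count_matrix: gene axis does not match gene_ids/gene_symbols")
  if (ncol(counts) != length(cell_barcodes))
    stop("count_matrix: cell axis does not match cell_barcodes")
  if (anyDuplicated(cell_barcodes))
    stop("count_matrix: cell barcodes must be unique within a sample")
  if (anyDuplicated(gene_ids))
    stop("count_matrix: gene_ids must be unique")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stop("count_matrix: counts must be non-negative integers")
  for (nm in names(layers)) {
    layers[[nm]] <- methods::as(methods::as(layers[[nm]], "CsparseMatrix"),
                                "generalMatrix")
    if (!identical(dim(layers[[nm]]), dim(counts)))
      stop("count_matrix: layer '", nm, "' is not congruent with counts")
  }
  rownames(counts) <- gene_ids
  colnames(counts) <- cell_barcodes
  structure(
    list(counts = counts, gene_ids = as.character(gene_ids),
         gene_symbols = as.character(gene_symbols),
         cell_barcodes = as.character(cell_barcodes),
         sample_id = sample_id, layers = layers),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> sample '%s': %d genes x %d cells, %d layer(s)\n",
              x$sample_id, nrow(x$counts), ncol(x$counts), length(x$layers)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix to a set of cells
#'
#' Gene axis and layer congruence are preserved; cell order follows `cells`.
#'
#' @param mat a [count_matrix()].
#' @param cells logical mask over columns, or character barcodes.
#' @return a `count_matrix` restricted to the requested cells.
#' @export
subset_cells <- function(mat, cells) {
  if (is.logical(cells)) {
    stopifnot(length(cells) == ncol(mat$counts))
    idx <- which(cells)
  } else {
    idx <- match(cells, mat$cell_barcodes)
    if (anyNA(idx)) stop("subset_cells: unknown barcodes requested")
  }
  count_matrix(mat$counts[, idx, drop = FALSE], mat$gene_ids, mat$gene_symbols,
               mat$cell_barcodes[idx], mat$sample_id,
               layers = lapply(mat$layers, function(l) l[, idx, drop = FALSE]))
}

#' Read a 10x-style MatrixMarket count triplet
#'
#' Transcribes the matrix exactly as stored: genes are rows, cells columns,
#' no reordering, duplicate symbols preserved. Gzipped files are accepted
#' transparently by extension. Features files may have one column (symbol,
#' duplicated into the id) or two or more (id, symbol, ...).
#'
#' @param matrix_path path to the `.mtx[.gz]` file.
#' @param features_path path to the features/genes TSV.
#' @param barcodes_path path to the barcodes list.
#' @param sample_id sample label attached to the result.
#' @param layer_paths optional named character vector of additional `.mtx`
#'   files (e.g. `c(spliced = ..., unspliced = ...)`) with identical axes.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(matrix_path, features_path, barcodes_path,
                              sample_id, layer_paths = NULL) {
  counts <- read_mtx_file(matrix_path)
  feats <- read_features_file(features_path)
  barcodes <- readLines(barcodes_path)
  if (nrow(counts) != nrow(feats))
    stop(sprintf("dimension mismatch: %s declares %d genes but %s has %d rows",
                 matrix_path, nrow(counts), features_path, nrow(feats)))
  if (ncol(counts) != length(barcodes))
    stop(sprintf("dimension mismatch: %s declares %d cells but %s has %d lines",
                 matrix_path, ncol(counts), barcodes_path, length(barcodes)))
  layers <- list()
  for (nm in names(layer_paths)) {
    l <- read_mtx_file(layer_paths[[nm]])
    if (!identical(dim(l), dim(counts)))
      stop(sprintf("dimension mismatch: layer file %s is %dx%d, expected %dx%d",
                   layer_paths[[nm]], nrow(l), ncol(l), nrow(counts), ncol(counts)))
    layers[[nm]] <- l
  }
  count_matrix(counts, feats$id, feats$symbol, barcodes, sample_id, layers)
}

read_mtx_file <- function(path) {
  m <- Matrix::readMM(path)
  if (any(m@x < 0) || any(m@x != round(m@x)))
    stop(sprintf("format error: %s contains non-integer or negative entries", path))
  methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
}

read_features_file <- function(path) {
  tab <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) == 1) data.frame(id = tab[[1]], symbol = tab[[1]])
  else data.frame(id = tab[[1]], symbol = tab[[2]])
}

#' Read a 10x VDJ `filtered_contig_annotations.csv`
#'
#' One record per data row. Boolean-like 10x fields (`"True"`, `"true"`,
#' `"False"`, `"None"`) are normalised to `TRUE`/`FALSE`/`NA`; `"None"` or
#' empty CDR3 sequences become `NA`.
#'
#' @param path CSV path (optionally gzipped).
#' @return data.frame with columns barcode, is_cell, high_confidence, chain,
#'   v_gene, j_gene, c_gene, full_length, productive, cdr3_nt, umis,
#'   raw_clonotype_id.
#' @export
read_contig_annotations <- function(path) {
  tab <- read.csv(path, colClasses = "character")
  parse_contig_table(tab)
}

# Normalise a raw 10x-dialect contig table (all-character columns).
parse_contig_table <- function(tab) {
  tab[] <- lapply(tab, as.character)
  required <- c("barcode", "is_cell", "high_confidence", "chain",
                "productive", "cdr3_nt", "umis")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("format error: contig file is missing required column(s): ",
         paste(missing, collapse = ", "))
  as_flag <- function(x) {
    x <- tolower(trimws(x))
    out <- rep(NA, length(x))
    out[x %in% c("true", "t", "1")] <- TRUE
    out[x %in% c("false", "f", "0")] <- FALSE
    out
  }
  opt <- function(nm) if (nm %in% names(tab)) tab[[nm]] else rep(NA_character_, nrow(tab))
  cdr3 <- toupper(trimws(tab$cdr3_nt))
  cdr3[cdr3 %in% c("", "NONE", "NA")] <- NA_character_
  bad <- !is.na(cdr3) & grepl("[^ACGT]", cdr3)
  if (any(bad))
    stop("format error: cdr3_nt contains non-ACGT characters in ",
         sum(bad), " row(s)")
  umis <- suppressWarnings(as.integer(tab$umis))
  if (anyNA(umis) || any(umis < 0))
    stop("format error: umis must be non-negative integers")
  data.frame(
    barcode = tab$barcode,
    is_cell = as_flag(tab$is_cell),
    high_confidence = as_flag(tab$high_confidence),
    chain = ifelse(tab$chain %in% c("TRA", "TRB"), tab$chain, "other"),
    v_gene = opt("v_gene"), j_gene = opt("j_gene"), c_gene = opt("c_gene"),
    full_length = as_flag(opt("full_length")),
    productive = as_flag(tab$productive),
    cdr3_nt = cdr3,
    umis = umis,
    raw_clonotype_id = opt("raw_clonotype_id"),
    stringsAsFactors = FALSE)
}

#' Read a gene-position table
#'
#' Four-or-five-column TSV: gene, chromosome, start, end (1-based inclusive),
#' optional strand. Chromosome labels with or without a `chr` prefix are
#' accepted; each gene may appear at most once.
#'
#' @param path TSV path.
#' @return data.frame with columns gene, chrom, start, end, strand.
#' @export
read_gene_positions <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(tab)[1:4] <- c("gene", "chrom", "start", "end")
  if (!"strand" %in% names(tab)) tab$strand <- "+"
  if (anyDuplicated(tab$gene))
    stop("format error: duplicated gene in position table")
  if (any(tab$start > tab$end))
    stop("format error: start > end in position table")
  tab[, c("gene", "chrom", "start", "end", "strand")]
}

#' Import gene positions from a GTF file
#'
#' Convenience wrapper (requires the rtracklayer package) collapsing `gene`
#' records of a GTF into the four-column schema of [read_gene_positions()].
#'
#' @param path GTF path.
#' @param attribute GTF attribute holding the gene name.
#' @return data.frame with columns gene, chrom, start, end, strand.
#' @export
gene_positions_from_gtf <- function(path, attribute = "gene_name") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("gene_positions_from_gtf requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  gene <- as.character(S4Vectors::mcols(gr)[[attribute]])
  keep <- !is.na(gene) & !duplicated(gene)
  gr <- gr[keep]
  data.frame(gene = gene[keep],
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Write a result table
#'
#' Tables round-trip: [read_table_file()] on the written file recovers the
#' values (within floating-point print precision for CSV/TSV).
#'
#' @param rows data.frame sharing one schema.
#' @param path output path.
#' @param format one of `"csv"`, `"tsv"`, `"json"`.
#' @export
write_table <- function(rows, path, format = c("csv", "tsv", "json")) {
  format <- match.arg(format)
  rows <- as.data.frame(rows)
  switch(format,
    csv = write.csv(rows, path, row.names = FALSE),
    tsv = write.table(rows, path, sep = "\t", row.names = FALSE, quote = TRUE),
    json = jsonlite::write_json(rows, path, dataframe = "rows", digits = NA,
                                na = "null"))
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_file <- function(path, format = c("csv", "tsv", "json")) {
  format <- match.arg(format)
  switch(format,
    csv = read.csv(path, stringsAsFactors = FALSE),
    tsv = read.delim(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE)))
}

#' Write a count matrix as a 10x-style triplet
#'
#' Emits `matrix.mtx`, `features.tsv` (id, symbol, type), `barcodes.tsv` and
#' one `<layer>.mtx` per layer into `dir`.
#'
#' @param mat a [count_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(mat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(mat$counts, file.path(dir, "matrix.mtx"))
  write.table(
    data.frame(mat$gene_ids, mat$gene_symbols, "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(mat$cell_barcodes, file.path(dir, "barcodes.tsv"))
  for (nm in names(mat$layers))
    Matrix::writeMM(mat$layers[[nm]], file.path(dir, paste0(nm, ".mtx")))
  invisible(dir)
}
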