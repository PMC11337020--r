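# Copy-number scoring of malignant cells against the reactive-T reference in
# the style of expression-based CNV inference: order genes along the genome,
# centre by the reference mean, cap extreme per-gene deviations, smooth with
# a moving average that never crosses a chromosome boundary, and re-centre
# each cell by its own median. Scores stay continuous (no HMM state calls).

#' Order genes genomically
#'
#' Deterministic order by chromosome (1..22, X; `chr` prefixes tolerated)
#' then start coordinate then gene name. Genes without a position and
#' chromosomes retaining fewer than `min_genes_per_chrom` genes are dropped
#' (counts reported via message).
#'
#' @param genes gene symbols present in the expression matrix.
#' @param positions gene-position table ([read_gene_positions()] schema).
#' @param min_genes_per_chrom minimum genes to retain a chromosome.
#' @return list: genes (ordered character), boundaries (data.frame chrom,
#'   start_idx, end_idx), n_unplaced.
#' @export
order_genes <- function(genes, positions, min_genes_per_chrom = 5) {
  idx <- match(genes, positions$gene)
  unplaced <- sum(is.na(idx))
  pos <- positions[na.omit(idx), , drop = FALSE]
  pos$rank <- chromosome_rank(pos$chrom)
  off_vocab <- sum(is.na(pos$rank))
  pos <- pos[!is.na(pos$rank), , drop = FALSE]
  if (!nrow(pos))
    stop("configuration error: no gene of the matrix has a genomic position")
  keep_chrom <- names(which(table(pos$rank) >= min_genes_per_chrom))
  pos <- pos[pos$rank %in% as.integer(keep_chrom), , drop = FALSE]
  pos <- pos[order(pos$rank, pos$start, pos$gene), , drop = FALSE]
  if (unplaced + off_vocab > 0)
    message(sprintf("order_genes: dropped %d unplaced and %d off-vocabulary gene(s)",
                    unplaced, off_vocab))
  runs <- rle(pos$rank)
  ends <- cumsum(runs$lengths)
  boundaries <- data.frame(
    chrom = chromosome_levels()[runs$values],
    start_idx = c(1L, head(ends, -1) + 1L),
    end_idx = ends, stringsAsFactors = FALSE)
  list(genes = pos$gene, boundaries = boundaries,
       n_unplaced = unplaced + off_vocab)
}

# centred moving average along rows of a block, window never crossing the
# block; the window shrinks at the edges.
smooth_block <- function(X, window) {
  L <- nrow(X)
  half <- (window - 1) %/% 2
  cs <- rbind(0, apply(X, 2, cumsum))
  i <- seq_len(L)
  lo <- pmax(1L, i - half)
  hi <- pmin(L, i + half)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

#' Reference-centred, smoothed CNV scores
#'
#' Per gene, expression is centred by the reference-cell mean and capped at
#' `clip_sd` reference standard deviations; the centred values are smoothed
#' along the genomic order with a centred moving average of `window` genes
#' that shrinks at chromosome edges and never spans two chromosomes; finally
#' each cell is re-centred by its own median score.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param gene_order result of [order_genes()].
#' @param reference_cells barcodes of the reference (reactive T) cells;
#'   at least `min_reference` required.
#' @param window moving-average width in genes (odd; default 101).
#' @param clip_sd per-gene cap in reference standard deviations (default 3).
#' @param min_reference minimum number of reference cells (default 10).
#' @return object of class `cnv_matrix`: scores (ordered genes x cells),
#'   boundaries, reference_cells, window, clip_sd.
#' @export
cnv_scores <- function(norm, gene_order, reference_cells, window = 101,
                       clip_sd = 3, min_reference = 10) {
  if (window %% 2 != 1) stop("cnv_scores: window must be odd")
  ref_idx <- match(reference_cells, colnames(norm))
  if (anyNA(ref_idx)) stop("cnv_scores: unknown reference barcodes")
  if (length(ref_idx) < min_reference)
    stop(sprintf("cnv_scores: need >= %d reference cells, got %d",
                 min_reference, length(ref_idx)))
  E <- as.matrix(norm[gene_order$genes, , drop = FALSE])
  ref_mean <- rowMeans(E[, ref_idx, drop = FALSE])
  ref_sd <- apply(E[, ref_idx, drop = FALSE], 1, sd)
  ref_sd <- pmax(ref_sd, 1e-3)          # guard: all-equal reference genes
  C <- E - ref_mean
  bound <- clip_sd * ref_sd
  C <- pmin(pmax(C, -bound), bound)
  S <- matrix(0, nrow(C), ncol(C), dimnames = dimnames(C))
  for (r in seq_len(nrow(gene_order$boundaries))) {
    b <- gene_order$boundaries[r, ]
    L <- b$end_idx - b$start_idx + 1L
    w <- window
    if (w >= L) {
      warning(sprintf("cnv_scores: window %d >= %d genes on chr%s; shrinking",
                      window, L, b$chrom))
      w <- if (L %% 2 == 1) L else L - 1L
    }
    rows <- b$start_idx:b$end_idx
    S[rows, ] <- smooth_block(C[rows, , drop = FALSE], w)
  }
  S <- sweep(S, 2, apply(S, 2, median))
  structure(list(scores = S, boundaries = gene_order$boundaries,
                 genes = gene_order$genes,
                 reference_cells = reference_cells,
                 window = window, clip_sd = clip_sd),
            class = "cnv_matrix")
}

#' @export
print.cnv_matrix <- function(x, ...) {
  cat(sprintf("<cnv_matrix> %d ordered genes x %d cells (%d reference), window %d\n",
              nrow(x$scores), ncol(x$scores), length(x$reference_cells), x$window))
  invisible(x)
}

#' Per-clone mean CNV profiles
#'
#' @param cnv a [cnv_scores()] result.
#' @param groups named list of barcode vectors (e.g. per-patient malignant
#'   cells).
#' @return matrix of mean profiles, ordered genes x groups.
#' @export
clone_cnv_profile <- function(cnv, groups) {
  sapply(groups, function(cells) {
    idx <- match(cells, colnames(cnv$scores))
    if (anyNA(idx)) stop("clone_cnv_profile: unknown barcodes in group")
    rowMeans(cnv$scores[, idx, drop = FALSE])
  })
}

#' Sliding-block scores along a CNV profile
#'
#' Mean profile score over every contiguous `block_size`-gene block within
#' each chromosome; used to locate candidate gains/losses and to calibrate a
#' detection threshold on reference cells.
#'
#' @param profile numeric per-ordered-gene profile (a column of
#'   [clone_cnv_profile()]).
#' @param boundaries chromosome boundary table from [order_genes()].
#' @param block_size block width in genes (default 30).
#' @return data.frame: chrom, start_idx, end_idx, score.
#' @export
sliding_block_scores <- function(profile, boundaries, block_size = 30) {
  out <- list()
  for (r in seq_len(nrow(boundaries))) {
    b <- boundaries[r, ]
    L <- b$end_idx - b$start_idx + 1L
    if (L < block_size) next
    x <- profile[b$start_idx:b$end_idx]
    cs <- c(0, cumsum(x))
    starts <- seq_len(L - block_size + 1L)
    out[[length(out) + 1L]] <- data.frame(
      chrom = b$chrom,
      start_idx = b$start_idx + starts - 1L,
      end_idx = b$start_idx + starts + block_size - 2L,
      score = (cs[starts + block_size] - cs[starts]) / block_size,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Split malignant cells into CNV subclones
#'
#' k-means on the per-cell CNV score vectors, exposing intra-patient CNV
#' heterogeneity. Deterministic given `seed`.
#'
#' @param cnv a [cnv_scores()] result.
#' @param cells barcodes to cluster.
#' @param k number of subclones (default 2).
#' @param seed RNG seed.
#' @return integer cluster label per cell (named by barcode).
#' @export
cnv_subclusters <- function(cnv, cells, k = 2, seed = 42L) {
  idx <- match(cells, colnames(cnv$scores))
  if (anyNA(idx)) stop("cnv_subclusters: unknown barcodes")
  X <- t(cnv$scores[, idx, drop = FALSE])
  km <- with_seed(seed, kmeans(X, centers = k, nstart = 10))
  setNames(km$cluster, cells)
}
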