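# The transcriptome core: log-normalization, gene-module (cell-cycle) scores,
# covariate regression, highly-variable-gene selection, PCA with an elbow
# rule clamped to 15-25 components, SNN-Louvain clustering at resolution 0.5,
# and a 2-D UMAP used for visualisation only. Samples are processed
# individually and merged afterwards (then re-log-normalized).

#' Log-normalize UMI counts
#'
#' entry = ln(1 + count / cell_total * scale_factor). Cells with zero total
#' counts map to an all-zero column.
#'
#' @param mat a [count_matrix()], or a genes x cells (sparse) matrix.
#' @param scale_factor library-size target (default 10000).
#' @return sparse genes x cells matrix of log-normalized expression, with
#'   gene symbols as rownames and attributes `scale_factor` and `sample_id`.
#' @export
log_normalize <- function(mat, scale_factor = 10000) {
  if (inherits(mat, "count_matrix")) {
    counts <- mat$counts
    rn <- mat$gene_symbols
    sample_id <- mat$sample_id
  } else {
    counts <- methods::as(methods::as(mat, "CsparseMatrix"), "generalMatrix")
    rn <- rownames(counts)
    sample_id <- NULL
  }
  totals <- Matrix::colSums(counts)
  sf <- ifelse(totals > 0, scale_factor / totals, 0)
  norm <- counts %*% Matrix::Diagonal(x = sf)
  norm@x <- log1p(norm@x)
  norm <- methods::as(methods::as(norm, "CsparseMatrix"), "generalMatrix")
  if (!is.null(rn)) {
    if (anyDuplicated(rn)) rn <- make.unique(rn)
    rownames(norm) <- rn
  }
  colnames(norm) <- colnames(counts)
  attr(norm, "scale_factor") <- scale_factor
  attr(norm, "sample_id") <- sample_id
  norm
}

#' Score a gene module per cell
#'
#' Expression-bin-matched control score: the per-cell mean expression of the
#' module genes minus the mean over control genes drawn from the same
#' average-expression bins, so the score is centred against genes of
#' comparable abundance. Deterministic given `seed`.
#'
#' @param norm log-normalized genes x cells matrix.
#' @param gene_set module gene symbols; at least one must be present.
#' @param n_bins number of average-expression bins (default 25).
#' @param n_ctrl control genes sampled per module gene (default 100).
#' @param seed RNG seed for control sampling.
#' @return numeric per-cell score vector.
#' @export
score_gene_module <- function(norm, gene_set, n_bins = 25, n_ctrl = 100,
                              seed = 1L) {
  present <- intersect(gene_set, rownames(norm))
  if (!length(present))
    stop("configuration error: no gene of the module is present in the matrix")
  avg <- Matrix::rowMeans(norm)
  n_bins <- max(1L, min(n_bins, floor(nrow(norm) / 2)))
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- rownames(norm)
  ctrl <- with_seed(seed, {
    unique(unlist(lapply(present, function(g) {
      pool <- names(bin)[bin == bin[[g]]]
      sample(pool, size = min(n_ctrl, length(pool)))
    })))
  })
  set_score <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_score <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  as.numeric(set_score - ctrl_score)
}

#' Regress covariates out of a normalized matrix
#'
#' Per gene, ordinary-least-squares residuals of expression on the covariates
#' (with intercept), with the intercept added back so the output stays on the
#' expression scale. Collinear covariate columns are dropped with a warning.
#'
#' @param norm genes x cells matrix (sparse accepted, densified internally).
#' @param covariates data.frame/matrix of per-cell numeric covariates
#'   (e.g. S score, G2M score, mitochondrial fraction).
#' @return dense genes x cells matrix of corrected expression.
#' @export
regress_covariates <- function(norm, covariates) {
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != ncol(norm))
    stop("regress_covariates: covariates must have one row per cell")
  if (!all(is.finite(covariates)))
    stop("regress_covariates: covariates must be finite")
  X <- cbind(`(Intercept)` = 1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- qx$pivot[seq.int(qx$rank + 1L, ncol(X))]
    warning("regress_covariates: dropping collinear covariate column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
    qx <- qr(X)
  }
  Y <- t(as.matrix(norm))                     # cells x genes
  beta <- qr.coef(qx, Y)                      # coefficients x genes
  fitted <- X %*% beta
  resid <- Y - fitted
  out <- t(resid) + beta["(Intercept)", ]     # add intercept back, genes x cells
  dimnames(out) <- dimnames(norm)
  out
}

#' Select highly variable genes
#'
#' Genes are ranked by mean-variance-trend-corrected dispersion: a loess fit
#' of log10 variance on log10 mean over all expressed genes defines the
#' expected variance at each abundance, and the ranking statistic is the
#' residual log-dispersion. Constant genes are never selected. Deterministic
#' order (ties break by gene name).
#'
#' @param norm genes x cells normalized matrix.
#' @param n number of genes to select (default 2000).
#' @param span loess span for the mean-variance trend.
#' @return character vector of gene names, most variable first.
#' @export
select_hvg <- function(norm, n = 2000, span = 0.3) {
  nc <- ncol(norm)
  mu <- Matrix::rowMeans(norm)
  ex2 <- Matrix::rowMeans(norm^2)
  v <- (ex2 - mu^2) * nc / max(1, nc - 1)
  ok <- v > 1e-12 & mu > 0
  if (!any(ok)) stop("select_hvg: no gene with nonzero variance")
  disp <- rep(NA_real_, length(v))
  lm_ok <- which(ok)
  if (length(lm_ok) >= 30) {
    fit <- tryCatch(
      loess(lv ~ lmu, data = data.frame(lv = log10(v[lm_ok]),
                                        lmu = log10(mu[lm_ok])),
            span = span, degree = 2),
      error = function(e) NULL)
    if (!is.null(fit)) disp[lm_ok] <- log10(v[lm_ok]) - predict(fit)
  }
  if (all(is.na(disp[lm_ok]))) disp[lm_ok] <- log10(v[lm_ok] / mu[lm_ok])
  nm <- rownames(norm) %||% as.character(seq_along(v))
  ord <- order(-disp, nm, na.last = TRUE)
  ord <- ord[ok[ord]]
  if (length(ord) < n)
    warning(sprintf("select_hvg: only %d genes with nonzero variance (requested %d)",
                    length(ord), n))
  nm[head(ord, n)]
}

#' Principal component analysis of a gene subset
#'
#' The gene submatrix is centred and unit-scaled per gene, standardized
#' values are capped at +/- `scale_cap` (so single outlier cells cannot
#' dominate a component), and PCs are computed by SVD.
#'
#' @param norm genes x cells matrix.
#' @param genes genes to use (e.g. from [select_hvg()]); default all rows.
#' @param n_pcs_max maximum number of components to retain (default 50).
#' @param scale_cap cap on standardized values (default 10).
#' @return object of class `pca_embedding`: coords (cells x k), loadings
#'   (genes x k), var_per_dim, center, scale, genes.
#' @export
run_pca <- function(norm, genes = NULL, n_pcs_max = 50, scale_cap = 10) {
  genes <- genes %||% rownames(norm)
  X <- t(as.matrix(norm[genes, , drop = FALSE]))   # cells x genes
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  X[X > scale_cap] <- scale_cap
  X[X < -scale_cap] <- -scale_cap
  k <- min(n_pcs_max, nrow(X) - 1L, ncol(X))
  if (k < n_pcs_max)
    warning(sprintf("run_pca: reducing to %d components (matrix is %d x %d)",
                    k, nrow(X), ncol(X)))
  p <- prcomp(X, center = FALSE, scale. = FALSE, rank. = k)
  structure(
    list(coords = p$x[, seq_len(k), drop = FALSE],
         loadings = p$rotation[, seq_len(k), drop = FALSE],
         var_per_dim = p$sdev[seq_len(k)]^2,
         center = ctr, scale = scl, genes = genes, scale_cap = scale_cap),
    class = "pca_embedding")
}

#' @export
print.pca_embedding <- function(x, ...) {
  cat(sprintf("<pca_embedding> %d cells x %d PCs over %d genes\n",
              nrow(x$coords), ncol(x$coords), length(x$genes)))
  invisible(x)
}

#' Choose the number of PCs by the elbow rule
#'
#' The elbow is formalised as the component with the largest second
#' difference of the ranked variance curve, clamped to `k_range`
#' (default 15-25).
#'
#' @param pca a `pca_embedding` or a numeric variance-per-dimension vector.
#' @param k_range admissible range for the chosen dimensionality.
#' @return integer k.
#' @export
choose_n_pcs <- function(pca, k_range = c(15L, 25L)) {
  v <- if (inherits(pca, "pca_embedding")) pca$var_per_dim else as.numeric(pca)
  n <- length(v)
  if (n < 3) return(min(max(n, k_range[1]), k_range[2], n))
  i <- 2:(n - 1)
  d2 <- v[i - 1] - 2 * v[i] + v[i + 1]
  knee <- i[which.max(d2)]
  as.integer(min(max(knee, k_range[1]), min(k_range[2], n)))
}

#' Cluster cells on a shared-nearest-neighbor graph by Louvain optimisation
#'
#' A k-nearest-neighbor graph in PC space (neighbor sets include the cell
#' itself) is converted to a shared-nearest-neighbor graph with Jaccard edge
#' weights, edges below `prune` are removed, and communities are found by
#' Louvain modularity optimisation at the given resolution. Deterministic
#' given `seed`; labels are dense integers 0..n_clusters-1 ordered by
#' decreasing cluster size.
#'
#' @param coords cells x k coordinate matrix (or a `pca_embedding`).
#' @param n_dims number of leading dimensions to use (default all).
#' @param n_neighbors neighborhood size (default 20).
#' @param resolution Louvain resolution (default 0.5).
#' @param prune minimum Jaccard weight kept (default 1/15).
#' @param seed RNG seed.
#' @return list: labels (integer per cell), resolution, n_clusters.
#' @export
cluster_snn_louvain <- function(coords, n_dims = NULL, n_neighbors = 20,
                                resolution = 0.5, prune = 1 / 15, seed = 42L) {
  if (inherits(coords, "pca_embedding")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (!is.null(n_dims)) coords <- coords[, seq_len(min(n_dims, ncol(coords))), drop = FALSE]
  n <- nrow(coords)
  if (n <= 2) {
    warning("cluster_snn_louvain: too few cells; returning a single cluster")
    return(list(labels = rep(0L, n), resolution = resolution, n_clusters = 1L))
  }
  k <- min(n_neighbors, n)
  nn <- RANN::nn2(coords, k = k)$nn.idx
  M <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn), x = 1,
                            dims = c(n, n))
  S <- Matrix::tcrossprod(M)               # shared-neighbor counts
  S <- methods::as(methods::as(S, "CsparseMatrix"), "generalMatrix")
  S@x <- S@x / (2 * k - S@x)               # Jaccard
  S@x[S@x < prune] <- 0
  S <- Matrix::drop0(S)
  Matrix::diag(S) <- 0
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE)
  memb <- with_seed(seed, igraph::membership(
    igraph::cluster_louvain(g, resolution = resolution)))
  sizes <- table(memb)
  new_id <- setNames(seq_along(sizes) - 1L,
                     names(sort(sizes, decreasing = TRUE)))
  labels <- as.integer(new_id[as.character(memb)])
  list(labels = labels, resolution = resolution,
       n_clusters = length(unique(labels)))
}

#' 2-D UMAP embedding
#'
#' Visualisation (and velocity arrow projection) only; no statistic in the
#' pipeline depends on UMAP coordinates. Deterministic given `seed`
#' (single-threaded layout).
#'
#' @param coords cells x k matrix or `pca_embedding`.
#' @param n_dims leading dimensions to use.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed RNG seed.
#' @return cells x 2 coordinate matrix.
#' @export
embed_umap <- function(coords, n_dims = NULL, n_neighbors = 30,
                       min_dist = 0.3, seed = 42L) {
  if (inherits(coords, "pca_embedding")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (!is.null(n_dims)) coords <- coords[, seq_len(min(n_dims, ncol(coords))), drop = FALSE]
  k <- max(2L, min(n_neighbors, nrow(coords) - 1L))
  init <- if (nrow(coords) < 20) "random" else "spectral"
  emb <- with_seed(seed,
    uwot::umap(coords, n_neighbors = k, min_dist = min_dist, init = init,
               n_threads = 1, n_sgd_threads = 1, verbose = FALSE))
  rownames(emb) <- rownames(coords)
  emb
}

#' Merge per-sample count matrices
#'
#' Columns are concatenated over the union of gene identifiers (absent genes
#' fill with zeros); barcodes are prefixed with the sample id so they stay
#' unique. Layers present in every sample are merged congruently. The merged
#' object is typically re-log-normalized afterwards.
#'
#' @param mats list of [count_matrix()] objects.
#' @param merged_id sample id of the merged object.
#' @return a [count_matrix()].
#' @export
merge_count_matrices <- function(mats, merged_id = "merged") {
  stopifnot(length(mats) >= 1)
  ids <- Reduce(union, lapply(mats, function(m) m$gene_ids))
  sym <- character(length(ids)); names(sym) <- ids
  for (m in mats) sym[m$gene_ids[!nzchar(sym[m$gene_ids])]] <-
      m$gene_symbols[!nzchar(sym[m$gene_ids])]
  layer_names <- Reduce(intersect, lapply(mats, function(m) names(m$layers)))
  expand <- function(x, gene_ids) {
    idx <- match(gene_ids, ids)
    tm <- methods::as(x, "TsparseMatrix")
    Matrix::sparseMatrix(i = idx[tm@i + 1L], j = tm@j + 1L, x = tm@x,
                         dims = c(length(ids), ncol(x)))
  }
  counts <- do.call(cbind, lapply(mats, function(m) expand(m$counts, m$gene_ids)))
  layers <- list()
  for (nm in layer_names)
    layers[[nm]] <- do.call(cbind, lapply(mats, function(m)
      expand(m$layers[[nm]], m$gene_ids)))
  barcodes <- unlist(lapply(mats, function(m)
    paste(m$sample_id, m$cell_barcodes, sep = "_")))
  count_matrix(counts, ids, unname(sym), barcodes, merged_id, layers)
}
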