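# Steady-state RNA velocity from spliced/unspliced layers, projection of
# predicted future states into PC space, and the transition-distance (td)
# statistic with per-sample median and IQR. The module works on linearly
# size-normalized layers (one shared per-cell factor from the spliced
# totals), so the fitted slope is the kinetic ratio gamma and the PCA
# projection of a velocity displacement is an exact matrix product.

#' Size-normalize spliced/unspliced layers with a shared per-cell factor
#'
#' Both layers are scaled by the same factor (median spliced total / cell
#' spliced total), preserving the per-cell unspliced-to-spliced ratio that
#' the steady-state model interprets.
#'
#' @param mat a [count_matrix()] carrying `spliced` and `unspliced` layers.
#' @return list with dense genes x cells matrices `spliced`, `unspliced`.
#' @export
normalize_layers <- function(mat) {
  if (!all(c("spliced", "unspliced") %in% names(mat$layers)))
    stop("configuration error: velocity requires spliced/unspliced layers")
  s <- mat$layers$spliced
  u <- mat$layers$unspliced
  totals <- Matrix::colSums(s)
  f <- ifelse(totals > 0, median(totals[totals > 0]) / totals, 0)
  D <- Matrix::Diagonal(x = f)
  out <- list(spliced = as.matrix(s %*% D), unspliced = as.matrix(u %*% D))
  dimnames(out$spliced) <- dimnames(out$unspliced) <-
    list(mat$gene_symbols, mat$cell_barcodes)
  out
}

#' Fit per-gene degradation/splicing ratios (gamma)
#'
#' Under first-order splicing kinetics a gene at steady state satisfies
#' u = gamma * s; gamma is estimated as the slope of a zero-intercept fit of
#' unspliced on spliced restricted to cells in the extreme (top and bottom
#' `extreme_quantile`) of the gene's spliced expression, where the
#' steady-state assumption is most informative. Genes expressed in fewer
#' than `min_cells_expressing` cells are flagged unused.
#'
#' @param spliced,unspliced genes x cells matrices (see [normalize_layers()]).
#' @param extreme_quantile fraction at each extreme used for the fit.
#' @param min_cells_expressing minimum expressing cells for a usable fit.
#' @return object of class `velocity_model`: data.frame (gene, gamma, used,
#'   n_expressing) plus the fit quantile.
#' @export
fit_gamma <- function(spliced, unspliced, extreme_quantile = 0.05,
                      min_cells_expressing = 20) {
  stopifnot(identical(dim(spliced), dim(unspliced)))
  ng <- nrow(spliced)
  gamma <- numeric(ng)
  n_expr <- integer(ng)
  for (g in seq_len(ng)) {
    s <- spliced[g, ]; u <- unspliced[g, ]
    n_expr[g] <- sum(s > 0 | u > 0)
    qs <- quantile(s, c(extreme_quantile, 1 - extreme_quantile), names = FALSE)
    sel <- s <= qs[1] | s >= qs[2]
    denom <- sum(s[sel]^2)
    gamma[g] <- if (denom > 0) sum(u[sel] * s[sel]) / denom else 0
  }
  structure(
    list(genes = data.frame(
           gene = rownames(spliced) %||% as.character(seq_len(ng)),
           gamma = gamma, used = n_expr >= min_cells_expressing,
           n_expressing = n_expr, stringsAsFactors = FALSE),
         fit_quantile = extreme_quantile),
    class = "velocity_model")
}

#' @export
print.velocity_model <- function(x, ...) {
  cat(sprintf("<velocity_model> %d genes (%d used), fit quantile %.2f\n",
              nrow(x$genes), sum(x$genes$used), x$fit_quantile))
  invisible(x)
}

#' Per-cell, per-gene RNA velocity
#'
#' v = u - gamma * s on used genes, after pooling spliced and unspliced
#' signal over each cell's k nearest neighbours in PC space (the residual is
#' taken on the smoothed values). Unused genes get zero velocity.
#'
#' @param spliced,unspliced genes x cells matrices.
#' @param model a [fit_gamma()] result.
#' @param pc_coords optional cells x k PC coordinates for neighbour
#'   smoothing; `NULL` skips smoothing.
#' @param k neighbourhood size (default 30).
#' @return genes x cells velocity matrix.
#' @export
compute_velocity <- function(spliced, unspliced, model, pc_coords = NULL,
                             k = 30) {
  if (!is.null(pc_coords)) {
    n <- ncol(spliced)
    kk <- min(k, n)
    nn <- RANN::nn2(pc_coords, k = kk)$nn.idx
    W <- Matrix::sparseMatrix(i = as.vector(nn), j = rep(seq_len(n), kk),
                              x = 1 / kk, dims = c(n, n))
    spliced <- as.matrix(spliced %*% W)
    unspliced <- as.matrix(unspliced %*% W)
  }
  v <- unspliced - model$genes$gamma * spliced
  v[!model$genes$used, ] <- 0
  dimnames(v) <- dimnames(spliced)
  v
}

#' Project predicted future states into PC space
#'
#' The future expression state is current + velocity * dt, floored at zero
#' gene-wise, and both states are pushed through the PCA's centring/scaling
#' and loadings; the displacement is their coordinate difference. The
#' transform is linear (no cap is applied to the displacement), so the
#' projection is an explicit matrix product.
#'
#' @param pca a [run_pca()] embedding fitted on the same gene space.
#' @param current genes x cells expression on the PCA input scale.
#' @param velocity genes x cells velocity matrix.
#' @param dt time step in model units (default 1).
#' @return list: delta (cells x k displacement), current_coords,
#'   future_coords.
#' @export
project_future <- function(pca, current, velocity, dt = 1) {
  if (!inherits(pca, "pca_embedding"))
    stop("contract error: project_future requires a pca_embedding with loadings")
  genes <- pca$genes
  cur <- as.matrix(current[genes, , drop = FALSE])
  fut <- pmax(cur + dt * as.matrix(velocity[genes, , drop = FALSE]), 0)
  transform <- function(X)
    sweep(sweep(t(X), 2, pca$center), 2, pca$scale, "/") %*% pca$loadings
  cc <- transform(cur)
  fc <- transform(fut)
  list(delta = fc - cc, current_coords = cc, future_coords = fc)
}

#' Transition distances and per-sample dynamics summary
#'
#' td = sqrt(dPC1^2 + dPC2^2) per cell (the length of the velocity arrow in
#' the first two PCs). Within each sample td is normalized as
#' `(td - min(td)) / max(td)` (set `strict_minmax = TRUE` for the strict
#' `(td - min) / (max - min)` variant) and summarised by
#' the median and the inter-quartile range (75% quantile - 25% quantile,
#' linear-interpolation quantiles).
#'
#' @param delta_pc cells x >=2 displacement matrix (from [project_future()]).
#' @param sample per-cell sample labels (default: one sample).
#' @param normalize `"per_sample"` (each sample scaled by its own min/max)
#'   or `"cohort"` (one min/max across all cells,
#'   preserving cross-sample ordering of the raw distances).
#' @param strict_minmax use the strict min-max normalization variant.
#' @return list: cells (data.frame sample, td, td_normalized), summary
#'   (data.frame sample, median_td, iqr_td, n_cells).
#' @export
transition_distance <- function(delta_pc, sample = NULL,
                                normalize = c("per_sample", "cohort"),
                                strict_minmax = FALSE) {
  normalize <- match.arg(normalize)
  delta_pc <- as.matrix(delta_pc)
  stopifnot(ncol(delta_pc) >= 2)
  td <- sqrt(delta_pc[, 1]^2 + delta_pc[, 2]^2)
  sample <- sample %||% rep("sample", length(td))
  tdn <- numeric(length(td))
  groups <- if (normalize == "cohort") list(rep(TRUE, length(td)))
            else lapply(unique(sample), function(s) sample == s)
  for (i in groups) {
    mx <- max(td[i]); mn <- min(td[i])
    if (mx == 0) {
      warning("transition_distance: all cells static in a normalization group")
      tdn[i] <- 0
    } else {
      tdn[i] <- (td[i] - mn) / (if (strict_minmax) mx - mn else mx)
    }
  }
  cells <- data.frame(sample = sample, td = td, td_normalized = tdn,
                      stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(cells, cells$sample), function(d) {
    q <- quantile(d$td_normalized, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(sample = d$sample[1], median_td = q[2], iqr_td = q[3] - q[1],
               n_cells = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(cells = cells, summary = summ)
}

#' Velocity vector field on an embedding grid
#'
#' Each cell's embedding-space displacement is the correlation-weighted mean
#' direction toward its embedding neighbours (weights softmax of the Pearson
#' correlation between the cell's velocity vector and the expression
#' difference toward each neighbour, minus the uniform baseline); a regular
#' grid then aggregates cell displacements with a Gaussian kernel. Export is
#' for visualisation only.
#'
#' @param embedding cells x 2 coordinates (e.g. UMAP).
#' @param expression genes x cells matrix on the velocity scale.
#' @param velocity genes x cells velocity matrix.
#' @param grid grid resolution per axis (default 30).
#' @param k embedding neighbourhood size (default 30).
#' @param corr_sigma softmax temperature on correlations (default 0.05).
#' @return data.frame: x, y, dx, dy, n_cells (empty grid cells omitted).
#' @export
vector_field <- function(embedding, expression, velocity, grid = 30, k = 30,
                         corr_sigma = 0.05) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  kk <- min(k + 1L, n)
  nn <- RANN::nn2(embedding, k = kk)$nn.idx
  E <- as.matrix(expression)
  V <- as.matrix(velocity)
  disp <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    nbr <- setdiff(nn[i, ], i)
    if (!length(nbr)) next
    dirs <- embedding[nbr, , drop = FALSE] -
      matrix(embedding[i, ], length(nbr), 2, byrow = TRUE)
    len <- sqrt(rowSums(dirs^2))
    ok <- len > 0
    if (!any(ok)) next
    dirs <- dirs[ok, , drop = FALSE] / len[ok]
    nbr <- nbr[ok]
    v <- V[, i]
    if (sd(v) == 0) { cc <- rep(0, length(nbr)) } else {
      D <- E[, nbr, drop = FALSE] - E[, i]
      cc <- suppressWarnings(as.vector(cor(v, D)))
      cc[is.na(cc)] <- 0
    }
    w <- exp(cc / corr_sigma)
    w <- w / sum(w)
    disp[i, ] <- colSums(dirs * w) - colMeans(dirs)
  }
  gx <- seq(min(embedding[, 1]), max(embedding[, 1]), length.out = grid)
  gy <- seq(min(embedding[, 2]), max(embedding[, 2]), length.out = grid)
  sigma <- max(diff(gx)[1], diff(gy)[1], 1e-9)
  out <- list()
  for (ix in seq_along(gx)) for (iy in seq_along(gy)) {
    d2 <- (embedding[, 1] - gx[ix])^2 + (embedding[, 2] - gy[iy])^2
    sel <- d2 < (2 * sigma)^2
    if (!any(sel)) next
    w <- exp(-d2[sel] / (2 * sigma^2))
    w <- w / sum(w)
    out[[length(out) + 1L]] <- data.frame(
      x = gx[ix], y = gy[iy],
      dx = sum(disp[sel, 1] * w), dy = sum(disp[sel, 2] * w),
      n_cells = sum(sel))
  }
  do.call(rbind, out)
}
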