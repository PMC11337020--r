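test_that("log-normalization matches a dense oracle and handles zero-count cells", {
  set.seed(1)
  counts <- matrix(rpois(600, 2), 30, 20)
  counts[, 3] <- 0
  m <- make_matrix(counts)
  norm <- log_normalize(m)
  oracle <- apply(counts, 2, function(x) {
    t <- sum(x)
    if (t == 0) rep(0, length(x)) else log1p(x / t * 1e4)
  })
  expect_equal(as.matrix(norm), oracle, ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(as.matrix(norm)[, 3] == 0))
  expect_equal(as.matrix(norm)[counts == 0], rep(0, sum(counts == 0)))
  # cell at exactly the scale factor total: count 10 -> ln(11)
  counts2 <- matrix(0, 2, 1); counts2[1, 1] <- 10; counts2[2, 1] <- 9990
  expect_equal(as.matrix(log_normalize(make_matrix(counts2)))[1, 1], log(11))
})

test_that("module scores are bin-controlled, seeded, and separate planted cycling cells", {
  set.seed(2)
  counts <- matrix(rpois(200 * 50, 3), 200, 50)
  m <- make_matrix(counts)
  norm <- log_normalize(m)
  zero_set <- rownames(norm)[1:5]
  normz <- norm; normz[1:5, ] <- 0
  expect_true(all(score_gene_module(normz, zero_set, seed = 1) <= 0))
  s1 <- score_gene_module(norm, rownames(norm)[6:10], seed = 3)
  s2 <- score_gene_module(norm, rownames(norm)[6:10], seed = 3)
  expect_identical(s1, s2)
  expect_error(score_gene_module(norm, "ABSENT"), "configuration error")

  co <- small_cohort()
  sid <- "P1"
  truth <- co$truth$cells[co$truth$cells$sample == sid, ]
  nrm <- log_normalize(co$samples[[sid]]$matrix)
  s_score <- score_gene_module(nrm, default_gene_list("s"), seed = 1)
  s_cells <- s_score[truth$cycling == "S"]
  rest <- s_score[truth$cycling == "none"]
  pairs <- outer(s_cells, rest, ">")
  expect_gte(mean(pairs), 0.95)
})

test_that("covariate regression equals the normal-equations oracle and degrades gracefully", {
  set.seed(3)
  Y <- matrix(rnorm(40 * 15, 5), 40, 15)  # genes x cells
  rownames(Y) <- sprintf("G%02d", 1:40)
  cov <- data.frame(a = rnorm(15), b = runif(15))
  out <- regress_covariates(Y, cov)
  X <- cbind(1, as.matrix(cov))
  beta <- solve(crossprod(X)) %*% t(X) %*% t(Y)     # normal equations
  resid <- t(t(Y) - X %*% beta)                     # genes x cells
  oracle <- resid + beta[1, ]                       # intercept added back
  expect_equal(unname(out), unname(oracle), tolerance = 1e-8)
  # identically-zero covariate: output equals input (column dropped)
  expect_warning(out0 <- regress_covariates(Y, data.frame(z = rep(0, 15))),
                 "collinear")
  expect_equal(out0, Y, tolerance = 1e-10)
  # gene exactly linear in the covariate: residual variance ~ 0
  cov1 <- data.frame(s = rnorm(15))
  Y1 <- Y; Y1[1, ] <- 2 + 3 * cov1$s
  r1 <- regress_covariates(Y1, cov1)
  expect_lt(var(r1[1, ]), 1e-20)
})

test_that("HVG selection is trend-corrected, excludes constants, and finds planted dispersion", {
  set.seed(4)
  n_cells <- 200
  # background genes follow a smooth mean-variance trend over a wide
  # abundance range; planted genes sit on the trend's mean axis but with
  # bimodal (high-dispersion) expression
  mu_bg <- runif(500, 0.5, 8)
  norm <- matrix(abs(rnorm(500 * n_cells, mean = mu_bg,
                           sd = 0.2 * sqrt(mu_bg))), 500, n_cells)
  rownames(norm) <- sprintf("G%03d", 1:500)
  colnames(norm) <- sprintf("BC%04d", 1:n_cells)
  norm[1:10, ] <- 2                      # constant genes
  hot <- 11:60                           # bimodal, high-dispersion genes
  norm[hot, ] <- abs(rnorm(50 * n_cells, mean = 2, sd = 0.3))
  on_cells <- sample(n_cells, n_cells / 2)
  norm[hot, on_cells] <- norm[hot, on_cells] + 4
  hvg <- select_hvg(norm, 100)
  expect_false(any(rownames(norm)[1:10] %in% hvg))
  expect_true(all(rownames(norm)[hot] %in% hvg))
  expect_warning(all_g <- select_hvg(norm, 1e5), "only")
  expect_false(any(rownames(norm)[1:10] %in% all_g))
})

test_that("PCA explains all variance of a low-rank fixture and the elbow rule clamps to 15-25", {
  set.seed(5)
  r <- 3
  X <- matrix(rnorm(20 * r), 20, r) %*% matrix(rnorm(r * 100), r, 100)
  X <- X + 5
  rownames(X) <- sprintf("G%02d", 1:20)
  pca <- run_pca(X, n_pcs_max = 10, scale_cap = 1e6)
  expect_gte(sum(pca$var_per_dim[1:r]) / sum(pca$var_per_dim), 1 - 1e-8)
  # constructed spectra for the elbow rule
  knee17 <- c(seq(100, 40, length.out = 16), rep(2, 24))   # sharp knee at 17
  expect_equal(choose_n_pcs(c(knee17)), 17L)
  expect_equal(choose_n_pcs(50 * 0.9^(1:40)), 15L)          # featureless -> clamp low
  knee40 <- c(seq(400, 50, length.out = 39), rep(0.5, 11))  # knee at 40 -> clamp 25
  expect_equal(choose_n_pcs(knee40), 25L)
})

test_that("SNN-Louvain separates well-separated blobs and degenerates to one cluster", {
  set.seed(6)
  blob <- rbind(matrix(rnorm(60 * 5), 60, 5),
                matrix(rnorm(60 * 5, mean = 30), 60, 5))
  cl <- cluster_snn_louvain(blob, n_neighbors = 15, seed = 1)
  expect_equal(cl$n_clusters, 2L)
  agreement <- max(mean(cl$labels[1:60] == cl$labels[1]) *
                     mean(cl$labels[61:120] == cl$labels[61]))
  expect_gte(agreement, 0.99)
  expect_true(cl$labels[1] != cl$labels[61])
  same <- matrix(1, 50, 3)
  cl1 <- cluster_snn_louvain(same, seed = 1)
  expect_equal(cl1$n_clusters, 1L)
  expect_warning(cluster_snn_louvain(matrix(0, 2, 2)), "too few")
})

test_that("UMAP is finite, seeded-deterministic, and separates blobs", {
  set.seed(7)
  tri <- matrix(rnorm(9), 3, 3)
  e3 <- embed_umap(tri, seed = 5)
  expect_true(all(is.finite(e3)))
  expect_equal(dim(e3), c(3L, 2L))
  blob <- rbind(matrix(rnorm(40 * 5), 40, 5),
                matrix(rnorm(40 * 5, mean = 25), 40, 5))
  u1 <- embed_umap(blob, seed = 9)
  u2 <- embed_umap(blob, seed = 9)
  expect_identical(u1, u2)
  d <- as.matrix(dist(u1))
  intra <- mean(d[1:40, 1:40])
  inter <- mean(d[1:40, 41:80])
  expect_gt(inter, intra)
})

test_that("merging concatenates cells over the gene union and keeps per-sample identity", {
  co <- small_cohort()
  mats <- lapply(co$samples, function(s) s$matrix)
  merged <- merge_count_matrices(mats)
  expect_equal(ncol(merged$counts), sum(vapply(mats, function(m) ncol(m$counts), 0)))
  expect_equal(merged$gene_ids, mats[[1]]$gene_ids)
  bc <- paste("P2", mats[["P2"]]$cell_barcodes[5], sep = "_")
  expect_equal(as.numeric(merged$counts[, bc]),
               as.numeric(mats[["P2"]]$counts[, 5]))
  expect_equal(names(merged$layers), c("spliced", "unspliced"))
})

test_that("malignant cells cluster by patient while reactive cells co-cluster", {
  res <- preset_run()
  labels <- res$labels
  cl <- res$clusters$labels
  maj <- function(idx) as.integer(names(which.max(table(cl[idx]))))
  mal_major <- vapply(unique(labels$sample), function(sid)
    maj(which(labels$sample == sid & labels$label == "malignant")), 0L)
  expect_equal(length(unique(mal_major)), length(mal_major))
  reac_major <- vapply(unique(labels$sample), function(sid)
    maj(which(labels$sample == sid & labels$label == "reactive")), 0L)
  expect_equal(length(unique(reac_major)), 1L)
  # and the malignant majority clusters differ from the shared reactive one
  expect_false(any(mal_major == reac_major[1]))
})
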