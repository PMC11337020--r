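test_that("gamma fitting matches exact-line and degenerate cases and recovers 0.7 at n=500", {
  n <- 500
  set.seed(30)
  s <- matrix(rnbinom(3 * n, mu = 3, size = 2), 3, n)
  u <- rbind(2 * s[1, ],                                    # u = 2s exactly
             rep(0, n),                                     # u == 0
             rnbinom(n, mu = 0.7 * s[3, ], size = 5))       # gamma_true 0.7
  rownames(s) <- rownames(u) <- c("exact", "zero", "steady")
  model <- fit_gamma(s, u)
  expect_equal(model$genes$gamma[1], 2)
  expect_equal(model$genes$gamma[2], 0)
  expect_true(all(model$genes$used))
  expect_lt(abs(model$genes$gamma[3] - 0.7), 0.1)
  # genes below the expressing-cell minimum are flagged unused
  s2 <- s; s2[2, ] <- 0
  m2 <- fit_gamma(s2, u * 0)
  expect_false(m2$genes$used[2])
  # missing layers are a configuration error
  co <- small_cohort()
  m <- co$samples[[1]]$matrix
  m$layers$unspliced <- NULL
  expect_error(normalize_layers(m), "configuration error")
})

test_that("velocity obeys the sign law around the steady-state line", {
  s_fit <- matrix(1:40, 1)
  model <- fit_gamma(s_fit, 2 * s_fit, min_cells_expressing = 1)  # gamma = 2
  s <- matrix(c(4, 4, 4), 1, 3)
  u <- matrix(c(8, 12, 2), 1, 3)     # on-line, induced, repressed
  v <- compute_velocity(s, u, model)
  expect_equal(v[1, 1], 0)
  expect_gt(v[1, 2], 0)
  expect_lt(v[1, 3], 0)
})

test_that("future-state projection is an exact linear map of the displacement", {
  set.seed(31)
  X <- matrix(rnorm(30 * 50, mean = 10, sd = 2), 30, 50)
  rownames(X) <- sprintf("G%02d", 1:30)
  colnames(X) <- sprintf("BC%04d", 1:50)
  pca <- run_pca(X, n_pcs_max = 5, scale_cap = 1e6)
  v <- matrix(rnorm(30 * 50, sd = 0.1), 30, 50, dimnames = dimnames(X))
  proj <- project_future(pca, X, v, dt = 1)
  # dense oracle: explicit centring/scaling and matrix product
  tr <- function(M) sweep(sweep(t(M), 2, pca$center), 2, pca$scale, "/") %*%
    pca$loadings
  fut <- pmax(X + v, 0)
  expect_equal(proj$delta, tr(fut) - tr(X), tolerance = 1e-10)
  # zero velocity -> zero displacement
  p0 <- project_future(pca, X, v * 0)
  expect_true(all(abs(p0$delta) < 1e-12))
  # velocity aligned with the PC1 loading vector leaves PC2 untouched
  v1 <- matrix(pca$loadings[, 1] * pca$scale, 30, 50,
               dimnames = dimnames(X)) * 0.01
  p1 <- project_future(pca, X, v1)
  expect_lt(max(abs(p1$delta[, 2])), max(abs(p1$delta[, 1])) * 1e-8)
  expect_error(project_future(list(), X, v), "contract error")
})

test_that("transition distances follow Euclidean geometry and the quantile oracle", {
  td1 <- transition_distance(cbind(3, 4))
  expect_identical(td1$cells$td, 5)
  # constant td: normalized constant, IQR exactly 0
  tdc <- transition_distance(matrix(c(1, 1, 1, 0, 0, 0), 3, 2))
  expect_equal(tdc$summary$iqr_td, 0)
  expect_equal(length(unique(tdc$cells$td_normalized)), 1L)
  # sort-based quantile oracle on 1,000 random cells
  set.seed(32)
  d <- matrix(rnorm(2000), 1000, 2)
  res <- transition_distance(d)
  td <- sqrt(d[, 1]^2 + d[, 2]^2)
  tdn <- (td - min(td)) / max(td)
  expect_equal(res$summary$median_td, sorted_quantile(tdn, 0.5),
               tolerance = 1e-12)
  expect_equal(res$summary$iqr_td,
               sorted_quantile(tdn, 0.75) - sorted_quantile(tdn, 0.25),
               tolerance = 1e-12)
  # invariance under joint rotation of current and future coordinates
  theta <- 0.83
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  res_rot <- transition_distance(d %*% R)
  expect_equal(res_rot$cells$td, res$cells$td, tolerance = 1e-10)
  # all-static sample: td_normalized defined as zero with a warning
  expect_warning(tds <- transition_distance(matrix(0, 4, 2)), "static")
  expect_true(all(tds$cells$td_normalized == 0))
  # strict min-max variant reaches exactly [0, 1]
  strict <- transition_distance(d, strict_minmax = TRUE)
  expect_equal(range(strict$cells$td_normalized), c(0, 1))
})

test_that("per-sample summaries normalize within or across samples as requested", {
  set.seed(33)
  d <- rbind(matrix(rnorm(200, sd = 1), 100, 2),
             matrix(rnorm(200, sd = 10), 100, 2))
  smp <- rep(c("a", "b"), each = 100)
  per <- transition_distance(d, smp)
  coh <- transition_distance(d, smp, normalize = "cohort")
  # per-sample normalization erases the scale difference; cohort keeps it
  expect_lt(abs(per$summary$median_td[1] - per$summary$median_td[2]), 0.3)
  expect_gt(coh$summary$median_td[2], coh$summary$median_td[1] * 3)
})

test_that("the vector field is silent without velocity and coherent under a constructed flow", {
  set.seed(34)
  n <- 120
  emb <- cbind(seq(0, 10, length.out = n), rnorm(n, sd = 0.05))
  expr <- rbind(seq(0, 10, length.out = n), matrix(rnorm(4 * n, sd = 0.05), 4, n))
  rownames(expr) <- sprintf("G%d", 1:5)
  # all cells move "rightward": velocity along gene 1
  vel <- rbind(rep(1, n), matrix(0, 4, n))
  field <- vector_field(emb, expr, vel, grid = 8, k = 15)
  expect_true(nrow(field) > 0)
  # arrows agree in direction: mean pairwise cosine of (dx, dy) > 0.9
  keep <- sqrt(field$dx^2 + field$dy^2) > 1e-8
  vv <- cbind(field$dx, field$dy)[keep, , drop = FALSE]
  vv <- vv / sqrt(rowSums(vv^2))
  cosines <- tcrossprod(vv)
  expect_gt(mean(cosines[upper.tri(cosines)]), 0.9)
  # interior arrows point in +x, the direction of the constructed flow
  interior <- keep & field$x > 2 & field$x < 8
  expect_true(all(field$dx[interior] > 0))
  # zero velocities -> zero arrows
  f0 <- vector_field(emb, expr, vel * 0, grid = 8, k = 15)
  expect_lt(max(abs(c(f0$dx, f0$dy))), 1e-12)
  # far-apart blobs leave empty grid cells with no arrow emitted
  emb2 <- rbind(matrix(rnorm(40, sd = 0.1), 20, 2),
                matrix(rnorm(40, 100, sd = 0.1), 20, 2))
  f2 <- vector_field(emb2, expr[, 1:40], vel[, 1:40], grid = 10, k = 5)
  expect_lt(nrow(f2), 100)
})

test_that("velocity recovers the planted dynamics of induced and repressed genes", {
  # a minority of cells is mid-transition: the steady-state estimator is
  # premised on the expression extremes being dominated by steady cells
  gen <- function(regime, seed) generate_cohort(cohort_config(
    seed = seed, n_patients = 1, n_cells = 550, malignant_fraction = 0.85,
    n_subpops = 1, dynamics_regime = regime, dynamic_cell_fraction = 0.25,
    nonproductive_patient = NA))
  # sign recovery is judged on cell-level velocities aggregated over the
  # transitioning population; population averaging is the noise control here
  # (neighbour pooling cannot help when the embedding does not resolve the
  # kinetic state, and the embedding is not given truth labels)
  run_velocity <- function(co) {
    truth <- co$truth$cells
    mat <- subset_cells(co$samples[[1]]$matrix,
                        truth$barcode[truth$is_malignant])
    nl <- normalize_layers(mat)
    model <- fit_gamma(nl$spliced, nl$unspliced)
    v <- compute_velocity(nl$spliced, nl$unspliced, model)
    list(co = co, truth = truth, model = model, v = v,
         dyn_cells = match(truth$barcode[truth$is_malignant & truth$dynamic_cell],
                           mat$cell_barcodes))
  }
  ind <- fixture("vel_induction", function() run_velocity(gen("induction", 41L)))
  rep_ <- fixture("vel_repression", function() run_velocity(gen("repression", 42L)))
  dyn_genes <- ind$co$config$plan$dynamic_genes
  sign_ok <- function(run, want_pos) {
    mv <- rowMeans(run$v[dyn_genes, run$dyn_cells, drop = FALSE])
    used <- run$model$genes$used[match(dyn_genes, run$model$genes$gene)]
    mean(if (want_pos) mv[used] > 0 else mv[used] < 0)
  }
  expect_gte(sign_ok(ind, TRUE), 0.9)
  expect_gte(sign_ok(rep_, FALSE), 0.9)
})
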