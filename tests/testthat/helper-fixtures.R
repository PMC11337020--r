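# Shared fixtures (memoised so expensive cohorts are generated once per run)
# and independent oracles used across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

# small 3-patient cohort for pipeline-level tests
small_cohort <- function() fixture("small_cohort", function() {
  generate_cohort(cohort_config(
    seed = 7L, n_patients = 3, n_cells = 160,
    malignant_fraction = c(0.5, 0.6, 0.7), n_subpops = 1,
    dynamics_regime = c("steady", "induction", "steady"),
    nonproductive_patient = 3))
})

small_run <- function() fixture("small_run", function() {
  suppressWarnings(run_pipeline(small_cohort()))
})

# the preset cohort + one full pipeline run (shared by several tests)
preset_cohort <- function() fixture("preset_cohort", function() {
  emulate_lesion_cohort(11L)
})

preset_run <- function() fixture("preset_run", function() {
  suppressWarnings(run_pipeline(preset_cohort()))
})

# hand-built count matrix: counts is genes x cells (dense ok)
make_matrix <- function(counts, symbols = NULL, sample_id = "S1",
                        layers = list()) {
  ng <- nrow(counts)
  symbols <- symbols %||% sprintf("G%03d", seq_len(ng))
  count_matrix(Matrix::Matrix(counts, sparse = TRUE),
               gene_ids = paste0("ID", seq_len(ng)), gene_symbols = symbols,
               cell_barcodes = sprintf("BC%04d", seq_len(ncol(counts))),
               sample_id = sample_id, layers = layers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact two-sided rank-sum p by enumeration of all labelings
exact_rank_sum_p <- function(xa, xb) {
  vals <- c(xa, xb)
  na <- length(xa)
  r <- rank(vals)
  mu <- na * length(xb) / 2
  off <- na * (na + 1) / 2
  u_obs <- sum(r[seq_len(na)]) - off
  combs <- utils::combn(length(vals), na)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - off)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# type-7 quantile by explicit sort + linear interpolation
sorted_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

# brute-force per-cell re-evaluation of the four QC gates from raw counts
brute_force_qc <- function(mat, hk_genes, mito_prefix = "MT-") {
  counts <- as.matrix(mat$counts)
  sym <- mat$gene_symbols
  vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    tot <- sum(x)
    mito <- if (tot > 0) sum(x[startsWith(sym, mito_prefix)]) / tot else 0
    genes <- sum(x > 0)
    hk <- sum(x[sym %in% hk_genes] > 0)
    (mito < 0.12) && (tot > 500) && (genes > 200) && (hk > 40)
  }, logical(1))
}
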