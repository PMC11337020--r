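pos_table <- function(genes, chrom, start) {
  data.frame(gene = genes, chrom = chrom, start = start,
             end = start + 10, strand = "+", stringsAsFactors = FALSE)
}

test_that("genomic ordering sorts by chromosome rank then start and drops unplaced genes", {
  pos <- pos_table(c("g2", "g1", "g3", paste0("x", 1:12)),
                   c("chr2", "chr1", "chr1", rep(c("1", "2"), 6)),
                   c(100, 500, 200, seq(1000, 12000, 1000)))
  ord <- suppressMessages(order_genes(c("g1", "g2", "g3", paste0("x", 1:12), "nowhere"), pos))
  expect_equal(ord$genes[1:2], c("g3", "g1"))     # chr1: start 200 < 500
  expect_equal(ord$n_unplaced, 1L)
  expect_equal(ord$boundaries$chrom, c("1", "2"))
  # order is invariant to the input order of the gene list
  set.seed(20)
  ord2 <- suppressMessages(order_genes(sample(c("g1", "g2", "g3", paste0("x", 1:12))), pos))
  expect_equal(ord2$genes, ord$genes)
  # chromosomes below the retention minimum are dropped
  pos_small <- pos_table(c("a1", "a2", "a3", "a4", "a5", "lone"),
                         c(rep("1", 5), "2"), 1:6 * 10)
  ord3 <- order_genes(c(paste0("a", 1:5), "lone"), pos_small)
  expect_false("lone" %in% ord3$genes)
  expect_error(order_genes("q", pos), "configuration error")
})

test_that("reference-matched cells score near zero; planted gains/losses show as signed blocks", {
  # two chromosomes of 60 genes; 30-gene 1.5x gain on chr1, 0.5x loss on chr2
  set.seed(21)
  ng <- 120; n_ref <- 60; n_mal <- 60
  base <- rlnorm(ng, log(3), 0.3)
  mu <- cbind(matrix(base, ng, n_ref),
              matrix(base, ng, n_mal))
  gain <- 16:45; loss <- 76:105
  mu[gain, n_ref + 1:n_mal] <- mu[gain, n_ref + 1:n_mal] * 1.5
  mu[loss, n_ref + 1:n_mal] <- mu[loss, n_ref + 1:n_mal] * 0.5
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 2), ng)
  m <- make_matrix(counts)
  norm <- log_normalize(m)
  pos <- pos_table(rownames(norm), rep(c("1", "2"), each = 60),
                   rep(1:60 * 100, 2))
  ord <- order_genes(rownames(norm), pos)
  ref <- colnames(norm)[1:n_ref]
  cnv <- cnv_scores(norm, ord, ref, window = 31)
  mal <- colnames(norm)[n_ref + 1:n_mal]
  prof <- clone_cnv_profile(cnv, list(mal = mal, ref = ref))
  blocks <- sliding_block_scores(prof[, "mal"], cnv$boundaries, 30)
  top_gain <- blocks[which.max(blocks$score), ]
  top_loss <- blocks[which.min(blocks$score), ]
  expect_equal(top_gain$chrom, "1")
  expect_gt(top_gain$score, 0)
  expect_true(top_gain$start_idx <= 45 && top_gain$end_idx >= 16)
  expect_equal(top_loss$chrom, "2")
  expect_lt(top_loss$score, 0)
  # reference profile stays inside the detection envelope everywhere
  ref_blocks <- sliding_block_scores(prof[, "ref"], cnv$boundaries, 30)
  expect_lt(max(abs(ref_blocks$score)),
            min(abs(c(top_gain$score, top_loss$score))) / 2)
  # gain block exceeds both the reference and its own flanking regions
  flank <- mean(prof[setdiff(1:60, gain), "mal"])
  expect_gt(mean(prof[gain, "mal"]), flank)
})

test_that("scores are shift-equivariant before median centring and invariant after", {
  set.seed(22)
  counts <- matrix(rnbinom(80 * 40, mu = 4, size = 2), 80, 40)
  m <- make_matrix(counts)
  norm <- as.matrix(log_normalize(m))
  pos <- pos_table(rownames(norm), rep(c("1", "2"), each = 40), rep(1:40, 2))
  ord <- order_genes(rownames(norm), pos)
  ref <- colnames(norm)[1:20]
  c1 <- cnv_scores(norm, ord, ref, window = 11)
  shifted <- norm
  shifted[, 30] <- shifted[, 30] + 0.7          # constant shift of one query cell
  c2 <- cnv_scores(shifted, ord, ref, window = 11)
  expect_equal(c2$scores[, 30], c1$scores[, 30], tolerance = 1e-10)
  expect_equal(c2$scores[, -30], c1$scores[, -30], tolerance = 1e-12)
})

test_that("smoothing never crosses chromosome boundaries", {
  # an impulse at the end of chr1 must not bleed into chr2 scores
  ng <- 40
  norm <- matrix(1, ng, 30)
  rownames(norm) <- sprintf("G%03d", 1:ng)
  colnames(norm) <- sprintf("BC%04d", 1:30)
  pos <- pos_table(rownames(norm), rep(c("1", "2"), each = 20), rep(1:20, 2))
  ord <- order_genes(rownames(norm), pos)
  spike <- norm
  spike[20, 21:30] <- 11                       # last gene of chr1, query cells
  ref <- colnames(norm)[1:20]
  cs <- suppressWarnings(cnv_scores(spike, ord, ref, window = 9, clip_sd = 1e6))
  q <- 25                                       # a query cell column
  expect_true(all(cs$scores[21:40, q] == cs$scores[21, q]))  # chr2 flat
  expect_gt(cs$scores[20, q] - cs$scores[21, q], 0)          # chr1 end raised
})

test_that("per-clone profiles separate patients with disjoint planted blocks", {
  co <- fixture("cnv_cohort", function() generate_cohort(cohort_config(
    seed = 23L, n_patients = 2, n_cells = 250,
    malignant_fraction = c(0.6, 0.6), n_subpops = 1,
    cnv_gain_chrom = c("1", "7"), cnv_loss_chrom = c("6", "13"),
    dynamics_regime = "steady")))
  mats <- lapply(co$samples, function(s) s$matrix)
  merged <- merge_count_matrices(mats)
  norm <- log_normalize(merged)
  truth <- co$truth$cells
  bc <- paste(truth$sample, truth$barcode, sep = "_")
  ref <- bc[truth$is_t & !truth$is_malignant]
  ord <- suppressMessages(order_genes(rownames(norm), co$gene_positions))
  cnv <- suppressWarnings(cnv_scores(norm, ord, ref, window = 51))
  groups <- list(P1 = bc[truth$sample == "P1" & truth$is_malignant],
                 P2 = bc[truth$sample == "P2" & truth$is_malignant])
  prof <- clone_cnv_profile(cnv, groups)
  # cross-patient profile correlation below within-patient cell-to-profile
  cells_p1 <- cnv$scores[, groups$P1]
  within <- mean(cor(cells_p1, prof[, "P1"]))
  between <- cor(prof[, "P1"], prof[, "P2"])
  expect_gt(within, between)
})

test_that("CNV-based 2-means recovers planted subclonal gains", {
  # one patient, two malignant subclones distinguished by a private gain:
  # construct directly by giving half the malignant cells an extra block
  set.seed(24)
  ng <- 120
  base <- rlnorm(ng, log(3), 0.2)
  n_ref <- 60; n_a <- 40; n_b <- 40
  mu <- matrix(base, ng, n_ref + n_a + n_b)
  mu[11:40, n_ref + seq_len(n_a)] <- mu[11:40, n_ref + seq_len(n_a)] * 1.6
  mu[71:100, n_ref + n_a + seq_len(n_b)] <-
    mu[71:100, n_ref + n_a + seq_len(n_b)] * 1.6
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 2), ng)
  m <- make_matrix(counts)
  norm <- log_normalize(m)
  pos <- pos_table(rownames(norm), rep(c("1", "2"), each = 60), rep(1:60, 2))
  ord <- order_genes(rownames(norm), pos)
  cnv <- cnv_scores(norm, ord, colnames(norm)[1:n_ref], window = 31)
  mal <- colnames(norm)[n_ref + 1:(n_a + n_b)]
  cl <- cnv_subclusters(cnv, mal, k = 2, seed = 1)
  truth <- rep(1:2, c(n_a, n_b))
  acc <- max(mean((cl == 1) == (truth == 1)), mean((cl == 2) == (truth == 1)))
  expect_gte(acc, 0.9)
})
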