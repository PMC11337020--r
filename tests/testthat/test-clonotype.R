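contig_rows <- function(barcode, chain, cdr3, umis, productive = TRUE,
                        is_cell = TRUE, high_confidence = TRUE) {
  data.frame(barcode = barcode, is_cell = is_cell,
             high_confidence = high_confidence, chain = chain,
             v_gene = "V", j_gene = "J", c_gene = "C", full_length = TRUE,
             productive = productive, cdr3_nt = cdr3, umis = umis,
             raw_clonotype_id = "c1", stringsAsFactors = FALSE)
}

test_that("cell clonotypes keep at most the top two contigs per chain by UMIs", {
  ct <- rbind(
    contig_rows("B1", "TRA", "AAA", 5), contig_rows("B1", "TRB", "CCC", 9),
    contig_rows("B2", "TRB", "GGG", 12), contig_rows("B2", "TRB", "TTT", 3),
    contig_rows("B3", "TRA", "AAA", 8), contig_rows("B3", "TRA", "CCC", 5),
    contig_rows("B3", "TRA", "GGG", 2),
    contig_rows("B4", "TRB", "AAA", 4, is_cell = FALSE),   # excluded
    contig_rows("B5", "other", "AAA", 4),                  # excluded
    contig_rows("B6", "TRB", NA, 4))                       # no CDR3
  cells <- build_cell_clonotypes(ct)
  expect_equal(cells$barcode, c("B1", "B2", "B3"))
  expect_equal(cells$clone_key[cells$barcode == "B1"], "TRA:AAA|TRB:CCC")
  b2 <- cells[cells$barcode == "B2", ]
  expect_equal(b2$clone_key, "TRB:GGG|TRB:TTT")   # both beta pairs retained
  expect_true(!b2$has_tra && b2$has_trb)
  # three TRA contigs: only the top 2 by UMIs survive (brute-force order)
  expect_equal(cells$clone_key[cells$barcode == "B3"], "TRA:AAA|TRA:CCC")
})

test_that("chain-subset cells merge into a unique compatible paired clone only", {
  ct <- rbind(
    contig_rows(sprintf("M%d", 1:3), "TRA", "AAA", 5),
    contig_rows(sprintf("M%d", 1:3), "TRB", "CCC", 5),
    contig_rows("SUB1", "TRB", "CCC", 4),            # unique -> merged
    contig_rows("AMB1", "TRB", "GGG", 4),            # in two paired clones
    contig_rows(c("X1", "X2"), "TRA", c("TTT", "TTA"), 5),
    contig_rows(c("X1", "X2"), "TRB", "GGG", 5))
  cells <- reconcile_chain_subsets(build_cell_clonotypes(ct))
  expect_equal(cells$clone_key[cells$barcode == "SUB1"], "TRA:AAA|TRB:CCC")
  expect_true(cells$merged[cells$barcode == "SUB1"])
  # ambiguous beta occurs in clones {TTT,GGG} and {TTA,GGG}: stays itself
  expect_equal(cells$clone_key[cells$barcode == "AMB1"], "TRB:GGG")
  expect_false(cells$merged[cells$barcode == "AMB1"])
  # reconciliation never changes a fully-paired cell
  full <- cells$has_tra & cells$has_trb
  expect_false(any(cells$merged[full]))
})

test_that("the dominant clone call follows counts, productivity and tie policy", {
  mk <- function(n, cdr3a, cdr3b, productive = TRUE, umis = 5, prefix = "B") {
    rbind(contig_rows(sprintf("%s%d", prefix, 1:n), "TRA", cdr3a, umis,
                      productive),
          contig_rows(sprintf("%s%d", prefix, 1:n), "TRB", cdr3b, umis,
                      productive))
  }
  # counts {A:60, B:5, C:1} -> A called, dominance ratio 12
  ct <- rbind(mk(60, "AAA", "TTT", prefix = "A"),
              mk(5, "CCC", "TTT2", prefix = "B"),
              mk(1, "GGG", "TTT3", prefix = "C"))
  ct$cdr3_nt <- sub("TTT2", "TTA", sub("TTT3", "TTG", ct$cdr3_nt))
  call <- call_malignant_clone(reconcile_chain_subsets(build_cell_clonotypes(ct)), "s1")
  expect_equal(call$malignant_clone_key, "TRA:AAA|TRB:TTT")
  expect_true(call$malignant_is_productive)
  expect_equal(call$dominance_ratio, 12)

  # dominant non-productive clone at 80%, largest productive at 2%
  ct2 <- rbind(mk(80, "AAA", "TTT", productive = FALSE, prefix = "N"),
               mk(2, "CCC", "TTA", prefix = "P"),
               do.call(rbind, lapply(1:18, function(i)
                 mk(1, paste0(strrep("A", i %% 3 + 1), "C"),
                    paste0(strrep("G", i %% 5 + 1), "C"), prefix = paste0("R", i)))))
  call2 <- call_malignant_clone(reconcile_chain_subsets(build_cell_clonotypes(ct2)), "s2")
  expect_equal(call2$malignant_clone_key, "TRA:AAA|TRB:TTT")
  expect_false(call2$malignant_is_productive)

  # exact tie: deterministic lexicographic winner plus a warning
  ct3 <- rbind(mk(10, "AAA", "TTT", prefix = "A"), mk(10, "CCC", "GGG", prefix = "B"))
  expect_warning(call3 <- call_malignant_clone(
    reconcile_chain_subsets(build_cell_clonotypes(ct3)), "s3"), "tie")
  expect_equal(call3$malignant_clone_key, "TRA:AAA|TRB:TTT")

  # no clonotypes at all
  expect_error(call_malignant_clone(build_cell_clonotypes(ct3[0, ]), "s4"),
               "no TCR information")
})

test_that("partition covers all T cells disjointly and computes the malignant fraction", {
  ct <- rbind(
    contig_rows(sprintf("M%d", 1:60), "TRA", "AAA", 5),
    contig_rows(sprintf("M%d", 1:60), "TRB", "TTT", 5),
    contig_rows(sprintf("R%d", 1:30), "TRA",
                sprintf("C%sG", strrep("A", 1:30 %% 7 + 1)), 5),
    contig_rows(sprintf("R%d", 1:30), "TRB",
                sprintf("G%sC", strrep("T", 1:30 %% 7 + 1)), 5))
  cells <- reconcile_chain_subsets(build_cell_clonotypes(ct))
  call <- call_malignant_clone(cells, "s")
  t_cells <- c(sprintf("M%d", 1:60), sprintf("R%d", 1:30), sprintf("U%d", 1:10))
  part <- partition_cells(t_cells, cells, call)
  expect_equal(unname(part$counts), c(60L, 30L, 10L))
  expect_equal(part$malignant_fraction, 60 / 90)
  expect_setequal(part$labels$label[part$labels$barcode %in% sprintf("U%d", 1:10)],
                  "unassigned")
  expect_equal(sum(part$counts), length(t_cells))
})

test_that("identical contig inputs give identical calls regardless of row order", {
  co <- small_cohort()
  ct <- co$samples[[1]]$contigs
  run <- function(tab) {
    cells <- reconcile_chain_subsets(build_cell_clonotypes(tab))
    call_malignant_clone(cells, "P1")
  }
  c1 <- run(ct)
  c2 <- run(ct[rev(seq_len(nrow(ct))), ])
  set.seed(99); c3 <- run(ct[sample(nrow(ct)), ])
  expect_equal(c1$malignant_clone_key, c2$malignant_clone_key)
  expect_equal(c1$clones, c3$clones)
})

test_that("the clone partition recovers generator truth, including alpha/beta-dropout cells", {
  co <- small_cohort()
  for (sid in names(co$samples)) {
    truth <- co$truth$cells[co$truth$cells$sample == sid, ]
    cells <- reconcile_chain_subsets(build_cell_clonotypes(co$samples[[sid]]$contigs))
    call <- call_malignant_clone(cells, sid)
    part <- partition_cells(truth$barcode[truth$is_t], cells, call)
    lab <- part$labels
    cmp <- merge(lab, truth, by = "barcode")
    with_tcr <- cmp[cmp$has_tcr, ]
    acc <- mean((with_tcr$label == "malignant") == with_tcr$is_malignant)
    expect_gte(acc, 0.99)
    expect_equal(part$malignant_fraction,
                 co$config$malignant_fraction[[as.integer(sub("P", "", sid))]],
                 tolerance = 0.05)
  }
  # the designated patient carries the non-productive clone
  cells3 <- reconcile_chain_subsets(build_cell_clonotypes(co$samples[["P3"]]$contigs))
  expect_false(call_malignant_clone(cells3, "P3")$malignant_is_productive)
})
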