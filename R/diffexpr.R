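# Wilcoxon rank-sum differential expression with the study gates
# (|lnFC| > 0.25, Bonferroni-adjusted p < 0.05), pooled and per patient,
# and the >=4-of-n recurrence signature across patients.

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Two-sided rank-sum test per gene on log-normalized (optionally
#' covariate-corrected) expression: the exact null distribution for small
#' untied samples (fewer than 50 values), otherwise the normal approximation
#' with tie and continuity correction (the regime every realistic single-cell
#' comparison falls into). The natural-log fold change uses the
#' back-transformed-mean convention
#' `ln((mean(exp(x_a)-1)+1) / (mean(exp(x_b)-1)+1))`. Only genes expressed
#' in at least `min_pct` of either group are tested, and the Bonferroni
#' denominator is the number of genes actually tested.
#'
#' @param norm genes x cells matrix.
#' @param cells_a,cells_b barcodes (or column indices) of the two groups;
#'   group a is the focal (malignant) group.
#' @param min_pct minimum expressing fraction in either group (default 0.10).
#' @param detection optional matrix used only for the expressing-fraction
#'   gate (defaults to `norm`); lets the test run on a covariate-corrected
#'   matrix while detection is judged on the uncorrected one.
#' @param min_cells minimum group size (default 3).
#' @param lnfc_gate,alpha significance gates (defaults 0.25 and 0.05).
#' @return data.frame per tested gene: gene, ln_fc, p_value, p_adjusted,
#'   pct_a, pct_b, significant.
#' @export
wilcoxon_de <- function(norm, cells_a, cells_b, min_pct = 0.10,
                        min_cells = 3, lnfc_gate = 0.25, alpha = 0.05,
                        detection = NULL) {
  col_idx <- function(cells) {
    if (is.character(cells)) {
      idx <- match(cells, colnames(norm))
      if (anyNA(idx)) stop("wilcoxon_de: unknown barcodes in group")
      idx
    } else as.integer(cells)
  }
  a <- col_idx(cells_a); b <- col_idx(cells_b)
  if (length(a) == 0 || length(b) == 0)
    stop("no reference cells: both groups must be non-empty")
  if (length(a) < min_cells || length(b) < min_cells)
    stop(sprintf("wilcoxon_de: groups must have >= %d cells (got %d and %d)",
                 min_cells, length(a), length(b)))
  Xa <- as.matrix(norm[, a, drop = FALSE])
  Xb <- as.matrix(norm[, b, drop = FALSE])
  det <- detection %||% norm
  pct_a <- rowMeans(as.matrix(det[, a, drop = FALSE]) > 0)
  pct_b <- rowMeans(as.matrix(det[, b, drop = FALSE]) > 0)
  tested <- which(pct_a >= min_pct | pct_b >= min_pct)
  na <- length(a); nb <- length(b); n <- na + nb
  mu <- na * nb / 2
  p <- ln_fc <- numeric(length(tested))
  for (k in seq_along(tested)) {
    g <- tested[k]
    vals <- c(Xa[g, ], Xb[g, ])
    r <- rank(vals)
    U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    ties <- table(vals)
    if (n < 50 && length(ties) == n) {
      # small untied sample: exact null distribution of the rank-sum
      p[k] <- if (U > mu) min(1, 2 * (1 - stats::pwilcox(U - 1, na, nb)))
              else min(1, 2 * stats::pwilcox(U, na, nb))
    } else {
      sigma2 <- (na * nb / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
      if (sigma2 <= 0) { p[k] <- 1 } else {
        z <- U - mu
        z <- z - sign(z) * 0.5        # continuity correction
        p[k] <- min(1, 2 * pnorm(-abs(z) / sqrt(sigma2)))
      }
    }
    ln_fc[k] <- log((mean(expm1(Xa[g, ])) + 1) / (mean(expm1(Xb[g, ])) + 1))
  }
  p_adj <- pmin(1, p * length(tested))
  res <- data.frame(
    gene = (rownames(norm) %||% as.character(seq_len(nrow(norm))))[tested],
    ln_fc = ln_fc, p_value = p, p_adjusted = p_adj,
    pct_a = pct_a[tested], pct_b = pct_b[tested],
    stringsAsFactors = FALSE)
  res$significant <- abs(res$ln_fc) > lnfc_gate & res$p_adjusted < alpha
  rownames(res) <- NULL
  res
}

#' Pooled malignant-vs-reactive differential expression
#'
#' Runs [wilcoxon_de()] on the merged cohort using the clone-partition
#' labels: malignant cells versus the pooled reactive infiltrate of all
#' patients (unassigned cells are excluded).
#'
#' @param norm merged genes x cells normalized matrix.
#' @param labels data.frame with columns barcode and label
#'   (malignant/reactive/unassigned); barcodes must match `colnames(norm)`.
#' @param ... passed to [wilcoxon_de()].
#' @return DE table as from [wilcoxon_de()].
#' @export
pooled_de <- function(norm, labels, ...) {
  wilcoxon_de(norm,
              labels$barcode[labels$label == "malignant"],
              labels$barcode[labels$label == "reactive"], ...)
}

#' Cross-patient recurrence signature
#'
#' Counts, per gene, the patients in which it is significantly regulated in
#' the stated direction (up in malignant by default), and flags members as
#' genes recurring in at least `min_patients` patients. Rows are ordered by
#' descending recurrence count, then gene name.
#'
#' @param per_patient_de named list of per-patient DE tables
#'   (each patient's malignant cells vs its own reactive infiltrate).
#' @param min_patients membership threshold (default 4).
#' @param direction `"up"` or `"down"` (in the malignant group).
#' @return data.frame: gene, n_patients_significant, n_up, n_down, member.
#' @export
recurrence_signature <- function(per_patient_de, min_patients = 4,
                                 direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(per_patient_de) < min_patients)
    warning("recurrence_signature: fewer DE tables than min_patients; ",
            "no gene can be a member")
  genes <- sort(unique(unlist(lapply(per_patient_de, `[[`, "gene"))))
  n_up <- n_down <- setNames(integer(length(genes)), genes)
  for (de in per_patient_de) {
    up <- de$gene[de$significant & de$ln_fc > 0]
    down <- de$gene[de$significant & de$ln_fc < 0]
    n_up[up] <- n_up[up] + 1L
    n_down[down] <- n_down[down] + 1L
  }
  n_dir <- if (direction == "up") n_up else n_down
  out <- data.frame(gene = genes,
                    n_patients_significant = as.integer(n_dir),
                    n_up = as.integer(n_up), n_down = as.integer(n_down),
                    member = n_dir >= min_patients,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_patients_significant, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Volcano-plot data export
#'
#' @param de a DE table from [wilcoxon_de()].
#' @return data.frame: gene, ln_fc, neg_log10_p_adjusted, significant.
#' @export
volcano_data <- function(de) {
  data.frame(gene = de$gene, ln_fc = de$ln_fc,
             neg_log10_p_adjusted = -log10(pmax(de$p_adjusted, 1e-300)),
             significant = de$significant, stringsAsFactors = FALSE)
}

#' Marker dot-plot summary (reporting view)
#'
#' Mean normalized expression and fraction of expressing cells for a set of
#' marker genes (e.g. exhaustion markers), per group of cells. No statistics
#' are computed.
#'
#' @param norm genes x cells matrix.
#' @param groups named list of barcode vectors (e.g. per-patient malignant
#'   cells).
#' @param genes marker genes to summarise.
#' @return data.frame: group, gene, mean_expression, pct_expressing.
#' @export
marker_dotplot_data <- function(norm, groups, genes) {
  genes <- intersect(genes, rownames(norm))
  if (!length(genes))
    stop("marker_dotplot_data: none of the requested genes are present")
  do.call(rbind, lapply(names(groups), function(gname) {
    X <- as.matrix(norm[genes, groups[[gname]], drop = FALSE])
    data.frame(group = gname, gene = genes,
               mean_expression = rowMeans(X),
               pct_expressing = rowMeans(X > 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
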