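# Clonotype construction from VDJ contigs, re-merging of chain-subset cells,
# the dominant-clone (malignant) call, and the malignant/reactive/unassigned
# partition. Clone identity is the exact nucleotide CDR3 per chain: a clone
# key is the sorted set of (chain, cdr3_nt) pairs.

pair_key <- function(pairs) paste(sort(unique(pairs)), collapse = "|")

#' Build per-cell clonotypes from contig records
#'
#' Uses only contigs that are cell-associated, high-confidence, on a TRA/TRB
#' chain and carry a CDR3 nucleotide sequence. Per barcode and chain at most
#' the top two contigs by UMI support are kept (a cell has at most two alleles
#' per locus); ties break by CDR3 sequence for determinism.
#'
#' @param contigs data.frame from [read_contig_annotations()].
#' @return data.frame with one row per barcode: barcode, clone_key (sorted
#'   `chain:cdr3` pairs joined by `|`), has_tra, has_trb, n_pairs,
#'   productive_all (all retained pairs productive; NA counts as not),
#'   umis (total UMI support). Barcodes with no usable contig are absent.
#' @export
build_cell_clonotypes <- function(contigs) {
  use <- contigs$is_cell %in% TRUE & contigs$high_confidence %in% TRUE &
    contigs$chain %in% c("TRA", "TRB") & !is.na(contigs$cdr3_nt)
  ct <- contigs[use, , drop = FALSE]
  if (!nrow(ct))
    return(data.frame(barcode = character(), clone_key = character(),
                      has_tra = logical(), has_trb = logical(),
                      n_pairs = integer(), productive_all = logical(),
                      umis = numeric(), stringsAsFactors = FALSE))
  ct <- ct[order(ct$barcode, ct$chain, -ct$umis, ct$cdr3_nt), , drop = FALSE]
  # top-2 per (barcode, chain) by UMIs
  grp <- paste(ct$barcode, ct$chain, sep = "\r")
  rank_in_grp <- stats::ave(seq_along(grp), grp, FUN = seq_along)
  ct <- ct[rank_in_grp <= 2, , drop = FALSE]
  ct$pair <- paste(ct$chain, ct$cdr3_nt, sep = ":")
  split_idx <- split(seq_len(nrow(ct)), ct$barcode)
  out <- lapply(split_idx, function(i) {
    data.frame(
      barcode = ct$barcode[i[1]],
      clone_key = pair_key(ct$pair[i]),
      has_tra = any(ct$chain[i] == "TRA"),
      has_trb = any(ct$chain[i] == "TRB"),
      n_pairs = length(unique(ct$pair[i])),
      productive_all = all(ct$productive[i] %in% TRUE),
      umis = sum(ct$umis[i]),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$barcode), , drop = FALSE]
}

#' Re-merge cells detected with only a chain subset of a paired clone
#'
#' Cells carrying only a subset of a fully paired (alpha+beta) clone's chain
#' pairs inherit that clone's key when the subset is compatible with exactly
#' one paired clone; cells compatible with two or more paired clones keep
#' their own key (ambiguity is never resolved by guessing). Fully paired
#' cells are never changed.
#'
#' @param cells output of [build_cell_clonotypes()].
#' @return the same data.frame with `clone_key` updated and a logical
#'   `merged` column marking re-assigned cells.
#' @export
reconcile_chain_subsets <- function(cells) {
  cells$merged <- FALSE
  if (!nrow(cells)) return(cells)
  full <- unique(cells$clone_key[cells$has_tra & cells$has_trb])
  if (!length(full)) return(cells)
  full_pairs <- strsplit(full, "|", fixed = TRUE)
  pair_to_full <- list()
  for (k in seq_along(full)) {
    for (p in full_pairs[[k]]) pair_to_full[[p]] <- c(pair_to_full[[p]], full[k])
  }
  partial <- which(!(cells$has_tra & cells$has_trb))
  for (i in partial) {
    pairs <- strsplit(cells$clone_key[i], "|", fixed = TRUE)[[1]]
    cand <- pair_to_full[[pairs[1]]]
    if (length(pairs) > 1) {
      for (p in pairs[-1]) cand <- intersect(cand, pair_to_full[[p]])
    }
    cand <- unique(cand)
    if (length(cand) == 1 && !identical(cand, cells$clone_key[i])) {
      cells$clone_key[i] <- cand
      cells$merged[i] <- TRUE
    }
  }
  cells
}

#' Tabulate clonotypes
#'
#' @param cells reconciled cell table from [reconcile_chain_subsets()].
#' @return data.frame per clone: clone_key, cell_count, umis, productive
#'   (majority of member cells carry only productive chains), sorted by
#'   cell_count, then UMI support, then key.
#' @export
clonotype_table <- function(cells) {
  if (!nrow(cells))
    return(data.frame(clone_key = character(), cell_count = integer(),
                      umis = numeric(), productive = logical()))
  agg <- do.call(rbind, lapply(split(cells, cells$clone_key), function(d) {
    data.frame(clone_key = d$clone_key[1], cell_count = nrow(d),
               umis = sum(d$umis),
               productive = mean(d$productive_all) >= 0.5,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(-agg$cell_count, -agg$umis, agg$clone_key), , drop = FALSE]
}

#' Call the dominant (malignant) clone of a sample
#'
#' The most frequent clonotype after chain reconciliation is assumed to be
#' the malignant T-cell clone. Productive clones are considered first; when
#' no productive clone reaches `min_fraction` of TCR-bearing cells, the
#' largest non-productive clone may be called (the expanded non-productive
#' rearrangement case), flagged via `malignant_is_productive = FALSE`. Ties
#' break by total UMI support, then lexicographic clone key, with a warning.
#'
#' @param cells reconciled cell table.
#' @param sample_id sample label.
#' @param min_fraction dominance policy: minimum fraction of TCR-bearing
#'   cells the called clone must reach (default 0.10).
#' @return object of class `clone_call`: sample_id, malignant_clone_key,
#'   malignant_is_productive, dominance_ratio, clones (the clone table).
#' @export
call_malignant_clone <- function(cells, sample_id = "sample",
                                 min_fraction = 0.10) {
  tab <- clonotype_table(cells)
  if (!nrow(tab)) stop("no TCR information: sample '", sample_id,
                       "' has no usable clonotypes")
  n_tcr <- sum(tab$cell_count)
  pick <- function(t) if (nrow(t) && t$cell_count[1] / n_tcr >= min_fraction)
    t[1, ] else NULL
  called <- pick(tab[tab$productive, , drop = FALSE])
  if (is.null(called)) called <- pick(tab[!tab$productive, , drop = FALSE])
  if (is.null(called))
    stop("no dominant clone: largest clonotype of sample '", sample_id,
         "' is below the dominance policy (min_fraction = ", min_fraction, ")")
  tied <- tab$clone_key != called$clone_key &
    tab$cell_count == called$cell_count & tab$umis == called$umis
  if (any(tied))
    warning("dominant-clone tie in sample '", sample_id,
            "' broken by lexicographic clone key")
  others <- tab$cell_count[tab$clone_key != called$clone_key]
  structure(
    list(sample_id = sample_id,
         malignant_clone_key = called$clone_key,
         malignant_is_productive = called$productive,
         dominance_ratio = if (length(others)) called$cell_count / max(others) else Inf,
         n_tcr_cells = n_tcr,
         clones = tab),
    class = "clone_call")
}

#' @export
print.clone_call <- function(x, ...) {
  cat(sprintf(
    "<clone_call> sample '%s': malignant clone %s (%s), dominance %.2f\n",
    x$sample_id, substr(x$malignant_clone_key, 1, 40),
    if (x$malignant_is_productive) "productive" else "NON-productive",
    x$dominance_ratio))
  invisible(x)
}

#' Partition T cells into malignant / reactive / unassigned
#'
#' T cells carrying the malignant clone key are malignant; T cells carrying
#' any other recovered clonotype are reactive (the polyclonal infiltrate);
#' T cells with no recovered TCR are unassigned (kept in embeddings, excluded
#' from malignant-vs-reactive contrasts). The malignant fraction is computed
#' over labelled (malignant + reactive) cells only.
#'
#' @param t_cell_barcodes barcodes of all QC-passing T cells.
#' @param cells reconciled cell table (clonotypes).
#' @param call a [call_malignant_clone()] result.
#' @return list: labels (data.frame barcode/label/clone_key),
#'   malignant_fraction, counts (named vector), call.
#' @export
partition_cells <- function(t_cell_barcodes, cells, call) {
  idx <- match(t_cell_barcodes, cells$barcode)
  clone_key <- ifelse(is.na(idx), NA_character_, cells$clone_key[idx])
  label <- ifelse(is.na(clone_key), "unassigned",
                  ifelse(clone_key == call$malignant_clone_key,
                         "malignant", "reactive"))
  counts <- c(malignant = sum(label == "malignant"),
              reactive = sum(label == "reactive"),
              unassigned = sum(label == "unassigned"))
  labelled <- counts[["malignant"]] + counts[["reactive"]]
  list(labels = data.frame(barcode = t_cell_barcodes, label = label,
                           clone_key = clone_key, stringsAsFactors = FALSE),
       malignant_fraction =
         if (labelled > 0) counts[["malignant"]] / labelled else NA_real_,
       counts = counts,
       call = call)
}
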