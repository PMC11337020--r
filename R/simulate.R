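# Synthetic cohort generator. Emits per-patient count matrices (with
# spliced/unspliced layers), 10x-dialect VDJ contig tables, a gene-position
# table and full truth tables, with the statistical structure the analysis
# assumes: one dominant (malignant) clonotype per lesion over a polyclonal
# reactive infiltrate, planted cross-patient signature genes, patient-private
# transcriptional programs, chromosome-scale gains/losses in malignant cells
# only, and spliced/unspliced counts following first-order splicing kinetics
# with per-sample dynamics regimes. Counts follow a negative-binomial
# hierarchy (log-normal per-gene base means, log-normal per-cell size
# factors, fixed dispersion). Fully deterministic per seed.

default_signature_genes <- function() {
  c("BATF", "IL32", "MIF", "CD9", "ENO1", "KDSR",
    "S100A4", "S100A6", "LGALS1", "LGALS3", "KRT81", "KRT86")
}

mito_gene_names <- function() {
  c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6", "MT-CO3",
    "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6", "MT-CYB")
}

# per-patient program gene themes: memory/naive-like vs cytotoxic-like,
# each patient gets a private set so no program gene can recur across >=4
# patients and contaminate the planted recurrence signature.
program_theme_genes <- function(p) {
  themes <- list(
    c("IL7R", "CCR7", "CXCL13", "TCF7", "CD28"),
    c("CD27", "SELL", "LEF1", "ICOS", "TNFRSF4"),
    c("GZMA", "NKG7", "KLRB1", "CTSW", "CST7"),
    c("GNLY", "GZMK", "KLRD1", "FGFBP2", "CX3CR1"),
    c("KLF2", "KLF3", "IL4", "GATA3", "CD40LG"),
    c("IL13", "CCR4", "IL2RB", "MAL", "TNFRSF9"),
    c("GZMB", "PRF1", "GZMH", "KLRG1", "ZEB2"))
  themes[[((p - 1) %% length(themes)) + 1]]
}

exhaustion_gene_names <- function() {
  c("PDCD1", "CTLA4", "LAG3", "TIGIT", "HAVCR2", "CD160")
}

#' Configure a synthetic cohort
#'
#' Builds the full, validated generation plan: the gene universe with
#' chromosome assignments and base means, the signature/decoy recurrence
#' plan, per-patient programs and CNV blocks, TCR clone sequences, and the
#' per-sample dynamics regimes. The defaults are the desk-scale study
#' conditions: 7 patients, ~265 cells each, malignant fractions spanning
#' 0.47-0.98, 12 signature genes planted up (ln shift 1.0) in >= 4 patients,
#' 20 decoys in <= 3, one patient with a non-productive malignant clone,
#' per-patient gains (1.5x) and losses (0.5x) of 30 contiguous genes.
#'
#' @param seed mandatory RNG seed; the whole cohort is a pure function of
#'   the configuration.
#' @param n_patients number of patients.
#' @param n_cells cells per patient (scalar or vector).
#' @param malignant_fraction per-patient malignant fraction of T cells.
#' @param n_genes size of the gene universe.
#' @param non_t_fraction,low_quality_fraction,cycling_fraction cell-class
#'   fractions.
#' @param dispersion NB dispersion of spliced counts (size = 1/dispersion).
#' @param unspliced_dispersion NB dispersion of unspliced counts.
#' @param size_factor_sdlog log-normal sd of per-cell size factors.
#' @param signature_shift,program_shift,subpop_shift ln-scale planted shifts.
#' @param planted_meanlog,planted_sdlog log-normal parameters of the base
#'   means of planted (signature/decoy/program/subpopulation/exhaustion)
#'   genes; the default centres them near the cohort-wide average abundance.
#' @param signature_patients optional list (one integer vector per signature
#'   gene) of patients carrying each signature gene; default draws 4-7.
#' @param decoy_patients same for the decoy genes; default draws 1-3.
#' @param n_decoys number of decoy genes.
#' @param n_subpops planted malignant subpopulations per patient.
#' @param cnv_gain_chrom,cnv_loss_chrom per-patient CNV target chromosomes
#'   (`NA` disables the block).
#' @param cnv_gain_mult,cnv_loss_mult CNV multipliers.
#' @param cnv_block_genes genes per CNV block.
#' @param dropout_alpha,dropout_beta fraction of malignant cells emitted
#'   with only the beta / only the alpha chain.
#' @param tcr_missing fraction of T cells with no recovered TCR.
#' @param nonproductive_patient index of the patient whose malignant clone
#'   is non-productive (`NA` for none).
#' @param reactive_diversity reactive clonotype pool size as a fraction of
#'   the reactive cell count.
#' @param dynamics_regime per-patient regime, `steady`, `induction` or
#'   `repression`.
#' @param dynamic_cell_fraction fraction of malignant cells in the dynamic
#'   state in non-steady samples.
#' @param n_dynamic_genes number of kinetically dynamic genes.
#' @param induction_unspliced,repression_unspliced unspliced fold factors in
#'   dynamic cells.
#' @param induction_spliced,repression_spliced spliced fold factors in
#'   dynamic cells (the partially-converted mid-transition signal).
#' @param gamma_meanlog,gamma_sdlog log-normal parameters of the per-gene
#'   kinetic ratio gamma.
#' @return validated object of class `cohort_config`.
#' @export
cohort_config <- function(seed,
                          n_patients = 7,
                          n_cells = 265,
                          malignant_fraction =
                            c(0.47, 0.55, 0.63, 0.72, 0.80, 0.90, 0.98),
                          n_genes = 1500,
                          non_t_fraction = 0.05,
                          low_quality_fraction = 0.05,
                          cycling_fraction = 0.10,
                          dispersion = 0.5,
                          unspliced_dispersion = 0.2,
                          size_factor_sdlog = 0.3,
                          signature_shift = 1.0,
                          program_shift = 1.2,
                          subpop_shift = 1.0,
                          planted_meanlog = log(1.5),
                          planted_sdlog = 0.4,
                          signature_patients = NULL,
                          decoy_patients = NULL,
                          n_decoys = 20,
                          n_subpops = rep(2, n_patients),
                          cnv_gain_chrom = c("1", "2", "3", "4", "5", "7", "8"),
                          cnv_loss_chrom = c("6", "17", "6", "6", "10", "6", "13"),
                          cnv_gain_mult = 1.5,
                          cnv_loss_mult = 0.5,
                          cnv_block_genes = 30,
                          dropout_alpha = 0.10,
                          dropout_beta = 0.10,
                          tcr_missing = 0.05,
                          nonproductive_patient = 7,
                          reactive_diversity = 0.8,
                          dynamics_regime =
                            c("steady", "induction", "steady", "steady",
                              "induction", "repression", "steady"),
                          dynamic_cell_fraction = 0.6,
                          n_dynamic_genes = 100,
                          induction_unspliced = 2.5,
                          repression_unspliced = 0.3,
                          induction_spliced = 1.5,
                          repression_spliced = 0.7,
                          gamma_meanlog = log(0.35),
                          gamma_sdlog = 0.4) {
  if (missing(seed)) stop("cohort_config: seed is mandatory")
  np <- n_patients
  rec <- function(x, default_len) if (length(x) == 1) rep(x, default_len) else x
  n_cells <- rec(n_cells, np)
  malignant_fraction <- rec(malignant_fraction, np)[seq_len(np)]
  n_subpops <- rec(n_subpops, np)[seq_len(np)]
  cnv_gain_chrom <- rec(cnv_gain_chrom, np)[seq_len(np)]
  cnv_loss_chrom <- rec(cnv_loss_chrom, np)[seq_len(np)]
  dynamics_regime <- rec(dynamics_regime, np)[seq_len(np)]
  stopifnot(length(n_cells) == np,
            all(malignant_fraction >= 0 & malignant_fraction <= 1),
            all(dynamics_regime %in% c("steady", "induction", "repression")),
            cnv_gain_mult > 0, cnv_loss_mult > 0)

  cfg <- list(seed = as.integer(seed), n_patients = np, n_cells = n_cells,
              malignant_fraction = malignant_fraction, n_genes = n_genes,
              non_t_fraction = non_t_fraction,
              low_quality_fraction = low_quality_fraction,
              cycling_fraction = cycling_fraction,
              dispersion = dispersion,
              unspliced_dispersion = unspliced_dispersion,
              size_factor_sdlog = size_factor_sdlog,
              signature_shift = signature_shift,
              program_shift = program_shift, subpop_shift = subpop_shift,
              planted_meanlog = planted_meanlog, planted_sdlog = planted_sdlog,
              n_decoys = n_decoys, n_subpops = n_subpops,
              cnv_gain_chrom = cnv_gain_chrom,
              cnv_loss_chrom = cnv_loss_chrom,
              cnv_gain_mult = cnv_gain_mult, cnv_loss_mult = cnv_loss_mult,
              cnv_block_genes = cnv_block_genes,
              dropout_alpha = dropout_alpha, dropout_beta = dropout_beta,
              tcr_missing = tcr_missing,
              nonproductive_patient = nonproductive_patient,
              reactive_diversity = reactive_diversity,
              dynamics_regime = dynamics_regime,
              dynamic_cell_fraction = dynamic_cell_fraction,
              n_dynamic_genes = n_dynamic_genes,
              induction_unspliced = induction_unspliced,
              repression_unspliced = repression_unspliced,
              induction_spliced = induction_spliced,
              repression_spliced = repression_spliced,
              gamma_meanlog = gamma_meanlog, gamma_sdlog = gamma_sdlog)

  with_seed(derive_seeds(cfg$seed, 1)[1], {
    # --- recurrence plans -------------------------------------------------
    sig_genes <- default_signature_genes()
    if (is.null(signature_patients))
      signature_patients <- lapply(seq_along(sig_genes), function(i)
        sort(sample(np, sample(min(4L, np):np, 1))))
    names(signature_patients) <- sig_genes
    decoy_genes <- sprintf("DECOY%02d", seq_len(n_decoys))
    if (is.null(decoy_patients))
      decoy_patients <- lapply(seq_len(n_decoys), function(i)
        sort(sample(np, sample(1:min(3, np), 1))))
    names(decoy_patients) <- decoy_genes

    program_genes <- lapply(seq_len(np), function(p)
      c(program_theme_genes(p), sprintf("PRG%d_%02d", p, 1:15)))
    subpop_genes <- lapply(seq_len(np), function(p) {
      if (n_subpops[p] < 2) return(list())
      lapply(2:n_subpops[p], function(s) sprintf("SUB%d_%d_%02d", p, s, 1:15))
    })
    exh_genes <- exhaustion_gene_names()
    # each exhaustion marker high in at most 2 patients
    exh_plan <- lapply(seq_along(exh_genes), function(i)
      sort(sample(np, sample(seq_len(min(2, np)), 1))))
    names(exh_plan) <- exh_genes
    dyn_genes <- sprintf("DYN%03d", seq_len(n_dynamic_genes))

    special <- c(mito_gene_names(), "CD3D", "CD3E", "CD3G",
                 head(default_gene_list("housekeeping"), 60),
                 default_gene_list("s"), default_gene_list("g2m"),
                 sig_genes, decoy_genes, unlist(program_genes),
                 unlist(subpop_genes), exh_genes, dyn_genes)
    if (anyDuplicated(special))
      stop("cohort_config: internal gene-name collision: ",
           paste(unique(special[duplicated(special)]), collapse = ", "))
    if (n_genes < length(special) + 23 * (cnv_block_genes + 2))
      stop("cohort_config: n_genes too small for the planted structure ",
           "(need >= ", length(special) + 23 * (cnv_block_genes + 2), ")")
    filler <- sprintf("SYN%04d", seq_len(n_genes - length(special)))

    # --- chromosome layout ------------------------------------------------
    # mito genes live on MT (outside the CNV vocabulary); everything else is
    # dealt round-robin over chr1..22,X, specials first, fillers appended,
    # so every chromosome ends in a contiguous run of neutral filler genes
    # where CNV blocks can be planted.
    chroms <- chromosome_levels()
    nonmito <- setdiff(special, mito_gene_names())
    deal <- function(x) split(x, rep_len(seq_along(chroms), length(x)))
    sp_deal <- deal(sample(nonmito))
    fl_deal <- deal(sample(filler))
    gene_rows <- list()
    for (k in seq_along(chroms)) {
      gs <- c(sp_deal[[k]], fl_deal[[k]])
      gene_rows[[k]] <- data.frame(
        gene = gs, chrom = chroms[k],
        start = seq_along(gs) * 100000L,
        end = seq_along(gs) * 100000L + 5000L,
        is_filler = gs %in% filler, stringsAsFactors = FALSE)
    }
    mito_rows <- data.frame(gene = mito_gene_names(), chrom = "MT",
                            start = seq_len(13) * 1000L,
                            end = seq_len(13) * 1000L + 900L,
                            is_filler = FALSE, stringsAsFactors = FALSE)
    genes <- rbind(do.call(rbind, gene_rows), mito_rows)

    # --- CNV plan (validated before any data are drawn) -------------------
    cnv_plan <- list()
    for (p in seq_len(np)) {
      for (type in c("gain", "loss")) {
        chrom <- if (type == "gain") cnv_gain_chrom[p] else cnv_loss_chrom[p]
        if (is.na(chrom)) next
        pool <- genes$gene[genes$chrom == chrom & genes$is_filler]
        if (length(pool) < cnv_block_genes)
          stop(sprintf(
            "cohort_config: infeasible CNV block: chr%s has %d neutral genes, need %d",
            chrom, length(pool), cnv_block_genes))
        block <- tail(pool, cnv_block_genes)
        cnv_plan[[length(cnv_plan) + 1]] <- list(
          patient = p, chrom = chrom, type = type,
          multiplier = if (type == "gain") cnv_gain_mult else cnv_loss_mult,
          genes = block)
      }
    }

    # --- base means -------------------------------------------------------
    base_mean <- rlnorm(nrow(genes), meanlog = -0.5, sdlog = 1.0)
    names(base_mean) <- genes$gene
    base_mean[mito_gene_names()] <- rlnorm(13, log(8), 0.3)
    base_mean[c("CD3D", "CD3E", "CD3G")] <- 2.0
    hk <- head(default_gene_list("housekeeping"), 60)
    base_mean[hk] <- rlnorm(length(hk), log(7), 0.25)
    base_mean[dyn_genes] <- rlnorm(length(dyn_genes), log(2), 0.3)
    planted <- c(sig_genes, decoy_genes, unlist(program_genes),
                 unlist(subpop_genes), exh_genes)
    base_mean[planted] <- rlnorm(length(planted), planted_meanlog, planted_sdlog)
    gamma_true <- rlnorm(nrow(genes), gamma_meanlog, gamma_sdlog)
    names(gamma_true) <- genes$gene

    # --- malignant clone TCR sequences ------------------------------------
    rand_nt <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                          replace = TRUE), collapse = "")
    clones <- lapply(seq_len(np), function(p)
      list(tra = rand_nt(36), trb = rand_nt(42),
           productive = !(p %in% nonproductive_patient)))

    cfg$plan <- list(
      signature_genes = sig_genes, signature_patients = signature_patients,
      decoy_genes = decoy_genes, decoy_patients = decoy_patients,
      program_genes = program_genes, subpop_genes = subpop_genes,
      exhaustion_plan = exh_plan, dynamic_genes = dyn_genes,
      housekeeping_genes = hk, cnv_plan = cnv_plan,
      gene_table = genes, base_mean = base_mean, gamma_true = gamma_true,
      malignant_clones = clones)
  })
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d patients, %s cells, %d genes, seed %d\n",
              x$n_patients, paste(range(x$n_cells), collapse = "-"),
              x$n_genes, x$seed))
  invisible(x)
}

rand_nt_vec <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a synthetic cohort
#'
#' Draws per-patient count matrices with spliced/unspliced layers, raw
#' 10x-dialect contig tables, the gene-position table and truth tables from
#' a [cohort_config()]. Deterministic: the same config yields byte-identical
#' output.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort`: samples (named list with elements
#'   `matrix` ([count_matrix()] with `spliced`/`unspliced` layers),
#'   `contigs_raw` (10x-dialect strings), `contigs` (parsed)), gene_positions,
#'   truth (`cells` and `genes` data.frames), config.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  plan <- config$plan
  genes <- plan$gene_table
  G <- nrow(genes)
  gname <- genes$gene
  row_of <- setNames(seq_len(G), gname)
  set.seed(derive_seeds(config$seed, 2)[2])

  mito_rows <- row_of[mito_gene_names()]
  cd3_rows <- row_of[c("CD3D", "CD3E", "CD3G")]
  s_rows <- row_of[default_gene_list("s")]
  g2m_rows <- row_of[default_gene_list("g2m")]
  dyn_rows <- row_of[plan$dynamic_genes]

  samples <- list()
  truth_cells <- list()
  for (p in seq_len(config$n_patients)) {
    sid <- sprintf("P%d", p)
    n <- config$n_cells[p]
    n_non_t <- round(config$non_t_fraction * n)
    n_t <- n - n_non_t
    n_mal <- round(config$malignant_fraction[p] * n_t)
    status <- sample(c(rep("non_t", n_non_t), rep("malignant", n_mal),
                       rep("reactive", n_t - n_mal)))
    is_t <- status != "non_t"
    is_mal <- status == "malignant"
    subpop <- rep(NA_integer_, n)
    subpop[is_mal] <- sample(seq_len(config$n_subpops[p]), n_mal,
                             replace = TRUE)
    cycling <- rep("none", n)
    cyc_idx <- which(runif(n) < config$cycling_fraction)
    cycling[cyc_idx] <- sample(c("S", "G2M"), length(cyc_idx), replace = TRUE)
    lowq <- rep("none", n)
    lq_idx <- which(runif(n) < config$low_quality_fraction)
    lowq[lq_idx] <- sample(c("umi", "mito"), length(lq_idx), replace = TRUE)
    regime <- config$dynamics_regime[p]
    dynamic_cell <- is_mal & regime != "steady" &
      runif(n) < config$dynamic_cell_fraction

    # ---- mean matrix -----------------------------------------------------
    M <- matrix(plan$base_mean, G, n)
    M[cd3_rows, !is_t] <- 0
    mul <- function(rows, cols, f) {
      if (length(rows) && any(cols)) M[rows, cols] <<- M[rows, cols] * f
    }
    mul(row_of[plan$program_genes[[p]]], is_mal, exp(config$program_shift))
    for (g in plan$signature_genes)
      if (p %in% plan$signature_patients[[g]])
        mul(row_of[g], is_mal, exp(config$signature_shift))
    for (g in plan$decoy_genes)
      if (p %in% plan$decoy_patients[[g]])
        mul(row_of[g], is_mal, exp(config$signature_shift))
    for (g in names(plan$exhaustion_plan))
      if (p %in% plan$exhaustion_plan[[g]])
        mul(row_of[g], is_mal, exp(config$signature_shift))
    sp <- plan$subpop_genes[[p]]
    if (length(sp))
      for (s in seq_along(sp))
        mul(row_of[sp[[s]]], is_mal & subpop == s + 1L,
            exp(config$subpop_shift))
    for (blk in plan$cnv_plan)
      if (blk$patient == p) mul(row_of[blk$genes], is_mal, blk$multiplier)
    mul(s_rows, cycling == "S", 3)
    mul(g2m_rows, cycling == "G2M", 3)
    mul(mito_rows, lowq == "mito", 6)
    if (regime == "induction")
      mul(dyn_rows, dynamic_cell, config$induction_spliced)
    if (regime == "repression")
      mul(dyn_rows, dynamic_cell, config$repression_spliced)

    sf <- rlnorm(n, 0, config$size_factor_sdlog)
    sf[lowq == "umi"] <- sf[lowq == "umi"] * 0.06
    MU <- M * rep(sf, each = G)
    spliced <- matrix(rnbinom(G * n, mu = MU, size = 1 / config$dispersion),
                      G, n)

    ureg <- matrix(1, G, n)
    if (regime == "induction")
      ureg[dyn_rows, dynamic_cell] <- config$induction_unspliced
    if (regime == "repression")
      ureg[dyn_rows, dynamic_cell] <- config$repression_unspliced
    u_mu <- plan$gamma_true * spliced * ureg
    unspliced <- matrix(rnbinom(G * n, mu = u_mu,
                                size = 1 / config$unspliced_dispersion), G, n)

    barcodes <- sprintf("%s-C%04d", sid, seq_len(n))
    mat <- count_matrix(
      Matrix::Matrix(spliced, sparse = TRUE), gname, gname, barcodes, sid,
      layers = list(spliced = Matrix::Matrix(spliced, sparse = TRUE),
                    unspliced = Matrix::Matrix(unspliced, sparse = TRUE)))

    # ---- TCR contigs -----------------------------------------------------
    clone <- plan$malignant_clones[[p]]
    prod_str <- if (clone$productive) "True" else "False"
    mal_key <- pair_key(c(paste0("TRA:", clone$tra), paste0("TRB:", clone$trb)))
    rows <- list()
    emit <- function(bc, chain, cdr3, productive, umis, cid) {
      rows[[length(rows) + 1]] <<- data.frame(
        barcode = bc, is_cell = "True", high_confidence = "True",
        chain = chain,
        v_gene = paste0(chain, "V1-1"), j_gene = paste0(chain, "J1"),
        c_gene = paste0(chain, "C"), full_length = "True",
        productive = productive, cdr3_nt = cdr3,
        umis = as.character(umis), raw_clonotype_id = cid,
        stringsAsFactors = FALSE)
    }
    clone_key_truth <- rep(NA_character_, n)
    n_reac <- sum(status == "reactive")
    pool_n <- max(1L, round(config$reactive_diversity * max(1L, n_reac)))
    pool_tra <- rand_nt_vec(pool_n, 36)
    pool_trb <- rand_nt_vec(pool_n, 42)
    for (i in seq_len(n)) {
      if (!is_t[i]) next
      if (runif(1) < config$tcr_missing) next
      if (is_mal[i]) {
        u <- runif(1)
        um <- rpois(2, 6) + 2L
        if (u < config$dropout_alpha) {
          emit(barcodes[i], "TRB", clone$trb, prod_str, um[2], "clonotype1")
        } else if (u < config$dropout_alpha + config$dropout_beta) {
          emit(barcodes[i], "TRA", clone$tra, prod_str, um[1], "clonotype1")
        } else {
          emit(barcodes[i], "TRA", clone$tra, prod_str, um[1], "clonotype1")
          emit(barcodes[i], "TRB", clone$trb, prod_str, um[2], "clonotype1")
        }
        clone_key_truth[i] <- mal_key
      } else {
        k <- sample.int(pool_n, 1)
        um <- rpois(2, 5) + 1L
        cid <- sprintf("clonotype%d", 1 + k)
        drop <- runif(2) < 0.05
        if (!drop[1]) emit(barcodes[i], "TRA", pool_tra[k], "True", um[1], cid)
        if (!drop[2]) emit(barcodes[i], "TRB", pool_trb[k], "True", um[2], cid)
        if (drop[1] && drop[2]) next
        clone_key_truth[i] <- pair_key(c(paste0("TRA:", pool_tra[k]),
                                         paste0("TRB:", pool_trb[k])))
      }
    }
    # junk rows every parser must ignore: non-cell and chain-ambiguous
    junk <- rbind(
      data.frame(barcode = barcodes[1], is_cell = "False",
                 high_confidence = "True", chain = "TRB",
                 v_gene = "TRBV9", j_gene = "TRBJ1", c_gene = "TRBC",
                 full_length = "True", productive = "True",
                 cdr3_nt = rand_nt_vec(1, 42), umis = "1",
                 raw_clonotype_id = "None", stringsAsFactors = FALSE),
      data.frame(barcode = barcodes[1], is_cell = "True",
                 high_confidence = "True", chain = "Multi",
                 v_gene = "None", j_gene = "None", c_gene = "None",
                 full_length = "False", productive = "None",
                 cdr3_nt = "None", umis = "1",
                 raw_clonotype_id = "None", stringsAsFactors = FALSE))
    contigs_raw <- rbind(do.call(rbind, rows), junk)

    samples[[sid]] <- list(matrix = mat, contigs_raw = contigs_raw,
                           contigs = parse_contig_table(contigs_raw))
    truth_cells[[sid]] <- data.frame(
      sample = sid, barcode = barcodes, is_t = is_t, is_malignant = is_mal,
      clone_key = clone_key_truth, subpop = subpop, cycling = cycling,
      low_quality = lowq, dynamic_cell = dynamic_cell,
      has_tcr = !is.na(clone_key_truth), stringsAsFactors = FALSE)
  }

  sig_count <- integer(G); names(sig_count) <- gname
  for (g in plan$signature_genes)
    sig_count[g] <- length(plan$signature_patients[[g]])
  for (g in plan$decoy_genes) sig_count[g] <- length(plan$decoy_patients[[g]])
  gain_pat <- loss_pat <- setNames(rep("", G), gname)
  for (blk in plan$cnv_plan) {
    slot <- if (blk$type == "gain") "gain" else "loss"
    tgt <- if (slot == "gain") gain_pat[blk$genes] else loss_pat[blk$genes]
    tgt <- ifelse(nzchar(tgt), paste(tgt, blk$patient, sep = ";"),
                  as.character(blk$patient))
    if (slot == "gain") gain_pat[blk$genes] <- tgt else loss_pat[blk$genes] <- tgt
  }
  truth_genes <- data.frame(
    gene = gname, chrom = genes$chrom, start = genes$start, end = genes$end,
    base_mean = unname(plan$base_mean[gname]),
    gamma_true = unname(plan$gamma_true[gname]),
    is_signature = gname %in% plan$signature_genes,
    is_decoy = gname %in% plan$decoy_genes,
    planted_patients = unname(sig_count),
    is_dynamic = gname %in% plan$dynamic_genes,
    cnv_gain_patients = unname(gain_pat),
    cnv_loss_patients = unname(loss_pat),
    is_housekeeping = gname %in% plan$housekeeping_genes,
    is_mito = gname %in% mito_gene_names(),
    stringsAsFactors = FALSE)

  structure(
    list(samples = samples,
         gene_positions = data.frame(
           gene = genes$gene, chrom = genes$chrom, start = genes$start,
           end = genes$end, strand = "+", stringsAsFactors = FALSE),
         truth = list(cells = do.call(rbind, truth_cells),
                      genes = truth_genes),
         config = config),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  nc <- sum(vapply(x$samples, function(s) ncol(s$matrix$counts), 0))
  cat(sprintf("<cohort> %d samples, %d cells, %d genes\n",
              length(x$samples), nc, x$config$n_genes))
  invisible(x)
}

#' Desk-scale preset cohort
#'
#' The default study conditions (7 patients, ~1,855 cells, malignant
#' fractions 0.47-0.98, 12 signature genes in >= 4 patients each, one
#' non-productive-clone patient), a ~10x scale-down of a full lesion cohort.
#'
#' @param seed RNG seed.
#' @return a [generate_cohort()] result.
#' @export
emulate_lesion_cohort <- function(seed) {
  generate_cohort(cohort_config(seed = seed))
}

#' Write a cohort in the on-disk formats the readers accept
#'
#' Per sample: a 10x-style triplet plus `spliced.mtx`/`unspliced.mtx` and a
#' `filtered_contig_annotations.csv`; cohort-level: `gene_positions.tsv` and
#' truth tables as CSV.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$samples)) {
    sdir <- file.path(dir, sid)
    write_count_matrix(cohort$samples[[sid]]$matrix, sdir)
    write.csv(cohort$samples[[sid]]$contigs_raw,
              file.path(sdir, "filtered_contig_annotations.csv"),
              row.names = FALSE)
  }
  write.table(cohort$gene_positions, file.path(dir, "gene_positions.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write_table(cohort$truth$cells, file.path(dir, "truth_cells.csv"), "csv")
  write_table(cohort$truth$genes, file.path(dir, "truth_genes.csv"), "csv")
  invisible(dir)
}

#' Read a written cohort back through the standard readers
#'
#' @param dir directory produced by [write_cohort()].
#' @return list: samples (each with `matrix` and `contigs`), gene_positions.
#' @export
read_cohort <- function(dir) {
  sids <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  samples <- lapply(sids, function(sid) {
    sdir <- file.path(dir, sid)
    list(matrix = read_count_matrix(
           file.path(sdir, "matrix.mtx"), file.path(sdir, "features.tsv"),
           file.path(sdir, "barcodes.tsv"), sid,
           layer_paths = c(spliced = file.path(sdir, "spliced.mtx"),
                           unspliced = file.path(sdir, "unspliced.mtx"))),
         contigs = read_contig_annotations(
           file.path(sdir, "filtered_contig_annotations.csv")))
  })
  names(samples) <- sids
  list(samples = samples,
       gene_positions = read_gene_positions(file.path(dir, "gene_positions.tsv")))
}
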