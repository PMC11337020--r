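#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef cor dist kmeans lm loess mad median model.matrix
#'   na.omit p.adjust pnorm prcomp predict quantile rbinom rlnorm rmultinom
#'   rnbinom rnorm rpois runif sd setNames var
#' @importFrom utils head read.csv read.delim tail write.csv write.table
NULL

# Run code with a temporary RNG state seeded at `seed`, restoring the caller's
# state afterwards so seeded helpers never perturb outer simulations.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# Derive a stream of child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 9973L * seq_len(n)) %% 2147483647L
}

#' Packaged marker-gene lists
#'
#' Curated default gene lists used by the QC and cell-cycle scoring steps:
#' housekeeping genes (dominated by ribosomal-protein genes), and S-phase /
#' G2M-phase cell-cycle markers. All are plain-text, one symbol per line, and
#' every function taking a gene list accepts a user-supplied replacement.
#'
#' @param which one of `"housekeeping"`, `"s"`, `"g2m"`.
#' @return character vector of gene symbols.
#' @export
default_gene_list <- function(which = c("housekeeping", "s", "g2m")) {
  which <- match.arg(which)
  file <- switch(which,
    housekeeping = "housekeeping_genes.txt",
    s = "cell_cycle_s_genes.txt",
    g2m = "cell_cycle_g2m_genes.txt")
  path <- system.file("extdata", file, package = "lymphclone", mustWork = TRUE)
  readLines(path)
}

# Ordered chromosome vocabulary (autosomes then X); "chr" prefixes tolerated.
chromosome_levels <- function() c(as.character(1:22), "X")

chromosome_rank <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  match(chrom, chromosome_levels())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
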