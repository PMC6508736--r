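#' Expression matrix with a normalization state
#'
#' Gene-by-sample matrix of non-negative (or, after log2, real) values
#' tagged with the normalization state it is in. Operations check the
#' state so that, e.g., actin ratios are only computed from raw CPM and
#' log2 values only from TMM-normalized CPM.
#'
#' @param values numeric matrix with gene row names and sample column names.
#' @param state one of `"raw_cpm"`, `"tmm_cpm"`, `"log2"`, `"actin_ratio"`,
#'   `"median_scaled"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values,
                              state = c("raw_cpm", "tmm_cpm", "log2",
                                        "actin_ratio", "median_scaled")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene and sample names", call. = FALSE)
  rownames(values) <- norm_symbol(rownames(values))
  if (any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  structure(list(values = values, state = state),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix [", x$state, "]: ", nrow(x$values), " genes x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

check_state <- function(em, allowed) {
  if (!inherits(em, "expression_matrix"))
    stop("expected an expression_matrix", call. = FALSE)
  if (!em$state %in% allowed)
    stop("expression matrix in state '", em$state, "'; expected ",
         paste(allowed, collapse = " or "), call. = FALSE)
  invisible(TRUE)
}

#' Counts per million mapped reads
#'
#' `CPM(g, s) = counts(g, s) / library_size(s) * 1e6`. When TMM factors
#' are supplied the effective library size `library_size * factor` is used
#' and the result is tagged `tmm_cpm`.
#'
#' @param cm a [count_matrix()].
#' @param tmm optional per-sample TMM factors from [tmm_factors()].
#' @return An `expression_matrix` in state `raw_cpm` or `tmm_cpm`.
#' @export
compute_cpm <- function(cm, tmm = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  lib <- cm$library_sizes
  state <- "raw_cpm"
  if (!is.null(tmm)) {
    if (length(tmm) != length(lib))
      stop("need one TMM factor per sample", call. = FALSE)
    lib <- lib * tmm
    state <- "tmm_cpm"
  }
  if (any(lib <= 0))
    stop("zero effective library size for sample(s): ",
         paste(names(lib)[lib <= 0], collapse = ", "), call. = FALSE)
  expression_matrix(sweep(cm$counts, 2, lib, "/") * 1e6, state)
}

#' Expression filter on CS libraries
#'
#' A gene is retained iff its CPM strictly exceeds `cfg$cpm_min` in at
#' least `cfg$min_cs_libraries` of the complete-spermatogenesis libraries.
#' When per-gene biotypes are available, genes outside the mRNA whitelist
#' (`protein_coding`) are purged first; without biotypes the purge is a
#' no-op.
#'
#' @param em `expression_matrix` in state `raw_cpm`.
#' @param cs_sample_ids ids of the CS libraries.
#' @param cfg a [sertoli_config()].
#' @param gene_biotype optional per-gene biotype (named or ordered as rows).
#' @param mrna_biotypes biotype whitelist defining "encodes mRNA".
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(em, cs_sample_ids, cfg = sertoli_config(),
                             gene_biotype = NULL,
                             mrna_biotypes = "protein_coding") {
  check_state(em, "raw_cpm")
  cs_sample_ids <- intersect(cs_sample_ids, colnames(em$values))
  if (length(cs_sample_ids) == 0)
    stop("no CS samples present in the matrix", call. = FALSE)
  if (length(cs_sample_ids) < cfg$min_cs_libraries)
    stop("fewer CS samples (", length(cs_sample_ids),
         ") than min_cs_libraries (", cfg$min_cs_libraries, ")",
         call. = FALSE)
  v <- em$values
  if (!is.null(gene_biotype)) {
    bt <- if (!is.null(names(gene_biotype)))
      gene_biotype[rownames(v)] else gene_biotype
    v <- v[!is.na(bt) & bt %in% mrna_biotypes, , drop = FALSE]
  }
  n_pass <- rowSums(v[, cs_sample_ids, drop = FALSE] > cfg$cpm_min)
  rownames(v)[n_pass >= cfg$min_cs_libraries]
}

#' TMM between-sample scale factors
#'
#' Trimmed mean of M-values scaling factors (Robinson & Oshlack 2010) via
#' edgeR: per-gene log-ratios (M) against a reference sample are trimmed
#' 30% on M and 5% on absolute intensity (A) and combined by a
#' precision-weighted mean; factors are renormalized so their geometric
#' mean is 1. The reference defaults to the sample whose upper-quartile
#' CPM is closest to the mean upper quartile.
#'
#' @param cm a [count_matrix()].
#' @param genes optional gene subset (e.g. the expression-filtered set).
#' @param ref_sample optional reference sample id.
#' @param cfg a [sertoli_config()] supplying the trim fractions.
#' @return Named positive per-sample factors with geometric mean 1.
#' @export
tmm_factors <- function(cm, genes = NULL, ref_sample = NULL,
                        cfg = sertoli_config()) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (ncol(counts) < 2) stop("TMM needs >= 2 samples", call. = FALSE)
  ref <- NULL
  if (!is.null(ref_sample)) {
    ref <- match(ref_sample, colnames(counts))
    if (is.na(ref)) stop("unknown reference sample: ", ref_sample,
                         call. = FALSE)
  }
  f <- edgeR::calcNormFactors(counts, lib.size = cm$library_sizes,
                              method = "TMM", refColumn = ref,
                              logratioTrim = cfg$tmm_trim_m,
                              sumTrim = cfg$tmm_trim_a)
  if (any(!is.finite(f) | f <= 0))
    stop("TMM failed for sample(s): ",
         paste(colnames(counts)[!is.finite(f) | f <= 0], collapse = ", "),
         " (no co-expressed genes with the reference?)", call. = FALSE)
  names(f) <- colnames(counts)
  f
}

#' log2 transform of TMM-normalized CPM
#'
#' `log2(cpm + prior)`; the prior (default 1 CPM) keeps zeros finite.
#'
#' @param em `expression_matrix` in state `tmm_cpm`.
#' @param prior non-negative pseudo-CPM.
#' @return An `expression_matrix` in state `log2`.
#' @export
log2_transform <- function(em, prior = 1.0) {
  check_state(em, "tmm_cpm")
  if (!is.finite(prior) || prior < 0)
    stop("log2 prior must be non-negative", call. = FALSE)
  if (any(em$values < 0)) stop("negative CPM values", call. = FALSE)
  expression_matrix(log2(em$values + prior), "log2")
}

#' Beta-actin ratio normalization
#'
#' Divides every gene's CPM by the CPM of the housekeeping actin gene in
#' the same sample, the scale used to compare somatic- and germ-cell
#' marker transcripts across histologies with very different cellular
#' makeup.
#'
#' @param em `expression_matrix` in state `raw_cpm`.
#' @param actin_gene actin gene symbol (default `ACTB`).
#' @return An `expression_matrix` in state `actin_ratio`.
#' @export
actin_normalize <- function(em, actin_gene = "ACTB") {
  check_state(em, "raw_cpm")
  actin_gene <- norm_symbol(actin_gene)
  if (!actin_gene %in% rownames(em$values))
    stop(actin_gene, " not present in the expression matrix", call. = FALSE)
  a <- em$values[actin_gene, ]
  if (any(a <= 0))
    stop(actin_gene, " has zero CPM in sample(s): ",
         paste(names(a)[a <= 0], collapse = ", "), call. = FALSE)
  expression_matrix(sweep(em$values, 2, a, "/"), "actin_ratio")
}

#' Rescale signature-panel CPMs to a common per-sample median
#'
#' Before re-testing the signature panel, each sample's signature-gene
#' CPMs are multiplied by `target / median_s`, where `median_s` is that
#' sample's median over the panel and `target` is the median of the
#' per-sample medians. After scaling every sample has the same panel
#' median; the operation is idempotent.
#'
#' @param em `expression_matrix` in state `tmm_cpm` (or `median_scaled`,
#'   for which it is the identity up to the shared median).
#' @param signature_genes panel gene ids (>= 3 must be present).
#' @return An `expression_matrix` over the panel, state `median_scaled`.
#' @export
median_scale_signature <- function(em, signature_genes) {
  check_state(em, c("tmm_cpm", "median_scaled"))
  genes <- intersect(norm_symbol(signature_genes), rownames(em$values))
  if (length(genes) < 3)
    stop("need >= 3 signature genes present in the matrix", call. = FALSE)
  v <- em$values[genes, , drop = FALSE]
  if (ncol(v) == 1L) return(expression_matrix(v, "median_scaled"))
  med <- apply(v, 2, stats::median)
  if (any(med <= 0))
    stop("zero signature median in sample(s): ",
         paste(colnames(v)[med <= 0], collapse = ", "), call. = FALSE)
  target <- stats::median(med)
  expression_matrix(sweep(v, 2, target / med, "*"), "median_scaled")
}
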