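#' Per-cell-type reference expression panel
#'
#' Gene-by-cell-type matrix of per-cell relative expression. Columns are
#' rescaled to sum 1e6 so that every cell type is expressed in the same
#' CPM-like per-cell units; with that convention a composition-weighted
#' mixture of columns (weights summing to 1) is itself a CPM vector, and
#' composition fractions are interpretable as mRNA-mass fractions.
#'
#' The rat panel (`rat5`) must carry the five purified cell types used by
#' the cross-species screen: Sertoli, Leydig, spermatogonia, pachytene
#' spermatocytes, round spermatids. The human panel carries the measured
#' non-Sertoli types (Leydig plus germ types); the Sertoli column is the
#' unmeasured quantity the subtraction estimates.
#'
#' @param expr non-negative numeric matrix, genes x cell types, with row
#'   and column names.
#' @param panel_id `"rat5"` or `"human"`.
#' @param rescale rescale each column to sum 1e6 (default TRUE).
#' @return An object of class `cell_type_reference`.
#' @export
cell_type_reference <- function(expr, panel_id = c("rat5", "human"),
                                rescale = TRUE) {
  panel_id <- match.arg(panel_id)
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("reference needs gene row names and cell-type column names",
         call. = FALSE)
  rownames(expr) <- norm_symbol(rownames(expr))
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene ids in reference", call. = FALSE)
  if (any(!is.finite(expr)) || any(expr < 0))
    stop("reference expression must be finite and non-negative",
         call. = FALSE)
  if (panel_id == "rat5") {
    need <- rat5_cell_types()
    miss <- setdiff(need, colnames(expr))
    if (length(miss) > 0)
      stop("rat5 panel missing cell type(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  if (rescale) {
    cs <- colSums(expr)
    if (any(cs <= 0))
      stop("reference column(s) with zero total: ",
           paste(colnames(expr)[cs <= 0], collapse = ", "), call. = FALSE)
    expr <- sweep(expr, 2, cs, "/") * 1e6
  }
  structure(list(expr = expr, panel_id = panel_id,
                 cell_types = colnames(expr)),
            class = "cell_type_reference")
}

#' @export
print.cell_type_reference <- function(x, ...) {
  cat("cell_type_reference [", x$panel_id, "]: ", nrow(x$expr),
      " genes x ", ncol(x$expr), " cell types (",
      paste(x$cell_types, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Canonical rat five-cell-type panel column names
#' @return Character vector of the five cell types.
#' @export
rat5_cell_types <- function() {
  c("Sertoli", "Leydig", "spermatogonia", "pachytene_spermatocytes",
    "round_spermatids")
}

#' Relative cell-number composition of a testis
#'
#' Relative cell numbers `n_k` per cell type with optional per-cell mRNA
#' content `s_k` (default 1: equal transcript mass per cell). The derived
#' mixing fractions are `f_k = n_k * s_k / sum_j n_j * s_j`, which sum to
#' one and weight the per-cell reference columns when reconstructing or
#' subtracting bulk expression.
#'
#' @param weights named non-negative numeric vector of relative cell
#'   numbers (zero = depleted type).
#' @param mrna_content positive scalar or named vector of per-cell mRNA
#'   content multipliers.
#' @return An object of class `cell_composition` with element `fractions`.
#' @export
#' @examples
#' comp <- cell_composition(c(Sertoli = 0.15, Leydig = 0.10,
#'                            spermatogonia = 0.10,
#'                            pachytene_spermatocytes = 0.25,
#'                            round_spermatids = 0.40))
#' sum(comp$fractions)  # 1
cell_composition <- function(weights, mrna_content = 1.0) {
  w <- as.numeric(weights)
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("composition weights must be named by cell type", call. = FALSE)
  names(w) <- names(weights)
  if (any(!is.finite(w) | w < 0))
    stop("composition weights must be non-negative; offending: ",
         paste(names(w)[!is.finite(w) | w < 0], collapse = ", "),
         call. = FALSE)
  if (sum(w) <= 0) stop("all composition weights are zero", call. = FALSE)
  s <- as.numeric(mrna_content)
  if (length(s) == 1L) s <- rep(s, length(w))
  if (length(s) != length(w))
    stop("mrna_content must be scalar or one value per cell type",
         call. = FALSE)
  if (any(!is.finite(s) | s <= 0))
    stop("mrna_content must be positive", call. = FALSE)
  names(s) <- names(w)
  f <- w * s / sum(w * s)
  structure(list(weights = w, mrna_content = s, fractions = f),
            class = "cell_composition")
}

#' @export
print.cell_composition <- function(x, ...) {
  cat("cell_composition:\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Default testis cell compositions for the two histologies
#'
#' The complete-spermatogenesis (CS) testis is germ-cell dominated; the
#' Sertoli-cell-only (SCO) testis has germ cells depleted to a residual
#' 10% and its somatic fractions enriched roughly 3-fold, matching the
#' somatic-transcript enrichment seen between the two histologies. The SCO
#' residual germ mass is split across germ types in the CS proportions.
#'
#' @param group `"CS"` or `"SCO"`.
#' @return A [cell_composition()].
#' @export
default_composition <- function(group = c("CS", "SCO")) {
  group <- match.arg(group)
  if (group == "CS") {
    cell_composition(c(Sertoli = 0.15, Leydig = 0.10,
                       spermatogonia = 0.10,
                       pachytene_spermatocytes = 0.25,
                       round_spermatids = 0.40))
  } else {
    germ_cs <- c(spermatogonia = 0.10, pachytene_spermatocytes = 0.25,
                 round_spermatids = 0.40)
    cell_composition(c(c(Sertoli = 0.55, Leydig = 0.35),
                       0.10 * germ_cs / sum(germ_cs)))
  }
}
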