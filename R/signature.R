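#' Rat Sertoli fold-enrichment screen
#'
#' Step one of the two-step screen: keep a gene iff its rat Sertoli
#' per-cell expression is at least `fold` times its expression in each of
#' the other four purified cell types (inclusive, "at least"). Genes with
#' zero expression in every non-Sertoli type are kept iff the Sertoli
#' value is positive.
#'
#' @param ref a [cell_type_reference()] with `panel_id = "rat5"`.
#' @param fold enrichment floor (default 4).
#' @return Character vector of candidate rat gene ids.
#' @export
rat_screen <- function(ref, fold = 4.0) {
  stopifnot(inherits(ref, "cell_type_reference"))
  if (!"Sertoli" %in% ref$cell_types)
    stop("reference has no Sertoli column", call. = FALSE)
  s <- ref$expr[, "Sertoli"]
  others <- ref$expr[, setdiff(ref$cell_types, "Sertoli"), drop = FALSE]
  max_other <- apply(others, 1, max)
  keep <- ifelse(max_other > 0, s >= fold * max_other, s > 0)
  rownames(ref$expr)[keep]
}

#' Map rat candidates to human orthologues
#'
#' Only one-to-one mappings pass. Unmapped and multi-mapping candidates
#' are excluded and listed, with reasons, in the mapping report.
#'
#' @param candidates rat gene ids from [rat_screen()].
#' @param orthologs data.frame from [read_orthologs()] (columns
#'   `rat_gene`, `human_gene`, optional `multi`).
#' @return list with `human_genes` (character) and `report` (data.frame
#'   `rat_gene`, `status`, `human_gene`).
#' @export
map_orthologs <- function(candidates, orthologs) {
  candidates <- norm_symbol(candidates)
  if (is.null(orthologs$multi)) {
    n_targets <- tapply(orthologs$human_gene, orthologs$rat_gene,
                        function(x) length(unique(x)))
    orthologs$multi <- unname(n_targets[orthologs$rat_gene] > 1L)
  }
  status <- character(length(candidates))
  human <- rep(NA_character_, length(candidates))
  for (i in seq_along(candidates)) {
    hits <- orthologs[orthologs$rat_gene == candidates[i], , drop = FALSE]
    if (nrow(hits) == 0) {
      status[i] <- "unmapped"
    } else if (any(hits$multi) || length(unique(hits$human_gene)) > 1) {
      status[i] <- "multi"
    } else {
      status[i] <- "mapped"
      human[i] <- hits$human_gene[1]
    }
  }
  report <- data.frame(rat_gene = candidates, status = status,
                       human_gene = human, stringsAsFactors = FALSE)
  list(human_genes = unique(human[status == "mapped"]), report = report)
}

#' Add the manual augmentation list to the mapped candidates
#'
#' Set union preserving first-seen order (mapped candidates first);
#' duplicates between the two lists are reported in the `duplicates`
#' attribute.
#'
#' @param mapped human gene ids from [map_orthologs()].
#' @param manual manually curated additions (e.g. blood-testis-barrier
#'   components and SSC growth factors not covered by the arrays).
#' @return Character vector of tentative candidates.
#' @export
augment_candidates <- function(mapped, manual = character(0)) {
  mapped <- unique(norm_symbol(mapped))
  manual <- unique(norm_symbol(manual))
  dups <- intersect(manual, mapped)
  out <- c(mapped, setdiff(manual, mapped))
  attr(out, "duplicates") <- dups
  out
}

#' Estimate Sertoli cell expression by composition subtraction
#'
#' For each candidate gene, the composition-weighted contribution of every
#' measured non-Sertoli cell type is subtracted from the total testis
#' CPM: `nonsertoli(g) = sum_{k != Sertoli} f_k * E_k(g)`,
#' `S(g) = max(0, T(g) - nonsertoli(g))` (floored so fractions stay in
#' `[0, 1]`), `fraction = S/T` (0 where `T = 0`), and the per-cell level
#' `S / f_Sertoli`. Genes absent from the reference contribute zero
#' non-Sertoli signal and are flagged.
#'
#' @param total_cpm named vector of mean CS testis CPM per candidate gene.
#' @param ref a [cell_type_reference()] of the measured non-Sertoli types
#'   (any Sertoli column present is ignored for the subtraction).
#' @param comp a [cell_composition()] including a positive Sertoli
#'   fraction.
#' @return data.frame with `gene_id`, `total_cpm`,
#'   `nonsertoli_contribution`, `sertoli_amount`, `sertoli_fraction`,
#'   `sertoli_percell`, `in_reference`.
#' @export
estimate_sertoli <- function(total_cpm, ref, comp) {
  stopifnot(inherits(ref, "cell_type_reference"),
            inherits(comp, "cell_composition"))
  f <- comp$fractions
  if (!"Sertoli" %in% names(f) || f[["Sertoli"]] <= 0)
    stop("composition must include a positive Sertoli fraction",
         call. = FALSE)
  genes <- norm_symbol(names(total_cpm))
  if (is.null(genes) || any(!nzchar(genes)))
    stop("total_cpm must be named by gene", call. = FALSE)
  types <- setdiff(ref$cell_types, "Sertoli")
  miss_f <- setdiff(types, names(f))
  if (length(miss_f) > 0)
    stop("composition missing cell type(s): ",
         paste(miss_f, collapse = ", "), call. = FALSE)
  idx <- match(genes, rownames(ref$expr))
  in_ref <- !is.na(idx)
  contrib <- numeric(length(genes))
  if (any(in_ref)) {
    e <- ref$expr[idx[in_ref], types, drop = FALSE]
    contrib[in_ref] <- as.numeric(e %*% f[types])
  }
  total <- as.numeric(total_cpm)
  amount <- pmax(0, total - contrib)
  fraction <- ifelse(total > 0, amount / total, 0)
  data.frame(gene_id = genes, total_cpm = total,
             nonsertoli_contribution = contrib,
             sertoli_amount = amount, sertoli_fraction = fraction,
             sertoli_percell = amount / f[["Sertoli"]],
             in_reference = in_ref,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the three signature criteria
#'
#' A gene is a Sertoli cell signature transcript iff
#' (a) Sertoli cells supply at least `sertoli_fraction_min` (default 60%)
#' of the transcript in the testis (inclusive),
#' (b) its Sertoli per-cell expression is at least
#' `sertoli_leydig_ratio_min` (default 2) times the Leydig per-cell level
#' (inclusive), and
#' (c) its Sertoli per-cell expression strictly exceeds every germ cell
#' type. Criteria (b) and (c) compare per-cell levels; (a) is a share of
#' the testis total.
#'
#' @param est data.frame from [estimate_sertoli()].
#' @param ref the same non-Sertoli [cell_type_reference()].
#' @param cfg a [sertoli_config()].
#' @param leydig_type Leydig column name in the reference.
#' @return data.frame with the supporting numbers and `pass_a`, `pass_b`,
#'   `pass_c`, `is_signature`.
#' @export
call_signatures <- function(est, ref, cfg = sertoli_config(),
                            leydig_type = "Leydig") {
  stopifnot(inherits(ref, "cell_type_reference"))
  if (!leydig_type %in% ref$cell_types)
    stop("reference has no '", leydig_type, "' column", call. = FALSE)
  germ_types <- setdiff(ref$cell_types, c(leydig_type, "Sertoli"))
  idx <- match(est$gene_id, rownames(ref$expr))
  leydig <- ifelse(is.na(idx), 0, ref$expr[idx, leydig_type])
  germ <- matrix(0, nrow(est), length(germ_types))
  ok <- !is.na(idx)
  germ[ok, ] <- ref$expr[idx[ok], germ_types, drop = FALSE]
  max_germ <- apply(germ, 1, max)
  pass_a <- est$sertoli_fraction >= cfg$sertoli_fraction_min
  pass_b <- est$sertoli_percell >= cfg$sertoli_leydig_ratio_min * leydig
  pass_c <- est$sertoli_percell > max_germ
  data.frame(est,
             leydig_percell = leydig, max_germ_percell = max_germ,
             pass_a = pass_a, pass_b = pass_b, pass_c = pass_c,
             is_signature = pass_a & pass_b & pass_c,
             stringsAsFactors = FALSE)
}

#' Overlap of a signature list with a mouse Sertoli transcript list
#'
#' Case-insensitive symbol intersection; a cross-species sanity check of
#' the called signature.
#'
#' @param signature human signature gene ids.
#' @param mouse_list mouse Sertoli-detected transcript symbols.
#' @return list with `intersection`, `count`, `fraction` (of the
#'   signature).
#' @export
mouse_overlap <- function(signature, mouse_list) {
  signature <- unique(norm_symbol(signature))
  mouse_list <- unique(norm_symbol(mouse_list))
  if (length(signature) == 0 || length(mouse_list) == 0)
    stop("both gene lists must be non-empty", call. = FALSE)
  inter <- intersect(signature, mouse_list)
  list(intersection = inter, count = length(inter),
       fraction = length(inter) / length(signature))
}

#' Run the full two-step Sertoli signature screen
#'
#' Chains the cross-species fold-change screen, ortholog mapping, manual
#' augmentation, composition-subtraction deconvolution of the mean CS
#' testis CPM, and the three pass/fail criteria into one call, returning a
#' classed object with the intermediate tables.
#'
#' @param total_cpm named vector of mean CS testis CPM per gene (the gene
#'   universe after expression filtering), or an `expression_matrix` of CS
#'   samples whose row means are used.
#' @param rat_ref rat five-cell-type [cell_type_reference()].
#' @param human_ref human non-Sertoli [cell_type_reference()].
#' @param comp CS [cell_composition()] including Sertoli.
#' @param orthologs ortholog table (see [read_orthologs()]).
#' @param augment manual augmentation gene list.
#' @param mouse_list optional mouse Sertoli transcript list for the
#'   overlap check.
#' @param cfg a [sertoli_config()].
#' @return An object of class `sertoli_screen` with elements `candidates`
#'   (rat), `mapping`, `tentative`, `estimates`, `calls`,
#'   `signature_genes`, `mouse`, `config`.
#' @export
#' @examples
#' refs <- simulate_references(n_genes = 300, n_signature = 20, seed = 5)
#' mix <- expected_mixture(refs, default_composition("CS"))
#' scr <- sertoli_screen(mix, refs$rat_ref, refs$human_ref,
#'                       default_composition("CS"), refs$orthologs)
#' print(scr)
sertoli_screen <- function(total_cpm, rat_ref, human_ref, comp,
                           orthologs, augment = character(0),
                           mouse_list = NULL, cfg = sertoli_config()) {
  if (inherits(total_cpm, "expression_matrix"))
    total_cpm <- rowMeans(total_cpm$values)
  candidates <- rat_screen(rat_ref, fold = cfg$rat_fold)
  mapping <- map_orthologs(candidates, orthologs)
  tentative <- augment_candidates(mapping$human_genes, augment)
  present <- intersect(tentative, norm_symbol(names(total_cpm)))
  est <- estimate_sertoli(total_cpm[present], human_ref, comp)
  calls <- call_signatures(est, human_ref, cfg)
  sig <- calls$gene_id[calls$is_signature]
  mouse <- if (!is.null(mouse_list) && length(sig) > 0)
    mouse_overlap(sig, mouse_list)
  structure(list(candidates = candidates, mapping = mapping,
                 tentative = as.character(tentative),
                 dropped_absent = setdiff(tentative, present),
                 estimates = est, calls = calls, signature_genes = sig,
                 mouse = mouse, config = cfg),
            class = "sertoli_screen")
}

#' @export
print.sertoli_screen <- function(x, ...) {
  cat("Sertoli cell signature screen\n")
  cat(sprintf("  rat-screen candidates (>= %g-fold): %d\n",
              x$config$rat_fold, length(x$candidates)))
  cat(sprintf("  mapped 1:1 to human:                %d\n",
              length(x$mapping$human_genes)))
  cat(sprintf("  tentative after augmentation:       %d\n",
              length(x$tentative)))
  cat(sprintf("  signature transcripts called:       %d\n",
              length(x$signature_genes)))
  if (!is.null(x$mouse))
    cat(sprintf("  detected in mouse Sertoli cells:    %d (%.1f%%)\n",
                x$mouse$count, 100 * x$mouse$fraction))
  invisible(x)
}

#' @export
summary.sertoli_screen <- function(object, ...) {
  calls <- object$calls
  out <- list(
    n_candidates = length(object$candidates),
    n_mapped = length(object$mapping$human_genes),
    n_unmapped = sum(object$mapping$report$status == "unmapped"),
    n_multi = sum(object$mapping$report$status == "multi"),
    n_tentative = length(object$tentative),
    n_pass_a = sum(calls$pass_a),
    n_pass_b = sum(calls$pass_b),
    n_pass_c = sum(calls$pass_c),
    n_signature = length(object$signature_genes),
    median_fraction = stats::median(calls$sertoli_fraction)
  )
  class(out) <- "summary.sertoli_screen"
  out
}

#' @export
print.summary.sertoli_screen <- function(x, ...) {
  cat("Signature screen summary\n")
  cat(sprintf("  candidates: %d (unmapped %d, multi-mapped %d)\n",
              x$n_candidates, x$n_unmapped, x$n_multi))
  cat(sprintf("  tentative candidates: %d\n", x$n_tentative))
  cat(sprintf("  pass (a) >=60%% share: %d; (b) >=2x Leydig: %d; ",
              x$n_pass_a, x$n_pass_b))
  cat(sprintf("(c) > all germ: %d\n", x$n_pass_c))
  cat(sprintf("  signature transcripts: %d (median Sertoli share %.2f)\n",
              x$n_signature, x$median_fraction))
  invisible(x)
}

#' @export
as.data.frame.sertoli_screen <- function(x, ...) x$calls

#' Plot method for a signature screen
#'
#' Sertoli share of the testis total against the Sertoli/Leydig per-cell
#' ratio (log10), with the criterion thresholds drawn and called
#' signature transcripts highlighted.
#'
#' @param x a `sertoli_screen` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sertoli_screen <- function(x, ...) {
  calls <- x$calls
  ratio <- ifelse(calls$leydig_percell > 0,
                  calls$sertoli_percell / calls$leydig_percell, Inf)
  ratio <- pmin(ratio, 1e4)
  graphics::plot(calls$sertoli_fraction, log10(pmax(ratio, 1e-4)),
                 col = ifelse(calls$is_signature, "firebrick", "grey50"),
                 pch = 16, cex = 0.6,
                 xlab = "Sertoli fraction of testis total",
                 ylab = "log10 Sertoli/Leydig per-cell ratio", ...)
  graphics::abline(v = x$config$sertoli_fraction_min, lty = 2)
  graphics::abline(h = log10(x$config$sertoli_leydig_ratio_min), lty = 2)
  invisible(x)
}
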