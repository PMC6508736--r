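#' Simulate rat and human reference panels with known signature truth
#'
#' Builds the inputs of the two-step screen with designated ground truth.
#' Per-cell baseline expression is drawn log-normally (meanlog 1,
#' sdlog 1.2) per gene and cell type and every column is scaled to
#' CPM-like units (sum 1e6). Truth signature genes have their Sertoli
#' per-cell expression set to `enrichment` times the maximum of the other
#' cell types *on the rescaled panel*, so the generative enrichment holds
#' exactly by construction (the remaining baseline Sertoli genes are
#' scaled so the Sertoli column still sums to 1e6). Near-miss decoys are
#' planted the same way at `decoy_enrichment` (default 3.5-fold, below the
#' 4-fold screen) in 5% of genes to keep specificity testing honest.
#'
#' The human panel mirrors the rat one with multiplicative log-normal
#' cross-species noise; the human Sertoli profile is returned separately
#' (`sertoli_profile`) because the screen treats it as unmeasured. A 1:1
#' ortholog table links the panels, with configurable fractions of
#' unmapped and multi-mapped decoy rows among non-truth genes; one
#' non-truth gene is named ACTB so actin-ratio stages are exercisable. A
#' synthetic mouse Sertoli transcript list detects truth genes at
#' `mouse_detect_rate` plus a random background.
#'
#' @param n_genes number of genes.
#' @param n_signature number of designated signature (truth) genes.
#' @param enrichment Sertoli fold-enrichment of truth genes over the
#'   maximum other cell type (must exceed 1; default 8).
#' @param decoy_frac fraction of genes planted as near-miss decoys.
#' @param decoy_enrichment enrichment of the decoys.
#' @param unmapped_frac fraction of non-truth genes dropped from the
#'   ortholog table.
#' @param multi_frac fraction of non-truth genes given a second (bogus)
#'   human target.
#' @param meanlog,sdlog log-normal baseline parameters.
#' @param offtarget_scale multiplier applied to the non-Sertoli expression
#'   of truth and decoy genes before rescaling (default 0.25): signature
#'   transcripts are marker-like, i.e. lowly expressed off-target, which
#'   also keeps the forced Sertoli mass a small share of the cell's
#'   transcriptome.
#' @param cross_species_sdlog log-normal sd of rat-to-human noise.
#' @param mouse_detect_rate detection rate of truth genes in the mouse
#'   list.
#' @param seed integer seed; the whole object is reproducible from it.
#' @return list with `rat_ref`, `human_ref` (non-Sertoli),
#'   `sertoli_profile`, `orthologs`, `mouse_list`, and `truth`
#'   (class `synthetic_truth`).
#' @export
simulate_references <- function(n_genes = 1000, n_signature = 50,
                                enrichment = 8.0, decoy_frac = 0.05,
                                decoy_enrichment = 3.5,
                                unmapped_frac = 0.03, multi_frac = 0.02,
                                meanlog = 1, sdlog = 1.2,
                                offtarget_scale = 0.25,
                                cross_species_sdlog = 0.15,
                                mouse_detect_rate = 0.87, seed = 17L) {
  if (enrichment <= 1) stop("enrichment must exceed 1", call. = FALSE)
  if (n_signature >= n_genes)
    stop("n_signature must be smaller than n_genes", call. = FALSE)
  set.seed(seed)
  human_ids <- sprintf("GENE%05d", seq_len(n_genes))
  truth_idx <- sort(sample(n_genes, n_signature))
  pool <- setdiff(seq_len(n_genes), truth_idx)
  decoy_idx <- sort(sample(pool, round(decoy_frac * n_genes)))
  free_idx <- setdiff(pool, decoy_idx)
  human_ids[sample(free_idx, 1)] <- "ACTB"
  rat_ids <- paste0("R-", human_ids)
  other_types <- setdiff(rat5_cell_types(), "Sertoli")

  build_panel <- function(base_others, base_sertoli) {
    others <- sweep(base_others, 2, colSums(base_others), "/") * 1e6
    max_other <- apply(others, 1, max)
    sertoli <- base_sertoli
    forced <- c(truth_idx, decoy_idx)
    sertoli[truth_idx] <- enrichment * max_other[truth_idx]
    sertoli[decoy_idx] <- decoy_enrichment * max_other[decoy_idx]
    rest <- setdiff(seq_along(sertoli), forced)
    budget <- 1e6 - sum(sertoli[forced])
    if (budget <= 0)
      stop("forced Sertoli mass exceeds the column total; ",
           "reduce n_signature or enrichment", call. = FALSE)
    sertoli[rest] <- sertoli[rest] * budget / sum(sertoli[rest])
    cbind(Sertoli = sertoli, others)
  }

  rat_base_others <- matrix(rlnorm(n_genes * 4, meanlog, sdlog), n_genes, 4,
                            dimnames = list(rat_ids, other_types))
  rat_base_others[c(truth_idx, decoy_idx), ] <-
    rat_base_others[c(truth_idx, decoy_idx), ] * offtarget_scale
  rat_base_s <- rlnorm(n_genes, meanlog, sdlog)
  rat_panel <- build_panel(rat_base_others, rat_base_s)
  rat_ref <- cell_type_reference(rat_panel, "rat5", rescale = FALSE)

  noise <- matrix(rlnorm(n_genes * 4, 0, cross_species_sdlog), n_genes, 4)
  hum_base_others <- rat_base_others * noise
  dimnames(hum_base_others) <- list(human_ids, other_types)
  hum_base_s <- rat_base_s * rlnorm(n_genes, 0, cross_species_sdlog)
  hum_panel <- build_panel(hum_base_others, hum_base_s)
  sertoli_profile <- hum_panel[, "Sertoli"]
  names(sertoli_profile) <- human_ids
  human_ref <- cell_type_reference(hum_panel[, other_types], "human",
                                   rescale = FALSE)

  orth <- data.frame(rat_gene = norm_symbol(rat_ids),
                     human_gene = human_ids, stringsAsFactors = FALSE)
  n_unmapped <- round(unmapped_frac * n_genes)
  n_multi <- round(multi_frac * n_genes)
  perturb <- sample(free_idx, n_unmapped + n_multi)
  drop_idx <- perturb[seq_len(n_unmapped)]
  multi_idx <- setdiff(perturb, drop_idx)
  if (length(multi_idx) > 0)
    orth <- rbind(orth, data.frame(
      rat_gene = orth$rat_gene[multi_idx],
      human_gene = paste0(orth$human_gene[multi_idx], "-ALT"),
      stringsAsFactors = FALSE))
  if (length(drop_idx) > 0)
    orth <- orth[!orth$rat_gene %in% norm_symbol(rat_ids[drop_idx]), ]
  n_targets <- tapply(orth$human_gene, orth$rat_gene,
                      function(x) length(unique(x)))
  orth$multi <- unname(n_targets[orth$rat_gene] > 1L)

  detected <- runif(n_signature) < mouse_detect_rate
  mouse_list <- unique(c(human_ids[truth_idx][detected],
                         sample(human_ids[pool],
                                round(0.3 * length(pool)))))

  truth <- structure(list(
    signature_genes = human_ids[truth_idx],
    decoy_genes = human_ids[decoy_idx],
    enrichment = stats::setNames(rep(enrichment, n_signature),
                                 human_ids[truth_idx]),
    decoy_enrichment = decoy_enrichment,
    unmapped_genes = human_ids[drop_idx],
    multi_genes = human_ids[multi_idx],
    seed = seed,
    params = list(n_genes = n_genes, n_signature = n_signature,
                  meanlog = meanlog, sdlog = sdlog,
                  cross_species_sdlog = cross_species_sdlog)
  ), class = "synthetic_truth")

  list(rat_ref = rat_ref, human_ref = human_ref,
       sertoli_profile = sertoli_profile, orthologs = orth,
       mouse_list = mouse_list, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", length(x$signature_genes), "signature genes of",
      x$params$n_genes, "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Expected bulk CPM mixture for a composition
#'
#' `mix(g) = sum_k f_k * E_k(g)` over the full panel (measured non-Sertoli
#' columns plus the Sertoli profile). Because every column sums to 1e6 and
#' the fractions sum to 1, the mixture is itself a CPM vector (sums to
#' 1e6) — the generator's pre-noise bookkeeping.
#'
#' @param refs list from [simulate_references()].
#' @param comp a [cell_composition()].
#' @return Named numeric vector of expected CPM.
#' @export
expected_mixture <- function(refs, comp) {
  e_full <- cbind(Sertoli = refs$sertoli_profile, refs$human_ref$expr)
  f <- comp$fractions
  miss <- setdiff(colnames(e_full), names(f))
  if (length(miss) > 0)
    stop("composition missing cell type(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  mix <- as.numeric(e_full %*% f[colnames(e_full)])
  names(mix) <- rownames(e_full)
  mix
}

#' Simulate a bulk CS/SCO cohort of negative-binomial counts
#'
#' Draws `count(g, s) ~ NB(mean = lib_size_s * mix_group(g) / 1e6,
#' dispersion phi)` with `variance = mu + phi * mu^2`; `phi = 0`
#' degenerates to Poisson. The default cohort matches the study design: 4
#' complete-spermatogenesis and 7 Sertoli-cell-only libraries at an
#' average depth of 17 million reads, with the SCO composition
#' germ-depleted and somatically enriched about 3-fold. Per-sample depths
#' are drawn log-normally around `lib_size` (sdlog `lib_sdlog`) so that
#' depth-normalization code paths are exercised.
#'
#' @param refs list from [simulate_references()].
#' @param comp_cs,comp_sco group compositions (defaults:
#'   [default_composition()]).
#' @param n_cs,n_sco samples per group (defaults 4 and 7).
#' @param lib_size average library depth in reads (default 17e6).
#' @param phi NB dispersion (default 0.1; 0 gives Poisson).
#' @param lib_sdlog log-normal sd of per-sample depth (0 for exact).
#' @param seed integer seed.
#' @return list with `counts` (a [count_matrix()]), `samples`
#'   (data.frame), `mix_cs`, `mix_sco` (expected CPM), and `truth`
#'   (the reference truth augmented with the cohort conditions).
#' @export
simulate_cohort <- function(refs, comp_cs = default_composition("CS"),
                            comp_sco = default_composition("SCO"),
                            n_cs = 4, n_sco = 7, lib_size = 17e6,
                            phi = 0.1, lib_sdlog = 0.1, seed = 17L) {
  if (phi < 0) stop("phi must be >= 0", call. = FALSE)
  set.seed(seed + 1L)
  mix_cs <- expected_mixture(refs, comp_cs)
  mix_sco <- expected_mixture(refs, comp_sco)
  ids <- c(paste0("C", seq_len(n_cs)), paste0("SCO", seq_len(n_sco)))
  group <- c(rep("CS", n_cs), rep("SCO", n_sco))
  libs <- if (lib_sdlog > 0)
    round(rlnorm(n_cs + n_sco, log(lib_size) - lib_sdlog^2 / 2, lib_sdlog))
  else rep(lib_size, n_cs + n_sco)
  n_genes <- length(mix_cs)
  counts <- matrix(0, n_genes, n_cs + n_sco,
                   dimnames = list(names(mix_cs), ids))
  for (j in seq_along(ids)) {
    mu <- (if (group[j] == "CS") mix_cs else mix_sco) / 1e6 * libs[j]
    counts[, j] <- if (phi == 0) rpois(n_genes, mu)
                   else rnbinom(n_genes, size = 1 / phi, mu = mu)
  }
  samples <- data.frame(
    sample_id = ids, group = group,
    histology = ifelse(group == "CS", "complete spermatogenesis",
                       "SCO 100%"),
    age = NA_real_, weight_lbs = NA_real_, fsh_miu_ml = NA_real_,
    eggs_injected = NA_real_, embryos = NA_real_,
    stringsAsFactors = FALSE)
  truth <- refs$truth
  truth$composition <- list(CS = comp_cs$fractions,
                            SCO = comp_sco$fractions)
  truth$library_sizes <- stats::setNames(libs, ids)
  truth$phi <- phi
  truth$cohort_seed <- seed
  truth$mix_cs <- mix_cs
  truth$mix_sco <- mix_sco
  list(counts = count_matrix(counts, library_sizes = libs),
       samples = samples, mix_cs = mix_cs, mix_sco = mix_sco,
       truth = truth)
}

#' Sensitivity and specificity of signature recovery
#'
#' Compares a called signature set with the designated synthetic truth
#' over a gene universe: sensitivity is the recovered fraction of truth
#' genes, specificity the correctly rejected fraction of non-truth genes.
#'
#' @param calls called signature genes — a character vector, a
#'   `sertoli_screen` object, or a calls data.frame with `is_signature`.
#' @param truth a `synthetic_truth` object.
#' @param universe gene universe for the negative class (default: every
#'   gene the generator produced).
#' @return list with `sensitivity`, `specificity`, and a 2x2 `confusion`
#'   table.
#' @export
evaluate_recovery <- function(calls, truth, universe = NULL) {
  if (inherits(calls, "sertoli_screen")) calls <- calls$signature_genes
  if (is.data.frame(calls)) calls <- calls$gene_id[calls$is_signature]
  calls <- unique(norm_symbol(calls))
  pos <- norm_symbol(truth$signature_genes)
  if (is.null(universe)) {
    universe <- if (!is.null(truth$mix_cs)) names(truth$mix_cs)
                else union(calls, pos)
  }
  universe <- unique(norm_symbol(universe))
  neg <- setdiff(universe, pos)
  tp <- length(intersect(calls, pos))
  fn <- length(setdiff(pos, calls))
  fp <- length(intersect(calls, neg))
  tn <- length(neg) - fp
  conf <- matrix(c(tp, fn, fp, tn), 2, 2,
                 dimnames = list(c("called", "rejected"),
                                 c("truth", "non_truth")))
  list(sensitivity = if (length(pos) > 0) tp / length(pos) else NA_real_,
       specificity = if (length(neg) > 0) tn / length(neg) else NA_real_,
       confusion = conf)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits the TSV files every reader in the package consumes (counts,
#' samples, rat and human references, compositions, orthologs, gene
#' lists) plus `truth.json`, so a full file-based pipeline run is possible
#' without any external data.
#'
#' @param refs list from [simulate_references()].
#' @param cohort list from [simulate_cohort()].
#' @param out_dir output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_fixtures <- function(refs, cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_counts(cohort$counts, p("counts.tsv"))
  write.table(cohort$samples, p("samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  wr_ref <- function(ref, f) {
    df <- data.frame(gene_id = rownames(ref$expr), ref$expr,
                     check.names = FALSE)
    write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr_ref(refs$rat_ref, "rat_reference.tsv")
  wr_ref(refs$human_ref, "human_reference.tsv")
  wr_comp <- function(comp, f) {
    write.table(data.frame(cell_type = names(comp$fractions),
                           weight = as.numeric(comp$weights),
                           mrna_content = as.numeric(comp$mrna_content)),
                p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  comp_cs <- cell_composition(cohort$truth$composition$CS)
  comp_sco <- cell_composition(cohort$truth$composition$SCO)
  wr_comp(comp_cs, "composition_cs.tsv")
  wr_comp(comp_sco, "composition_sco.tsv")
  write.table(refs$orthologs[c("rat_gene", "human_gene")],
              p("orthologs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(refs$mouse_list, p("mouse_sertoli.txt"))
  tr <- cohort$truth
  jsonlite::write_json(
    list(signature_genes = tr$signature_genes,
         decoy_genes = tr$decoy_genes,
         enrichment = as.list(tr$enrichment),
         composition = lapply(tr$composition, as.list),
         library_sizes = as.list(tr$library_sizes),
         phi = tr$phi, seed = tr$seed, cohort_seed = tr$cohort_seed),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  paths <- list(counts = p("counts.tsv"), samples = p("samples.tsv"),
                rat_ref = p("rat_reference.tsv"),
                human_ref = p("human_reference.tsv"),
                composition = p("composition_cs.tsv"),
                composition_sco = p("composition_sco.tsv"),
                orthologs = p("orthologs.tsv"),
                mouse = p("mouse_sertoli.txt"),
                truth = p("truth.json"))
  invisible(paths)
}

#' @importFrom stats runif setNames
NULL
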