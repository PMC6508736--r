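#' Run the full analysis pipeline end to end
#'
#' Orchestrates every stage on one configuration and seed: expression
#' filtering, TMM normalization and log2 transform, whole-transcriptome
#' negative-binomial exact testing with BH FDR, actin-ratio t-tests with
#' percent-of-CS values, the two-step Sertoli signature screen, signature
#' panel median rescaling and re-testing, k-means and PCA views, and the
#' donor cohort summary. All stage tables are written to `out_dir` with a
#' JSON manifest; outputs depend only on (inputs, config, seed).
#'
#' Inputs are given either as loaded objects or as file paths in
#' `inputs`; alternatively `simulate` generates a synthetic cohort (and
#' writes its fixture files alongside the results). The signature re-test
#' runs the exact test on signature-gene counts with library sizes folded
#' by the median-rescaling factors, so its CPMs are exactly the
#' median-scaled panel values.
#'
#' @param inputs named list of file paths (`counts`, `samples`,
#'   `rat_ref`, `human_ref`, `composition`, `orthologs`, optionally
#'   `augment`, `mouse`), or NULL when `simulate` is given.
#' @param out_dir output directory.
#' @param cfg a [sertoli_config()] (or path to a YAML config).
#' @param simulate optional named list of [simulate_references()] /
#'   [simulate_cohort()] arguments; when given, inputs are generated.
#' @param seed seed for the simulated cohort and k-means (defaults to
#'   `cfg$seed`).
#' @param force overwrite existing outputs.
#' @param verbose log stage progress to stderr.
#' @return The run manifest, invisibly, with the screen object attached
#'   as attribute `screen`.
#' @export
run_pipeline <- function(inputs = NULL, out_dir, cfg = sertoli_config(),
                         simulate = NULL, seed = NULL, force = FALSE,
                         verbose = FALSE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  if (!inherits(cfg, "sertoli_config"))
    stop("cfg must be a sertoli_config or a YAML path",
         call. = FALSE)
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(inputs) && is.null(simulate))
    stop("provide either inputs or simulate", call. = FALSE)

  if (!is.null(simulate)) {
    sig_log("simulating references and cohort", verbose = verbose)
    ref_args <- simulate[intersect(names(simulate),
                                   names(formals(simulate_references)))]
    ref_args$seed <- seed
    refs <- do.call(simulate_references, ref_args)
    coh_args <- simulate[intersect(names(simulate),
                                   names(formals(simulate_cohort)))]
    coh_args$refs <- refs
    coh_args$seed <- seed
    cohort <- do.call(simulate_cohort, coh_args)
    write_fixtures(refs, cohort, file.path(out_dir, "fixtures"))
    cm <- cohort$counts
    samples <- cohort$samples
    rat_ref <- refs$rat_ref; human_ref <- refs$human_ref
    comp <- if (!is.null(coh_args$comp_cs)) coh_args$comp_cs
            else default_composition("CS")
    orthologs <- refs$orthologs
    augment <- character(0)
    mouse <- refs$mouse_list
  } else {
    req <- c("counts", "samples", "rat_ref", "human_ref", "composition",
             "orthologs")
    for (f in req) {
      if (is.null(inputs[[f]]) || !file.exists(inputs[[f]]))
        stop(structure(class = c("sertoli_missing_input", "error",
                                 "condition"),
                       list(message = paste0("missing input file: ",
                                             if (is.null(inputs[[f]])) f
                                             else inputs[[f]]),
                            call = NULL)))
    }
    sig_log("reading inputs", verbose = verbose)
    cm <- read_counts(inputs$counts)
    samples <- read_sample_table(inputs$samples)
    bundle <- read_reference_bundle(inputs)
    rat_ref <- bundle$rat_ref; human_ref <- bundle$human_ref
    comp <- bundle$composition; orthologs <- bundle$orthologs
    augment <- if (!is.null(bundle$augment)) bundle$augment
               else character(0)
    mouse <- bundle$mouse
  }
  check_samples_match(cm, samples)
  groups <- samples$group[match(colnames(cm$counts), samples$sample_id)]
  cs_ids <- colnames(cm$counts)[groups == "CS"]

  sig_log("filtering and normalizing", verbose = verbose)
  cpm_raw <- compute_cpm(cm)
  retained <- filter_expressed(cpm_raw, cs_ids, cfg,
                               gene_biotype = cm$gene_biotype)
  cm_f <- count_matrix(cm$counts[retained, , drop = FALSE],
                       library_sizes = cm$library_sizes)
  tmm <- tmm_factors(cm_f, cfg = cfg)
  cpm_tmm <- compute_cpm(cm_f, tmm = tmm)
  log2_em <- log2_transform(cpm_tmm, prior = cfg$log_prior)

  sig_log("whole-transcriptome exact test", verbose = verbose)
  disp <- estimate_dispersion(cm_f, groups, tmm = tmm)
  de <- nb_exact_test(cm_f, groups, disp, tmm = tmm,
                      prior = cfg$log_prior)
  de <- ratio_percent(classify_de(de, cfg, mode = "nb"))
  diag_tabs <- ma_volcano_tables(de, prior = cfg$log_prior)

  actin_de <- NULL
  if (cfg$actin_gene %in% retained) {
    sig_log("actin-ratio t-tests", verbose = verbose)
    cpm_raw_f <- compute_cpm(cm_f)
    actin_em <- actin_normalize(cpm_raw_f, cfg$actin_gene)
    actin_de <- group_ttest(actin_em, groups, cfg)
    actin_de <- ratio_percent(classify_de(actin_de, cfg, mode = "ttest"))
  }

  sig_log("signature screen", verbose = verbose)
  mean_cs_cpm <- rowMeans(compute_cpm(cm_f)$values[, cs_ids, drop = FALSE])
  screen <- sertoli_screen(mean_cs_cpm, rat_ref, human_ref, comp,
                           orthologs, augment = augment,
                           mouse_list = mouse, cfg = cfg)
  sig <- screen$signature_genes

  sig_de <- NULL; panel_pca <- NULL
  if (length(sig) >= 3) {
    sig_log("signature panel re-test", verbose = verbose)
    panel <- median_scale_signature(cpm_tmm, sig)
    med <- apply(cpm_tmm$values[rownames(panel$values), , drop = FALSE],
                 2, stats::median)
    k_s <- stats::median(med) / med  # per-sample rescale factors
    cm_sig <- count_matrix(cm_f$counts[rownames(panel$values), ,
                                       drop = FALSE],
                           library_sizes = cm$library_sizes)
    libs_sig <- cm$library_sizes * tmm / k_s
    disp_sig <- estimate_dispersion(cm_sig, groups,
                                    tmm = libs_sig / cm$library_sizes)
    sig_de <- nb_exact_test(cm_sig, groups, disp_sig,
                            tmm = libs_sig / cm$library_sizes,
                            prior = cfg$log_prior)
    sig_de <- ratio_percent(classify_de(sig_de, cfg, mode = "nb"))
    panel_log <- expression_matrix(log2(panel$values + cfg$log_prior),
                                   "log2")
    panel_pca <- pca_scores(panel_log)
  }

  sig_log("exploratory views", verbose = verbose)
  de_genes <- de$gene_id[de$direction != "ns"]
  km_genes <- if (length(de_genes) >= cfg$kmeans_k) de_genes else retained
  km <- kmeans_clusters(
    expression_matrix(log2_em$values[km_genes, , drop = FALSE], "log2"),
    k = cfg$kmeans_k, seed = seed)

  cohort_tab <- if (any(!is.na(samples$age))) summarize_cohort(samples)

  tables <- list(
    retained_genes = data.frame(gene_id = retained),
    tmm_factors = data.frame(sample_id = names(tmm), factor = tmm),
    de_transcriptome = de,
    ma_table = diag_tabs$ma,
    volcano_table = diag_tabs$volcano,
    signature_calls = screen$calls,
    mapping_report = screen$mapping$report,
    clusters = data.frame(gene_id = names(km$cluster),
                          cluster = as.integer(km$cluster))
  )
  if (!is.null(actin_de)) tables$de_actin_ratio <- actin_de
  if (!is.null(sig_de)) tables$de_signature <- sig_de
  if (!is.null(panel_pca)) {
    tables$pca_scores <- data.frame(sample_id = rownames(panel_pca$scores),
                                    panel_pca$scores[, 1:min(4,
                                      ncol(panel_pca$scores)),
                                      drop = FALSE])
    tables$variance_explained <- data.frame(
      component = seq_along(panel_pca$variance_explained),
      percent = panel_pca$variance_explained)
  }
  if (!is.null(cohort_tab)) tables$cohort_summary <- cohort_tab

  sig_log("writing results", verbose = verbose)
  manifest <- write_results(tables, out_dir, config = cfg, seed = seed,
                            force = force)
  attr(manifest, "screen") <- screen
  invisible(manifest)
}
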