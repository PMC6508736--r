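#' Analysis thresholds and tuning constants
#'
#' Bundles every threshold used by the pipeline in one validated object.
#' Defaults are the screen's published operating point: genes must exceed
#' 0.4 CPM in at least 2 complete-spermatogenesis libraries to count as
#' expressed; whole-transcriptome differential expression is called at
#' BH FDR < 0.05 (strict) and actin-ratio t-tests at p <= 0.005
#' (inclusive); rat Sertoli candidates need >= 4-fold enrichment over every
#' other cell type; a signature call needs a Sertoli share of at least 60%
#' of the testis total and per-cell expression at least twice the Leydig
#' level and strictly above every germ type.
#'
#' @param cpm_min expression filter threshold, CPM (strictly greater-than).
#' @param min_cs_libraries number of CS libraries that must pass `cpm_min`.
#' @param fdr_max BH FDR significance bound (strict `<`).
#' @param ttest_alpha t-test significance bound (inclusive `<=`).
#' @param rat_fold rat Sertoli fold-enrichment floor (inclusive `>=`).
#' @param sertoli_fraction_min minimum Sertoli share of the testis total
#'   for criterion (a), in `(0, 1]` (inclusive).
#' @param sertoli_leydig_ratio_min minimum Sertoli/Leydig per-cell ratio
#'   for criterion (b) (inclusive).
#' @param kmeans_k number of k-means clusters for the exploratory view.
#' @param log_prior pseudo-CPM added before log2 and fold-change ratios.
#' @param seed integer seed recorded with the configuration.
#' @param actin_gene housekeeping gene symbol for ratio normalization.
#' @param tmm_trim_m,tmm_trim_a TMM trim fractions on M and A values.
#' @param ttest_var `"welch"` (default) or `"student"` pooled variance.
#' @return An object of class `sertoli_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sertoli_config()
#' cfg$rat_fold
sertoli_config <- function(cpm_min = 0.4,
                           min_cs_libraries = 2L,
                           fdr_max = 0.05,
                           ttest_alpha = 0.005,
                           rat_fold = 4.0,
                           sertoli_fraction_min = 0.6,
                           sertoli_leydig_ratio_min = 2.0,
                           kmeans_k = 10L,
                           log_prior = 1.0,
                           seed = 17L,
                           actin_gene = "ACTB",
                           tmm_trim_m = 0.30,
                           tmm_trim_a = 0.05,
                           ttest_var = c("welch", "student")) {
  cfg <- list(
    cpm_min = as.numeric(cpm_min),
    min_cs_libraries = as.integer(min_cs_libraries),
    fdr_max = as.numeric(fdr_max),
    ttest_alpha = as.numeric(ttest_alpha),
    rat_fold = as.numeric(rat_fold),
    sertoli_fraction_min = as.numeric(sertoli_fraction_min),
    sertoli_leydig_ratio_min = as.numeric(sertoli_leydig_ratio_min),
    kmeans_k = as.integer(kmeans_k),
    log_prior = as.numeric(log_prior),
    seed = as.integer(seed),
    actin_gene = toupper(trimws(actin_gene)),
    tmm_trim_m = as.numeric(tmm_trim_m),
    tmm_trim_a = as.numeric(tmm_trim_a),
    ttest_var = match.arg(ttest_var)
  )
  num <- c("cpm_min", "fdr_max", "ttest_alpha", "rat_fold",
           "sertoli_fraction_min", "sertoli_leydig_ratio_min", "log_prior")
  for (nm in num) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("config field '", nm, "' must be a positive finite number",
           call. = FALSE)
  }
  if (cfg$sertoli_fraction_min > 1)
    stop("sertoli_fraction_min must lie in (0, 1]", call. = FALSE)
  if (cfg$min_cs_libraries < 1L)
    stop("min_cs_libraries must be >= 1", call. = FALSE)
  if (cfg$kmeans_k < 1L) stop("kmeans_k must be >= 1", call. = FALSE)
  structure(cfg, class = "sertoli_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [sertoli_config()] argument names exactly;
#' unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return A `sertoli_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  known <- names(formals(sertoli_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(sertoli_config, raw)
}

#' @export
print.sertoli_config <- function(x, ...) {
  cat("Sertoli signature screen configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Stable short hash of a configuration (FNV-1a over the deparsed list);
# used to stamp output manifests so reruns are comparable.
config_hash <- function(cfg) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
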