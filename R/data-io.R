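#' @importFrom utils read.delim write.table
NULL

norm_symbol <- function(x) toupper(trimws(as.character(x)))

#' Gene-by-sample count matrix
#'
#' Light container for raw RNA-seq counts: an integer-valued matrix with
#' unique gene symbols as row names and unique sample ids as column names,
#' per-sample library sizes (defaulting to column sums; they may exceed the
#' column sums when the matrix has been filtered), and an optional per-gene
#' biotype label used by the non-mRNA purge.
#'
#' @param counts numeric matrix of non-negative whole numbers with row and
#'   column names.
#' @param library_sizes optional positive per-sample totals, recycled from
#'   column sums when missing.
#' @param gene_biotype optional character vector, one label per gene.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, library_sizes = NULL, gene_biotype = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names",
         call. = FALSE)
  rownames(counts) <- norm_symbol(rownames(counts))
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g) > 0)
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "), call. = FALSE)
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s) > 0)
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("counts must be non-negative integers; first offending entry at ",
         "gene '", rownames(counts)[bad[1, 1]], "', sample '",
         colnames(counts)[bad[1, 2]], "'", call. = FALSE)
  storage.mode(counts) <- "double"
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  library_sizes <- as.numeric(library_sizes)
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes must have one entry per sample", call. = FALSE)
  if (any(!is.finite(library_sizes) | library_sizes <= 0))
    stop("library sizes must be positive; offending sample(s): ",
         paste(colnames(counts)[library_sizes <= 0], collapse = ", "),
         call. = FALSE)
  names(library_sizes) <- colnames(counts)
  if (!is.null(gene_biotype)) {
    if (length(gene_biotype) != nrow(counts))
      stop("gene_biotype must have one entry per gene", call. = FALSE)
    gene_biotype <- as.character(gene_biotype)
    names(gene_biotype) <- rownames(counts)
  }
  structure(list(counts = counts, library_sizes = library_sizes,
                 gene_biotype = gene_biotype),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("  library sizes:", paste(format(x$library_sizes, big.mark = ","),
                                collapse = ", "), "\n")
  if (!is.null(x$gene_biotype))
    cat("  biotypes:", paste(names(table(x$gene_biotype)), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

read_table_checked <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (format == "tsv") "\t" else ","
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Read a count matrix from TSV/CSV
#'
#' Expects gene ids in the first column (header `gene_id`) and one column
#' per sample. Duplicated ids and negative or fractional entries are hard
#' errors naming the offender.
#'
#' @param path file path.
#' @param format `"tsv"` (canonical) or `"csv"`.
#' @param library_sizes optional per-sample totals overriding column sums
#'   (e.g. pre-filter mapped-read totals).
#' @param gene_biotype optional per-gene biotype labels.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("tsv", "csv"),
                        library_sizes = NULL, gene_biotype = NULL) {
  df <- read_table_checked(path, format)
  if (ncol(df) < 2) stop("count table needs gene ids plus >= 1 sample",
                         call. = FALSE)
  ids <- norm_symbol(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate gene ids in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0)
      stop("non-integer or negative count at gene '", ids[bad[1]],
           "', sample '", names(body)[j], "'", call. = FALSE)
    body[[j]] <- v
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  count_matrix(m, library_sizes = library_sizes, gene_biotype = gene_biotype)
}

#' Write a count matrix to TSV
#'
#' @param cm a [count_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a donor/sample table
#'
#' TSV with columns `sample_id`, `group` (CS or SCO), `histology`, and the
#' donor covariates `age`, `weight_lbs`, `fsh_miu_ml`, `eggs_injected`,
#' `embryos`. Empty cells and the literal `No data` become `NA`.
#'
#' @param path TSV file path.
#' @return A data.frame, one row per sample.
#' @export
read_sample_table <- function(path) {
  df <- read_table_checked(path, "tsv")
  req <- c("sample_id", "group")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("sample table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sample_id <- trimws(as.character(df$sample_id))
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0)
    stop("duplicate sample ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  df$group <- toupper(trimws(as.character(df$group)))
  if (!all(df$group %in% c("CS", "SCO")))
    stop("group must be CS or SCO for every sample", call. = FALSE)
  for (col in c("age", "weight_lbs", "fsh_miu_ml", "eggs_injected",
                "embryos")) {
    if (col %in% names(df)) {
      v <- as.character(df[[col]])
      v[trimws(v) == "" | tolower(trimws(v)) == "no data"] <- NA
      df[[col]] <- suppressWarnings(as.numeric(v))
    }
  }
  df
}

check_samples_match <- function(cm, samples) {
  miss <- setdiff(colnames(cm$counts), samples$sample_id)
  if (length(miss) > 0)
    stop("samples absent from sample table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Read a per-cell-type reference expression table
#'
#' Gene-by-cell-type numeric table; columns are rescaled to CPM-like units
#' (sum 1e6) by the [cell_type_reference()] constructor.
#'
#' @param path TSV path (first column gene ids, remaining columns cell types).
#' @param panel_id `"rat5"` or `"human"`.
#' @param rescale rescale columns to sum 1e6 (default TRUE).
#' @return A [cell_type_reference()].
#' @export
read_reference <- function(path, panel_id = c("rat5", "human"),
                           rescale = TRUE) {
  panel_id <- match.arg(panel_id)
  df <- read_table_checked(path, "tsv")
  if (nrow(df) == 0) stop("empty reference table: ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- norm_symbol(df[[1]])
  cell_type_reference(m, panel_id, rescale = rescale)
}

#' Read a cell-composition table
#'
#' TSV with columns `cell_type`, `weight` and optionally `mrna_content`.
#' Zero weights are valid (a depleted cell type); negative weights are an
#' error.
#'
#' @param path TSV path.
#' @return A [cell_composition()].
#' @export
read_composition <- function(path) {
  df <- read_table_checked(path, "tsv")
  if (!all(c("cell_type", "weight") %in% names(df)))
    stop("composition table needs columns cell_type and weight",
         call. = FALSE)
  w <- as.numeric(df$weight)
  names(w) <- trimws(df$cell_type)
  s <- if ("mrna_content" %in% names(df)) as.numeric(df$mrna_content) else 1
  cell_composition(w, mrna_content = s)
}

#' Read an ortholog mapping table
#'
#' TSV with columns `rat_gene` and `human_gene`. Rat genes mapping to more
#' than one human symbol are retained but flagged multi-mapping; the
#' mapping filter in [map_orthologs()] acts on the flag.
#'
#' @param path TSV path.
#' @return A data.frame with columns `rat_gene`, `human_gene`, `multi`.
#' @export
read_orthologs <- function(path) {
  df <- read_table_checked(path, "tsv")
  if (!all(c("rat_gene", "human_gene") %in% names(df)))
    stop("ortholog table needs columns rat_gene and human_gene",
         call. = FALSE)
  out <- data.frame(rat_gene = norm_symbol(df$rat_gene),
                    human_gene = norm_symbol(df$human_gene),
                    stringsAsFactors = FALSE)
  n_targets <- tapply(out$human_gene, out$rat_gene,
                      function(x) length(unique(x)))
  out$multi <- unname(n_targets[out$rat_gene] > 1L)
  out
}

#' Read a plain gene-symbol list (one symbol per line)
#'
#' @param path text file path.
#' @return Upper-cased, de-duplicated character vector (first-seen order).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- norm_symbol(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Read every reference input declared in a named path list
#'
#' Convenience bundle loader for the signature screen: rat and human
#' reference panels, CS composition, ortholog table, manual augmentation
#' list and mouse Sertoli transcript list. Missing optional entries are
#' returned as `NULL`.
#'
#' @param paths named list with entries `rat_ref`, `human_ref`,
#'   `composition`, `orthologs`, and optionally `augment`, `mouse`.
#' @return Named list of loaded objects.
#' @export
read_reference_bundle <- function(paths) {
  req <- c("rat_ref", "human_ref", "composition", "orthologs")
  miss <- setdiff(req, names(paths))
  if (length(miss) > 0)
    stop("reference bundle missing path(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  list(
    rat_ref = read_reference(paths$rat_ref, "rat5"),
    human_ref = read_reference(paths$human_ref, "human"),
    composition = read_composition(paths$composition),
    orthologs = read_orthologs(paths$orthologs),
    augment = if (!is.null(paths$augment)) read_gene_list(paths$augment),
    mouse = if (!is.null(paths$mouse)) read_gene_list(paths$mouse)
  )
}

#' Write result tables with a JSON manifest
#'
#' Writes one TSV per named table (deterministic column order as given) and
#' a `manifest.json` recording file names, row counts, the configuration
#' hash and the seed. Refuses to overwrite an existing manifest unless
#' `force = TRUE`.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param config optional `sertoli_config` stamped into the manifest.
#' @param seed optional seed recorded in the manifest.
#' @param force overwrite an existing manifest.
#' @return The manifest, invisibly.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL,
                          force = FALSE) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force)
    stop("manifest already exists in ", out_dir,
         " (use force = TRUE to overwrite)", call. = FALSE)
  files <- list()
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    fname <- paste0(nm, ".tsv")
    write.table(tab, file.path(out_dir, fname), sep = "\t", quote = FALSE,
                row.names = FALSE)
    files[[nm]] <- list(file = fname, rows = nrow(tab))
  }
  manifest <- list(
    config_hash = if (!is.null(config)) config_hash(config) else NA,
    seed = if (!is.null(seed)) seed else NA,
    files = files,
    version = as.character(utils::packageVersion("sertolisig"))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Timestamped log line to standard error
#'
#' @param ... message parts, pasted.
#' @param verbose emit only when TRUE.
#' @export
sig_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose))
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  invisible(NULL)
}
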