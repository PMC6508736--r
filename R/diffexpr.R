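#' @importFrom stats median rnbinom rpois rlnorm pt var sd prcomp kmeans
#'   p.adjust dbinom
NULL

# Rescale counts to a common effective library size (geometric mean of
# library_size * TMM factor) and round half-to-even, so per-sample totals
# are exchangeable and the conditional exact test applies.
equalize_counts <- function(cm, tmm = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  eff <- cm$library_sizes
  if (!is.null(tmm)) eff <- eff * tmm
  common <- exp(mean(log(eff)))
  pseudo <- sweep(cm$counts, 2, common / eff, "*")
  round(pseudo)  # base round is half-to-even
}

#' Per-gene negative-binomial dispersion by moments
#'
#' Method-of-moments estimate on library-size-equalized pseudo-counts:
#' within each group `phi = max(0, (s^2 - mu) / mu^2)` (variance
#' `mu + phi mu^2`), pooled across groups with degrees-of-freedom weights,
#' then shrunk half-way toward the across-gene median (`w = 0.5`), a
#' deliberately simple stabilizer for small cohorts.
#'
#' @param cm a [count_matrix()].
#' @param groups factor/character of group labels, one per sample.
#' @param tmm optional TMM factors for the equalization.
#' @param shrink shrinkage weight toward the common (median) value.
#' @return data.frame with `gene_id`, `phi`, `phi_raw`, `method`.
#' @export
estimate_dispersion <- function(cm, groups, tmm = NULL, shrink = 0.5) {
  groups <- as.character(groups)
  if (any(table(groups) < 2))
    stop("need >= 2 samples per group", call. = FALSE)
  pseudo <- equalize_counts(cm, tmm)
  lv <- unique(groups)
  num <- matrix(0, nrow(pseudo), length(lv))
  df <- numeric(length(lv))
  for (i in seq_along(lv)) {
    sub <- pseudo[, groups == lv[i], drop = FALSE]
    mu <- rowMeans(sub)
    s2 <- apply(sub, 1, var)
    phi_g <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
    num[, i] <- phi_g
    df[i] <- ncol(sub) - 1
  }
  phi_raw <- as.numeric(num %*% df / sum(df))
  common <- median(phi_raw)
  phi <- (1 - shrink) * phi_raw + shrink * common
  data.frame(gene_id = rownames(pseudo), phi = phi, phi_raw = phi_raw,
             method = "moments", stringsAsFactors = FALSE)
}

# Two-sided conditional exact p-value for an NB split.
# Conditional on the total T, the group-1 sum of n1 iid NB(mu, phi) counts
# (against n2 in group 2, equal per-sample means) is beta-binomial with
# shape r1 = n1/phi, r2 = n2/phi; at phi = 0 it degenerates to
# Binomial(T, n1/(n1+n2)). p = sum of probabilities of all splits at most
# as probable as the observed one (minimum-likelihood two-sided rule).
# For large T the enumeration window is clipped to mean +/- 50 sd; the
# excluded tail mass is far below double precision.
exact_nb_pvalue <- function(s1, total, n1, n2, phi) {
  if (total == 0) return(1)
  if (phi < 0 || !is.finite(phi)) stop("phi must be finite and >= 0")
  p1 <- n1 / (n1 + n2)
  if (phi == 0) {
    mu <- total * p1
    sdv <- sqrt(total * p1 * (1 - p1))
  } else {
    r1 <- n1 / phi; r2 <- n2 / phi; r <- r1 + r2
    mu <- total * r1 / r
    sdv <- sqrt(total * (r1 * r2 / r^2) * (total + r) / (r + 1))
  }
  lo <- max(0, floor(mu - 50 * sdv) - 1)
  hi <- min(total, ceiling(mu + 50 * sdv) + 1)
  x <- lo:hi
  if (phi == 0) {
    logp <- dbinom(x, total, p1, log = TRUE)
    logp_obs <- dbinom(s1, total, p1, log = TRUE)
  } else {
    bb <- function(k) {
      lgamma(k + r1) - lgamma(k + 1) - lgamma(r1) +
        lgamma(total - k + r2) - lgamma(total - k + 1) - lgamma(r2) -
        (lgamma(total + r) - lgamma(total + 1) - lgamma(r1 + r2))
    }
    logp <- bb(x)
    logp_obs <- bb(s1)
  }
  min(1, sum(exp(logp[logp <= logp_obs + 1e-8])))
}

#' Negative-binomial conditional exact test, two groups
#'
#' Counts are equalized to a common effective library size (TMM-scaled,
#' rounded half-to-even), summed within groups, and each gene's split of
#' the total pseudo-count between groups is tested against its conditional
#' beta-binomial law under equal per-sample means (see
#' [estimate_dispersion()] for the dispersion). `T = 0` gives `p = 1` by
#' convention. Returns p-values only; apply [bh_fdr()] and
#' [classify_de()] downstream.
#'
#' @param cm a [count_matrix()].
#' @param groups group labels, one per sample; `cs_level` marks the
#'   reference (CS) group.
#' @param dispersion data.frame from [estimate_dispersion()], or a single
#'   phi recycled over genes.
#' @param tmm optional TMM factors.
#' @param cs_level label of the reference group (default `"CS"`).
#' @param prior pseudo-CPM for the fold-change ratio.
#' @return data.frame with `gene_id`, `mean_cs`, `mean_sco`, `log_fc`,
#'   `p_value` (means in CPM; `log_fc = log2((mean_sco + prior) /
#'   (mean_cs + prior))`).
#' @export
nb_exact_test <- function(cm, groups, dispersion, tmm = NULL,
                          cs_level = "CS", prior = 1.0) {
  groups <- as.character(groups)
  if (length(unique(groups)) != 2)
    stop("exactly two groups required", call. = FALSE)
  if (!cs_level %in% groups)
    stop("cs_level '", cs_level, "' not found in groups", call. = FALSE)
  is_cs <- groups == cs_level
  n1 <- sum(is_cs); n2 <- sum(!is_cs)
  pseudo <- equalize_counts(cm, tmm)
  s1 <- rowSums(pseudo[, is_cs, drop = FALSE])
  s2 <- rowSums(pseudo[, !is_cs, drop = FALSE])
  if (is.data.frame(dispersion)) {
    phi <- dispersion$phi[match(rownames(pseudo), dispersion$gene_id)]
    if (any(is.na(phi)))
      stop("dispersion missing for some genes", call. = FALSE)
  } else {
    phi <- rep(as.numeric(dispersion), nrow(pseudo))
  }
  pv <- vapply(seq_len(nrow(pseudo)), function(i)
    exact_nb_pvalue(s1[i], s1[i] + s2[i], n1, n2, phi[i]), numeric(1))
  cpm <- compute_cpm(cm, tmm = tmm)$values
  mean_cs <- rowMeans(cpm[, is_cs, drop = FALSE])
  mean_sco <- rowMeans(cpm[, !is_cs, drop = FALSE])
  data.frame(gene_id = rownames(pseudo),
             mean_cs = mean_cs, mean_sco = mean_sco,
             log_fc = log2((mean_sco + prior) / (mean_cs + prior)),
             p_value = pv, stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Attach FDR and a direction call to a DE table
#'
#' Direction is `ns` unless the significance rule holds: in `nb` mode
#' strictly `fdr < cfg$fdr_max`; in `ttest` mode `p <= cfg$ttest_alpha`
#' (inclusive). Significant genes are split by the sign of `log_fc` into
#' `up_in_sco` / `down_in_sco`.
#'
#' @param de data.frame from [nb_exact_test()] or [group_ttest()].
#' @param cfg a [sertoli_config()].
#' @param mode `"nb"` (FDR rule) or `"ttest"` (alpha rule).
#' @return `de` with columns `fdr` and `direction` added.
#' @export
classify_de <- function(de, cfg = sertoli_config(),
                        mode = c("nb", "ttest")) {
  mode <- match.arg(mode)
  de$fdr <- bh_fdr(de$p_value)
  sig <- if (mode == "nb") de$fdr < cfg$fdr_max
         else de$p_value <= cfg$ttest_alpha
  de$direction <- ifelse(!sig, "ns",
                         ifelse(de$log_fc > 0, "up_in_sco", "down_in_sco"))
  de
}

#' Two-sample t-tests on actin-ratio values
#'
#' Two-tailed Welch (default) or pooled-variance Student t-test per gene.
#' Degenerate genes with zero variance in both groups get `p = 1` when the
#' means agree and `p = 0` otherwise.
#'
#' @param em `expression_matrix` in state `actin_ratio` (any state is
#'   accepted for reuse on median-scaled panels).
#' @param groups group labels, one per sample.
#' @param cfg a [sertoli_config()] (`ttest_var` picks the flavor).
#' @param cs_level reference group label.
#' @param prior pseudo value for the fold-change ratio.
#' @return data.frame with `gene_id`, `mean_cs`, `mean_sco`, `log_fc`,
#'   `t_stat`, `p_value`.
#' @export
group_ttest <- function(em, groups, cfg = sertoli_config(),
                        cs_level = "CS", prior = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  groups <- as.character(groups)
  is_cs <- groups == cs_level
  n1 <- sum(is_cs); n2 <- sum(!is_cs)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group", call. = FALSE)
  v <- em$values
  x <- v[, is_cs, drop = FALSE]
  y <- v[, !is_cs, drop = FALSE]
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, var); v2 <- apply(y, 1, var)
  if (cfg$ttest_var == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  }
  tstat <- (m2 - m1) / sqrt(se2)
  pv <- 2 * pt(-abs(tstat), df)
  zero <- se2 == 0
  tstat[zero] <- ifelse(m1[zero] == m2[zero], 0, Inf * sign(m2 - m1)[zero])
  pv[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  if (is.null(prior)) prior <- 0
  data.frame(gene_id = rownames(v), mean_cs = m1, mean_sco = m2,
             log_fc = log2((m2 + prior) / (m1 + prior)),
             t_stat = tstat, p_value = pv,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percent-of-CS expression
#'
#' `100 * mean_sco / mean_cs` per gene; undefined (NA) where the CS mean
#' is zero.
#'
#' @param de DE table with `mean_cs` and `mean_sco`.
#' @return `de` with a `percent_of_cs` column added.
#' @export
ratio_percent <- function(de) {
  de$percent_of_cs <- ifelse(de$mean_cs > 0,
                             100 * de$mean_sco / de$mean_cs, NA_real_)
  de
}

#' MA and volcano diagnostic tables
#'
#' Long-format tables backing the post-filter diagnostic check: average
#' log2 expression (A) against logFC, and logFC against -log10 FDR. Genes
#' with `|logFC| > 5` at mean CPM < 1 are flagged as low-expression
#' outliers; an abundance of such genes indicates a too-lenient expression
#' filter.
#'
#' @param de classified DE table (with `fdr`).
#' @param prior pseudo-CPM inside the A value.
#' @return list of data.frames `ma` and `volcano`, each with an `outlier`
#'   flag.
#' @export
ma_volcano_tables <- function(de, prior = 1.0) {
  if (nrow(de) == 0) {
    empty_ma <- data.frame(gene_id = character(0), a_value = numeric(0),
                           log_fc = numeric(0), outlier = logical(0))
    empty_v <- data.frame(gene_id = character(0), log_fc = numeric(0),
                          neg_log10_fdr = numeric(0), outlier = logical(0))
    return(list(ma = empty_ma, volcano = empty_v))
  }
  mean_cpm <- (de$mean_cs + de$mean_sco) / 2
  outlier <- abs(de$log_fc) > 5 & mean_cpm < 1
  a_val <- 0.5 * (log2(de$mean_cs + prior) + log2(de$mean_sco + prior))
  fdr <- if ("fdr" %in% names(de)) de$fdr else bh_fdr(de$p_value)
  list(
    ma = data.frame(gene_id = de$gene_id, a_value = a_val,
                    log_fc = de$log_fc, outlier = outlier,
                    stringsAsFactors = FALSE),
    volcano = data.frame(gene_id = de$gene_id, log_fc = de$log_fc,
                         neg_log10_fdr = -log10(pmax(fdr, 1e-300)),
                         outlier = outlier, stringsAsFactors = FALSE)
  )
}
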