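#' Round half away from zero
#'
#' Decimal rounding with the half-up tie rule (0.5 rounds away from
#' zero), as used in the printed donor summaries; base R's `round()`
#' rounds half to even. A tiny epsilon guards against binary
#' representation error in decimal inputs.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Donor cohort summary
#'
#' Group-wise arithmetic means of the donor covariates with explicit
#' missing-data and rounding rules: means are taken over non-missing
#' values only (e.g. a donor with no recorded FSH is skipped for that
#' field); age and weight are rounded half-up to 1 decimal, FSH to 2
#' decimals; eggs injected and embryos are reported both at 2 decimals
#' and rounded to the nearest integer (the convention the printed table
#' mixes across groups). A field with every value missing is `NA` with a
#' full missing count.
#'
#' @param samples sample table (see [read_sample_table()]) with columns
#'   `group`, `age`, `weight_lbs`, `fsh_miu_ml`, `eggs_injected`,
#'   `embryos`.
#' @return data.frame of class `cohort_summary`, one row per group.
#' @export
summarize_cohort <- function(samples) {
  stopifnot(is.data.frame(samples), "group" %in% names(samples))
  groups <- unique(samples$group)
  if (any(table(samples$group) == 0) || length(groups) == 0)
    stop("each group needs at least one donor", call. = FALSE)
  fields <- c(age = 1, weight_lbs = 1, fsh_miu_ml = 2,
              eggs_injected = 2, embryos = 2)
  rows <- lapply(groups, function(g) {
    sub <- samples[samples$group == g, , drop = FALSE]
    out <- list(group = g, n = nrow(sub))
    for (f in names(fields)) {
      v <- if (f %in% names(sub)) sub[[f]] else rep(NA_real_, nrow(sub))
      ok <- !is.na(v)
      out[[paste0("mean_", f)]] <-
        if (any(ok)) round_half_up(mean(v[ok]), fields[[f]]) else NA_real_
      out[[paste0("missing_", f)]] <- sum(!ok)
    }
    out$mean_eggs_injected_int <-
      if (!is.na(out$mean_eggs_injected))
        round_half_up(out$mean_eggs_injected, 0) else NA_real_
    out$mean_embryos_int <-
      if (!is.na(out$mean_embryos))
        round_half_up(out$mean_embryos, 0) else NA_real_
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("cohort_summary", class(res))
  res
}
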