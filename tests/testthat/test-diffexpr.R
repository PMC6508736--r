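test_that("moments dispersion follows its defining formula", {
  m <- rbind(REP = c(10L, 10L, 10L, 10L),
             VAR = c(5L, 15L, 5L, 15L),
             ZERO = c(0L, 0L, 0L, 0L))
  colnames(m) <- c("C1", "C2", "S1", "S2")
  cm <- count_matrix(m, library_sizes = rep(100, 4))  # equal -> no rescale
  d <- estimate_dispersion(cm, c("CS", "CS", "SCO", "SCO"))
  expect_equal(d$phi_raw[d$gene_id == "REP"], 0)
  # mu = 10, s^2 = 50 in both groups -> raw phi = (50 - 10) / 100 = 0.4
  expect_equal(d$phi_raw[d$gene_id == "VAR"], 0.4)
  expect_equal(d$phi_raw[d$gene_id == "ZERO"], 0)
  # shrinkage halves the distance to the median raw value
  med <- median(d$phi_raw)
  expect_equal(d$phi, 0.5 * d$phi_raw + 0.5 * med)
})

test_that("Poisson data yields near-zero dispersion estimates", {
  set.seed(11)
  m <- matrix(rpois(1000 * 8, 50), 1000, 8,
              dimnames = list(sprintf("G%04d", 1:1000),
                              paste0("S", 1:8)))
  cm <- count_matrix(m, library_sizes = rep(sum(m) / 8, 8))
  d <- estimate_dispersion(cm, rep(c("CS", "SCO"), each = 4))
  expect_lte(median(d$phi_raw), 0.05)
})

test_that("exact NB p-values match brute-force conditional enumeration", {
  for (phi in c(0, 0.1, 0.5)) {
    for (total in c(0, 1, 4, 6, 13, 30)) {
      for (s1 in 0:total) {
        expect_equal(
          sertolisig:::exact_nb_pvalue(s1, total, 4, 7, phi),
          brute_nb_pvalue(s1, total, 4, 7, phi),
          tolerance = 1e-12,
          label = sprintf("p(s1=%d, T=%d, phi=%g)", s1, total, phi))
      }
    }
  }
  # symmetric groups, observation at the mode: every split is at most as
  # probable, so the two-sided mass is 1
  expect_equal(sertolisig:::exact_nb_pvalue(5, 10, 2, 2, 0), 1)
  expect_equal(sertolisig:::exact_nb_pvalue(0, 0, 4, 7, 0.5), 1)
})

test_that("at phi = 0 the conditional test is the exact binomial test", {
  for (total in c(4, 9, 17)) {
    for (s1 in 0:total) {
      expect_equal(sertolisig:::exact_nb_pvalue(s1, total, 2, 2, 0),
                   binom.test(s1, total, 0.5)$p.value, tolerance = 1e-12)
      expect_equal(sertolisig:::exact_nb_pvalue(s1, total, 4, 7, 0),
                   binom.test(s1, total, 4 / 11)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("nb_exact_test returns coherent per-gene tables", {
  cm <- make_counts(40, 11, seed = 8)
  groups <- rep(c("CS", "SCO"), c(4, 7))
  d <- estimate_dispersion(cm, groups)
  de <- nb_exact_test(cm, groups, d)
  expect_equal(nrow(de), 40)
  expect_true(all(de$p_value >= 0 & de$p_value <= 1))
  de2 <- classify_de(de)
  expect_true(all(de2$direction %in% c("ns", "up_in_sco", "down_in_sco")))
  expect_true(all(de2$direction[de2$fdr >= 0.05] == "ns"))
})

test_that("BH step-up matches hand evaluation and stays monotone", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) > -1e-12))
  }
})

test_that("group t-tests handle symmetry and degenerate variance", {
  v <- rbind(SAME = c(1, 2, 3, 1, 2, 3),
             SHIFT = c(1, 2, 3, 4, 5, 6),
             CONST = c(2, 2, 2, 2, 2, 2),
             CONST2 = c(2, 2, 2, 5, 5, 5))
  colnames(v) <- c(paste0("C", 1:3), paste0("S", 1:3))
  em <- expression_matrix(v, "actin_ratio")
  groups <- rep(c("CS", "SCO"), each = 3)
  tt <- group_ttest(em, groups)
  expect_equal(tt$t_stat[tt$gene_id == "SAME"], 0)
  expect_equal(tt$p_value[tt$gene_id == "SAME"], 1)
  # closed-form Welch check: means 2 vs 5, var 1 each, n = 3:
  # t = 3 / sqrt(2/3), df = 4
  t_exp <- 3 / sqrt(2 / 3)
  expect_equal(tt$t_stat[tt$gene_id == "SHIFT"], t_exp)
  expect_equal(tt$p_value[tt$gene_id == "SHIFT"], 2 * pt(-t_exp, 4))
  expect_equal(tt$p_value[tt$gene_id == "CONST"], 1)
  expect_equal(tt$p_value[tt$gene_id == "CONST2"], 0)
  # label swap flips t, keeps p
  tt2 <- group_ttest(em, rep(c("SCO", "CS"), each = 3), cs_level = "CS")
  expect_equal(tt2$p_value, tt$p_value)
  expect_equal(tt2$t_stat[tt$gene_id == "SHIFT"], -t_exp)
})

test_that("percent-of-CS is the ratio of means and scale-invariant", {
  de <- data.frame(gene_id = c("A", "B", "C"),
                   mean_cs = c(25, 10, 0), mean_sco = c(2, 10, 5))
  rp <- ratio_percent(de)
  expect_equal(rp$percent_of_cs, c(8, 100, NA))
  de2 <- de; de2$mean_cs <- de$mean_cs * 3; de2$mean_sco <- de$mean_sco * 3
  expect_equal(ratio_percent(de2)$percent_of_cs, rp$percent_of_cs)
})

test_that("MA/volcano tables flag planted low-expression outliers", {
  empty <- ma_volcano_tables(data.frame(gene_id = character(0),
                                        mean_cs = numeric(0),
                                        mean_sco = numeric(0),
                                        log_fc = numeric(0),
                                        p_value = numeric(0)))
  expect_equal(nrow(empty$ma), 0)
  expect_equal(nrow(empty$volcano), 0)
  de <- data.frame(gene_id = c("OK1", "OK2", "OUT"),
                   mean_cs = c(100, 50, 0.01),
                   mean_sco = c(110, 45, 0.9),
                   log_fc = c(0.1, -0.2, 6.5),
                   p_value = c(0.5, 0.6, 0.01))
  tabs <- ma_volcano_tables(de)
  expect_equal(sum(tabs$ma$outlier), 1)
  expect_equal(tabs$volcano$gene_id[tabs$volcano$outlier], "OUT")
})
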