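test_that("the generator is reproducible from its seed", {
  a <- simulate_references(n_genes = 200, n_signature = 15, seed = 8)
  b <- simulate_references(n_genes = 200, n_signature = 15, seed = 8)
  expect_identical(a$rat_ref$expr, b$rat_ref$expr)
  expect_identical(a$truth$signature_genes, b$truth$signature_genes)
  ca <- simulate_cohort(a, lib_size = 1e5, seed = 8)
  cb <- simulate_cohort(b, lib_size = 1e5, seed = 8)
  expect_identical(ca$counts$counts, cb$counts$counts)
})

test_that("truth genes pass the rat screen and decoys fail it", {
  refs <- simulate_references(n_genes = 600, n_signature = 40,
                              enrichment = 8, seed = 14)
  kept <- rat_screen(refs$rat_ref, fold = 4)
  rat_truth <- toupper(paste0("R-", refs$truth$signature_genes))
  expect_nested(rat_truth, kept)
  rat_decoys <- toupper(paste0("R-", refs$truth$decoy_genes))
  expect_length(intersect(rat_decoys, kept), 0)
  expect_error(simulate_references(enrichment = 1), "exceed")
  expect_error(simulate_references(n_genes = 10, n_signature = 10),
               "smaller")
})

test_that("reference columns are CPM-scaled and mixtures conserve mass", {
  refs <- simulate_references(n_genes = 300, n_signature = 20, seed = 2)
  expect_equal(unname(colSums(refs$rat_ref$expr)), rep(1e6, 5),
               tolerance = 1e-6)
  expect_equal(unname(colSums(refs$human_ref$expr)), rep(1e6, 4),
               tolerance = 1e-6)
  expect_equal(sum(refs$sertoli_profile), 1e6, tolerance = 1e-6)
  for (g in c("CS", "SCO"))
    expect_equal(sum(expected_mixture(refs, default_composition(g))), 1e6,
                 tolerance = 1e-6)
})

test_that("most truth genes satisfy the 60% share criterion by design", {
  refs <- simulate_references(seed = 17)
  comp <- default_composition("CS")
  mix <- expected_mixture(refs, comp)
  est <- estimate_sertoli(mix[refs$truth$signature_genes],
                          refs$human_ref, comp)
  expect_gte(mean(est$sertoli_fraction >= 0.6), 0.95)
})

test_that("phi = 0 cohorts are Poisson and germ-exclusive genes vanish", {
  refs <- simulate_references(n_genes = 30, n_signature = 1, seed = 6)
  coh <- simulate_cohort(refs, n_cs = 5000, n_sco = 2, lib_size = 1e5,
                         phi = 0, lib_sdlog = 0, seed = 6)
  counts <- coh$counts$counts[, 1:5000]
  vm <- apply(counts, 1, var) / rowMeans(counts)
  expect_true(all(vm > 0.95 & vm < 1.05))
  # a germ-only gene under a germ-free composition draws Poisson(0) = 0
  expr <- rbind(GERM = c(Leydig = 0, round_spermatids = 10),
                SOMA = c(Leydig = 10, round_spermatids = 0))
  refs2 <- list(human_ref = cell_type_reference(expr, "human",
                                                rescale = FALSE),
                sertoli_profile = c(GERM = 0, SOMA = 5),
                truth = structure(list(signature_genes = character(0),
                                       params = list()),
                                  class = "synthetic_truth"))
  comp_sco <- cell_composition(c(Sertoli = 0.6, Leydig = 0.4,
                                 round_spermatids = 0))
  coh2 <- simulate_cohort(refs2, comp_cs = comp_sco, comp_sco = comp_sco,
                          n_cs = 2, n_sco = 20, lib_size = 1e4, phi = 0,
                          lib_sdlog = 0, seed = 1)
  expect_true(all(coh2$counts$counts["GERM", ] == 0))
  expect_true(any(coh2$counts$counts["SOMA", ] > 0))
})

test_that("simulated mean CPM converges to the generating mixture", {
  refs <- simulate_references(n_genes = 100, n_signature = 3, seed = 27)
  coh <- simulate_cohort(refs, n_cs = 4000, n_sco = 2, lib_size = 1e6,
                         phi = 0.1, lib_sdlog = 0, seed = 27)
  cs_ids <- coh$samples$sample_id[coh$samples$group == "CS"]
  mean_cpm <- rowMeans(compute_cpm(coh$counts)$values[, cs_ids])
  sel <- coh$mix_cs >= 10
  rel <- abs(mean_cpm[sel] / coh$mix_cs[sel] - 1)
  expect_true(all(rel < 0.02))
})

test_that("recovery metrics score calls against designated truth", {
  truth <- structure(list(signature_genes = c("A", "B"),
                          mix_cs = setNames(numeric(4),
                                            c("A", "B", "C", "D"))),
                     class = "synthetic_truth")
  perfect <- evaluate_recovery(c("A", "B"), truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  none <- evaluate_recovery(character(0), truth)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  mixed <- evaluate_recovery(c("A", "C"), truth)
  expect_equal(mixed$sensitivity, 0.5)
  expect_equal(mixed$specificity, 0.5)
  expect_equal(sum(mixed$confusion), 4)
})
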