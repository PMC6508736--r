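test_that("rat screen keeps genes at or above the fold boundary", {
  expr <- rbind(AT_BOUNDARY = c(40, 10, 9, 8, 7),
                BELOW       = c(39.9, 10, 9, 8, 7),
                ZERO_OTHERS = c(3, 0, 0, 0, 0),
                ALL_ZERO    = c(0, 0, 0, 0, 0))
  colnames(expr) <- rat5_cell_types()
  ref <- cell_type_reference(expr, "rat5", rescale = FALSE)
  kept <- rat_screen(ref, fold = 4)
  expect_setequal(kept, c("AT_BOUNDARY", "ZERO_OTHERS"))
  bad <- cell_type_reference(expr[, -1], "human", rescale = FALSE)
  expect_error(rat_screen(bad), "Sertoli")
})

test_that("rat screen equals a brute-force row filter on random panels", {
  refs <- simulate_references(n_genes = 500, n_signature = 30, seed = 21)
  expect_setequal(rat_screen(refs$rat_ref, 4),
                  brute_rat_screen(refs$rat_ref$expr, 4))
})

test_that("ortholog mapping passes only one-to-one pairs", {
  orth <- data.frame(rat_gene = c("GDNF", "WT1", "WT1"),
                     human_gene = c("GDNF", "WT1", "WT1B"))
  res <- map_orthologs(c("GDNF", "WT1", "NOVEL"), orth)
  expect_identical(res$human_genes, "GDNF")
  expect_equal(res$report$status,
               c("mapped", "multi", "unmapped"))
})

test_that("augmentation is an order-preserving set union", {
  expect_identical(as.character(augment_candidates(c("A", "B"),
                                                   c("B", "C"))),
                   c("A", "B", "C"))
  expect_identical(attr(augment_candidates(c("A", "B"), c("B", "C")),
                        "duplicates"), "B")
  expect_identical(as.character(augment_candidates(c("A", "B"))),
                   c("A", "B"))
})

test_that("subtraction recovers the Sertoli term on a hand example", {
  ref <- make_tiny_ref()
  comp <- tiny_comp()
  # GA: nonSertoli = .2*10 + .3*5 + .3*1 = 3.8; total 10 -> S = 6.2
  est <- estimate_sertoli(c(GA = 10, GB = 3, GX = 4), ref, comp)
  expect_equal(est$nonsertoli_contribution, c(3.8, 6, 0))
  expect_equal(est$sertoli_amount, c(6.2, 0, 4))  # GB floored at 0
  expect_equal(est$sertoli_fraction, c(0.62, 0, 1))
  expect_equal(est$sertoli_percell, c(6.2, 0, 4) / 0.2)
  expect_false(est$in_reference[3])
  # T = 0 gives fraction 0
  est0 <- estimate_sertoli(c(GA = 0), ref, comp)
  expect_equal(est0$sertoli_fraction, 0)
  comp0 <- cell_composition(c(Leydig = 0.5, spermatogonia = 0.25,
                              round_spermatids = 0.25))
  expect_error(estimate_sertoli(c(GA = 1), ref, comp0), "Sertoli")
})

test_that("noiseless mixtures are deconvolved exactly", {
  refs <- simulate_references(n_genes = 400, n_signature = 25, seed = 13)
  comp <- default_composition("CS")
  mix <- expected_mixture(refs, comp)
  est <- estimate_sertoli(mix, refs$human_ref, comp)
  truth_amount <- comp$fractions[["Sertoli"]] * refs$sertoli_profile
  expect_equal(est$sertoli_amount, unname(truth_amount[est$gene_id]),
               tolerance = 1e-9)
  expect_true(all(est$sertoli_fraction >= 0 & est$sertoli_fraction <= 1))
})

test_that("criteria boundaries are inclusive for a/b and strict for c", {
  expr <- rbind(G1 = c(Leydig = 5, round_spermatids = 2),
                G2 = c(Leydig = 5, round_spermatids = 10))
  ref <- cell_type_reference(expr, "human", rescale = FALSE)
  comp <- cell_composition(c(Sertoli = 0.5, Leydig = 0.25,
                             round_spermatids = 0.25))
  # choose totals so that G1: fraction exactly 0.6, percell exactly 2x Leydig
  # S = percell * f_S = 10 * 0.5 = 5; nonS = .25*5 + .25*2 = 1.75
  # total = S / 0.6 -> nonS_needed = total - S; craft total accordingly
  est <- data.frame(gene_id = c("G1", "G2"),
                    total_cpm = c(5 / 0.6, 10),
                    nonsertoli_contribution = c(5 / 0.6 - 5, 5),
                    sertoli_amount = c(5, 5),
                    sertoli_fraction = c(0.6, 0.5),
                    sertoli_percell = c(10, 10),
                    in_reference = TRUE)
  calls <- call_signatures(est, ref)
  # G1: fraction == 0.6 passes (a); percell == 2 * 5 passes (b);
  # percell 10 > spermatid 2 passes (c)
  expect_true(calls$is_signature[1])
  # G2: percell == spermatid level 10 -> criterion (c) strict, fails
  expect_true(calls$pass_b[2])
  expect_false(calls$pass_c[2])
  expect_false(calls$is_signature[2])
})

test_that("calls are invariant to reference column order", {
  refs <- simulate_references(n_genes = 300, n_signature = 20, seed = 31)
  comp <- default_composition("CS")
  mix <- expected_mixture(refs, comp)
  scr1 <- sertoli_screen(mix, refs$rat_ref, refs$human_ref, comp,
                         refs$orthologs)
  perm_ref <- cell_type_reference(
    refs$human_ref$expr[, rev(colnames(refs$human_ref$expr))],
    "human", rescale = FALSE)
  rat_perm <- cell_type_reference(
    refs$rat_ref$expr[, sample(colnames(refs$rat_ref$expr))],
    "rat5", rescale = FALSE)
  scr2 <- sertoli_screen(mix, rat_perm, perm_ref, comp, refs$orthologs)
  expect_setequal(scr1$signature_genes, scr2$signature_genes)
})

test_that("raising any threshold never enlarges the called set", {
  refs <- simulate_references(n_genes = 400, n_signature = 30, seed = 23)
  comp <- default_composition("CS")
  mix <- expected_mixture(refs, comp)
  call_with <- function(...) {
    sertoli_screen(mix, refs$rat_ref, refs$human_ref, comp,
                   refs$orthologs, cfg = sertoli_config(...))$signature_genes
  }
  prev <- NULL
  for (fold in c(2, 3, 4, 6, 8)) {
    cur <- call_with(rat_fold = fold)
    if (!is.null(prev)) expect_nested(cur, prev)
    prev <- cur
  }
  prev <- NULL
  for (fr in c(0.4, 0.5, 0.6, 0.75, 0.9)) {
    cur <- call_with(sertoli_fraction_min = fr)
    if (!is.null(prev)) expect_nested(cur, prev)
    prev <- cur
  }
  prev <- NULL
  for (rat in c(1, 1.5, 2, 3, 5)) {
    cur <- call_with(sertoli_leydig_ratio_min = rat)
    if (!is.null(prev)) expect_nested(cur, prev)
    prev <- cur
  }
})

test_that("mouse overlap is a case-insensitive intersection", {
  ov <- mouse_overlap(c("A", "B", "C"), c("b", "c", "D"))
  expect_setequal(ov$intersection, c("B", "C"))
  expect_equal(ov$count, 2)
  expect_equal(mouse_overlap(c("A", "B"), c("X", "Y"))$count, 0)
  syms <- sprintf("G%03d", 1:500)
  expect_equal(mouse_overlap(syms, syms)$fraction, 1)
})

test_that("screen object methods report consistent stage counts", {
  refs <- simulate_references(n_genes = 300, n_signature = 20, seed = 5)
  comp <- default_composition("CS")
  mix <- expected_mixture(refs, comp)
  scr <- sertoli_screen(mix, refs$rat_ref, refs$human_ref, comp,
                        refs$orthologs, mouse_list = refs$mouse_list)
  s <- summary(scr)
  expect_equal(s$n_signature, length(scr$signature_genes))
  expect_equal(s$n_candidates, length(scr$candidates))
  expect_lte(s$n_mapped, s$n_candidates)
  expect_equal(sum(as.data.frame(scr)$is_signature), s$n_signature)
  expect_output(print(scr), "signature transcripts called")
  expect_output(print(s), "Signature screen summary")
})
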