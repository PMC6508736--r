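test_that("CPM is counts over library size times one million", {
  m <- matrix(c(4L, 6L), 2, 1, dimnames = list(c("A", "B"), "S1"))
  cm <- count_matrix(m, library_sizes = 10)
  expect_equal(unname(compute_cpm(cm)$values[, 1]), c(4e5, 6e5))
  one <- count_matrix(matrix(7L, 1, 1, dimnames = list("A", "S1")))
  expect_equal(unname(compute_cpm(one)$values[1, 1]), 1e6)
})

test_that("CPM columns sum to 1e6 when library sizes are column sums", {
  cm <- make_counts(50, 4)
  expect_equal(unname(colSums(compute_cpm(cm)$values)), rep(1e6, 4))
})

test_that("expression filter applies strict CPM and library-count rules", {
  v <- rbind(boundary_pass = c(0.41, 0.41, 0.0, 0.0),
             boundary_fail = c(0.4, 0.4, 0.4, 0.4),
             one_library   = c(9.0, 0.0, 0.0, 0.0),
             strong        = c(5, 5, 5, 5))
  colnames(v) <- paste0("C", 1:4)
  em <- expression_matrix(v, "raw_cpm")
  kept <- filter_expressed(em, paste0("C", 1:4))
  expect_setequal(kept, c("BOUNDARY_PASS", "STRONG"))
  expect_error(filter_expressed(em, "C1"), "min_cs_libraries")
})

test_that("non-mRNA genes are purged when biotypes are known", {
  v <- rbind(CODING = c(5, 5), LINC = c(5, 5))
  colnames(v) <- c("C1", "C2")
  em <- expression_matrix(v, "raw_cpm")
  bt <- c(CODING = "protein_coding", LINC = "lincRNA")
  expect_identical(filter_expressed(em, c("C1", "C2"), gene_biotype = bt),
                   "CODING")
})

test_that("TMM factors are 1 for identical or depth-scaled samples", {
  cm <- make_counts(100, 2)
  same <- count_matrix(cbind(A = cm$counts[, 1], B = cm$counts[, 1]))
  expect_equal(unname(tmm_factors(same)), c(1, 1))
  doubled <- count_matrix(cbind(A = cm$counts[, 1], B = 2 * cm$counts[, 1]))
  expect_equal(unname(tmm_factors(doubled)), c(1, 1))
})

test_that("TMM factors match the brute-force trimmed weighted mean", {
  cm <- make_counts(200, 4, seed = 42)
  counts <- cm$counts
  counts[1:10, 2] <- counts[1:10, 2] * 8  # composition shift in sample B
  cm <- count_matrix(counts)
  expect_equal(tmm_factors(cm), brute_tmm(counts, cm$library_sizes),
               tolerance = 1e-6)
  # invariance to gene order
  perm <- sample(nrow(counts))
  cm_p <- count_matrix(counts[perm, ], library_sizes = cm$library_sizes)
  expect_equal(tmm_factors(cm_p), tmm_factors(cm), tolerance = 1e-12)
})

test_that("log2 transform adds the prior and checks its sign", {
  v <- matrix(c(0, 1, 7), 3, 1, dimnames = list(c("A", "B", "C"), "S1"))
  em <- expression_matrix(v, "tmm_cpm")
  expect_equal(unname(log2_transform(em, prior = 1)$values[, 1]),
               c(0, 1, 3))
  expect_error(log2_transform(em, prior = -1), "non-negative")
  expect_error(log2_transform(expression_matrix(v, "raw_cpm")),
               "tmm_cpm")
})

test_that("actin normalization divides by the per-sample actin CPM", {
  v <- rbind(ACTB = c(100, 200), GDNF = c(50, 50))
  colnames(v) <- c("C1", "SCO1")
  em <- expression_matrix(v, "raw_cpm")
  an <- actin_normalize(em)
  expect_equal(unname(an$values["GDNF", ]), c(0.5, 0.25))
  expect_equal(unname(an$values["ACTB", ]), c(1, 1))
  v0 <- v; v0["ACTB", 2] <- 0
  expect_error(actin_normalize(expression_matrix(v0, "raw_cpm")), "SCO1")
  expect_error(actin_normalize(em, "VIM"), "VIM")
})

test_that("median rescaling equalizes per-sample panel medians", {
  v <- rbind(A = c(5, 10), B = c(10, 20), C = c(20, 40))
  colnames(v) <- c("S1", "S2")
  em <- expression_matrix(v, "tmm_cpm")
  sc <- median_scale_signature(em, c("A", "B", "C"))
  # sample medians 10 and 20 -> target 15, factors 1.5 and 0.75
  expect_equal(unname(sc$values["B", ]), c(15, 15))
  expect_equal(unname(sc$values["A", ]), c(7.5, 7.5))
  # idempotent
  sc2 <- median_scale_signature(sc, c("A", "B", "C"))
  expect_equal(sc2$values, sc$values, tolerance = 1e-12)
  # single sample unchanged
  one <- expression_matrix(v[, 1, drop = FALSE], "tmm_cpm")
  expect_equal(median_scale_signature(one, c("A", "B", "C"))$values,
               v[, 1, drop = FALSE])
})

test_that("median rescaling equalizes medians on random panels", {
  set.seed(7)
  v <- matrix(rlnorm(100 * 11, 3, 1), 100, 11,
              dimnames = list(sprintf("G%03d", 1:100), paste0("S", 1:11)))
  em <- expression_matrix(v, "tmm_cpm")
  sc <- median_scale_signature(em, rownames(v))
  med <- apply(sc$values, 2, median)
  expect_true(max(med) - min(med) < 1e-9)
})
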