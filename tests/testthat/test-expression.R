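test_that("min_support_samples implements the ceiling rule", {
  expect_identical(min_support_samples(818, 0.01), 9L)
  expect_identical(min_support_samples(100, 0.01), 1L)
  expect_identical(min_support_samples(818, 0.5), 409L)
  expect_error(min_support_samples(818, 0), "fraction")
})

test_that("filter_expressed applies the TPM/support thresholds", {
  set.seed(3)
  n <- 818
  tpm <- rbind(
    boundary = c(rep(1.0, 9), rep(0, n - 9)),    # exactly 9 samples at 1 TPM
    below = rep(0.99, n),                        # everywhere just under
    high = rep(5, n))
  meta <- data.frame(sample_id = sprintf("s%03d", 1:n), tissue_label = "mix",
                     is_cancer_line = FALSE, is_control = TRUE)
  colnames(tpm) <- meta$sample_id
  em <- expression_matrix(tpm, meta)
  kept <- filter_expressed(em)
  expect_true("boundary" %in% kept)
  expect_false("below" %in% kept)
  expect_true("high" %in% kept)
})

test_that("filter_expressed equals brute force and is monotone", {
  set.seed(4)
  tpm <- matrix(rexp(50 * 20, 1), nrow = 50,
                dimnames = list(sprintf("t%02d", 1:50), sprintf("s%02d", 1:20)))
  meta <- data.frame(sample_id = colnames(tpm), tissue_label = "x",
                     is_cancer_line = FALSE, is_control = TRUE)
  em <- expression_matrix(tpm, meta)
  for (min_tpm in c(0.5, 1, 2)) for (fr in c(0.05, 0.2, 0.5)) {
    need <- ceiling(20 * fr)
    brute <- rownames(tpm)[apply(tpm, 1, function(r) sum(r >= min_tpm) >= need)]
    expect_setequal(filter_expressed(em, min_tpm, fr), brute)
  }
  base <- filter_expressed(em, 1, 0.2)
  expect_true(all(filter_expressed(em, 2, 0.2) %in% base))
  expect_true(all(filter_expressed(em, 1, 0.5) %in% base))
})

test_that("classify_pattern covers the closed pattern set and partitions", {
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:12),
    tissue_label = c(rep("spleen", 3), rep("liver", 3), "nerve",
                     rep("K562", 3), rep("HepG2", 2)),
    is_cancer_line = c(rep(FALSE, 7), rep(TRUE, 5)),
    is_control = c(rep(TRUE, 10), FALSE, TRUE))
  mk <- function(...) {
    m <- rbind(...)
    colnames(m) <- samples$sample_id
    m
  }
  tpm <- mk(
    ubi = rep(2, 12),
    spleen_only = c(2, 2, 0, rep(0, 9)),
    cancer_only = c(rep(0, 7), 2, 2, 2, 2, 2),
    silent = rep(0, 12),
    multi = c(2, 0, 0, 2, 0, 0, 0, rep(0, 5)),
    nerve_only = c(rep(0, 6), 2, rep(0, 5)))   # nerve has 1 sample: ineligible
  em <- expression_matrix(tpm, samples)
  pat <- classify_pattern(em)
  got <- setNames(pat$pattern, pat$retro_id)
  expect_equal(got[["ubi"]], "ubiquitous")
  expect_equal(got[["spleen_only"]], "tissue_specific")
  expect_equal(pat$tissue[pat$retro_id == "spleen_only"], "spleen")
  expect_equal(got[["cancer_only"]], "cancer_only")
  expect_equal(got[["silent"]], "not_expressed")
  expect_equal(got[["multi"]], "other")
  # detected only in an ineligible tissue: not tissue-specific
  expect_equal(got[["nerve_only"]], "other")
  # partition: exactly one pattern per row
  expect_true(all(!is.na(pat$pattern)))
})

test_that("spearman_rho matches the brute-force mid-rank oracle", {
  expect_equal(spearman_rho(1:10, 1:10)$rho, 1)
  expect_equal(spearman_rho(1:10, 1:10)$p, 0)
  expect_equal(spearman_rho(1:10, 10:1)$rho, -1)
  set.seed(5)
  for (i in 1:20) {
    x <- sample(1:6, 12, replace = TRUE)   # ties exercised
    y <- rnorm(12)
    r <- spearman_rho(x, y)
    expect_equal(r$rho, oracle_spearman(x, y), tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(r$p, unname(ct$p.value), tolerance = 1e-9)
  }
  # symmetry and monotone invariance
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman_rho(x, y)$rho, spearman_rho(y, x)$rho)
  expect_equal(spearman_rho(exp(x), y)$rho, spearman_rho(x, y)$rho)
  # constant vector -> undefined
  expect_true(is.na(spearman_rho(rep(1, 12), y[1:12])$rho))
})

test_that("correlate_pairs respects sample-selection modes", {
  set.seed(6)
  n <- 40
  a <- c(rexp(30) + 0.1, rep(0, 10))
  b <- c(rexp(35) + 0.1, rep(0, 5))
  tpm <- rbind(A = a, B = b)
  meta <- data.frame(sample_id = sprintf("s%02d", 1:n), tissue_label = "x",
                     is_cancer_line = FALSE, is_control = TRUE)
  colnames(tpm) <- meta$sample_id
  em <- expression_matrix(tpm, meta)
  pairs <- data.frame(id_a = "A", id_b = "B")
  expect_equal(correlate_pairs(em, pairs, "coexpressed")$n_used, 30L)
  expect_equal(correlate_pairs(em, pairs, "all")$n_used, 40L)
  # too few joint samples -> no row
  tpm2 <- rbind(A = c(rexp(5) + 0.1, rep(0, 35)), B = b)
  colnames(tpm2) <- meta$sample_id
  em2 <- expression_matrix(tpm2, meta)
  expect_equal(nrow(correlate_pairs(em2, pairs, "coexpressed")), 0L)
  expect_error(correlate_pairs(em, data.frame(id_a = "A", id_b = "nope")),
               "nope")
})

test_that("filter_correlations applies strict thresholds and is idempotent", {
  res <- data.frame(id_a = "r", id_b = c("a", "b", "c"),
                    mode = "all", n_used = 100,
                    rho = c(0.26, 0.25, 0.90), p = c(1e-4, 1e-9, 0.002))
  kept <- filter_correlations(res)
  expect_equal(kept$id_b, "a")             # 0.25 and p=0.002 both excluded
  expect_equal(filter_correlations(kept), kept)
  expect_true(all(rownames(kept) %in% rownames(res)))
})
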