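test_that("predict_sites finds canonical seed matches", {
  # miRNA 5'->3': pos 1 U, pos 2-8 = GAGGUAG (let-7 style seed)
  mir <- c(let7 = "UGAGGUAGUAGGUUGUAUAGUU")
  m8 <- "CTACCTC"                       # revcomp of GAGGTAG
  seqs <- c(hit = paste0("AAAA", m8, "AAAA"),
            eightmer = paste0("AAAA", m8, "A", "AAAA"),
            none = "ACGTACGTACGTACGT",
            polyn = paste(rep("N", 30), collapse = ""))
  sm <- predict_sites(seqs, mir)
  expect_setequal(sm$sites$sequence_id, c("hit", "eightmer"))
  expect_equal(sm$universe_size, 1L)
  expect_error(predict_sites(seqs, character()), "empty")
  expect_error(predict_sites(seqs, c(x = "ACGU")), ">= 8")
  # brute-force sliding-window oracle on random sequences
  set.seed(31)
  mirs <- setNames(vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "U"), 21, replace = TRUE), collapse = ""), ""),
    sprintf("mir%d", 1:5))
  rseqs <- setNames(vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""), ""),
    sprintf("t%02d", 1:20))
  sm2 <- predict_sites(rseqs, mirs)
  for (mi in names(mirs)) {
    seed7 <- chartr("U", "T", substr(mirs[[mi]], 2, 8))
    target <- vapply(strsplit(seed7, "")[[1]][7:1], function(b)
      c(A = "T", C = "G", G = "C", T = "A")[[b]], "")
    target <- paste(target, collapse = "")
    manual <- names(rseqs)[vapply(rseqs, function(s) {
      any(vapply(seq_len(nchar(s) - 6), function(p)
        substr(s, p, p + 6) == target, TRUE))
    }, TRUE)]
    fam <- sm2$families[[mi]]
    got <- sm2$sites$sequence_id[sm2$sites$family == fam]
    expect_setequal(got, manual)
  }
})

test_that("sponge_pvalue is the inclusive upper tail", {
  expect_equal(sponge_pvalue(10, 10, 3, 3), 1)
  expect_equal(sponge_pvalue(10, 4, 3, 2), 1 / 3)
  expect_equal(sponge_pvalue(200, 10, 10, 0), 1)
  expect_error(sponge_pvalue(10, 4, 3, 4), "inconsistent")
})

test_that("sponge_pvalue equals exhaustive enumeration for all M <= 12", {
  for (M in c(4, 7, 10, 12)) {
    for (K in seq(1, M, by = 3)) for (n in seq(1, M, by = 3)) {
      for (k in 0:min(K, n)) {
        expect_equal(sponge_pvalue(M, K, n, k), oracle_hyper_upper(M, K, n, k),
                     tolerance = 1e-12,
                     info = sprintf("M=%d K=%d n=%d k=%d", M, K, n, k))
      }
    }
  }
  # p non-increasing in k
  ps <- vapply(0:5, function(k) sponge_pvalue(50, 10, 8, k), 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("bh_correct implements step-up BH", {
  out <- bh_correct(c(0.01, 0.02, 0.03))
  expect_equal(out$q, c(0.03, 0.03, 0.03))
  expect_true(all(out$reject))
  expect_equal(bh_correct(0.04)$q, 0.04)
  expect_false(any(bh_correct(rep(1, 5))$reject))
  set.seed(32)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_correct(p)$q, p.adjust(p, "BH"))
  }
  # rejections only grow with alpha
  p <- runif(30, 0, 0.2)
  r1 <- bh_correct(p, alpha = 0.01)$reject
  r2 <- bh_correct(p, alpha = 0.10)$reject
  expect_true(all(!r1 | r2))
})

test_that("call_sponges combines enrichment and co-expression", {
  sites <- rbind(
    data.frame(sequence_id = "retroA", family = sprintf("f%02d", 1:10)),
    data.frame(sequence_id = "tx1", family = sprintf("f%02d", 1:8)),
    data.frame(sequence_id = "tx2", family = sprintf("f%02d", c(1, 30:35))),
    data.frame(sequence_id = "tx3", family = sprintf("f%02d", 60:65)))
  site_map <- list(sites = sites, universe_size = 200L)
  corr <- data.frame(id_a = "retroA", id_b = c("tx1", "tx2"),
                     mode = "coexpressed", n_used = 100,
                     rho = c(0.5, 0.1), p = c(1e-6, 1e-6))
  out <- call_sponges(site_map, "retroA", c("tx1", "tx2", "tx3"), corr)
  expect_false("tx3" %in% out$transcript_id)        # k = 0: never tested
  r1 <- out[out$transcript_id == "tx1", ]
  expect_equal(r1$k, 8L)
  expect_true(r1$called)
  expect_equal(r1$corr_sign, "positive")
  r2 <- out[out$transcript_id == "tx2", ]
  expect_false(r2$called)                           # |rho| below 0.25
  # negative rho with q pass stays called, flagged negative
  corr$rho[1] <- -0.5
  out2 <- call_sponges(site_map, "retroA", c("tx1", "tx2"), corr)
  expect_true(out2$called[out2$transcript_id == "tx1"])
  expect_equal(out2$corr_sign[out2$transcript_id == "tx1"], "negative")
})

test_that("null site assignment keeps the false-call rate at the BH level", {
  set.seed(33)
  n_universe <- 200
  called <- 0L; tested <- 0L
  for (u in seq_len(n_universe)) {
    fams <- sprintf("f%03d", 1:60)
    sites <- do.call(rbind, lapply(c("r1", "r2", sprintf("t%d", 1:8)),
                                   function(id)
      data.frame(sequence_id = id, family = sample(fams, 5))))
    sm <- list(sites = sites, universe_size = 60L)
    pairs <- expand.grid(id_a = c("r1", "r2"), id_b = sprintf("t%d", 1:8),
                         stringsAsFactors = FALSE)
    # correlation gate held open so the hypergeometric+BH chain is measured
    corr <- data.frame(id_a = pairs$id_a, id_b = pairs$id_b,
                       mode = "coexpressed", n_used = 100, rho = 0.9, p = 1e-9)
    out <- call_sponges(sm, c("r1", "r2"), sprintf("t%d", 1:8), corr)
    called <- called + sum(out$called)
    tested <- tested + nrow(out)
  }
  rate <- called / max(1, tested)
  se <- sqrt(0.05 * 0.95 / max(1, tested))
  expect_lte(rate, 0.05 + 3 * se)
})
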