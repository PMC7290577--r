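test_that("find_gene_overlaps matches the all-vs-all oracle", {
  set.seed(41)
  n_r <- 300; n_g <- 120
  retros <- retro_catalog(data.frame(
    retro_id = sprintf("r%03d", 1:n_r),
    chrom = sample(c("c1", "c2"), n_r, replace = TRUE),
    start = (s <- sample(0:50000, n_r)), end = s + sample(200:800, n_r, TRUE),
    strand = sample(c("+", "-"), n_r, TRUE),
    status = "known_pseudogene", parental_gene_id = "gP"))
  exons <- data.frame(
    transcript_id = sprintf("t%03d", 1:n_g),
    chrom = sample(c("c1", "c2"), n_g, replace = TRUE),
    start = (gs <- sample(0:50000, n_g)), end = gs + sample(500:3000, n_g, TRUE),
    strand = sample(c("+", "-"), n_g, TRUE))
  tx <- data.frame(transcript_id = sprintf("t%03d", 1:n_g),
                   gene_id = sprintf("g%03d", 1:n_g), biotype = "other")
  ann <- annotation(exons, tx)
  got <- find_gene_overlaps(retros, ann)
  want <- oracle_overlaps(retros,
                          data.frame(gene_id = tx$gene_id, chrom = exons$chrom,
                                     start = exons$start, end = exons$end))
  key <- function(d) sort(paste(d$retro_id, d$gene_id, d$overlap_bases))
  expect_equal(key(got), key(want))
  # single-exon genes: every overlap is exonic
  expect_true(all(got$context == "exonic"))
})

test_that("overlap context distinguishes exonic / intronic / mixed", {
  ann <- toy_annotation()   # gA: exons [100,200) [300,400) [600,700)
  cat <- retro_catalog(data.frame(
    retro_id = c("r_in_intron", "r_in_exon", "r_mixed", "r_outside"),
    chrom = "chrT",
    start = c(210L, 120L, 150L, 5000L), end = c(290L, 180L, 350L, 5100L),
    strand = "-", status = "known_pseudogene", parental_gene_id = "gZ"))
  ov <- find_gene_overlaps(cat, ann)
  ctx <- setNames(ov$context, ov$retro_id)
  expect_equal(ctx[["r_in_intron"]], "intronic")
  expect_equal(ctx[["r_in_exon"]], "exonic")
  expect_equal(ctx[["r_mixed"]], "mixed")
  expect_false("r_outside" %in% ov$retro_id)
  expect_true(all(ov$relative_strand[ov$gene_id == "gA"] == "opposite"))
})

test_that("cis-NAT candidacy needs opposite strand; calls need correlation", {
  ann <- toy_annotation()
  cat <- retro_catalog(data.frame(
    retro_id = c("rOpp", "rSame"), chrom = "chrT",
    start = c(210L, 220L), end = c(290L, 280L),
    strand = c("-", "+"),
    status = "known_pseudogene", parental_gene_id = "gZ"))
  ov <- find_gene_overlaps(cat, ann)
  corr <- data.frame(id_a = "rOpp", id_b = "tA1", mode = "all",
                     n_used = 100, rho = 0.89, p = 1e-7)
  cis <- classify_cis_nat(ov, ann, corr)
  expect_equal(cis$retro_id, "rOpp")              # same-strand never a candidate
  expect_true(cis$called)
  expect_equal(cis$best_partner, "tA1")
  # without a passing correlation: candidate but not called
  cis2 <- classify_cis_nat(ov, ann, corr[0, ])
  expect_true(cis2$candidate)
  expect_false(cis2$called)
})

test_that("trans-NAT route (c) applies the strand and window rules", {
  w <- default_world()
  cat <- retro_catalog(data.frame(
    retro_id = "rT", chrom = "chrT", start = 1000L, end = 1650L, strand = "+",
    status = "known_pseudogene", parental_gene_id = "gA"))
  ann <- toy_annotation()
  corr <- data.frame(id_a = "rT", id_b = "tA1", mode = "coexpressed",
                     n_used = 50, rho = 0.6, p = 1e-5)
  tnat <- function(tss) identify_trans_nat(cat, ann, tss, corr)
  # opposite strand, 200 b from the 3' end: candidate and called
  out <- tnat(data.frame(chrom = "chrT", pos = 1849L, strand = "-"))
  expect_equal(out$route, "c")
  expect_true(out$called)
  # same strand: no candidate
  expect_equal(nrow(tnat(data.frame(chrom = "chrT", pos = 1849L, strand = "+"))), 0L)
  # beyond the window: no candidate; shrinking the window is monotone
  expect_equal(nrow(tnat(data.frame(chrom = "chrT", pos = 2200L, strand = "-"))), 0L)
  out_narrow <- identify_trans_nat(cat, ann,
                                   data.frame(chrom = "chrT", pos = 1849L,
                                              strand = "-"),
                                   corr, tss_window = 100)
  expect_equal(nrow(out_narrow), 0L)
})

test_that("planted trans-NAT routes are recovered on the world", {
  w <- default_world()
  run <- default_run()
  trans <- run$trans_nat
  truth <- w$truth[w$truth$evidence_class == "trans_nat", ]
  called <- trans[trans$called, ]
  for (i in seq_len(nrow(truth))) {
    hit <- called[called$retro_id == truth$retro_id[i] &
                    called$route == truth$detail[i], ]
    expect_gte(nrow(hit), 1)
  }
  # no called trans-NATs beyond the planted set
  expect_true(all(called$retro_id %in% truth$retro_id))
})

test_that("exon contribution classes follow the CDS geometry", {
  w <- default_world()
  run <- default_run()
  exo <- run$exonization
  truth <- w$truth[w$truth$evidence_class == "exonization", ]
  for (i in seq_len(nrow(truth))) {
    row <- exo[exo$retro_id == truth$retro_id[i] &
                 exo$transcript_id == truth$partner_id[i], ]
    expect_equal(row$region_classes, truth$detail[i])
    expect_true(row$cds_complete)
  }
  # transcripts without CDS are flagged and carry no classes
  ann <- toy_annotation()
  cat <- retro_catalog(data.frame(
    retro_id = "rB", chrom = "chrT", start = 2100L, end = 2300L, strand = "+",
    status = "known_pseudogene", parental_gene_id = "gZ"))
  out <- classify_exon_contribution(cat, ann)
  expect_false(out$cds_complete[out$transcript_id == "tB1"])
  expect_true(is.na(out$region_classes[out$transcript_id == "tB1"]))
})

test_that("interference geometry respects the distance and intron rules", {
  # host gene: short isoform ends at 1000; long isoform intron [800, 5000)
  exons <- data.frame(
    transcript_id = c("short", "short", "long", "long"),
    chrom = "chrI",
    start = c(200L, 700L, 200L, 5000L), end = c(500L, 1000L, 800L, 5400L),
    strand = "+")
  tx <- data.frame(transcript_id = c("short", "long"), gene_id = "gH",
                   biotype = "protein_coding")
  ann <- annotation(exons, tx)
  mk_cat <- function(start, end) retro_catalog(data.frame(
    retro_id = "rI", chrom = "chrI", start = start, end = end, strand = "+",
    status = "known_pseudogene", parental_gene_id = "gZ"))
  corr <- data.frame(id_a = "rI", id_b = c("short", "long"), mode = "all",
                     n_used = 100, rho = c(0.6, 0.05), p = c(1e-6, 0.7))
  # 800 b downstream of the short TES, inside the long intron: called
  out <- detect_transcriptional_interference(mk_cat(1800L, 2400L), ann, corr)
  expect_equal(nrow(out), 1L)
  expect_equal(out$downstream_distance, 800L)
  expect_true(out$called)
  # 1200 b downstream: no candidate
  expect_equal(nrow(detect_transcriptional_interference(mk_cat(2200L, 2800L),
                                                        ann, corr)), 0L)
  # overlapping a long-isoform exon: no candidate
  expect_equal(nrow(detect_transcriptional_interference(mk_cat(1500L, 5100L),
                                                        ann, corr)), 0L)
  # abutting (distance 0) counts as downstream
  out0 <- detect_transcriptional_interference(mk_cat(1000L, 1600L), ann, corr)
  expect_equal(out0$downstream_distance, 0L)
  # correlation with the long isoform too disqualifies the call
  corr_bad <- corr; corr_bad$rho[2] <- 0.7; corr_bad$p[2] <- 1e-8
  out_bad <- detect_transcriptional_interference(mk_cat(1800L, 2400L), ann,
                                                 corr_bad)
  expect_false(out_bad$called)
  # shrinking max_downstream never adds candidates
  out_small <- detect_transcriptional_interference(mk_cat(1800L, 2400L), ann,
                                                   corr, max_downstream = 500)
  expect_equal(nrow(out_small), 0L)
})

test_that("planted interference candidates equal ground truth on the world", {
  w <- default_world()
  run <- default_run()
  intf <- run$interference
  truth <- w$truth[w$truth$evidence_class == "interference", ]
  expect_setequal(intf$retro_id, truth$retro_id)
  expect_equal(intf$downstream_distance[match(truth$retro_id, intf$retro_id)],
               truth$value)
  expect_true(all(intf$called))
})
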