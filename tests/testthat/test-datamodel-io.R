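test_that("catalog reader tallies statuses and enforces invariants", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  mk <- function(n_coding, n_pseudo, n_novel, n_other = 0) {
    n <- n_coding + n_pseudo + n_novel + n_other
    data.frame(retro_id = sprintf("r%05d", seq_len(n)),
               chrom = rep("chr1", n),
               start = seq_len(n) * 10L, end = seq_len(n) * 10L + 5L,
               strand = rep("+", n),
               status = rep(c("known_protein_coding", "known_pseudogene",
                              "novel", "weird_status"),
                            c(n_coding, n_pseudo, n_novel, n_other)),
               parental_gene_id = rep("gX", n))
  }
  write.table(mk(106, 4384, 121), tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  cat1 <- read_retrocopy_catalog(tmp)
  expect_equal(sum(attr(cat1, "status_tally")), 4611L)
  expect_equal(unname(attr(cat1, "status_tally")[["known_protein_coding"]]), 106L)

  write.table(mk(111, 4351, 77, 15), tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  cat2 <- read_retrocopy_catalog(tmp)
  expect_equal(sum(attr(cat2, "status_tally")), 4554L)
  # out-of-vocabulary statuses collapse to "other"
  expect_equal(unname(attr(cat2, "status_tally")[["other"]]), 15L)

  # duplicate ids rejected
  bad <- mk(2, 0, 0); bad$retro_id <- "dup"
  write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_retrocopy_catalog(tmp), "duplicate")

  # empty catalog: zero records, zero tally
  write.table(mk(0, 0, 0), tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  cat0 <- read_retrocopy_catalog(tmp)
  expect_equal(nrow(cat0), 0L)
  expect_equal(sum(attr(cat0, "status_tally")), 0L)
})

test_that("BED12 reader reconstructs exon structure and CDS", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  # 3-block plus-strand transcript and a 2-block minus-strand transcript
  writeLines(c(
    paste("chr1", 100, 1000, "txP|geneP|protein_coding", 0, "+", 150, 950,
          "0", 3, "100,200,100,", "0,400,800,", sep = "\t"),
    paste("chr1", 2000, 2600, "txM|geneM|lncRNA", 0, "-", 2000, 2000,
          "0", 2, "100,100,", "0,500,", sep = "\t")), tmp)
  ann <- read_annotation(tmp)
  expect_equal(nrow(ann$transcripts), 2L)
  # transcribed length equals brute-force per-base union of the blocks
  bases <- unique(c(seq(100, 199), seq(500, 699), seq(900, 999)))
  expect_equal(transcribed_length(ann, "txP"), length(bases))
  tp <- ann$transcripts[ann$transcripts$transcript_id == "txP", ]
  expect_equal(tp$tss, 100L)
  expect_equal(tp$tes, 999L)
  expect_equal(tp$cds_start, 150L)
  # minus strand: tss is the 3'-most genomic base
  tm <- ann$transcripts[ann$transcripts$transcript_id == "txM", ]
  expect_equal(tm$tss, 2599L)
  expect_equal(tm$tes, 2000L)
  expect_true(is.na(tm$cds_start))  # thickStart == thickEnd -> no CDS
})

test_that("GTF reader converts 1-based inclusive to 0-based half-open", {
  tmp <- withr::local_tempfile(fileext = ".gtf")
  attrs <- 'gene_id "g1"; transcript_id "t1"; transcript_biotype "protein_coding";'
  writeLines(c(
    paste("chr2", "src", "exon", 101, 400, ".", "+", ".", attrs, sep = "\t"),
    paste("chr2", "src", "CDS", 151, 350, ".", "+", ".", attrs, sep = "\t")), tmp)
  ann <- read_annotation(tmp)
  t1 <- ann$transcripts[1, ]
  expect_equal(t1$start, 100L)
  expect_equal(t1$end, 400L)
  expect_equal(t1$cds_start, 150L)
  expect_equal(t1$cds_end, 350L)
  expect_equal(t1$tss, 100L)
})

test_that("expression matrix IO validates and round-trips", {
  tpm <- matrix(c(1.5, 0, 2, 3.25, 0.1, 8), nrow = 3,
                dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), tissue_label = c("liver", "liver"),
                     is_cancer_line = FALSE, is_control = TRUE)
  em <- expression_matrix(tpm, meta)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(em, f1, f2)
  back <- read_expression_matrix(f1, f2)
  expect_equal(back$tpm, em$tpm)
  expect_equal(back$samples$tissue_label, em$samples$tissue_label)

  expect_error(expression_matrix(-tpm, meta), "non-negative")
  # sample present in matrix but missing from metadata
  writeLines("sample_id\ttissue_label\tis_cancer_line\tis_control\ns1\tliver\tFALSE\tTRUE", f2)
  expect_error(read_expression_matrix(f1, f2), "missing from metadata")
})

test_that("bedGraph reader enforces non-overlap and reconstructs depths", {
  tmp <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t100\t5", "chr1\t100\t200\t7"), tmp)
  tr <- read_bedgraph(tmp, "libX", "rna")
  expect_equal(nrow(tr$records), 2L)

  writeLines(c("chr1\t0\t100\t5", "chr1\t50\t150\t7"), tmp)
  expect_error(read_bedgraph(tmp), "overlapping")

  writeLines(c("chr1\t0\t100\tfive"), tmp)
  expect_error(read_bedgraph(tmp), "non-numeric depth")

  # random non-overlapping fixture round-trips to identical per-base depths
  set.seed(11)
  edges <- sort(sample(0:2000, 40))
  rec <- data.frame(chrom = "chr9", start = edges[seq(1, 39, 2)],
                    end = edges[seq(2, 40, 2)],
                    depth = sample(0:50, 20, replace = TRUE))
  rec <- rec[rec$end > rec$start, ]
  tr <- coverage_track(rec, "libR", "ribo")
  f <- withr::local_tempfile()
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, "libR", "ribo")
  expect_equal(oracle_mean_coverage(back$records, "chr9", 0, 2000),
               oracle_mean_coverage(rec[rec$depth > 0, ], "chr9", 0, 2000))
})

test_that("annotation invariants are enforced", {
  exons <- data.frame(transcript_id = "t1", chrom = "chr1",
                      start = c(0L, 50L), end = c(60L, 100L), strand = "+")
  tx <- data.frame(transcript_id = "t1", gene_id = "g1", biotype = "other")
  expect_error(annotation(exons, tx), "overlapping exons")
  exons$start <- c(0L, 70L)
  tx$cds_start <- 500L; tx$cds_end <- 600L
  expect_error(annotation(exons, tx), "CDS outside")
})
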