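# a 300-codon stop-free forward sequence makes ORF spans predictable
stopfree <- function(n_codons, seed = 1) {
  set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

test_that("six_frame_orfs enforces the 60-base overlap floor", {
  locus <- stopfree(300)
  # frame-0 ORF spans [0, 900); choose retro spans overlapping 59 vs 60
  o59 <- six_frame_orfs(locus, 841, 900, min_overlap = 60)
  o60 <- six_frame_orfs(locus, 840, 900, min_overlap = 60)
  f0_59 <- o59[o59$strand == "+" & o59$frame == 0, ]
  f0_60 <- o60[o60$strand == "+" & o60$frame == 0, ]
  expect_equal(nrow(f0_59), 0L)
  expect_equal(nrow(f0_60), 1L)
  expect_equal(f0_60$overlap_with_retro, 60L)
})

test_that("six_frame_orfs equals brute-force enumeration on random loci", {
  set.seed(21)
  for (i in 1:5) {
    locus <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                   collapse = "")
    got <- six_frame_orfs(locus, 200, 400, min_overlap = 60)
    expect_equal(sort(got$aa_sequence), oracle_orfs(locus, 200, 400))
  }
  # too-short locus yields nothing
  expect_equal(nrow(six_frame_orfs(stopfree(10), 0, 30)), 0L)
  expect_error(six_frame_orfs("ACGTJJ", 0, 6), "non-IUPAC")
})

test_that("ORF discovery is strand-symmetric", {
  set.seed(22)
  locus <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                 collapse = "")
  L <- nchar(locus)
  fwd <- six_frame_orfs(locus, 100, 350, retro_strand = "+")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(locus)))
  rev <- six_frame_orfs(rc, L - 350, L - 100, retro_strand = "-")
  expect_setequal(fwd$aa_sequence, rev$aa_sequence)
  # mirrored genomic coordinates
  key_f <- sort(paste(fwd$start, fwd$end))
  key_r <- sort(paste(L - rev$end, L - rev$start))
  expect_equal(key_f, key_r)
})

test_that("match_peptides applies length, identity and uniqueness rules", {
  orfs <- data.frame(retro_id = "rX", orf_id = "o1",
                     aa_sequence = "MAGICPEPTIDESEQVENCE", frame = 0,
                     orientation = "sense")
  peps <- data.frame(
    peptide_id = c("short9", "exact", "mismatch", "indecoy"),
    aa_sequence = c("AGICPEPTI", "AGICPEPTIDES", "AGICPEPTADES",
                    "PEPTIDESEQVE"))
  hits <- match_peptides(peps, orfs,
                         decoy_sequences = "XXPEPTIDESEQVEXX")
  expect_equal(attr(hits, "n_too_short"), 1L)
  expect_false("short9" %in% hits$peptide_id)
  expect_false("mismatch" %in% hits$peptide_id)      # one residue off
  expect_true(hits$unique[hits$peptide_id == "exact"])
  expect_false(hits$unique[hits$peptide_id == "indecoy"])
  expect_false(hits$final[hits$peptide_id == "indecoy"])
  # hit offset points at the verbatim substring
  h <- hits[hits$peptide_id == "exact", ]
  expect_equal(substr(orfs$aa_sequence, h$offset + 1,
                      h$offset + nchar("AGICPEPTIDES")), "AGICPEPTIDES")
  # a peptide matching two retrocopies is non-unique at the retro level
  orfs2 <- rbind(orfs, data.frame(retro_id = "rY", orf_id = "o2",
                                  aa_sequence = "ZZAGICPEPTIDESZZ", frame = 1,
                                  orientation = "sense"))
  hits2 <- match_peptides(peps[2, ], orfs2)
  expect_true(all(!hits2$unique))
})

test_that("frame concordance distinguishes parental-frame hits", {
  # retrocopy = verbatim parental mRNA (100 nt 5'UTR + stop-free CDS);
  # anchor at local position 100 marks parental codon boundaries
  cds <- stopfree(60, seed = 30)
  locus <- paste0(stopfree(40, seed = 31), cds, stopfree(30, seed = 32))
  # lay out: retro occupies the whole locus on "+"
  orfs <- six_frame_orfs(locus, 0, nchar(locus), retro_strand = "+",
                         min_overlap = 60)
  orfs$retro_id <- "r1"
  orfs$orf_id <- sprintf("o%d", seq_len(nrow(orfs)))
  peps <- data.frame(peptide_id = "p1",
                     aa_sequence = substr(translate_frame(cds), 5, 16))
  hits <- match_peptides(peps, orfs)
  spans <- data.frame(retro_id = "r1", start = 0, end = nchar(locus),
                      strand = "+")
  anchors <- data.frame(retro_id = "r1", codon_anchor = 120L)
  out <- annotate_frame_concordance(hits, orfs, spans, anchors)
  sense_hits <- out[out$orientation == "sense", ]
  expect_true(any(sense_hits$frame_concordance == "concordant"))
  # no anchor -> unmapped
  out2 <- annotate_frame_concordance(hits, orfs, spans,
                                     data.frame(retro_id = character(),
                                                codon_anchor = integer()))
  expect_true(all(out2$frame_concordance == "unmapped"))
})

test_that("a downstream in-frame peptide stays concordant past a frameshift stop", {
  # parental-frame CDS with a planted internal stop: the downstream
  # stop-to-stop ORF is still in the parental frame
  cds_a <- stopfree(30, seed = 33)
  cds_b <- stopfree(40, seed = 34)
  locus <- paste0(cds_a, "TAA", cds_b)
  orfs <- six_frame_orfs(locus, 0, nchar(locus), retro_strand = "+",
                         min_overlap = 60)
  orfs$retro_id <- "r2"; orfs$orf_id <- sprintf("o%d", seq_len(nrow(orfs)))
  pep <- substr(translate_frame(cds_b), 3, 14)
  hits <- match_peptides(data.frame(peptide_id = "pd", aa_sequence = pep), orfs)
  expect_true(nrow(hits) >= 1)
  spans <- data.frame(retro_id = "r2", start = 0, end = nchar(locus),
                      strand = "+")
  anchors <- data.frame(retro_id = "r2", codon_anchor = 0L)
  out <- annotate_frame_concordance(hits, orfs, spans, anchors)
  down <- out[out$orientation == "sense" & out$peptide_id == "pd", ]
  expect_true(any(down$frame_concordance == "concordant"))
})

test_that("planted peptides are recovered and decoys excluded on the world", {
  w <- default_world()
  run <- default_run()
  hits <- run$peptides
  planted <- w$peptides[w$peptides$truth == "planted", ]
  final <- hits[hits$final, ]
  expect_true(all(planted$peptide_id %in% final$peptide_id))
  # each planted peptide maps to its own retrocopy
  m <- merge(planted, final, by = "peptide_id")
  expect_true(all(m$retro_id.x == m$retro_id.y))
  # parental decoys and sub-length peptides never reach the final set
  bad <- w$peptides$peptide_id[w$peptides$truth != "planted"]
  expect_false(any(bad %in% final$peptide_id))
})
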