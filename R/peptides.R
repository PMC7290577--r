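## Six-frame ORF discovery on retrocopy loci and exact peptide matching.
##
## A retrocopy locus is its annotated span extended by `extension` bases on
## both sides (clipped at chromosome ends). ORFs are maximal stop-to-stop
## translations in all six frames, start-codon independent, of at least 20
## codons; only ORFs whose genomic span intersects the un-extended
## retrocopy span by >= 60 bases are kept. Peptide evidence requires an
## exact, gap-free, full-length substring match; peptides shorter than ten
## amino acids are rejected up front, and peptides found verbatim in any
## decoy sequence (the non-retrocopy transcriptome) are flagged non-unique
## and excluded from the final set.

MIN_ORF_AA <- 20L

translate_nt <- function(nt) {
  nt <- toupper(nt)
  if (grepl("[^ACGTRYSWKMBDHVNU]", nt))
    stop("sequence contains non-IUPAC characters")
  nt <- chartr("U", "T", nt)
  n_codon <- nchar(nt) %/% 3L
  if (n_codon == 0L) return("")
  codons <- substring(nt, 3L * (seq_len(n_codon) - 1L) + 1L, 3L * seq_len(n_codon))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

## stop-free aa runs of >= min_aa codons within one frame translation;
## returns aa-index (0-based) start and length
aa_runs <- function(aa, min_aa) {
  parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
  if (!length(parts)) return(data.frame(aa_start = integer(), aa_len = integer()))
  starts <- cumsum(c(0L, nchar(parts) + 1L))[seq_along(parts)]
  keep <- nchar(parts) >= min_aa
  data.frame(aa_start = starts[keep], aa_len = nchar(parts)[keep],
             aa_sequence = parts[keep], stringsAsFactors = FALSE)
}

#' Six-frame ORF discovery over a retrocopy locus
#'
#' @param locus_seq genome-forward nucleotide sequence of the locus window.
#' @param retro_start,retro_end retrocopy span within the locus (0-based
#'   half-open, local coordinates).
#' @param retro_strand annotated strand of the retrocopy; ORF orientation
#'   is reported relative to it.
#' @param min_overlap minimum intersection (bases) between the ORF genomic
#'   span and the un-extended retrocopy span (default 60, i.e. 20 codons).
#' @param min_aa minimum ORF length in amino acids (default 20).
#' @return data.frame of ORFs: local genomic start/end, strand, frame
#'   (0-2 within the strand), orientation (`sense`/`antisense` relative to
#'   `retro_strand`), aa_sequence, overlap_with_retro.
#' @export
six_frame_orfs <- function(locus_seq, retro_start, retro_end,
                           retro_strand = "+", min_overlap = 60,
                           min_aa = MIN_ORF_AA) {
  L <- nchar(locus_seq)
  out <- list()
  for (genome_strand in c("+", "-")) {
    s <- if (genome_strand == "+") locus_seq else revcomp(locus_seq)
    for (frame in 0:2) {
      aa <- translate_nt(substr(s, frame + 1L, L))
      runs <- aa_runs(aa, min_aa)
      if (!nrow(runs)) next
      nt_s <- frame + 3L * runs$aa_start            # on strand s
      nt_e <- nt_s + 3L * runs$aa_len
      if (genome_strand == "+") {
        g_s <- nt_s; g_e <- nt_e
      } else {
        g_s <- L - nt_e; g_e <- L - nt_s
      }
      ov <- pmin(g_e, retro_end) - pmax(g_s, retro_start)
      keep <- ov >= min_overlap
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        start = g_s[keep], end = g_e[keep], strand = genome_strand,
        frame = frame,
        orientation = if (genome_strand == retro_strand) "sense" else "antisense",
        aa_sequence = runs$aa_sequence[keep],
        overlap_with_retro = ov[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      frame = integer(), orientation = character(),
                      aa_sequence = character(), overlap_with_retro = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Exact peptide matching against retrocopy ORFs with a decoy filter
#'
#' @param peptides data.frame with peptide_id, aa_sequence.
#' @param orfs ORF table as from [six_frame_orfs()], with an added
#'   `retro_id` column and an `orf_id` column (caller-assigned).
#' @param decoy_sequences character vector of decoy protein sequences
#'   (translations of the non-retrocopy transcriptome).
#' @param min_peptide_len peptides shorter than this are rejected before
#'   matching (default 10 aa); the rejected count is attached as
#'   `attr(, "n_too_short")`.
#' @return data.frame of hits (peptide_id, retro_id, orf_id, offset, frame,
#'   orientation, unique). `unique` is FALSE when the peptide occurs in any
#'   decoy or matches ORFs of more than one retrocopy; the `final` column
#'   marks unique hits, the set peptide evidence is counted from.
#' @export
match_peptides <- function(peptides, orfs, decoy_sequences = character(),
                           min_peptide_len = 10) {
  stopifnot(all(c("peptide_id", "aa_sequence") %in% names(peptides)),
            all(c("retro_id", "orf_id", "aa_sequence") %in% names(orfs)))
  too_short <- nchar(peptides$aa_sequence) < min_peptide_len
  pep <- peptides[!too_short, , drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(pep))) {
    pseq <- pep$aa_sequence[i]
    in_decoy <- length(decoy_sequences) > 0 &&
      any(grepl(pseq, decoy_sequences, fixed = TRUE))
    pos <- regexpr(pseq, orfs$aa_sequence, fixed = TRUE)
    hit <- which(pos > 0)
    if (!length(hit)) next
    multi_retro <- length(unique(orfs$retro_id[hit])) > 1L
    hits[[length(hits) + 1L]] <- data.frame(
      peptide_id = pep$peptide_id[i], retro_id = orfs$retro_id[hit],
      orf_id = orfs$orf_id[hit], offset = as.integer(pos[hit]) - 1L,
      frame = orfs$frame[hit], orientation = orfs$orientation[hit],
      unique = !in_decoy && !multi_retro, stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(peptide_id = character(), retro_id = character(),
               orf_id = character(), offset = integer(), frame = integer(),
               orientation = character(), unique = logical())
  out$final <- out$unique
  rownames(out) <- NULL
  attr(out, "n_too_short") <- sum(too_short)
  out
}

#' Annotate peptide hits with reading-frame concordance vs the parental CDS
#'
#' Uses an ungapped anchoring between the retrocopy (sense orientation) and
#' the parental CDS: `codon_anchor` is the retrocopy-local position (0-based,
#' sense strand) of any parental codon's first base, so parental codon
#' boundaries fall at local positions congruent to it modulo 3. A hit on an
#' antisense ORF is `antisense`; a sense hit is `concordant` iff its first
#' codon starts on a parental codon boundary, else `discordant`. Retrocopies
#' without an anchor are `unmapped` and excluded from concordance tallies.
#'
#' @param hits hit table from [match_peptides()].
#' @param orfs the ORF table the hits refer to (with orf_id, start, end,
#'   strand, retro-local coordinates as produced by [six_frame_orfs()]).
#' @param retro_spans data.frame retro_id, start, end, strand in the same
#'   local coordinate system as the ORFs.
#' @param anchors data.frame retro_id, codon_anchor.
#' @return `hits` with a `frame_concordance` column.
#' @export
annotate_frame_concordance <- function(hits, orfs, retro_spans, anchors) {
  res <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    rid <- hits$retro_id[i]
    a <- anchors$codon_anchor[anchors$retro_id == rid]
    if (!length(a)) { res[i] <- "unmapped"; next }
    if (hits$orientation[i] == "antisense") { res[i] <- "antisense"; next }
    orf <- orfs[orfs$orf_id == hits$orf_id[i], ]
    sp <- retro_spans[retro_spans$retro_id == rid, ]
    # retro-local sense-strand coordinate of the hit's first base
    if (sp$strand == "+") {
      g <- orf$start + 3L * hits$offset[i]
      pos_local <- g - sp$start
    } else {
      g <- orf$end - 1L - 3L * hits$offset[i]
      pos_local <- (sp$end - 1L) - g
    }
    res[i] <- if ((pos_local - a[1]) %% 3L == 0L) "concordant" else "discordant"
  }
  hits$frame_concordance <- res
  hits
}
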