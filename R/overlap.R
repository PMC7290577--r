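## Strand-aware genomic overlap detection and its downstream classifiers:
## cis-NAT candidates, trans-NAT candidate routes, exon-contribution
## (exonization) classes, and transcriptional-interference geometry.

## exon union per gene (reduced across isoforms), one row per merged block
gene_exon_union <- function(ann) {
  e <- ann$exons
  gid <- ann$transcripts$gene_id[match(e$transcript_id, ann$transcripts$transcript_id)]
  sp <- split(e, paste(gid, e$chrom))
  out <- lapply(sp, function(x) {
    r <- IRanges::reduce(IRanges::IRanges(x$start + 1L, x$end))
    data.frame(gene_id = gid[match(x$transcript_id[1], e$transcript_id)],
               chrom = x$chrom[1], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Find retrocopy-gene overlaps
#'
#' One record per (retrocopy, gene) pair with at least one overlapping base
#' against the gene's transcribed span (union of all isoform exons and
#' introns). Context is `exonic` when every overlapping base falls in the
#' exon union of the gene, `intronic` when none does, `mixed` otherwise.
#'
#' @param catalog a [retro_catalog()].
#' @param ann a [annotation()] object.
#' @return data.frame retro_id, gene_id, relative_strand (`same`/`opposite`),
#'   context, overlap_bases.
#' @export
find_gene_overlaps <- function(catalog, ann) {
  genes <- gene_spans(ann)
  exu <- gene_exon_union(ann)
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    ov <- overlap_bases(genes, catalog$chrom[i], catalog$start[i], catalog$end[i])
    hit <- which(ov > 0)
    for (j in hit) {
      g <- genes$gene_id[j]
      eb <- exu[exu$gene_id == g, , drop = FALSE]
      ex_ov <- sum(overlap_bases(eb, catalog$chrom[i], catalog$start[i],
                                 catalog$end[i]))
      # exon overlap cannot exceed gene-span overlap
      context <- if (ex_ov >= ov[j]) "exonic" else if (ex_ov == 0) "intronic" else "mixed"
      rows[[length(rows) + 1L]] <- data.frame(
        retro_id = catalog$retro_id[i], gene_id = g,
        relative_strand = if (genes$strand[j] == catalog$strand[i]) "same" else "opposite",
        context = context, overlap_bases = ov[j], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(retro_id = character(), gene_id = character(),
               relative_strand = character(), context = character(),
               overlap_bases = integer())
  rownames(out) <- NULL
  out
}

#' Classify cis-NAT candidates and calls
#'
#' A retrocopy overlapping a gene on the opposite strand is a cis-NAT
#' candidate; it is called when at least one transcript of the host gene
#' passes the correlation filter against the retrocopy in all-samples mode
#' (transcription itself can interfere, so zero-TPM samples are kept).
#'
#' @param overlaps output of [find_gene_overlaps()].
#' @param ann the annotation.
#' @param correlations_all [correlate_pairs()] output in `"all"` mode over
#'   (retro, host transcript) pairs.
#' @param p_max,rho_abs_min correlation filter bounds.
#' @return data.frame retro_id, gene_id, context, candidate, called,
#'   best_partner, rho.
#' @export
classify_cis_nat <- function(overlaps, ann, correlations_all,
                             p_max = 0.001, rho_abs_min = 0.25) {
  cand <- overlaps[overlaps$relative_strand == "opposite", , drop = FALSE]
  filt <- filter_correlations(correlations_all, p_max, rho_abs_min)
  out <- cand[, c("retro_id", "gene_id", "context")]
  out$candidate <- TRUE
  out$called <- FALSE
  out$best_partner <- NA_character_
  out$rho <- NA_real_
  tx <- ann$transcripts
  for (i in seq_len(nrow(out))) {
    tids <- tx$transcript_id[tx$gene_id == out$gene_id[i]]
    pass <- filt[(filt$id_a == out$retro_id[i] & filt$id_b %in% tids) |
                   (filt$id_b == out$retro_id[i] & filt$id_a %in% tids), ,
                 drop = FALSE]
    if (nrow(pass)) {
      best <- pass[which.max(abs(pass$rho)), ]
      out$called[i] <- TRUE
      out$best_partner[i] <- ifelse(best$id_a == out$retro_id[i], best$id_b, best$id_a)
      out$rho[i] <- best$rho
    }
  }
  rownames(out) <- NULL
  out
}

#' Identify trans-NAT candidates via three routes
#'
#' Routes: (a) a lncRNA whose exons contain retrocopy sequence on the
#' strand opposite the retrocopy's parental-mRNA orientation; (b) a
#' protein-coding transcript carrying a retrocopy-derived exon in antisense
#' orientation; (c) a TSS on the opposite strand within `tss_window` of the
#' retrocopy 3' end (antisense transcription initiating there would yield a
#' parental-complementary RNA). A route (a)/(b) candidate is called when
#' the antisense transcript passes the correlation filter (coexpressed
#' mode) against at least one parental-gene transcript; route (c), where
#' the antisense transcript is not annotated, is called on the retrocopy's
#' own correlation with a parental transcript. A call lists every route it
#' satisfies.
#'
#' @param catalog retrocopy catalog.
#' @param ann annotation.
#' @param tss_table data.frame chrom, pos, strand (0-based positions).
#' @param correlations_coexpressed [correlate_pairs()] output, coexpressed
#'   mode, covering (candidate, parental transcript) pairs.
#' @param tss_window route (c) window in bases (default 500).
#' @param min_antisense_overlap minimum exon overlap for routes a/b
#'   (default 1 base).
#' @param p_max,rho_abs_min correlation filter bounds.
#' @return data.frame retro_id, route, partner_id, called.
#' @export
identify_trans_nat <- function(catalog, ann, tss_table, correlations_coexpressed,
                               tss_window = 500, min_antisense_overlap = 1,
                               p_max = 0.001, rho_abs_min = 0.25) {
  filt <- filter_correlations(correlations_coexpressed, p_max, rho_abs_min)
  tx <- ann$transcripts
  rows <- list()
  add <- function(retro_id, route, partner, called)
    rows[[length(rows) + 1L]] <<- data.frame(
      retro_id = retro_id, route = route, partner_id = partner,
      called = called, stringsAsFactors = FALSE)
  parental_pass <- function(id, parent_gene) {
    ptids <- tx$transcript_id[tx$gene_id == parent_gene]
    any((filt$id_a == id & filt$id_b %in% ptids) |
          (filt$id_b == id & filt$id_a %in% ptids))
  }
  for (i in seq_len(nrow(catalog))) {
    rid <- catalog$retro_id[i]
    parent <- catalog$parental_gene_id[i]
    # routes (a)/(b): antisense transcript whose exons cover retro sequence
    anti <- tx[tx$chrom == catalog$chrom[i] & tx$strand != catalog$strand[i], ,
               drop = FALSE]
    for (tid in anti$transcript_id) {
      e <- tx_exons(ann, tid)
      ov <- sum(overlap_bases(e, catalog$chrom[i], catalog$start[i],
                              catalog$end[i]))
      if (ov < min_antisense_overlap) next
      bt <- anti$biotype[anti$transcript_id == tid]
      route <- if (bt == "lncRNA") "a" else if (bt == "protein_coding") "b" else next
      add(rid, route, tid, parental_pass(tid, parent))
    }
    # route (c): opposite-strand TSS near the retro 3' end
    if (!is.null(tss_table) && nrow(tss_table)) {
      three_prime <- if (catalog$strand[i] == "+") catalog$end[i] - 1L else catalog$start[i]
      near <- tss_table$chrom == catalog$chrom[i] &
        tss_table$strand != catalog$strand[i] &
        abs(tss_table$pos - three_prime) <= tss_window
      if (any(near))
        add(rid, "c", NA_character_, parental_pass(rid, parent))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(retro_id = character(), route = character(),
               partner_id = character(), called = logical())
  rownames(out) <- NULL
  out
}

## genomic sub-spans of one transcript's exons by region (utr5/cds/utr3);
## strand-aware. NULL when the transcript has no CDS.
tx_region_spans <- function(ann, tid) {
  t <- tx_row(ann, tid)
  if (is.na(t$cds_start) || is.na(t$cds_end)) return(NULL)
  e <- tx_exons(ann, tid)
  pieces <- list()
  for (j in seq_len(nrow(e))) {
    s <- e$start[j]; en <- e$end[j]
    cuts <- sort(unique(pmax(s, pmin(en, c(s, t$cds_start, t$cds_end, en)))))
    for (kk in seq_len(length(cuts) - 1L)) {
      ps <- cuts[kk]; pe <- cuts[kk + 1L]
      if (pe <= ps) next
      region <- if (pe <= t$cds_start) {
        if (t$strand == "+") "utr5" else "utr3"
      } else if (ps >= t$cds_end) {
        if (t$strand == "+") "utr3" else "utr5"
      } else "cds"
      pieces[[length(pieces) + 1L]] <- data.frame(
        region = region, chrom = e$chrom[j], start = ps, end = pe,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, pieces)
}

#' Classify retrocopy contributions to host-gene exons (exonization)
#'
#' For every transcript with at least one exon intersecting a retrocopy,
#' the retro-derived exon portion is intersected with the transcript's
#' 5'UTR/CDS/3'UTR genomic sub-spans. Transcripts lacking a complete CDS
#' are flagged `cds_complete = FALSE` and carry no region classes; they are
#' excluded from CDS-impact tallies.
#'
#' @param catalog retrocopy catalog.
#' @param ann annotation.
#' @return data.frame retro_id, transcript_id, region_classes
#'   (comma-separated subset of utr5,cds,utr3), orientation, cds_complete.
#' @export
classify_exon_contribution <- function(catalog, ann) {
  tx <- ann$transcripts
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    cand <- tx[tx$chrom == catalog$chrom[i], , drop = FALSE]
    for (tid in cand$transcript_id) {
      e <- tx_exons(ann, tid)
      ov <- overlap_bases(e, catalog$chrom[i], catalog$start[i], catalog$end[i])
      if (!any(ov > 0)) next
      t <- cand[cand$transcript_id == tid, ]
      complete <- !is.na(t$cds_start) && !is.na(t$cds_end)
      classes <- NA_character_
      if (complete) {
        reg <- tx_region_spans(ann, tid)
        rov <- overlap_bases(reg, catalog$chrom[i], catalog$start[i],
                             catalog$end[i])
        hit <- unique(reg$region[rov > 0])
        classes <- paste(intersect(c("utr5", "cds", "utr3"), hit), collapse = ",")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        retro_id = catalog$retro_id[i], transcript_id = tid,
        region_classes = classes,
        orientation = if (t$strand == catalog$strand[i]) "same" else "opposite",
        cds_complete = complete, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(retro_id = character(), transcript_id = character(),
               region_classes = character(), orientation = character(),
               cds_complete = logical())
  rownames(out) <- NULL
  out
}

#' Detect transcriptional-interference candidate geometry and calls
#'
#' A retrocopy is a candidate when, within one host gene, (i) some "short"
#' isoform ends no more than `max_downstream` bases upstream of the
#' retrocopy (strand-aware; abutting counts, distance 0) and (ii) some
#' "long" isoform of the same gene has an intron fully containing the
#' retrocopy. Orientation is recorded but not filtered. The call requires
#' the retrocopy to pass the correlation filter with positive rho
#' (all-samples mode) against at least one short isoform and against none
#' of the long isoforms.
#'
#' @param catalog retrocopy catalog.
#' @param ann annotation.
#' @param correlations_all [correlate_pairs()] output, `"all"` mode.
#' @param max_downstream distance bound in bases (default 1000).
#' @param p_max,rho_abs_min correlation filter bounds.
#' @return data.frame retro_id, host_gene_id, short_isoform_ids,
#'   long_isoform_ids, downstream_distance, relative_strand, called.
#' @export
detect_transcriptional_interference <- function(catalog, ann, correlations_all,
                                                max_downstream = 1000,
                                                p_max = 0.001,
                                                rho_abs_min = 0.25) {
  filt <- filter_correlations(correlations_all, p_max, rho_abs_min)
  tx <- ann$transcripts
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    rs <- catalog$start[i]; re <- catalog$end[i]
    for (g in unique(tx$gene_id[tx$chrom == catalog$chrom[i]])) {
      iso <- tx[tx$gene_id == g & tx$chrom == catalog$chrom[i], , drop = FALSE]
      if (nrow(iso) < 2L) next
      # short isoforms: retrocopy starts 0..max_downstream past the 3' end
      d <- if (iso$strand[1] == "+") rs - iso$end else iso$start - re
      shorts <- iso$transcript_id[d >= 0 & d <= max_downstream]
      # long isoforms: an intron fully contains the retrocopy
      longs <- character()
      for (tid in iso$transcript_id) {
        intr <- tx_introns(ann, tid)
        if (nrow(intr) && any(intr$start <= rs & intr$end >= re))
          longs <- c(longs, tid)
      }
      if (!length(shorts) || !length(longs)) next
      pass_pos <- function(tid) {
        sub <- filt[((filt$id_a == catalog$retro_id[i] & filt$id_b == tid) |
                       (filt$id_b == catalog$retro_id[i] & filt$id_a == tid)), ,
                    drop = FALSE]
        nrow(sub) > 0 && any(sub$rho > 0)
      }
      pass_any <- function(tid) corr_passes(filt, catalog$retro_id[i], tid)
      called <- any(vapply(shorts, pass_pos, TRUE)) &&
        !any(vapply(longs, pass_any, TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        retro_id = catalog$retro_id[i], host_gene_id = g,
        short_isoform_ids = paste(shorts, collapse = ","),
        long_isoform_ids = paste(longs, collapse = ","),
        downstream_distance = min(d[d >= 0 & d <= max_downstream]),
        relative_strand = if (iso$strand[1] == catalog$strand[i]) "same" else "opposite",
        called = called, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(retro_id = character(), host_gene_id = character(),
               short_isoform_ids = character(), long_isoform_ids = character(),
               downstream_distance = integer(), relative_strand = character(),
               called = logical())
  rownames(out) <- NULL
  out
}
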