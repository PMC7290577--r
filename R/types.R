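#' retrofunc: multi-evidence functional annotation of retrocopies
#'
#' All coordinates handled by this package are 0-based, half-open
#' `[start, end)` on a named chromosome, the BED/bedGraph convention.
#' GTF input (1-based, inclusive) is converted on read.
#'
#' @keywords internal
"_PACKAGE"

VALID_STRANDS <- c("+", "-", ".")
RETRO_STATUSES <- c("known_pseudogene", "known_protein_coding", "novel", "other")
EVIDENCE_CLASSES <- c("expressed", "pattern", "ribosome", "peptide", "sponge",
                      "cis_nat", "trans_nat", "interference", "exonization",
                      "fusion")

#' Construct a table of genomic intervals
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand strand characters among `+`, `-`, `.`; recycled.
#' @return a data.frame with columns chrom, start, end, strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  gi <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(gi)
  gi
}

validate_intervals <- function(gi, allow_dot = TRUE) {
  if (any(is.na(gi$start)) || any(is.na(gi$end)))
    stop("interval coordinates must be non-missing integers")
  if (any(gi$start < 0)) stop("interval start must be >= 0")
  if (any(gi$end <= gi$start)) stop("interval end must be > start")
  ok <- if (allow_dot) VALID_STRANDS else c("+", "-")
  if (!all(gi$strand %in% ok))
    stop("strand must be one of: ", paste(ok, collapse = " "))
  invisible(gi)
}

#' Width of half-open intervals
#' @param gi an interval data.frame.
#' @return integer vector of widths.
#' @export
interval_width <- function(gi) gi$end - gi$start

## Number of overlapping bases between one interval and a table of intervals
## on the same chromosome scale.  Vectorised over `gi`.
overlap_bases <- function(gi, chrom, start, end) {
  same <- gi$chrom == chrom
  ov <- pmin(gi$end, end) - pmax(gi$start, start)
  ifelse(same & ov > 0, ov, 0L)
}

#' Construct a retrocopy catalog
#'
#' A catalog is a data.frame with one row per retrocopy and an attached
#' per-status tally. Status strings outside the four recognised classes
#' are mapped to `"other"`.
#'
#' @param df data.frame with columns retro_id, chrom, start, end, strand,
#'   status, parental_gene_id and optionally parental_transcript_id.
#' @return a `retro_catalog` data.frame; `attr(, "status_tally")` holds the
#'   per-status counts.
#' @export
retro_catalog <- function(df) {
  need <- c("retro_id", "chrom", "start", "end", "strand", "status",
            "parental_gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog missing columns: ", paste(miss, collapse = ", "))
  df$retro_id <- as.character(df$retro_id)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (anyDuplicated(df$retro_id))
    stop("duplicate retro_id in catalog: ",
         paste(unique(df$retro_id[duplicated(df$retro_id)]), collapse = ", "))
  if (any(!nzchar(df$parental_gene_id) | is.na(df$parental_gene_id)))
    stop("parental_gene_id must be non-empty")
  if (!"parental_transcript_id" %in% names(df))
    df$parental_transcript_id <- rep(NA_character_, nrow(df))
  df$status <- ifelse(df$status %in% RETRO_STATUSES, df$status, "other")
  if (nrow(df)) validate_intervals(df, allow_dot = FALSE)
  tally <- table(factor(df$status, levels = RETRO_STATUSES))
  stopifnot(sum(tally) == nrow(df))
  structure(df, status_tally = tally, class = c("retro_catalog", "data.frame"))
}

#' Build a transcript annotation from exon and transcript tables
#'
#' @param exons data.frame with transcript_id, chrom, start, end, strand
#'   (one row per exon, 0-based half-open).
#' @param transcripts data.frame with transcript_id, gene_id, biotype and
#'   optionally cds_start, cds_end (genomic, 0-based half-open; NA if the
#'   transcript carries no CDS).
#' @return a `retro_annotation` object: list with sorted `exons` and a
#'   per-transcript table carrying span, TSS/TES and CDS columns.
#' @export
annotation <- function(exons, transcripts) {
  stopifnot(all(c("transcript_id", "chrom", "start", "end", "strand") %in% names(exons)),
            all(c("transcript_id", "gene_id", "biotype") %in% names(transcripts)))
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  validate_intervals(exons, allow_dot = FALSE)
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (!"cds_start" %in% names(transcripts)) transcripts$cds_start <- NA_integer_
  if (!"cds_end" %in% names(transcripts)) transcripts$cds_end <- NA_integer_

  sp <- split(exons, exons$transcript_id)
  # per-transcript invariants: one chrom/strand, non-overlapping sorted exons
  for (tid in names(sp)) {
    e <- sp[[tid]]
    if (length(unique(e$chrom)) != 1L || length(unique(e$strand)) != 1L)
      stop("transcript ", tid, ": exons on multiple chroms/strands")
    if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)]))
      stop("transcript ", tid, ": overlapping exons")
  }
  tx <- transcripts[match(names(sp), transcripts$transcript_id), , drop = FALSE]
  if (any(is.na(tx$transcript_id)))
    stop("exons reference transcripts absent from the transcript table")
  tx$chrom <- vapply(sp, function(e) e$chrom[1], "")
  tx$strand <- vapply(sp, function(e) e$strand[1], "")
  tx$start <- vapply(sp, function(e) min(e$start), 0L)
  tx$end <- vapply(sp, function(e) max(e$end), 0L)
  tx$n_exons <- vapply(sp, nrow, 0L)
  # tss/tes as 0-based positions of the 5'-most / 3'-most transcribed base
  tx$tss <- ifelse(tx$strand == "+", tx$start, tx$end - 1L)
  tx$tes <- ifelse(tx$strand == "+", tx$end - 1L, tx$start)
  tx$cds_start <- as.integer(tx$cds_start); tx$cds_end <- as.integer(tx$cds_end)
  has_cds <- !is.na(tx$cds_start) & !is.na(tx$cds_end)
  for (i in which(has_cds)) {
    e <- sp[[tx$transcript_id[i]]]
    cov <- sum(pmin(e$end, tx$cds_end[i]) - pmax(e$start, tx$cds_start[i]) > 0)
    inside <- tx$cds_start[i] >= tx$start[i] && tx$cds_end[i] <= tx$end[i] && cov > 0
    if (!inside) stop("transcript ", tx$transcript_id[i], ": CDS outside exon span")
  }
  rownames(tx) <- NULL
  structure(list(exons = exons, transcripts = tx), class = "retro_annotation")
}

#' @export
print.retro_annotation <- function(x, ...) {
  cat("retro_annotation:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

tx_exons <- function(ann, tid) {
  ann$exons[ann$exons$transcript_id == tid, , drop = FALSE]
}

tx_row <- function(ann, tid) {
  ann$transcripts[ann$transcripts$transcript_id == tid, , drop = FALSE]
}

## introns of one transcript as an interval data.frame (may be empty)
tx_introns <- function(ann, tid) {
  e <- tx_exons(ann, tid)
  if (nrow(e) < 2L)
    return(e[0, c("chrom", "start", "end", "strand"), drop = FALSE])
  data.frame(chrom = e$chrom[1], start = e$end[-nrow(e)], end = e$start[-1],
             strand = e$strand[1], stringsAsFactors = FALSE)
}

#' Transcribed-length of transcripts (sum of exon widths)
#' @param ann a `retro_annotation`.
#' @param transcript_id one transcript id.
#' @return integer number of transcribed bases.
#' @export
transcribed_length <- function(ann, transcript_id) {
  e <- tx_exons(ann, transcript_id)
  sum(e$end - e$start)
}

## gene-level spans: one row per gene (union of isoform spans incl. introns)
gene_spans <- function(ann) {
  tx <- ann$transcripts
  sp <- split(tx, tx$gene_id)
  out <- do.call(rbind, lapply(sp, function(g) data.frame(
    gene_id = g$gene_id[1], chrom = g$chrom[1],
    start = min(g$start), end = max(g$end), strand = g$strand[1],
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Construct an expression matrix with sample metadata
#'
#' @param tpm numeric matrix (transcripts x samples) of non-negative TPM.
#' @param samples data.frame with sample_id, tissue_label, is_cancer_line,
#'   is_control; one row per matrix column, in column order.
#' @return an `ExpressionMatrix` (list with `tpm` and `samples`).
#' @export
expression_matrix <- function(tpm, samples) {
  stopifnot(is.matrix(tpm), all(c("sample_id", "tissue_label", "is_cancer_line",
                                  "is_control") %in% names(samples)))
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  if (ncol(tpm) != nrow(samples))
    stop("sample metadata rows (", nrow(samples), ") do not match matrix columns (",
         ncol(tpm), ")")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (is.null(colnames(tpm))) colnames(tpm) <- samples$sample_id
  if (!identical(colnames(tpm), as.character(samples$sample_id)))
    stop("matrix column names do not match metadata sample_ids")
  if (is.null(rownames(tpm))) stop("tpm matrix must have row names (transcript ids)")
  structure(list(tpm = tpm, samples = samples), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$tpm), "transcripts x", ncol(x$tpm), "samples\n")
  invisible(x)
}

#' Construct a coverage track
#'
#' @param records data.frame with chrom, start, end, depth; records must be
#'   non-overlapping within a chromosome (the standard for aggregate
#'   bedGraph tracks); overlap is an input error, never silently summed.
#' @param library_id library name.
#' @param assay `"ribo"` or `"rna"`.
#' @return a `CoverageTrack`.
#' @export
coverage_track <- function(records, library_id, assay = c("rna", "ribo")) {
  assay <- match.arg(assay)
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(records)))
  records$start <- as.integer(records$start); records$end <- as.integer(records$end)
  records$depth <- as.numeric(records$depth)
  if (any(is.na(records$depth))) stop("non-numeric depth in coverage records")
  if (any(records$depth < 0)) stop("coverage depth must be >= 0")
  records$strand <- NULL
  records <- records[order(records$chrom, records$start), , drop = FALSE]
  if (nrow(records)) {
    validate_intervals(cbind(records, strand = "."))
    by_chrom <- split(records, records$chrom)
    for (ch in names(by_chrom)) {
      r <- by_chrom[[ch]]
      if (nrow(r) > 1L && any(r$start[-1] < r$end[-nrow(r)]))
        stop("overlapping bedGraph records on ", ch)
    }
  }
  rownames(records) <- NULL
  structure(list(library_id = library_id, assay = assay, records = records),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack", x$library_id, "(", x$assay, "):", nrow(x$records),
      "records\n")
  invisible(x)
}

#' Construct a fusion-breakpoint table
#'
#' @param df data.frame with fusion_id, gene5_id, gene3_id, chrom5, pos5,
#'   chrom3, pos3 and optionally source_label.
#' @return validated fusion table.
#' @export
fusion_table <- function(df) {
  need <- c("fusion_id", "gene5_id", "gene3_id", "chrom5", "pos5", "chrom3", "pos3")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fusion table missing columns: ", paste(miss, collapse = ", "))
  df$pos5 <- as.integer(df$pos5); df$pos3 <- as.integer(df$pos3)
  if (any(df$pos5 < 0 | df$pos3 < 0, na.rm = TRUE)) stop("breakpoint positions must be >= 0")
  if (any(!nzchar(df$gene5_id) | !nzchar(df$gene3_id)))
    stop("fusion partner gene ids must be non-empty")
  if (!"source_label" %in% names(df)) df$source_label <- NA_character_
  df
}

## EvidenceCall rows: uniform container appended by every calling stage.
evidence_calls <- function(retro_id = character(), evidence_class = character(),
                           partner_id = character(), stats = list()) {
  stopifnot(all(evidence_class %in% EVIDENCE_CLASSES))
  n <- length(retro_id)
  df <- data.frame(retro_id = retro_id,
                   evidence_class = evidence_class,
                   partner_id = if (n) partner_id else character(),
                   stringsAsFactors = FALSE)
  for (nm in names(stats)) df[[nm]] <- stats[[nm]]
  df
}
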