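## Readers and writers for the external formats the pipeline touches.
## All tables are plain TSV; coordinates are converted to the internal
## 0-based half-open convention on read.

read_tsv_strict <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss))
      stop(path, ": missing required columns: ", paste(miss, collapse = ", "))
  }
  df
}

#' Read a transcript annotation from GTF or BED12
#'
#' GTF is recognised by the `.gtf` extension (or `format = "gtf"`); exon
#' rows build the transcript structure and CDS rows, when present, define
#' the genomic CDS span. GTF's 1-based inclusive coordinates are converted
#' to 0-based half-open. BED12 is consumed natively: blocks become exons,
#' thickStart/thickEnd (when distinct) become the CDS span, and the name
#' field is taken as `transcript_id` (or `transcript_id|gene_id|biotype`).
#'
#' @param path input file.
#' @param format `"auto"`, `"gtf"` or `"bed12"`.
#' @return a [annotation()] object.
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed12"
  if (format == "gtf") read_annotation_gtf(path) else read_annotation_bed12(path)
}

gtf_attr <- function(attr, key) {
  m <- regmatches(attr, regexpr(paste0(key, ' "[^"]*"'), attr))
  out <- rep(NA_character_, length(attr))
  hit <- nchar(m) > 0
  out[which(hit)] <- sub(paste0(key, ' "([^"]*)"'), "\\1", m[nchar(m) > 0])
  out
}

read_annotation_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 9L)
  if (length(bad)) stop(path, ": malformed GTF line ", bad[1])
  m <- do.call(rbind, lapply(f, function(x) x[1:9]))
  feat <- m[, 3]
  keep <- feat %in% c("exon", "CDS")
  m <- m[keep, , drop = FALSE]; feat <- feat[keep]
  start <- suppressWarnings(as.integer(m[, 4])) - 1L  # to 0-based
  end <- suppressWarnings(as.integer(m[, 5]))
  if (any(is.na(start)) || any(is.na(end)))
    stop(path, ": non-numeric coordinates")
  tid <- gtf_attr(m[, 9], "transcript_id")
  gid <- gtf_attr(m[, 9], "gene_id")
  bt <- gtf_attr(m[, 9], "transcript_biotype")
  if (any(is.na(tid))) stop(path, ": exon/CDS record without transcript_id")
  ex <- feat == "exon"
  exons <- data.frame(transcript_id = tid[ex], chrom = m[ex, 1],
                      start = start[ex], end = end[ex], strand = m[ex, 7],
                      stringsAsFactors = FALSE)
  tx <- unique(data.frame(transcript_id = tid[ex], gene_id = gid[ex],
                          biotype = ifelse(is.na(bt[ex]), "other", bt[ex]),
                          stringsAsFactors = FALSE))
  cds <- feat == "CDS"
  if (any(cds)) {
    agg_min <- tapply(start[cds], tid[cds], min)
    agg_max <- tapply(end[cds], tid[cds], max)
    tx$cds_start <- as.integer(agg_min[tx$transcript_id])
    tx$cds_end <- as.integer(agg_max[tx$transcript_id])
  }
  annotation(exons, tx)
}

read_annotation_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 12L)
  if (length(bad)) stop(path, ": line ", bad[1], " has fewer than 12 BED fields")
  exl <- list(); txl <- list()
  for (i in seq_along(f)) {
    x <- f[[i]]
    chrom <- x[1]
    start <- suppressWarnings(as.integer(x[2])); end <- suppressWarnings(as.integer(x[3]))
    if (is.na(start) || is.na(end)) stop(path, ": line ", i, ": non-numeric coordinates")
    name <- strsplit(x[4], "|", fixed = TRUE)[[1]]
    tid <- name[1]
    gid <- if (length(name) >= 2) name[2] else tid
    bt <- if (length(name) >= 3) name[3] else "other"
    strand <- x[6]
    thick_s <- as.integer(x[7]); thick_e <- as.integer(x[8])
    n_blocks <- as.integer(x[10])
    sizes <- as.integer(strsplit(sub(",$", "", x[11]), ",")[[1]])
    starts <- as.integer(strsplit(sub(",$", "", x[12]), ",")[[1]])
    if (length(sizes) != n_blocks || length(starts) != n_blocks)
      stop(path, ": line ", i, ": blockCount disagrees with block lists")
    exl[[i]] <- data.frame(transcript_id = tid, chrom = chrom,
                           start = start + starts, end = start + starts + sizes,
                           strand = strand, stringsAsFactors = FALSE)
    txl[[i]] <- data.frame(transcript_id = tid, gene_id = gid, biotype = bt,
                           cds_start = if (thick_e > thick_s) thick_s else NA_integer_,
                           cds_end = if (thick_e > thick_s) thick_e else NA_integer_,
                           stringsAsFactors = FALSE)
  }
  annotation(do.call(rbind, exl), do.call(rbind, txl))
}

#' Read a retrocopy catalog TSV
#'
#' Expects columns retro_id, chrom, start, end, strand, status,
#' parental_gene_id (0-based half-open coordinates). Status strings outside
#' the four recognised classes map to `"other"`. The attached status tally
#' always sums to the record count (asserted on every read).
#'
#' @param path TSV file.
#' @return a [retro_catalog()].
#' @export
read_retrocopy_catalog <- function(path) {
  df <- read_tsv_strict(path, required = c("retro_id", "chrom", "start", "end",
                                           "strand", "status", "parental_gene_id"))
  retro_catalog(df)
}

#' Write a retrocopy catalog TSV
#' @param catalog a [retro_catalog()].
#' @param path output file.
#' @export
write_retrocopy_catalog <- function(catalog, path) {
  write_stamped_tsv(as.data.frame(catalog), path, producer = "datamodel_io")
}

#' Read an expression matrix and its sample metadata
#'
#' The matrix TSV has transcripts in rows (first column `transcript_id`)
#' and samples in columns; the metadata TSV has one row per sample with
#' sample_id, tissue_label, is_cancer_line, is_control. Every matrix column
#' must be described in the metadata.
#'
#' @param path matrix TSV.
#' @param meta_path metadata TSV.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, meta_path) {
  df <- read_tsv_strict(path)
  if (names(df)[1] != "transcript_id")
    stop(path, ": first column must be transcript_id")
  meta <- read_tsv_strict(meta_path, required = c("sample_id", "tissue_label",
                                                  "is_cancer_line", "is_control"))
  meta$is_cancer_line <- as.logical(meta$is_cancer_line)
  meta$is_control <- as.logical(meta$is_control)
  tpm <- as.matrix(df[, -1, drop = FALSE])
  mode(tpm) <- "numeric"
  rownames(tpm) <- df$transcript_id
  missing_meta <- setdiff(colnames(tpm), meta$sample_id)
  if (length(missing_meta))
    stop("samples in matrix missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  meta <- meta[match(colnames(tpm), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  expression_matrix(tpm, meta)
}

#' Write an expression matrix and metadata to TSV
#' @param em an [expression_matrix()].
#' @param path matrix TSV path.
#' @param meta_path metadata TSV path.
#' @export
write_expression_matrix <- function(em, path, meta_path) {
  df <- data.frame(transcript_id = rownames(em$tpm), em$tpm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(em$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph coverage file
#'
#' Records must be non-overlapping within each chromosome; overlap is
#' rejected rather than summed, since aggregate tracks are flat by
#' construction.
#'
#' @param path bedGraph file.
#' @param library_id library name recorded on the track.
#' @param assay `"rna"` or `"ribo"` (the file itself does not say).
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, library_id = basename(path),
                          assay = c("rna", "ribo")) {
  assay <- match.arg(assay)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(coverage_track(data.frame(chrom = character(), start = integer(),
                                     end = integer(), depth = numeric()),
                          library_id, assay))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 4L)
  if (length(bad)) stop(path, ": line ", bad[1], " has fewer than 4 fields")
  m <- do.call(rbind, lapply(f, function(x) x[1:4]))
  depth <- suppressWarnings(as.numeric(m[, 4]))
  if (any(is.na(depth))) stop(path, ": non-numeric depth at line ",
                              which(is.na(depth))[1])
  rec <- data.frame(chrom = m[, 1],
                    start = suppressWarnings(as.integer(m[, 2])),
                    end = suppressWarnings(as.integer(m[, 3])),
                    depth = depth, stringsAsFactors = FALSE)
  if (any(is.na(rec$start)) || any(is.na(rec$end)))
    stop(path, ": non-numeric coordinates")
  coverage_track(rec, library_id, assay)
}

#' Write a coverage track as bedGraph
#' @param track a [coverage_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track$records[, c("chrom", "start", "end", "depth")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a fusion-breakpoint table
#' @param path TSV with fusion_id, gene5_id, gene3_id, chrom5, pos5, chrom3,
#'   pos3 columns.
#' @return validated fusion table.
#' @export
read_fusion_table <- function(path) {
  fusion_table(read_tsv_strict(path, required = c("fusion_id", "gene5_id",
                                                  "gene3_id", "chrom5", "pos5",
                                                  "chrom3", "pos3")))
}

## hash of an R object, via serialization to a temp file (no digest dep)
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(utils::capture.output(utils::str(x, give.head = FALSE)), tf)
  unname(tools::md5sum(tf))
}

#' Write a TSV with a commented provenance header
#'
#' Every writer in the pipeline emits tab-separated files carrying a
#' comment line naming the producing module and a hash of the parameters
#' used, so outputs are auditable.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param producer module name for the header.
#' @param params optional parameter list hashed into the header.
#' @export
write_stamped_tsv <- function(df, path, producer, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# producer=%s config=%s", producer,
                     if (is.null(params)) "default" else config_hash(params)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
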