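## Orchestration: run every stage on a directory of input files (the
## layout write_world() emits), write per-stage call TSVs, and aggregate
## an evidence summary with a regulatory-network edge list.

#' Pipeline parameters
#'
#' Collects every stage threshold in one audited place. Defaults follow
#' the documented analysis: 1 TPM in 1% of experiments; Spearman filter
#' p < 0.001 and |rho| > 0.25 with >= 10 usable samples; RNA coverage >= 10
#' and Z trimming/cutoff at 1.64; ORFs >= 20 codons overlapping the
#' retrocopy by >= 60 b within +/-500 b loci; peptides >= 10 aa; BH alpha
#' 0.05; TSS window 500 b; interference window 1000 b; fusion near bound
#' 1000 b. `ribo_min_positive_fraction` is the cross-library fraction of
#' positive libraries required to summarise a retrocopy as
#' ribosome-associated.
#'
#' @param ... overrides of any default listed above.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(min_tpm = 1, min_sample_fraction = 0.01,
            p_max = 0.001, rho_abs_min = 0.25, min_pair_samples = 10,
            min_rna_coverage = 10, z_abs_max = 1.64, utr_z_cutoff = 1.64,
            min_utr3_records = 20,
            min_orf_overlap = 60, extension = 500, min_peptide_len = 10,
            alpha = 0.05, tss_window = 500, max_downstream = 1000,
            near_max = 1000, ribo_min_positive_fraction = 0.3)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameters: ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}

read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

## spliced sequence of one transcript (5'->3')
tx_sequence <- function(genome, ann, tid) {
  e <- tx_exons(ann, tid)
  s <- paste(vapply(seq_len(nrow(e)), function(j)
    substr(genome[[e$chrom[j]]], e$start[j] + 1L, e$end[j]), ""), collapse = "")
  if (e$strand[1] == "-") revcomp(s) else s
}

## translated CDS of one transcript, NA when no CDS annotated
tx_protein <- function(genome, ann, tid) {
  t <- tx_row(ann, tid)
  if (is.na(t$cds_start)) return(NA_character_)
  e <- tx_exons(ann, tid)
  pieces <- character()
  for (j in seq_len(nrow(e))) {
    s <- max(e$start[j], t$cds_start); en <- min(e$end[j], t$cds_end)
    if (en > s) pieces <- c(pieces, substr(genome[[e$chrom[j]]], s + 1L, en))
  }
  nt <- paste(pieces, collapse = "")
  if (t$strand == "-") nt <- revcomp(nt)
  translate_nt(nt)
}

## six-frame ORFs for every catalog retrocopy, genomic coordinates
catalog_orfs <- function(genome, catalog, extension = 500, min_overlap = 60) {
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    chrom <- catalog$chrom[i]
    L <- nchar(genome[[chrom]])
    w_s <- max(0L, catalog$start[i] - extension)
    w_e <- min(L, catalog$end[i] + extension)
    locus <- substr(genome[[chrom]], w_s + 1L, w_e)
    orfs <- six_frame_orfs(locus, catalog$start[i] - w_s, catalog$end[i] - w_s,
                           retro_strand = catalog$strand[i],
                           min_overlap = min_overlap)
    if (!nrow(orfs)) next
    orfs$start <- orfs$start + w_s
    orfs$end <- orfs$end + w_s
    orfs$retro_id <- catalog$retro_id[i]
    rows[[length(rows) + 1L]] <- orfs
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), strand = character(),
               frame = integer(), orientation = character(),
               aa_sequence = character(), overlap_with_retro = integer(),
               retro_id = character())
  out$orf_id <- if (nrow(out)) sprintf("orf_%05d", seq_len(nrow(out))) else character()
  rownames(out) <- NULL
  out
}

## correlation pair plan: retro vs parental transcripts (coexpressed);
## antisense transcripts vs parental (coexpressed); retro vs host-gene
## isoforms (all mode); sponge-candidate pairs (coexpressed)
build_pair_plan <- function(catalog, ann, overlaps, site_map, em) {
  tx <- ann$transcripts
  ids <- rownames(em$tpm)
  pp <- function(a, b) {
    keep <- a %in% ids & b %in% ids & a != b
    data.frame(id_a = a[keep], id_b = b[keep], stringsAsFactors = FALSE)
  }
  coex <- list(); allm <- list()
  for (i in seq_len(nrow(catalog))) {
    rid <- catalog$retro_id[i]
    ptids <- tx$transcript_id[tx$gene_id == catalog$parental_gene_id[i]]
    coex[[length(coex) + 1L]] <- pp(rep(rid, length(ptids)), ptids)
    anti <- tx$transcript_id[tx$chrom == catalog$chrom[i] &
                               tx$strand != catalog$strand[i]]
    for (tid in anti) {
      e <- tx_exons(ann, tid)
      if (sum(overlap_bases(e, catalog$chrom[i], catalog$start[i],
                            catalog$end[i])) > 0)
        coex[[length(coex) + 1L]] <- pp(rep(tid, length(ptids)), ptids)
    }
  }
  for (i in seq_len(nrow(overlaps))) {
    htids <- tx$transcript_id[tx$gene_id == overlaps$gene_id[i]]
    allm[[length(allm) + 1L]] <- pp(rep(overlaps$retro_id[i], length(htids)), htids)
  }
  if (!is.null(site_map)) {
    fam_by_seq <- split(site_map$sites$family, site_map$sites$sequence_id)
    retro_in <- intersect(catalog$retro_id, names(fam_by_seq))
    t_in <- intersect(setdiff(names(fam_by_seq), catalog$retro_id), ids)
    for (rid in retro_in) {
      share <- vapply(t_in, function(t)
        length(intersect(fam_by_seq[[rid]], fam_by_seq[[t]])) > 0, TRUE)
      if (any(share))
        coex[[length(coex) + 1L]] <- pp(rep(rid, sum(share)), t_in[share])
    }
  }
  dedup <- function(l) {
    d <- do.call(rbind, l)
    if (is.null(d)) return(data.frame(id_a = character(), id_b = character()))
    unique(d)
  }
  list(coexpressed = dedup(coex), all = dedup(allm))
}

#' Run the full multi-evidence pipeline on a fixture directory
#'
#' Expects the file layout of [write_world()]: genome.fa, catalog.tsv,
#' annotation.bed, expression.tsv + samples.tsv, lib*_{rna,ribo}.bedgraph,
#' density_features.tsv, peptides.tsv, mirna_sites.tsv, tss.tsv,
#' fusions.tsv (any of which may be absent if its stage is disabled).
#' Stages run in dependency order: expression -> correlations -> ribo,
#' peptides, sponges, overlap/NAT/interference, fusion -> summary. Every
#' output TSV carries the producing module and a hash of the parameters; a
#' JSON run log records per-stage counts and warnings.
#'
#' @param input_dir directory of inputs.
#' @param outdir output directory (created).
#' @param params a [pipeline_params()] list.
#' @param stages character subset of
#'   c("expression","ribo","peptides","sponges","overlap","fusion").
#' @return invisible list of in-memory stage results (`summary` holds the
#'   evidence matrix and network).
#' @export
run_pipeline <- function(input_dir, outdir, params = pipeline_params(),
                         stages = c("expression", "ribo", "peptides",
                                    "sponges", "overlap", "fusion")) {
  need <- c(catalog = "catalog.tsv", annotation = "annotation.bed",
            expression = "expression.tsv", samples = "samples.tsv")
  for (f in need)
    if (!file.exists(file.path(input_dir, f)))
      stop("missing required input: ", f)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  log <- list(params = params, stages = list())
  res <- list()

  catalog <- read_retrocopy_catalog(file.path(input_dir, "catalog.tsv"))
  ann <- read_annotation(file.path(input_dir, "annotation.bed"))
  em <- read_expression_matrix(file.path(input_dir, "expression.tsv"),
                               file.path(input_dir, "samples.tsv"))

  ## expression stage
  expressed <- filter_expressed(em, params$min_tpm, params$min_sample_fraction)
  patterns <- classify_pattern(em, intersect(rownames(em$tpm), catalog$retro_id),
                               params$min_tpm)
  if ("expression" %in% stages) {
    write_stamped_tsv(data.frame(transcript_id = expressed), p("expressed_ids.tsv"),
                      "expression_analysis", params)
    write_stamped_tsv(patterns, p("patterns.tsv"), "expression_analysis", params)
  }
  log$stages$expression <- list(n_expressed = length(expressed),
                                n_retro_expressed = sum(catalog$retro_id %in% expressed))

  ## correlations (shared by several stages)
  overlaps <- find_gene_overlaps(catalog, ann)
  site_path <- file.path(input_dir, "mirna_sites.tsv")
  site_map <- if (file.exists(site_path)) read_site_table(site_path) else NULL
  plan <- build_pair_plan(catalog, ann, overlaps, site_map, em)
  corr_coex <- correlate_pairs(em, plan$coexpressed, "coexpressed",
                               params$min_pair_samples)
  corr_all <- correlate_pairs(em, plan$all, "all", params$min_pair_samples)
  corr <- rbind(corr_coex, corr_all)
  corr$kept <- corr$p < params$p_max & abs(corr$rho) > params$rho_abs_min
  write_stamped_tsv(corr, p("correlations.tsv"), "expression_analysis", params)
  log$stages$correlations <- list(n_pairs = nrow(corr), n_kept = sum(corr$kept))

  ## ribosome density
  if ("ribo" %in% stages &&
      file.exists(file.path(input_dir, "density_features.tsv"))) {
    feats <- read_tsv_strict(file.path(input_dir, "density_features.tsv"),
                             required = c("feature_id", "group", "chrom",
                                          "start", "end"))
    rna_files <- sort(list.files(input_dir, "_rna\\.bedgraph$", full.names = TRUE))
    recs <- list()
    for (rf in rna_files) {
      lib <- sub("_rna\\.bedgraph$", "", basename(rf))
      bf <- file.path(input_dir, paste0(lib, "_ribo.bedgraph"))
      if (!file.exists(bf)) next
      rna <- read_bedgraph(rf, lib, "rna")
      ribo <- read_bedgraph(bf, lib, "ribo")
      recs[[lib]] <- compute_density(ribo, rna, feats, params$min_rna_coverage)
    }
    dens <- do.call(rbind, recs)
    rc <- calibrate_and_call(dens, params$utr_z_cutoff, params$z_abs_max,
                             params$min_utr3_records)
    write_stamped_tsv(dens, p("density.tsv"), "ribosome_density", params)
    write_stamped_tsv(rc$calibration, p("calibration.tsv"), "ribosome_density", params)
    write_stamped_tsv(rc$summary, p("ribo_calls.tsv"), "ribosome_density", params)
    res$ribo <- rc
    log$stages$ribo <- list(n_libraries = nrow(rc$calibration),
                            n_positive_any = sum(rc$summary$n_positive_libraries > 0))
  }

  ## peptides
  if ("peptides" %in% stages &&
      file.exists(file.path(input_dir, "peptides.tsv")) &&
      file.exists(file.path(input_dir, "genome.fa"))) {
    genome <- read_genome_fasta(file.path(input_dir, "genome.fa"))
    peptides <- read_tsv_strict(file.path(input_dir, "peptides.tsv"),
                                required = c("peptide_id", "aa_sequence"))
    orfs <- catalog_orfs(genome, catalog, params$extension, params$min_orf_overlap)
    pc <- ann$transcripts$transcript_id[ann$transcripts$biotype == "protein_coding"]
    decoys <- vapply(pc, function(t) tx_protein(genome, ann, t), "")
    decoys <- decoys[!is.na(decoys)]
    hits <- match_peptides(peptides, orfs, decoys, params$min_peptide_len)
    anchor_path <- file.path(input_dir, "anchors.tsv")
    if (file.exists(anchor_path)) {
      anchors <- read_tsv_strict(anchor_path, required = c("retro_id", "codon_anchor"))
      hits <- annotate_frame_concordance(hits, orfs, catalog, anchors)
    }
    write_stamped_tsv(hits, p("peptide_hits.tsv"), "peptide_mapping", params)
    res$peptides <- hits
    log$stages$peptides <- list(n_hits = nrow(hits),
                                n_final = sum(hits$final),
                                n_retro_supported = length(unique(hits$retro_id[hits$final])))
  }

  ## sponges
  if ("sponges" %in% stages && !is.null(site_map)) {
    sponge <- call_sponges(site_map, catalog$retro_id,
                           setdiff(unique(site_map$sites$sequence_id),
                                   catalog$retro_id),
                           corr_coex, params$alpha, params$p_max,
                           params$rho_abs_min)
    write_stamped_tsv(sponge, p("sponge_calls.tsv"), "mirna_sponge", params)
    res$sponge <- sponge
    log$stages$sponges <- list(n_tested = nrow(sponge), n_called = sum(sponge$called))
  }

  ## overlap-derived classifiers
  if ("overlap" %in% stages) {
    tss_path <- file.path(input_dir, "tss.tsv")
    tss <- if (file.exists(tss_path))
      read_tsv_strict(tss_path, required = c("chrom", "pos", "strand")) else
      data.frame(chrom = character(), pos = integer(), strand = character())
    cis <- classify_cis_nat(overlaps, ann, corr_all, params$p_max,
                            params$rho_abs_min)
    trans <- identify_trans_nat(catalog, ann, tss, corr_coex,
                                params$tss_window, 1, params$p_max,
                                params$rho_abs_min)
    exo <- classify_exon_contribution(catalog, ann)
    intf <- detect_transcriptional_interference(catalog, ann, corr_all,
                                                params$max_downstream,
                                                params$p_max, params$rho_abs_min)
    write_stamped_tsv(overlaps, p("overlaps.tsv"), "overlap_regulation", params)
    write_stamped_tsv(cis, p("cis_nat_calls.tsv"), "overlap_regulation", params)
    write_stamped_tsv(trans, p("trans_nat_calls.tsv"), "overlap_regulation", params)
    write_stamped_tsv(exo, p("exon_contributions.tsv"), "overlap_regulation", params)
    write_stamped_tsv(intf, p("interference_calls.tsv"), "overlap_regulation", params)
    res$cis_nat <- cis; res$trans_nat <- trans; res$exonization <- exo
    res$interference <- intf
    log$stages$overlap <- list(n_overlaps = nrow(overlaps),
                               n_cis_called = sum(cis$called),
                               n_trans_called = sum(trans$called),
                               n_interference_called = sum(intf$called))
  }

  ## fusions
  if ("fusion" %in% stages && file.exists(file.path(input_dir, "fusions.tsv"))) {
    fus <- read_fusion_table(file.path(input_dir, "fusions.tsv"))
    fcls <- classify_fusions(fus, catalog, ann, params$near_max)
    write_stamped_tsv(fcls, p("fusion_calls.tsv"), "fusion_recombination", params)
    res$fusion <- fcls
    log$stages$fusion <- list(n_breakpoint_rows = nrow(fcls))
  }

  res$expressed <- expressed
  res$patterns <- patterns
  res$correlations <- corr
  res$summary <- summarize_evidence(catalog, res, params)
  write_stamped_tsv(res$summary$matrix, p("evidence_summary.tsv"),
                    "cli_pipeline", params)
  write_stamped_tsv(res$summary$network, p("network_edges.tsv"),
                    "cli_pipeline", params)
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Aggregate per-retrocopy evidence and build the regulatory network
#'
#' Rows are retrocopies, columns evidence classes; the network edge list
#' carries mechanism (sponge, cis_nat, trans_nat, interference) and the
#' correlation sign; retrocopies with more than one mechanism are flagged
#' dual-function.
#'
#' @param catalog retrocopy catalog.
#' @param res stage-result list as assembled by [run_pipeline()].
#' @param params a [pipeline_params()] list.
#' @return list with `matrix`, `network`, `counts`.
#' @export
summarize_evidence <- function(catalog, res, params = pipeline_params()) {
  rid <- catalog$retro_id
  m <- data.frame(retro_id = rid, stringsAsFactors = FALSE)
  m$expressed <- rid %in% res$expressed
  if (!is.null(res$patterns))
    m$pattern <- res$patterns$pattern[match(rid, res$patterns$retro_id)]
  if (!is.null(res$ribo)) {
    s <- res$ribo$summary
    frac <- s$n_positive_libraries / pmax(1, s$n_libraries_tested)
    pos <- s$retro_id[frac >= params$ribo_min_positive_fraction]
    m$ribosome <- rid %in% pos
  }
  if (!is.null(res$peptides))
    m$peptide <- rid %in% res$peptides$retro_id[res$peptides$final]
  edges <- list()
  add_edges <- function(df, retro_col, partner_col, mech, sign_col = NULL) {
    if (is.null(df) || !nrow(df)) return()
    called <- df[df$called, , drop = FALSE]
    if (!nrow(called)) return()
    sign <- if (!is.null(sign_col)) called[[sign_col]]
            else if (!is.null(called$rho))
              ifelse(is.na(called$rho), NA_character_,
                     ifelse(called$rho >= 0, "positive", "negative"))
            else rep(NA_character_, nrow(called))
    edges[[length(edges) + 1L]] <<- data.frame(
      retro_id = called[[retro_col]], partner = called[[partner_col]],
      mechanism = mech, sign = sign, stringsAsFactors = FALSE)
  }
  add_edges(res$sponge, "retro_id", "transcript_id", "sponge", "corr_sign")
  add_edges(res$cis_nat, "retro_id", "gene_id", "cis_nat")
  add_edges(res$trans_nat, "retro_id", "partner_id", "trans_nat")
  add_edges(res$interference, "retro_id", "host_gene_id", "interference")
  network <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(retro_id = character(), partner = character(),
               mechanism = character(), sign = character())
  rownames(network) <- NULL
  for (mech in c("sponge", "cis_nat", "trans_nat", "interference"))
    m[[mech]] <- rid %in% network$retro_id[network$mechanism == mech]
  n_mech <- rowSums(m[, intersect(c("sponge", "cis_nat", "trans_nat",
                                    "interference"), names(m)), drop = FALSE])
  m$dual_function <- n_mech >= 2
  counts <- colSums(m[vapply(m, is.logical, TRUE)])
  list(matrix = m, network = network, counts = as.list(counts))
}
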