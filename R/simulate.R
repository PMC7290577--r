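## Synthetic-data generator: a small genome with genes, retrocopies and
## planted evidence of every class the pipeline calls, plus the expression
## matrix, coverage tracks, peptide list, miRNA-site table, TSS table and
## fusion table that exercise each stage. Ground truth is machine-readable
## so recovery can be asserted.
##
## The stated world (defaults): 24 plain protein-coding genes acting as
## parental pool and density controls; host genes with large introns for
## nested retrocopies; two-isoform hosts for interference geometry;
## antisense lncRNAs; ~45 retrocopies as mutated single-exon copies of
## parental mRNAs (3% substitution rate); 40 normal samples over 5 tissues
## plus 10 cancer-line controls; planted Spearman rho 0.7 for correlated
## pairs (the p < 0.001 bar must be reachable at desk-scale sample counts);
## ribosome densities 2.5x RNA for CDS/positive retrocopies and 0.5x for
## 3'UTRs/negative retrocopies with negative-binomial counting noise.

#' Simulation configuration
#'
#' @param seed integer master seed; each generator op derives its own
#'   stream from it (seed + op offset) so single fixtures can be
#'   regenerated stage-locally.
#' @param tissue_plan data.frame(tissue, n, cancer) describing samples.
#' @param mutation_rate per-base substitution rate for retrocopy divergence.
#' @param planted_rho Spearman target for correlated plants.
#' @param rna_mean mean per-base RNA coverage of normal features.
#' @param density_means named list: cds, utr3, retro_positive,
#'   retro_negative ribosome-density ratios.
#' @param nb_size negative-binomial dispersion (size) of coverage noise.
#' @param n_libraries number of Ribo/RNA library pairs.
#' @param universe_families miRNA family universe size M.
#' @param sponge_shared planted shared families k for true sponge pairs.
#' @param background_families background families per sequence.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       tissue_plan = data.frame(
                         tissue = c("spleen", "liver", "brain", "lung", "skin",
                                    "K562", "HepG2"),
                         n = c(8, 8, 8, 8, 8, 5, 5),
                         cancer = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)),
                       mutation_rate = 0.03, planted_rho = 0.7,
                       rna_mean = 30, density_means = list(
                         cds = 2.5, utr3 = 0.5,
                         retro_positive = 2.5, retro_negative = 0.5),
                       nb_size = 5, n_libraries = 8,
                       universe_families = 200, sponge_shared = 8,
                       background_families = 5) {
  if (mutation_rate < 0 || mutation_rate > 1) stop("mutation_rate in [0,1]")
  if (abs(planted_rho) > 1) stop("planted_rho must be in [-1, 1]")
  if (any(unlist(density_means) <= 0)) stop("density_means must be positive")
  structure(list(seed = seed, tissue_plan = tissue_plan,
                 mutation_rate = mutation_rate, planted_rho = planted_rho,
                 rna_mean = rna_mean, density_means = density_means,
                 nb_size = nb_size, n_libraries = n_libraries,
                 universe_families = universe_families,
                 sponge_shared = sponge_shared,
                 background_families = background_families),
            class = "sim_config")
}

## run expr under a dedicated RNG stream (seed + offset), restoring state
with_op_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + offset)
  expr
}

BASES <- c("A", "C", "G", "T")
SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rand_cds <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  s <- strsplit(seq, "")[[1]]
  for (p in pos) s[p] <- sample(setdiff(BASES, s[p]), 1)
  paste(s, collapse = "")
}

#' Generate the synthetic genome, annotation, catalog and ground truth
#'
#' Builds one chromosome left to right: plain parental genes (3 exons,
#' stop-free 450-nt CDS), intronic host genes, two-isoform interference
#' hosts, exonization hosts, antisense lncRNAs, and retrocopies placed as
#' intergenic, intronic (sense/antisense), downstream-of-short-isoform and
#' exon-overlapping copies of parental mRNAs with point mutations.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character), `ann`, `catalog`, `truth`
#'   (data.frame retro_id, evidence_class, partner_id, detail, value),
#'   `anchors` (retro-to-parental codon anchors), `mrna` (parental mRNA
#'   sequences), `density_features`, `tss_table`, `fusions` and
#'   `corr_plan` (pairs the expression generator must correlate).
#' @export
generate_genome_and_catalog <- function(config) {
  with_op_seed(config$seed, 101L, {
    chrom <- "chrS"
    cursor <- 1000L
    seq_parts <- list()  # (start, seq) pieces to assemble
    exons <- list(); txs <- list(); cat_rows <- list()
    truth <- list(); corr_plan <- list(); tss <- list(); anchors <- list()
    mrna <- list(); density_features <- list()

    put_seq <- function(start, s)
      seq_parts[[length(seq_parts) + 1L]] <<- list(start = start, seq = s)
    add_tx <- function(tid, gid, biotype, ex, cds_start = NA, cds_end = NA) {
      exons[[length(exons) + 1L]] <<- data.frame(
        transcript_id = tid, chrom = chrom, start = ex$start, end = ex$end,
        strand = ex$strand[1], stringsAsFactors = FALSE)
      txs[[length(txs) + 1L]] <<- data.frame(
        transcript_id = tid, gene_id = gid, biotype = biotype,
        cds_start = cds_start, cds_end = cds_end, stringsAsFactors = FALSE)
    }
    add_truth <- function(rid, cls, partner = NA, detail = NA, value = NA)
      truth[[length(truth) + 1L]] <<- data.frame(
        retro_id = rid, evidence_class = cls, partner_id = as.character(partner),
        detail = as.character(detail), value = as.numeric(value),
        stringsAsFactors = FALSE)

    ## ---- plain parental genes: exons 150/300/200, CDS = mRNA[100..550) ----
    n_plain <- 24L
    plain <- character(n_plain)
    for (i in seq_len(n_plain)) {
      g <- sprintf("gene_%02d", i); tid <- paste0(g, "_t1")
      c0 <- cursor
      e <- data.frame(start = c0 + c(0L, 350L, 850L),
                      end = c0 + c(150L, 650L, 1050L), strand = "+")
      utr5 <- rand_dna(100L); cds <- rand_cds(150L); utr3 <- rand_dna(100L)
      m <- paste0(utr5, cds, utr3)                       # 650 nt mRNA
      put_seq(e$start[1], substr(m, 1, 150))
      put_seq(e$start[2], substr(m, 151, 450))
      put_seq(e$start[3], substr(m, 451, 650))
      add_tx(tid, g, "protein_coding", e,
             cds_start = c0 + 100L, cds_end = c0 + 950L)  # mRNA 100 & 550
      mrna[[g]] <- m
      plain[i] <- g
      # density control features: exon2 is pure CDS; 3'UTR tail of exon3
      density_features[[length(density_features) + 1L]] <- data.frame(
        feature_id = c(paste0(tid, "_cds"), paste0(tid, "_utr3")),
        group = c("cds", "utr3"), chrom = chrom,
        start = c(e$start[2], e$start[3] + 100L),
        end = c(e$end[2], e$end[3]), stringsAsFactors = FALSE)
      tss[[length(tss) + 1L]] <- data.frame(chrom = chrom, pos = c0,
                                            strand = "+", stringsAsFactors = FALSE)
      cursor <- cursor + 1500L
    }

    parent_cycle <- plain[1:12]
    p_i <- 0L
    next_parent <- function() {
      p_i <<- p_i %% 12L + 1L
      parent_cycle[p_i]
    }

    retro_n <- 0L
    make_retro_seq <- function(parent) {
      retro_n <<- retro_n + 1L
      list(rid = sprintf("retro_syn_%03d", retro_n),
           seq = mutate_dna(mrna[[parent]], config$mutation_rate))
    }
    ## place a retro sequence at [start, start+len) on `strand`
    place_retro <- function(rid, rseq, start, strand, parent, status = "known_pseudogene") {
      put_seq(start, if (strand == "+") rseq else revcomp(rseq))
      cat_rows[[length(cat_rows) + 1L]] <<- data.frame(
        retro_id = rid, chrom = chrom, start = start,
        end = start + nchar(rseq), strand = strand, status = status,
        parental_gene_id = parent,
        parental_transcript_id = paste0(parent, "_t1"),
        stringsAsFactors = FALSE)
      anchors[[length(anchors) + 1L]] <<- data.frame(
        retro_id = rid, codon_anchor = 100L, stringsAsFactors = FALSE)
    }
    intergenic_retro <- function(parent, strand = "+") {
      r <- make_retro_seq(parent)
      place_retro(r$rid, r$seq, cursor, strand, parent)
      cursor <<- cursor + nchar(r$seq) + 400L
      r$rid
    }

    ## ---- expression-pattern plants (intergenic retros) ----
    for (i in 1:3) add_truth(intergenic_retro(next_parent()), "pattern",
                             detail = "ubiquitous")
    for (t in c("spleen", "spleen", "liver", "brain"))
      add_truth(intergenic_retro(next_parent()), "pattern",
                detail = paste0("tissue_specific:", t))
    for (i in 1:2) add_truth(intergenic_retro(next_parent()), "pattern",
                             detail = "cancer_only")
    for (i in 1:3) add_truth(intergenic_retro(next_parent()), "pattern",
                             detail = "not_expressed")

    ## ---- ribosome-density plants ----
    for (i in 1:4) add_truth(intergenic_retro(next_parent()), "ribosome",
                             detail = "positive")
    for (i in 1:4) add_truth(intergenic_retro(next_parent()), "ribosome",
                             detail = "negative")

    ## ---- peptide plants ----
    for (i in 1:3) add_truth(intergenic_retro(next_parent()), "peptide",
                             detail = "planted")

    ## ---- sponge plants (partner = another plain gene's transcript) ----
    for (i in 1:4) {
      parent <- next_parent()
      rid <- intergenic_retro(parent)
      partner <- paste0(plain[12 + i], "_t1")   # non-parental partner
      add_truth(rid, "sponge", partner = partner, value = config$planted_rho)
      corr_plan[[length(corr_plan) + 1L]] <- data.frame(
        id_a = rid, id_b = partner, rho = config$planted_rho,
        stringsAsFactors = FALSE)
    }

    ## ---- intronic hosts: cis-NAT (antisense) and one sense control ----
    host_i <- 0L
    intronic_host <- function(retro_strand, correlate, evclass, parent) {
      host_i <<- host_i + 1L
      g <- sprintf("host_%02d", host_i); tid <- paste0(g, "_t1")
      c0 <- cursor
      e <- data.frame(start = c0 + c(0L, 1400L), end = c0 + c(200L, 1600L),
                      strand = "+")
      put_seq(e$start[1], rand_dna(200L)); put_seq(e$start[2], rand_dna(200L))
      add_tx(tid, g, "protein_coding", e, cds_start = c0 + 50L,
             cds_end = c0 + 1550L)
      r <- make_retro_seq(parent)
      place_retro(r$rid, r$seq, c0 + 300L, retro_strand, parent)
      if (!is.na(evclass)) {
        add_truth(r$rid, evclass, partner = tid,
                  value = if (correlate) config$planted_rho else NA)
        if (correlate)
          corr_plan[[length(corr_plan) + 1L]] <<- data.frame(
            id_a = r$rid, id_b = tid, rho = config$planted_rho,
            stringsAsFactors = FALSE)
      }
      cursor <<- cursor + 2000L
      list(rid = r$rid, gene = g)
    }
    for (i in 1:3) intronic_host("-", TRUE, "cis_nat", next_parent())
    intronic_host("+", FALSE, NA, next_parent())   # same-strand overlap control

    ## host_x_host fusion plants: two hosts with retros of one parent
    hh_parent <- plain[1]
    hh1 <- intronic_host("-", FALSE, NA, hh_parent)
    hh2 <- intronic_host("-", FALSE, NA, hh_parent)

    ## ---- interference hosts: short + long isoform, retro in long intron ----
    for (i in 1:3) {
      g <- sprintf("ihost_%02d", i)
      c0 <- cursor
      e_short <- data.frame(start = c0 + c(0L, 300L), end = c0 + c(200L, 500L),
                            strand = "+")
      e_long <- data.frame(start = c0 + c(0L, 2500L), end = c0 + c(200L, 2700L),
                           strand = "+")
      put_seq(c0, rand_dna(200L)); put_seq(c0 + 300L, rand_dna(200L))
      put_seq(c0 + 2500L, rand_dna(200L))
      add_tx(paste0(g, "_short"), g, "protein_coding", e_short)
      add_tx(paste0(g, "_long"), g, "protein_coding", e_long)
      parent <- next_parent()
      r <- make_retro_seq(parent)
      d <- c(400L, 0L, 950L)[i]            # downstream distances incl. edge cases
      place_retro(r$rid, r$seq, c0 + 500L + d, "+", parent)
      add_truth(r$rid, "interference", partner = paste0(g, "_short"),
                detail = g, value = d)
      corr_plan[[length(corr_plan) + 1L]] <- data.frame(
        id_a = r$rid, id_b = paste0(g, "_short"), rho = config$planted_rho,
        stringsAsFactors = FALSE)
      cursor <- cursor + 3100L
    }

    ## ---- exonization hosts ----
    # retro at [c+500, c+1150); host exon2 [c+1000, c+1400) overlaps 150 b
    exo_host <- function(i, host_strand, cds_end_off, classes) {
      g <- sprintf("xhost_%02d", i); tid <- paste0(g, "_t1")
      c0 <- cursor
      parent <- next_parent()
      r <- make_retro_seq(parent)
      place_retro(r$rid, r$seq, c0 + 500L, "+", parent)
      e <- data.frame(start = c0 + c(0L, 1000L), end = c0 + c(300L, 1400L),
                      strand = host_strand)
      put_seq(c0, rand_dna(300L)); put_seq(c0 + 1150L, rand_dna(250L))
      # exon2 head up to c0+1150 is retrocopy-derived sequence already placed
      add_tx(tid, g, "protein_coding", e, cds_start = c0 + 50L,
             cds_end = c0 + cds_end_off)
      add_truth(r$rid, "exonization", partner = tid, detail = classes)
      cursor <<- cursor + 1800L
      list(rid = r$rid, host_tx = tid, parent = parent)
    }
    exo_host(1L, "+", 290L, "utr3")          # CDS ends in exon1 -> pure 3'UTR
    exo_host(2L, "+", 1050L, "cds,utr3")     # CDS runs 50 b into the overlap
    xb <- exo_host(3L, "-", 1050L, "utr5,cds")  # antisense: overlap hits 5' side

    ## ---- trans-NAT plants ----
    # route (b): antisense exonization host correlated with the parent
    add_truth(xb$rid, "trans_nat", partner = xb$host_tx, detail = "b")
    corr_plan[[length(corr_plan) + 1L]] <- data.frame(
      id_a = xb$host_tx, id_b = paste0(xb$parent, "_t1"),
      rho = config$planted_rho, stringsAsFactors = FALSE)
    # route (a): antisense lncRNA over an intergenic retro
    for (i in 1:2) {
      parent <- next_parent()
      r <- make_retro_seq(parent)
      c0 <- cursor
      place_retro(r$rid, r$seq, c0, "+", parent)
      g <- sprintf("lnc_%02d", i); tid <- paste0(g, "_t1")
      e <- data.frame(start = c0 + 100L, end = c0 + 600L, strand = "-")
      add_tx(tid, g, "lncRNA", e)
      add_truth(r$rid, "trans_nat", partner = tid, detail = "a")
      corr_plan[[length(corr_plan) + 1L]] <- data.frame(
        id_a = tid, id_b = paste0(parent, "_t1"), rho = config$planted_rho,
        stringsAsFactors = FALSE)
      cursor <- cursor + 1100L
    }
    # route (c): opposite-strand TSS 200 b past the retro 3' end
    for (i in 1:2) {
      parent <- next_parent()
      rid <- intergenic_retro(parent)
      rrow <- cat_rows[[length(cat_rows)]]
      tss[[length(tss) + 1L]] <- data.frame(
        chrom = chrom, pos = rrow$end - 1L + 200L, strand = "-",
        stringsAsFactors = FALSE)
      add_truth(rid, "trans_nat", detail = "c")
      corr_plan[[length(corr_plan) + 1L]] <- data.frame(
        id_a = rid, id_b = paste0(parent, "_t1"), rho = config$planted_rho,
        stringsAsFactors = FALSE)
    }

    ## ---- fusion plants ----
    fus <- list(); fus_truth <- list()
    add_fusion <- function(fid, g5, g3, pos5, pos3, category, rid,
                           bp5_class, bp3_class) {
      fus[[length(fus) + 1L]] <<- data.frame(
        fusion_id = fid, gene5_id = g5, gene3_id = g3, chrom5 = chrom,
        pos5 = pos5, chrom3 = chrom, pos3 = pos3, source_label = "synthetic",
        stringsAsFactors = FALSE)
      fus_truth[[length(fus_truth) + 1L]] <<- data.frame(
        fusion_id = fid, category = category, retro_id = rid,
        bp5_class = bp5_class, bp3_class = bp3_class, stringsAsFactors = FALSE)
    }
    # retro_x_parental: breakpoint in body / downstream-near
    rp1 <- intergenic_retro(next_parent()); rr1 <- cat_rows[[length(cat_rows)]]
    add_fusion("fus_01", rp1, rr1$parental_gene_id,
               rr1$start + 300L, rr1$start + 100L, "retro_x_parental", rp1,
               "in_body", "in_body")
    rp2 <- intergenic_retro(next_parent()); rr2 <- cat_rows[[length(cat_rows)]]
    add_fusion("fus_02", rp2, rr2$parental_gene_id,
               rr2$end - 1L + 150L, rr2$start + 50L, "retro_x_parental", rp2,
               "downstream_near", "in_body")
    # parental_x_host via hosted (host_x_host) retros; one distant breakpoint
    r_hh1 <- cat_rows[[which(vapply(cat_rows, function(x) x$retro_id, "") == hh1$rid)]]
    add_fusion("fus_03", hh_parent, hh1$gene, r_hh1$start + 200L,
               r_hh1$end - 1L + 6500L, "parental_x_host", hh1$rid,
               "in_body", "distant")
    add_fusion("fus_04", hh_parent, hh2$gene,
               cat_rows[[which(vapply(cat_rows, function(x) x$retro_id, "") == hh2$rid)]]$start + 100L,
               cursor + 5000L, "parental_x_host", hh2$rid, "in_body", "distant")
    # host_x_host
    add_fusion("fus_05", hh1$gene, hh2$gene, r_hh1$start + 10L,
               r_hh1$start + 20L, "host_x_host", paste(hh1$rid, hh2$rid, sep = ","),
               "in_body", "in_body")
    # unrelated
    add_fusion("fus_06", plain[20], plain[21], cursor + 100L, cursor + 200L,
               "other", NA, NA, NA)
    for (ft in fus_truth)
      if (ft$category != "other")
        add_truth(strsplit(ft$retro_id, ",")[[1]][1], "fusion",
                  partner = ft$fusion_id, detail = ft$category)

    cursor <- cursor + 9000L   # headroom for distant breakpoints

    ## ---- assemble the chromosome ----
    genome_len <- cursor + 1000L
    s <- sample(BASES, genome_len, replace = TRUE)
    for (p in seq_parts) {
      piece <- strsplit(p$seq, "")[[1]]
      s[(p$start + 1L):(p$start + length(piece))] <- piece
    }
    genome <- stats::setNames(paste(s, collapse = ""), chrom)

    ann <- annotation(do.call(rbind, exons), do.call(rbind, txs))
    catalog <- retro_catalog(do.call(rbind, cat_rows))
    list(genome = genome, ann = ann, catalog = catalog,
         truth = do.call(rbind, truth),
         anchors = do.call(rbind, anchors), mrna = mrna,
         density_features = do.call(rbind, density_features),
         tss_table = do.call(rbind, tss),
         fusions = fusion_table(do.call(rbind, fus)),
         fusion_truth = do.call(rbind, fus_truth),
         corr_plan = do.call(rbind, corr_plan))
  })
}

## Pearson parameter reproducing a target Spearman under a Gaussian copula
pearson_from_spearman <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate the TPM expression matrix honouring the planted patterns
#'
#' Background transcripts and retrocopies draw i.i.d. log-normal TPM;
#' pattern plants override per-sample detection (ubiquitous >= 1 TPM
#' everywhere, tissue-specific only in their tissue, cancer-only in all
#' cancer-line controls, not-expressed at sub-threshold noise); correlated
#' plants draw from a Gaussian copula with the Pearson parameter
#' 2*sin(pi*rho_s/6), then map through a log-normal quantile (monotone, so
#' the population Spearman equals the target).
#'
#' @param config a [sim_config()].
#' @param world output of [generate_genome_and_catalog()].
#' @return an [expression_matrix()].
#' @export
generate_expression_matrix <- function(config, world) {
  with_op_seed(config$seed, 202L, {
    tp <- config$tissue_plan
    samples <- data.frame(
      sample_id = sprintf("s%03d", seq_len(sum(tp$n))),
      tissue_label = rep(tp$tissue, tp$n),
      is_cancer_line = rep(tp$cancer, tp$n),
      is_control = TRUE, stringsAsFactors = FALSE)
    n <- nrow(samples)
    ids <- c(world$ann$transcripts$transcript_id, world$catalog$retro_id)
    # background: low-ish, dispersed expression so unplanted rows are
    # detected in many but not all samples (pattern class "other")
    tpm <- matrix(stats::rlnorm(length(ids) * n, log(2), 1.0),
                  nrow = length(ids), dimnames = list(ids, samples$sample_id))
    # correlated plants (copula); overrides both members' rows
    q_tpm <- function(z) stats::qlnorm(stats::pnorm(z), log(2), 1.0)
    cp <- world$corr_plan
    for (i in seq_len(nrow(cp))) {
      r <- pearson_from_spearman(cp$rho[i])
      z1 <- stats::rnorm(n)
      z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
      tpm[cp$id_a[i], ] <- q_tpm(z1)
      tpm[cp$id_b[i], ] <- q_tpm(z2)
    }
    # pattern plants
    pat <- world$truth[world$truth$evidence_class == "pattern", , drop = FALSE]
    normal <- !samples$is_cancer_line
    for (i in seq_len(nrow(pat))) {
      rid <- pat$retro_id[i]; d <- pat$detail[i]
      row <- numeric(n)
      if (d == "ubiquitous") {
        row <- pmax(1.01, stats::rlnorm(n, log(6), 0.5))
      } else if (startsWith(d, "tissue_specific:")) {
        t <- sub("tissue_specific:", "", d)
        sel <- samples$tissue_label == t
        row[sel] <- pmax(1.01, stats::rlnorm(sum(sel), log(5), 0.5))
      } else if (d == "cancer_only") {
        sel <- samples$is_cancer_line
        row[sel] <- pmax(1.01, stats::rlnorm(sum(sel), log(5), 0.5))
      } else if (d == "not_expressed") {
        noisy <- sample.int(n, 3)
        row[noisy] <- stats::runif(3, 0, 0.5)
      }
      tpm[rid, ] <- row
    }
    expression_matrix(tpm, samples)
  })
}

#' Generate per-library Ribo-seq / RNA-seq coverage-track pairs
#'
#' Per-base depths over each density feature are negative-binomial around
#' the feature's library-specific mean; ribosome means are the RNA mean
#' times the group's density ratio with an extra log-normal feature-level
#' factor (sdlog 0.25) emulating gene-to-gene variability of aggregate
#' tracks. Retrocopies take the `retro_positive` or `retro_negative` ratio
#' per ground truth (unplanted retrocopies are negative). Two plain genes
#' are planted at low RNA coverage (mean 3) to exercise the >= 10 gate.
#'
#' @param config a [sim_config()].
#' @param world output of [generate_genome_and_catalog()].
#' @return list with `features` (feature_id, group, chrom, start, end) and
#'   `tracks`: per library a list(ribo=, rna=) of [coverage_track()]s.
#' @export
generate_coverage_tracks <- function(config, world) {
  with_op_seed(config$seed, 303L, {
    feats <- world$density_features
    retro_feats <- data.frame(feature_id = world$catalog$retro_id,
                              group = "retro", chrom = world$catalog$chrom,
                              start = world$catalog$start,
                              end = world$catalog$end, stringsAsFactors = FALSE)
    # drop retros overlapping host genes' CDS-span features is unnecessary:
    # density features and intergenic retros are disjoint by construction,
    # but nested retros would collide with nothing (hosts contribute no
    # density features).
    feats <- rbind(feats, retro_feats)
    pos <- world$truth$retro_id[world$truth$evidence_class == "ribosome" &
                                  world$truth$detail == "positive"]
    dm <- config$density_means
    ratio <- ifelse(feats$group == "cds", dm$cds,
             ifelse(feats$group == "utr3", dm$utr3,
             ifelse(feats$feature_id %in% pos, dm$retro_positive,
                    dm$retro_negative)))
    low_cov <- feats$feature_id %in% feats$feature_id[feats$group == "cds"][1:2]
    rna_mu_base <- ifelse(low_cov, 3, config$rna_mean)
    tracks <- vector("list", config$n_libraries)
    names(tracks) <- sprintf("lib%02d", seq_len(config$n_libraries))
    for (L in seq_len(config$n_libraries)) {
      rec_rna <- list(); rec_ribo <- list()
      for (i in seq_len(nrow(feats))) {
        len <- feats$end[i] - feats$start[i]
        rna_mu <- rna_mu_base[i] * stats::rlnorm(1, 0, 0.15)
        ribo_mu <- ratio[i] * rna_mu * stats::rlnorm(1, 0, 0.25)
        dr <- stats::rnbinom(len, mu = rna_mu, size = config$nb_size)
        db <- stats::rnbinom(len, mu = ribo_mu, size = config$nb_size)
        rec_rna[[i]] <- rle_records(feats$chrom[i], feats$start[i], dr)
        rec_ribo[[i]] <- rle_records(feats$chrom[i], feats$start[i], db)
      }
      lib <- names(tracks)[L]
      tracks[[L]] <- list(
        rna = coverage_track(do.call(rbind, rec_rna), lib, "rna"),
        ribo = coverage_track(do.call(rbind, rec_ribo), lib, "ribo"))
    }
    list(features = feats, tracks = tracks)
  })
}

## collapse a per-base depth vector into bedGraph-style records (zeros kept
## out: absent bases count 0 on read)
rle_records <- function(chrom, start, depths) {
  r <- rle(depths)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values > 0
  data.frame(chrom = chrom, start = start + starts[keep],
             end = start + ends[keep], depth = r$values[keep],
             stringsAsFactors = FALSE)
}

#' Generate the synthetic peptide list
#'
#' For peptide-planted retrocopies, 12-mer peptides are cut from the
#' retrocopy's translation in the parental reading frame, choosing windows
#' that differ from the parental protein (so they survive the decoy
#' uniqueness filter); when divergence gave no differing stop-free window,
#' one codon is edited in the genome to create one. Decoys: 12-mers taken
#' verbatim from parental proteins (non-unique by construction), random
#' 12-mers (no match) and sub-length 8-mers (rejected by the length
#' filter).
#'
#' @param config a [sim_config()].
#' @param world output of [generate_genome_and_catalog()] (its `genome` may
#'   be edited; the possibly-updated world is returned).
#' @return list with `peptides` (peptide_id, aa_sequence, truth columns),
#'   `decoy_proteins` and the (possibly edited) `world`.
#' @export
generate_peptides <- function(config, world) {
  with_op_seed(config$seed, 404L, {
    parents <- unique(world$catalog$parental_gene_id)
    decoys <- vapply(parents, function(g)
      translate_nt(substr(world$mrna[[g]], 101, 550)), "")
    pep_retros <- world$truth$retro_id[world$truth$evidence_class == "peptide"]
    peps <- list()
    add_pep <- function(id, aa, truth_class, rid = NA)
      peps[[length(peps) + 1L]] <<- data.frame(
        peptide_id = id, aa_sequence = aa, truth = truth_class,
        retro_id = rid, stringsAsFactors = FALSE)
    for (rid in pep_retros) {
      row <- world$catalog[world$catalog$retro_id == rid, ]
      rseq <- substr(world$genome[[row$chrom]], row$start + 1L, row$end)
      if (row$strand == "-") rseq <- revcomp(rseq)
      parent_aa <- decoys[[row$parental_gene_id]]
      win <- find_diff_window(rseq, parent_aa, width = 12L)
      if (is.null(win)) {
        # force one amino-acid difference mid-CDS, writing it back to the genome
        parent_cds <- substr(world$mrna[[row$parental_gene_id]], 101, 550)
        edit <- force_aa_edit(rseq, parent_cds)
        rseq <- edit$seq
        gseq <- if (row$strand == "-") revcomp(rseq) else rseq
        g <- world$genome[[row$chrom]]
        substr(g, row$start + 1L, row$end) <- gseq
        world$genome[[row$chrom]] <- g
        win <- find_diff_window(rseq, parent_aa, width = 12L)
      }
      add_pep(paste0("pep_", rid), win, "planted", rid)
    }
    # decoys
    for (i in 1:4) {
      aa <- substr(decoys[[i]], 30, 41)
      add_pep(sprintf("pep_decoy_parent_%d", i), aa, "parental_decoy")
    }
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in 1:4)
      add_pep(sprintf("pep_decoy_random_%d", i),
              paste(sample(aas, 12, replace = TRUE), collapse = ""), "random_decoy")
    for (i in 1:3)
      add_pep(sprintf("pep_short_%d", i),
              paste(sample(aas, 8, replace = TRUE), collapse = ""), "too_short")
    list(peptides = do.call(rbind, peps), decoy_proteins = unname(decoys),
         world = world)
  })
}

## 12-aa window of the retro translation (parental frame, CDS at mRNA
## offset 100) that (i) differs from the parental protein and (ii) lies in
## a stop-free run long enough to survive ORF discovery; NULL if none
find_diff_window <- function(retro_mrna, parent_aa, width = 12L) {
  raa <- translate_nt(substr(retro_mrna, 101, 550))
  runs <- aa_runs(raa, MIN_ORF_AA)
  for (ri in seq_len(nrow(runs))) {
    lo <- runs$aa_start[ri] + 1L
    hi <- lo + runs$aa_len[ri] - 1L
    for (s in lo:(hi - width + 1L)) {
      w <- substr(raa, s, s + width - 1L)
      if (grepl("X", w, fixed = TRUE)) next
      if (w != substr(parent_aa, s, s + width - 1L)) return(w)
    }
  }
  NULL
}

## guarantee a differing stop-free window: if divergence left no usable
## run, revert the CDS copy to the parental CDS, then substitute the
## middle codon of the longest run with a codon for a different amino acid
force_aa_edit <- function(retro_mrna, parent_cds) {
  raa <- translate_nt(substr(retro_mrna, 101, 550))
  runs <- aa_runs(raa, MIN_ORF_AA)
  if (!nrow(runs)) {
    substr(retro_mrna, 101, 550) <- parent_cds
    raa <- translate_nt(parent_cds)
    runs <- aa_runs(raa, MIN_ORF_AA)
  }
  ri <- which.max(runs$aa_len)
  codon_i <- runs$aa_start[ri] + runs$aa_len[ri] %/% 2L  # 0-based aa index
  nt_s <- 101L + 3L * codon_i
  old_aa <- substr(raa, codon_i + 1L, codon_i + 1L)
  new_codon <- SENSE_CODONS[Biostrings::GENETIC_CODE[SENSE_CODONS] != old_aa][1]
  substr(retro_mrna, nt_s, nt_s + 2L) <- new_codon
  list(seq = retro_mrna)
}

#' Generate the miRNA-family site table (with planted sponges)
#'
#' Every expression-matrix sequence receives `background_families` random
#' families from a universe of `universe_families`; each planted sponge
#' pair additionally shares `sponge_shared` dedicated families.
#'
#' @param config a [sim_config()].
#' @param world output of [generate_genome_and_catalog()].
#' @return a `TargetSiteMap` (list sites/universe_size) as consumed by
#'   [call_sponges()].
#' @export
generate_site_table <- function(config, world) {
  with_op_seed(config$seed, 505L, {
    M <- config$universe_families
    fams <- sprintf("fam_%03d", seq_len(M))
    ids <- c(world$ann$transcripts$transcript_id, world$catalog$retro_id)
    sp <- world$truth[world$truth$evidence_class == "sponge", , drop = FALSE]
    k <- config$sponge_shared
    if (nrow(sp) * k > M - config$background_families)
      stop("planted shared families exceed the universe")
    shared_pool <- fams[seq_len(nrow(sp) * k)]
    bg_pool <- fams[(nrow(sp) * k + 1L):M]
    rows <- list()
    for (id in ids)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = id, family = sample(bg_pool, config$background_families),
        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sp))) {
      fam_i <- shared_pool[((i - 1L) * k + 1L):(i * k)]
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = sp$retro_id[i], family = fam_i, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = sp$partner_id[i], family = fam_i, stringsAsFactors = FALSE)
    }
    sites <- unique(do.call(rbind, rows))
    rownames(sites) <- NULL
    list(sites = sites, families = NULL, universe_size = M)
  })
}

#' Generate the full synthetic world
#'
#' Runs every generator op under its own seed stream and returns the
#' complete fixture set plus ground truth.
#'
#' @param config a [sim_config()].
#' @return list: genome, ann, catalog, truth, anchors, expression,
#'   density_features, tracks, peptides, decoy_proteins, site_map,
#'   tss_table, fusions, fusion_truth, corr_plan.
#' @export
simulate_world <- function(config = sim_config()) {
  world <- generate_genome_and_catalog(config)
  pep <- generate_peptides(config, world)
  world <- pep$world
  world$peptides <- pep$peptides
  world$decoy_proteins <- pep$decoy_proteins
  world$expression <- generate_expression_matrix(config, world)
  cov <- generate_coverage_tracks(config, world)
  world$density_features <- cov$features
  world$tracks <- cov$tracks
  world$site_map <- generate_site_table(config, world)
  world$config <- config
  world
}

#' Write a simulated world to a directory of plain-text fixture files
#'
#' Emits exactly the dialects the readers consume: genome FASTA, catalog
#' TSV, annotation BED12, expression + metadata TSV, per-library bedGraph
#' pairs, peptide TSV, site TSV, TSS BED, fusion TSV and a ground-truth
#' TSV.
#'
#' @param world output of [simulate_world()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  # genome FASTA
  con <- file(p("genome.fa"), "w")
  for (ch in names(world$genome)) {
    writeLines(paste0(">", ch), con)
    s <- world$genome[[ch]]
    writeLines(substring(s, seq(1, nchar(s), 80),
                         pmin(nchar(s), seq(80, nchar(s) + 79, 80))), con)
  }
  close(con)
  write_retrocopy_catalog(world$catalog, p("catalog.tsv"))
  write_annotation_bed12(world$ann, p("annotation.bed"))
  write_expression_matrix(world$expression, p("expression.tsv"), p("samples.tsv"))
  for (lib in names(world$tracks)) {
    write_bedgraph(world$tracks[[lib]]$rna, p(paste0(lib, "_rna.bedgraph")))
    write_bedgraph(world$tracks[[lib]]$ribo, p(paste0(lib, "_ribo.bedgraph")))
  }
  utils::write.table(world$density_features, p("density_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$peptides, p("peptides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$site_map$sites, p("mirna_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$tss_table, p("tss.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(world$fusions, p("fusions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$truth, p("ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$anchors, p("anchors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

## BED12 writer for annotations (one line per transcript)
write_annotation_bed12 <- function(ann, path) {
  lines <- character(nrow(ann$transcripts))
  for (i in seq_len(nrow(ann$transcripts))) {
    t <- ann$transcripts[i, ]
    e <- tx_exons(ann, t$transcript_id)
    thick <- if (!is.na(t$cds_start)) c(t$cds_start, t$cds_end) else c(t$start, t$start)
    lines[i] <- paste(t$chrom, t$start, t$end,
                      paste(t$transcript_id, t$gene_id, t$biotype, sep = "|"),
                      0, t$strand, thick[1], thick[2], "0", nrow(e),
                      paste0(paste(e$end - e$start, collapse = ","), ","),
                      paste0(paste(e$start - t$start, collapse = ","), ","),
                      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
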