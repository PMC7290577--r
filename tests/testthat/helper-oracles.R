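# Independent brute-force oracles. Each recomputes the quantity by a
# different algorithm than the implementation under test.

# frame-0 translation via Biostrings (independent of the package path)
translate_frame <- function(nt) {
  n <- 3 * (nchar(nt) %/% 3)
  as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1, n))))
}

# mid-rank Pearson via explicit counting and moment sums
oracle_spearman <- function(x, y) {
  midrank <- function(v) vapply(v, function(a)
    sum(v < a) + (sum(v == a) + 1) / 2, 0)
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# per-base expansion of a coverage track over [start, end)
oracle_mean_coverage <- function(records, chrom, start, end) {
  depth <- numeric(end - start)
  r <- records[records$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(r))) {
    lo <- max(r$start[i], start); hi <- min(r$end[i], end)
    if (hi > lo) depth[(lo - start + 1):(hi - start)] <- r$depth[i]
  }
  mean(depth)
}

# all-vs-all interval intersection
oracle_overlaps <- function(retros, genes) {
  out <- list()
  for (i in seq_len(nrow(retros))) for (j in seq_len(nrow(genes))) {
    if (retros$chrom[i] != genes$chrom[j]) next
    ov <- min(retros$end[i], genes$end[j]) - max(retros$start[i], genes$start[j])
    if (ov > 0)
      out[[length(out) + 1L]] <- data.frame(retro_id = retros$retro_id[i],
                                            gene_id = genes$gene_id[j],
                                            overlap_bases = ov)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(retro_id = character(), gene_id = character(),
               overlap_bases = integer())
}

# codon-by-codon scan for maximal stop-free runs in all six frames
oracle_orfs <- function(locus, retro_start, retro_end, min_overlap = 60,
                        min_aa = 20) {
  gc <- Biostrings::GENETIC_CODE
  L <- nchar(locus)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(locus)))
  found <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") locus else rc
    for (frame in 0:2) {
      i <- frame + 1
      run_start <- NULL; run_aa <- character()
      flush <- function(end_nt) {
        if (!is.null(run_start) && length(run_aa) >= min_aa) {
          nt_s <- run_start - 1; nt_e <- end_nt - 1
          g <- if (strand == "+") c(nt_s, nt_e) else c(L - nt_e, L - nt_s)
          ov <- min(g[2], retro_end) - max(g[1], retro_start)
          if (ov >= min_overlap)
            found[[length(found) + 1L]] <<- paste(run_aa, collapse = "")
        }
      }
      while (i + 2 <= L) {
        codon <- substr(s, i, i + 2)
        aa <- gc[[codon]]
        if (is.null(aa)) aa <- "X"
        if (aa == "*") {
          flush(i)
          run_start <- NULL; run_aa <- character()
        } else {
          if (is.null(run_start)) run_start <- i
          run_aa <- c(run_aa, aa)
        }
        i <- i + 3
      }
      flush(i)
    }
  }
  sort(unlist(found))
}

# exhaustive hypergeometric upper tail by enumerating all draws
oracle_hyper_upper <- function(M, K, n, k) {
  draws <- utils::combn(M, n)
  hits <- colSums(draws <= K)   # items 1..K are the "successes"
  mean(hits >= k)
}
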