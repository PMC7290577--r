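## miRNA-sponge (ceRNA) testing.
##
## Target sites are called by canonical seed matching (7mer-m8 / 8mer), a
## documented stand-in for full Miranda scoring: the downstream statistic
## only consumes site presence per miRNA family. Mature miRNAs are
## collapsed to seed families (identical positions 2-8) before counting.
## For a retrocopy-transcript pair sharing k families out of a universe of
## M screened families, with K families targeting the transcript and n the
## retrocopy, enrichment is the inclusive upper tail of the
## hypergeometric(M, K, n) distribution; Benjamini-Hochberg correction runs
## across all tested pairs at alpha = 0.05, and a sponge call additionally
## requires the pair to pass the co-expression filter (negative-rho pairs
## are retained in the output with the sign flagged, not removed).

#' Predict miRNA target sites by canonical seed matching
#'
#' A 7mer-m8 site is the reverse complement of miRNA positions 2-8 found in
#' the transcript; an 8mer site is that heptamer followed by an A (opposite
#' miRNA position 1). Both count as one site type; a family is reported for
#' a sequence when it has at least one site.
#'
#' @param sequences named character vector of transcript/retrocopy
#'   nucleotide sequences.
#' @param mirnas named character vector of mature miRNA sequences (5'->3',
#'   RNA or DNA alphabet), each >= 8 nt.
#' @return a `TargetSiteMap`: list with `sites` (data.frame sequence_id,
#'   family), `families` (family id per miRNA) and `universe_size` M.
#' @export
predict_sites <- function(sequences, mirnas) {
  if (!length(mirnas)) stop("empty miRNA universe")
  mir <- toupper(chartr("U", "T", mirnas))
  if (any(nchar(mir) < 8)) stop("miRNA sequences must be >= 8 nt")
  seed <- substr(mir, 2, 8)                      # positions 2-8
  fam <- paste0("fam_", seed)
  fam_seed <- tapply(seed, fam, `[`, 1)
  seqs <- toupper(chartr("U", "T", sequences))
  sites <- list()
  for (fi in names(fam_seed)) {
    m8 <- revcomp(fam_seed[[fi]])                # 7mer-m8 match
    hit <- grepl(m8, seqs, fixed = TRUE)         # 8mer = m8 + "A" is a superset
    if (any(hit))
      sites[[fi]] <- data.frame(sequence_id = names(seqs)[hit], family = fi,
                                stringsAsFactors = FALSE)
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(sequence_id = character(), family = character())
  rownames(sites) <- NULL
  list(sites = sites,
       families = stats::setNames(fam, names(mirnas)),
       universe_size = length(fam_seed))
}

#' Load a precomputed target-site table
#'
#' For users who run an external predictor (e.g. Miranda): a TSV with
#' columns sequence_id, family is consumed verbatim.
#'
#' @param path site TSV.
#' @param universe_size total number of miRNA families screened; defaults
#'   to the number of distinct families in the file.
#' @return a `TargetSiteMap` as in [predict_sites()].
#' @export
read_site_table <- function(path, universe_size = NULL) {
  sites <- read_tsv_strict(path, required = c("sequence_id", "family"))
  M <- if (is.null(universe_size)) length(unique(sites$family)) else universe_size
  if (M < 1) stop("empty miRNA universe")
  if (M < length(unique(sites$family)))
    stop("universe_size smaller than the number of observed families")
  list(sites = sites, families = NULL, universe_size = M)
}

#' Hypergeometric sponge p-value (inclusive upper tail)
#'
#' P(X >= k) for X ~ hypergeometric with M families in the universe, K
#' targeting the transcript and n targeting the retrocopy.
#'
#' @param M universe size; @param K transcript families; @param n retrocopy
#'   families; @param k shared families.
#' @return upper-tail probability.
#' @export
sponge_pvalue <- function(M, K, n, k) {
  if (k > min(K, n) || K > M || n > M || min(M, K, n, k) < 0)
    stop("inconsistent hypergeometric parameters")
  stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up correction
#'
#' q_(i) = min over j >= i of m * p_(j) / j, capped at 1; reject iff
#' q <= alpha.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `q` (same order as input) and `reject` flags.
#' @export
bh_correct <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must be in [0, 1]")
  m <- length(pvalues)
  if (!m) return(list(q = numeric(), reject = logical()))
  o <- order(pvalues)
  q_sorted <- pmin(1, rev(cummin(rev(m * pvalues[o] / seq_len(m)))))
  q <- numeric(m); q[o] <- q_sorted
  list(q = q, reject = q <= alpha)
}

#' Test retrocopy-transcript pairs for shared-miRNA-site enrichment
#'
#' Pairs sharing at least one family are tested; BH correction runs across
#' all tested pairs; `called` requires q <= alpha and the pair passing the
#' co-expression filter (computed in coexpressed mode). Pairs with negative
#' rho are kept and flagged via `corr_sign`.
#'
#' @param site_map a `TargetSiteMap`.
#' @param retro_ids retrocopy sequence ids.
#' @param transcript_ids candidate partner transcript ids.
#' @param correlations output of [correlate_pairs()] in coexpressed mode
#'   over (retro, transcript) pairs; may omit pairs (treated as failing).
#' @param alpha BH level (default 0.05).
#' @param p_max,rho_abs_min co-expression filter bounds.
#' @return data.frame retro_id, transcript_id, M, K, n, k, p, q, rho,
#'   corr_p, called, corr_sign.
#' @export
call_sponges <- function(site_map, retro_ids, transcript_ids, correlations,
                         alpha = 0.05, p_max = 0.001, rho_abs_min = 0.25) {
  sites <- site_map$sites
  M <- site_map$universe_size
  fam_by_seq <- split(sites$family, sites$sequence_id)
  rows <- list()
  for (r in retro_ids) {
    fr <- unique(fam_by_seq[[r]])
    if (!length(fr)) next
    for (t in transcript_ids) {
      ft <- unique(fam_by_seq[[t]])
      k <- length(intersect(fr, ft))
      if (k < 1) next
      rows[[length(rows) + 1L]] <- data.frame(
        retro_id = r, transcript_id = t, M = M, K = length(ft),
        n = length(fr), k = k,
        p = sponge_pvalue(M, length(ft), length(fr), k),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(retro_id = character(), transcript_id = character(),
                      M = integer(), K = integer(), n = integer(), k = integer(),
                      p = numeric(), q = numeric(), rho = numeric(),
                      corr_p = numeric(), called = logical(),
                      corr_sign = character()))
  out <- do.call(rbind, rows)
  bh <- bh_correct(out$p, alpha)
  out$q <- bh$q
  key <- paste(correlations$id_a, correlations$id_b)
  idx <- match(paste(out$retro_id, out$transcript_id), key)
  idx2 <- match(paste(out$transcript_id, out$retro_id), key)
  idx[is.na(idx)] <- idx2[is.na(idx)]
  out$rho <- correlations$rho[idx]
  out$corr_p <- correlations$p[idx]
  corr_ok <- !is.na(out$rho) & out$corr_p < p_max & abs(out$rho) > rho_abs_min
  out$called <- bh$reject & corr_ok
  out$corr_sign <- ifelse(is.na(out$rho), NA_character_,
                          ifelse(out$rho >= 0, "positive", "negative"))
  rownames(out) <- NULL
  out
}
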