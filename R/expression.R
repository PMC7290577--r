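## Expression filtering, pattern classification and Spearman co-expression.
##
## The filter keeps transcripts expressed at >= min_tpm TPM in at least
## min_sample_fraction of the experiments (ceiling rule on the sample
## count). Correlations run in two sample-selection modes: "coexpressed"
## (only samples where both partners have TPM > 0; used for transcript-level
## mechanisms such as sponges and trans-NATs) and "all" (every sample,
## zeros included; used for cis-NAT and transcriptional-interference calls
## where the act of transcription itself matters).

#' Smallest number of samples satisfying a support fraction
#'
#' @param n_experiments total number of experiments.
#' @param fraction required fraction (default 0.01, i.e. 1%).
#' @return smallest integer n with n / n_experiments >= fraction; for 818
#'   experiments at 1% this is 9.
#' @export
min_support_samples <- function(n_experiments, fraction = 0.01) {
  if (n_experiments < 1) stop("n_experiments must be >= 1")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  as.integer(ceiling(n_experiments * fraction))
}

#' Filter transcripts by minimum expression support
#'
#' A transcript is kept iff its TPM is >= `min_tpm` in at least
#' `min_support_samples(n_samples, min_sample_fraction)` samples.
#'
#' @param em an [expression_matrix()].
#' @param min_tpm TPM threshold (default 1).
#' @param min_sample_fraction required fraction of experiments (default 0.01).
#' @return character vector of retained transcript ids.
#' @export
filter_expressed <- function(em, min_tpm = 1, min_sample_fraction = 0.01) {
  if (min_tpm <= 0) stop("min_tpm must be > 0")
  need <- min_support_samples(ncol(em$tpm), min_sample_fraction)
  n_pass <- rowSums(em$tpm >= min_tpm)
  rownames(em$tpm)[n_pass >= need]
}

#' Classify per-retrocopy expression patterns
#'
#' Patterns over normal tissues and cancer-line control samples:
#' `ubiquitous` (detected in every sample), `tissue_specific` (detected in
#' >= 1 sample of exactly one eligible normal tissue and nowhere else among
#' normal tissues), `cancer_only` (detected in all cancer-line control
#' samples and in zero normal-tissue samples), `not_expressed` (detected
#' nowhere), else `other`. "Detected" means TPM >= `min_tpm`, the same bar
#' as the expression filter. Normal tissues with fewer than two samples are
#' excluded from eligibility; cancer-line samples must be controls to count.
#'
#' @param em an [expression_matrix()].
#' @param ids transcript ids to classify (default: all rows).
#' @param min_tpm detection threshold.
#' @return data.frame with retro_id, pattern, tissue and per-row fraction
#'   columns (fraction of normal / cancer-control samples detected).
#' @export
classify_pattern <- function(em, ids = rownames(em$tpm), min_tpm = 1) {
  s <- em$samples
  normal <- !s$is_cancer_line
  cancer_ctrl <- s$is_cancer_line & s$is_control
  tissue_n <- table(s$tissue_label[normal])
  eligible <- names(tissue_n)[tissue_n >= 2]
  if (!length(eligible) && !any(cancer_ctrl))
    stop("no eligible normal tissue (>= 2 samples) and no cancer-line controls")
  det <- em$tpm[ids, , drop = FALSE] >= min_tpm
  out <- data.frame(retro_id = ids, pattern = NA_character_,
                    tissue = NA_character_,
                    frac_normal = NA_real_, frac_cancer = NA_real_,
                    stringsAsFactors = FALSE)
  elig_norm <- normal & s$tissue_label %in% eligible
  for (i in seq_along(ids)) {
    d <- det[i, ]
    out$frac_normal[i] <- if (any(normal)) mean(d[normal]) else NA_real_
    out$frac_cancer[i] <- if (any(cancer_ctrl)) mean(d[cancer_ctrl]) else NA_real_
    if (!any(d)) { out$pattern[i] <- "not_expressed"; next }
    if (all(d)) { out$pattern[i] <- "ubiquitous"; next }
    tissues_hit <- unique(s$tissue_label[elig_norm & d])
    any_normal_hit <- any(d[normal])
    if (!any_normal_hit && any(cancer_ctrl) && all(d[cancer_ctrl])) {
      out$pattern[i] <- "cancer_only"; next
    }
    if (length(tissues_hit) == 1L && !any(d[normal & !(s$tissue_label %in% tissues_hit)])) {
      out$pattern[i] <- "tissue_specific"
      out$tissue[i] <- tissues_hit
      next
    }
    out$pattern[i] <- "other"
  }
  out
}

#' Spearman rank correlation with large-sample p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks on ties);
#' the two-sided p-value uses the t approximation
#' t = rho * sqrt((n-2) / (1-rho^2)) on n-2 degrees of freedom. A vector
#' with zero rank variance yields an undefined result (`NA` rho), which
#' callers exclude downstream.
#'
#' @param x,y equal-length numeric vectors.
#' @return list with `rho`, `p` and `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Correlate transcript pairs in one of two sample-selection modes
#'
#' @param em an [expression_matrix()].
#' @param pairs data.frame with columns id_a, id_b.
#' @param mode `"coexpressed"` restricts to samples where both TPM > 0;
#'   `"all"` uses every sample, zeros included.
#' @param min_pair_samples pairs with fewer usable samples return no row
#'   (default 10; rank p-values are unstable below that).
#' @return data.frame id_a, id_b, mode, n_used, rho, p. Undefined
#'   correlations (constant ranks) are dropped and counted in
#'   `attr(, "n_undefined")`.
#' @export
correlate_pairs <- function(em, pairs, mode = c("coexpressed", "all"),
                            min_pair_samples = 10) {
  mode <- match.arg(mode)
  ids <- unique(c(pairs$id_a, pairs$id_b))
  unknown <- setdiff(ids, rownames(em$tpm))
  if (length(unknown))
    stop("ids absent from expression matrix: ", paste(unknown, collapse = ", "))
  res <- vector("list", nrow(pairs))
  n_undefined <- 0L
  for (i in seq_len(nrow(pairs))) {
    a <- em$tpm[pairs$id_a[i], ]; b <- em$tpm[pairs$id_b[i], ]
    use <- if (mode == "coexpressed") a > 0 & b > 0 else rep(TRUE, length(a))
    if (sum(use) < min_pair_samples) next
    r <- spearman_rho(a[use], b[use])
    if (is.na(r$rho)) { n_undefined <- n_undefined + 1L; next }
    res[[i]] <- data.frame(id_a = pairs$id_a[i], id_b = pairs$id_b[i],
                           mode = mode, n_used = r$n, rho = r$rho, p = r$p,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(id_a = character(), id_b = character(), mode = character(),
                      n_used = integer(), rho = numeric(), p = numeric())
  attr(out, "n_undefined") <- n_undefined
  out
}

#' Keep significantly correlated pairs
#'
#' Retains results with p < `p_max` and |rho| > `rho_abs_min`, both strict.
#'
#' @param results output of [correlate_pairs()].
#' @param p_max p-value bound (default 0.001).
#' @param rho_abs_min absolute-rho bound (default 0.25).
#' @return the retained subset.
#' @export
filter_correlations <- function(results, p_max = 0.001, rho_abs_min = 0.25) {
  results[results$p < p_max & abs(results$rho) > rho_abs_min, , drop = FALSE]
}

## TRUE where an id pair appears in the filtered correlation set
corr_passes <- function(filtered, id_a, id_b) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  if (!nrow(filtered)) return(rep(FALSE, length(id_a)))
  key(id_a, id_b) %in% key(filtered$id_a, filtered$id_b)
}
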