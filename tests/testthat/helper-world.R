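# Shared fixtures: the default simulated world and one pipeline run over
# it, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

default_world <- function() {
  if (is.null(.fixture_env$world))
    .fixture_env$world <- simulate_world(sim_config(seed = 42))
  .fixture_env$world
}

default_run <- function() {
  if (is.null(.fixture_env$run)) {
    w <- default_world()
    d <- file.path(tempdir(), "rf_world")
    o <- file.path(tempdir(), "rf_out")
    write_world(w, d)
    .fixture_env$run <- run_pipeline(d, o)
    .fixture_env$run_dirs <- c(input = d, output = o)
  }
  .fixture_env$run
}

run_dirs <- function() {
  default_run()
  .fixture_env$run_dirs
}

truth_ids <- function(world, class, detail_prefix = NULL) {
  t <- world$truth[world$truth$evidence_class == class, , drop = FALSE]
  if (!is.null(detail_prefix))
    t <- t[startsWith(t$detail, detail_prefix), , drop = FALSE]
  unique(t$retro_id)
}

# sensitivity/specificity of a called id set against planted truth
sens_spec <- function(called, truth, universe) {
  called <- intersect(called, universe)
  tp <- length(intersect(called, truth))
  fp <- length(setdiff(called, truth))
  neg <- setdiff(universe, truth)
  c(sens = if (length(truth)) tp / length(truth) else NA_real_,
    spec = if (length(neg)) 1 - fp / length(neg) else NA_real_)
}

# small hand-built annotation: two genes on chrT
toy_annotation <- function() {
  exons <- data.frame(
    transcript_id = c("tA1", "tA1", "tA1", "tB1"),
    chrom = "chrT",
    start = c(100L, 300L, 600L, 2000L),
    end = c(200L, 400L, 700L, 2500L),
    strand = c("+", "+", "+", "-"))
  tx <- data.frame(transcript_id = c("tA1", "tB1"),
                   gene_id = c("gA", "gB"),
                   biotype = c("protein_coding", "lncRNA"),
                   cds_start = c(150L, NA), cds_end = c(650L, NA))
  annotation(exons, tx)
}

# fixture expression matrix planting the bundled ubiquitous /
# tissue-restricted / cancer-only identifier lists
table1_fixture <- function(seed = 7) {
  tab <- utils::read.delim(system.file("extdata", "table1_patterns.tsv",
                                       package = "retrofunc"),
                           stringsAsFactors = FALSE)
  set.seed(seed)
  tissues <- sort(unique(tab$tissue[tab$pattern == "tissue_specific"]))
  plan <- data.frame(tissue = c(tissues, "K562", "HepG2"),
                     n = c(rep(3L, length(tissues)), 3L, 3L),
                     cancer = c(rep(FALSE, length(tissues)), TRUE, TRUE))
  samples <- data.frame(sample_id = sprintf("f%03d", seq_len(sum(plan$n))),
                        tissue_label = rep(plan$tissue, plan$n),
                        is_cancer_line = rep(plan$cancer, plan$n),
                        is_control = TRUE)
  n <- nrow(samples)
  tpm <- matrix(0, nrow = nrow(tab), ncol = n,
                dimnames = list(tab$retro_id, samples$sample_id))
  for (i in seq_len(nrow(tab))) {
    if (tab$pattern[i] == "ubiquitous") {
      tpm[i, ] <- runif(n, 1, 20)
    } else if (tab$pattern[i] == "cancer_only") {
      sel <- samples$is_cancer_line
      tpm[i, sel] <- runif(sum(sel), 1, 20)
    } else {
      sel <- samples$tissue_label == tab$tissue[i]
      tpm[i, sel] <- runif(sum(sel), 1, 20)
    }
  }
  list(em = expression_matrix(tpm, samples), table = tab)
}
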