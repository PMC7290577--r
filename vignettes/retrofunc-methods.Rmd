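---
title: "retrofunc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retrofunc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`retrofunc` screens a retrocopy catalog for functional evidence across
seven streams: expression, co-expression, ribosome association, peptide
support, miRNA-sponge (ceRNA) activity, antisense/overlap regulation, and
fusion-breakpoint geometry. This vignette records the models, the
parameters that matter, the decisions taken where the design was open, and
what the bundled synthetic world does and does not establish. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## Coordinates

All internal coordinates are 0-based, half-open `[start, end)` (the
BED/bedGraph convention). GTF input (1-based, inclusive) is converted on
read; BED12 is consumed natively. A single internal convention prevents
off-by-one drift across the many geometric rules below. `tss`/`tes` are
the 0-based positions of the 5'-most and 3'-most transcribed bases.

## Expression filter and patterns

A transcript is expressed when its TPM is at least `min_tpm` (default 1)
in at least `ceiling(n_experiments * min_sample_fraction)` samples
(default fraction 0.01; for 818 experiments the ceiling rule gives 9).
Both bounds are inclusive; the monotonicity of the filter in both
parameters is asserted by a property test.

Pattern classification uses the same detection bar as the filter
(TPM >= `min_tpm`), applied per sample:

* *ubiquitous* — detected in every sample (normal and cancer-line alike);
* *tissue-specific(t)* — detected in >= 1 sample of exactly one eligible
  normal tissue and in no other normal tissue; cancer-line samples are
  ignored for this class, since tissue restriction is a statement about
  normal tissues;
* *cancer-only* — detected in all cancer-line control samples and in zero
  normal-tissue samples;
* *not expressed* — detected nowhere; everything else is *other*.

Normal tissues represented by fewer than two samples are ineligible (a
single sample cannot distinguish tissue restriction from noise); only
cancer-line samples flagged as controls count toward *cancer-only*.

## Co-expression

Spearman's rho is the Pearson correlation of mid-ranks (average ranks on
ties); two-sided p-values use the t approximation
`t = rho * sqrt((n-2)/(1-rho^2))`, adequate at the sample counts this
pipeline targets (hundreds of experiments; the synthetic default is 50).
Small-n users should treat p-values below ~10 points as unstable — which
is why `min_pair_samples = 10`: pairs with fewer usable samples return no
result at all rather than a fragile one. Constant-rank vectors yield an
undefined correlation; these are excluded and counted in the run log.

Two sample-selection modes reflect two mechanistic regimes:

* `coexpressed` keeps only samples where both partners have TPM > 0 —
  appropriate for transcript-level interactions (sponges, trans-NATs),
  which require both RNAs to be present;
* `all` keeps every sample including zeros — appropriate for cis-NAT and
  transcriptional-interference calls, where the act of transcription
  itself can regulate regardless of steady-state transcript level.

The significance filter is strict on both sides: p < 0.001 **and**
|rho| > 0.25.

## Ribosome density

For each feature and library, density is the ratio of mean Ribo-seq to
mean RNA-seq per-base coverage, with bases absent from a track counting
zero. Features with mean RNA coverage below `min_rna_coverage = 10` are
excluded (and features with zero RNA coverage are excluded before the
gate — the ratio is undefined).

CDSs of protein-coding genes are positive controls and their 3'UTRs
negative controls. Per library, each group (cds, utr3, retro) is trimmed
once at |Z| <= 1.64 with mean/SD taken from the untrimmed values — a
single pass, not iterated, which retains about 90% of normal data
(2Φ(1.64) − 1 ≈ 0.899). The calling cutoff is the trimmed 3'UTR mean +
1.64 trimmed SD; whether the cutoff statistics should come from the
trimmed or untrimmed 3'UTR distribution is genuinely open, so
`calibrate_and_call(cutoff_on=)` exposes both, defaulting to trimmed
(outlier removal is described as happening first). Calibration is per
library, not pooled, because coverage scales differ across libraries. A
retrocopy is positive in a library only when its density strictly exceeds
the cutoff; a value exactly at the cutoff is negative.

Note what this calibration implies: the negative-control group exceeds
its own 95th-percentile-style cutoff in roughly 5% of (feature, library)
pairs *by construction*. Cross-library summaries therefore report
positive-library counts, and the bundled summary rule flags a retrocopy
as ribosome-associated when it is positive in at least
`ribo_min_positive_fraction = 0.3` of usable libraries: with 8 libraries
and ~5% per-library false-positive rate, requiring >= 3 positives bounds
the expected false-call rate near 1%, while truly translated features
(density several-fold above the cutoff) are positive in essentially every
library. Tests on planted negatives accordingly assert the group-level
below-cutoff rate (>= 80% of retro × library pairs), not a per-retrocopy
guarantee that the calibration cannot provide.

## ORFs and peptides

Retrocopy loci are the annotated span extended by 500 b on each side
(clipped at chromosome ends). ORFs are maximal stop-to-stop translations
in all six frames, **start-codon independent**, of at least 20 codons:
peptide evidence does not require an annotated ATG, and ORF validity is
established instead by the requirement that the ORF span intersect the
un-extended retrocopy by >= 60 b (20 codons). Exact, gap-free, full-length
substring matching replaces alignment-based peptide mapping: the
acceptance rule is 100% identity with no gaps, which substring search
implements deterministically. Peptides shorter than 10 aa are rejected
before matching; a peptide found verbatim in any decoy sequence (the
translations of all non-retrocopy protein-coding transcripts supplied to
the run) or matching ORFs of more than one retrocopy is flagged
non-unique and excluded from the final evidence set.

Frame concordance against the parental CDS uses an **ungapped anchor**: a
retrocopy-local position marking a parental codon boundary. A sense hit is
concordant when its first codon starts on a boundary congruent to the
anchor modulo 3 — which correctly keeps a downstream in-frame peptide
concordant even when divergence introduced an internal stop upstream.
Retrocopies with indels relative to their parent would need a gapped map;
the ungapped choice is documented and the anchor table is an explicit
input, so a user can substitute an alignment-derived one.

## miRNA sponges

Site prediction is canonical seed matching — a 7mer-m8 site (reverse
complement of miRNA positions 2–8) or an 8mer (that heptamer followed by
an A) — as a documented stand-in for full Miranda scoring, whose output
the downstream statistic reduces to site presence per miRNA anyway.
Mature miRNAs are collapsed to seed families before counting, so
paralogous mature sequences are not double-counted. A precomputed site
table can be supplied instead; when it is, the family universe defaults
to the number of distinct families observed in the file unless the true
screened universe is passed explicitly (pass it: a smaller M makes the
test conservative in K and n but anti-conservative in overlap).

The enrichment test is the inclusive upper tail of
hypergeometric(M, K, n) at the observed shared-family count k, with
universe = families screened, successes = families targeting the
transcript, draws = families targeting the retrocopy. The
parameterisation is symmetric in (K, n), so the unavoidable orientation
choice does not affect p. Benjamini–Hochberg (step-up, q capped at 1)
runs across **all** tested pairs in one family at alpha = 0.05. A sponge
call additionally requires the coexpressed-mode correlation filter;
negative-rho pairs that pass are kept with the sign flagged, because
apparent negative correlation can reflect double functions or larger
ceRNA networks rather than a false pair.

## Overlaps, NATs, interference, exonization

Gene span for overlap detection is the union of all isoform exons and
introns; context is *exonic* when every overlapping base falls in the
gene's exon union, *intronic* when none does, *mixed* otherwise (the
three classes partition the overlap records). Opposite-strand overlap
makes a cis-NAT candidate; the call needs one host transcript passing the
all-mode correlation filter against the retrocopy.

Trans-NAT candidates come via three routes, each tagged on the call so a
call lists every route it satisfies: (a) an antisense lncRNA overlapping
the retrocopy, (b) a protein-coding transcript with an antisense
retrocopy-derived exon, (c) an opposite-strand TSS within `tss_window` of
the retrocopy 3' end. The window defaults to 500 b — the scale at which
CAGE clusters are conventionally assigned to nearby gene ends — and is
config-exposed because "near" has no canonical value. Routes (a)/(b) are
called on the antisense transcript's correlation with a parental-gene
transcript; route (c), whose antisense transcript is unannotated, is
called on the retrocopy's own parental correlation.

Transcriptional-interference candidates need, within one host gene, a
short isoform whose 3' end lies 0–1000 b upstream of the retrocopy
(strand-aware; abutting counts as distance 0) and a long isoform with an
intron fully containing the retrocopy. Orientation is recorded, not
filtered (interference geometry is strand-agnostic). The call requires a
positive passing correlation with at least one short isoform and **no**
passing correlation (either sign, the full p-and-rho filter) with any
long isoform.

Exon contributions intersect the retrocopy-derived exon portion with the
transcript's 5'UTR/CDS/3'UTR genomic sub-spans; transcripts without a
complete CDS are flagged and excluded from CDS-impact tallies since their
regions are undefined.

## Fusions

A gene hosts a retrocopy when the retrocopy lies fully inside the gene's
transcribed span (partial overlap is excluded from categories).
Categories: retro×parental, parental×host, host×host (both partners host
retrocopies of one common parent), else other. Breakpoints: *in-body*
when the position is inside the half-open span (the start base counts,
the end base does not); *downstream-near* when within `near_max = 1000` b
downstream of the 3' end per the retrocopy's strand (distance 1 is the
first base past the span); *distant* otherwise on the same chromosome —
including upstream-near positions, since only downstream breaks carry the
hot-spot interpretation; *unrelated* on another chromosome. The observed
near-range in real data is tens to ~200 b; 1000 b is a deliberate,
config-exposed bound, not an empirical estimate.

## The synthetic world

The generator states a small, fully-controlled world; its defaults are
the conditions the tests certify:

* **Layout** — one chromosome; 24 plain 3-exon protein-coding genes
  (650-nt mRNA, stop-free 450-nt CDS) serving as parental pool and
  density controls; intronic hosts, two-isoform interference hosts,
  exonization hosts and antisense lncRNAs for the geometric classes; 45
  retrocopies as single-exon copies of parental mRNAs with 3% per-base
  substitutions (typical processed-pseudogene divergence is a few
  percent).
* **Samples** — 40 normal samples over 5 tissues plus 10 cancer-line
  controls. Real compendia are an order of magnitude larger; the planted
  Spearman target is 0.7 so that the p < 0.001 bar is reliably reachable
  at n = 50 (at rho 0.5 it would not be, and that would test the sample
  size, not the code).
* **Expression** — background rows are log-normal(log 2, 1), dispersed
  enough that unplanted rows are detected in many but not all samples;
  correlated pairs use a Gaussian copula with Pearson parameter
  2·sin(π·rho_s/6) mapped through the log-normal quantile, so the
  population Spearman equals the target exactly.
* **Coverage** — 8 Ribo/RNA library pairs; per-base depths are
  negative-binomial (size 5) around feature × library means; RNA mean 30
  (two features planted at 3 to exercise the >= 10 gate); ribosome-density
  ratios 2.5 for CDS and positive retrocopies, 0.5 for 3'UTRs and
  negative retrocopies, with a log-normal (sdlog 0.25) feature-level
  factor emulating gene-to-gene variability of aggregate tracks.
  Overdispersed counts resemble aggregate Ribo-seq better than Poisson.
* **Sites** — 200 miRNA families; every sequence draws 5 background
  families; true sponge pairs share 8 dedicated families.
* **Determinism** — every generator op runs on its own stream seeded from
  `seed` plus an op-specific offset, so one fixture can be regenerated
  without disturbing the others; the same config is byte-identical.

What a green test does **not** establish: recovery at realistic
signal-to-noise (planted effects are strong by design), behaviour under
indels or assembly error (substitution-only divergence), multi-mapping
ambiguity (coverage is assigned, not aligned), or the paper-scale counts
from public compendia, which depend on hundreds of external libraries and
are out of desk-scale reach. The per-stage logic, thresholds, boundary
conventions and statistics are what the suite certifies — against
independent brute-force oracles wherever a second route exists
(all-vs-all interval scan, codon-scan ORF enumeration, exhaustive
hypergeometric draws at M <= 12, explicit mid-rank Pearson).

## Known limitations

* bedGraph tracks must be non-overlapping per chromosome; overlapping
  records are an input error, never silently summed.
* BAM/bigWig are out of scope; convert upstream.
* The seed-match site caller ignores pairing energetics and conservation;
  supply a precomputed table to use an external predictor.
* Frame concordance assumes an ungapped retro-parent map.
* Catalogs are consumed as given: liftover between assemblies, and the
  reconciliation of alternative published totals for the same catalog, are
  upstream concerns the readers deliberately do not arbitrate.
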