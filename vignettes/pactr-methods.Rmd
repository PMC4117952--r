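---
title: "Determining poly(A) sites and comparing alternative polyadenylation with pactr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining poly(A) sites and comparing alternative polyadenylation with pactr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pactr)
```

## The problem

3'-end sequencing protocols (PAT-seq and relatives) produce short cDNA tags
that span the mRNA/poly(A) junction. After alignment, each tag defines one
cleavage coordinate: the last transcribed nucleotide before the poly(A)
tail. Three obstacles stand between those raw coordinates and a usable
poly(A)-site catalogue:

1. **Artifacts.** Oligo-dT primers also anneal to genome-encoded A-rich
   tracts, producing tags at positions that are not polyadenylation sites
   (internal priming), and tags whose 5' mates failed to map uniquely are
   unreliable.
2. **Microheterogeneity.** Cleavage around one biological poly(A) site
   varies by a few nucleotides, so raw coordinates must be clustered before
   counting sites.
3. **Incomplete annotation.** In genomes annotated mostly from
   protein-coding predictions, many genuine 3'-UTR sites fall just
   downstream of the annotated gene end and would be miscalled intergenic.

`pactr` implements the full path from mapped tags to a poly(A)-site-cluster
(PAC) catalogue, assigns PACs to genomic regions under rule-extended gene
models, classifies antisense PACs around convergently transcribed gene
pairs, profiles the nucleotide composition around cleavage sites, and runs
the cross-species conservation statistics used to ask whether alternative
polyadenylation (APA) in introns, coding regions, or antisense orientation
is conserved between orthologous genes.

## Tag curation

`curate_tags()` applies three steps, in order:

* **Mate concordance** (`filter_pairing()`): only tags whose paired 5' end
  mapped uniquely are kept. Upstream of this, `classify_raw_tag()` decides
  whether a raw read is a poly(T) tag at all; the default threshold of 8
  leading T is a deliberately stringent sub-length of the 18-nt oligo-dT
  primer and is configurable (`min_t_run`).
* **Internal-priming removal** (`filter_internal_priming()`): a tag is
  discarded iff the 10 genomic nt immediately downstream of its cleavage
  position — read on the tag's sense strand, reverse-complemented for
  minus-strand tags — contain a run of 6 or more consecutive A. The 6-base
  run is the published rule; the 10-nt window is an implementation choice:
  it is the smallest window that cannot miss a 6-run starting at the
  cleavage site while tolerating nucleotide-scale jitter. Strict
  consecutive-run semantics were chosen over A-fraction rules used in some
  related pipelines; both the run length and the window are parameters.
* **Aggregation** (`aggregate_tags()`): tags sharing (chromosome, strand,
  position) collapse into one record with summed count, because clustering
  semantics depend on distinct positions, not read multiplicity.

The per-stage counts are kept as a cascade report
(`curation_report()`) and are monotonically non-increasing.

## PAC clustering

`cluster_tags()` chains distinct cleavage positions per chromosome and
strand: adjacent positions separated by **fewer than 24 nt** join the same
PAC. The gap is read as *adjacent-pair* separation (single-linkage
chaining), not cluster-span diameter — the reading used by reference PAC
callers; a cluster may therefore span more than 24 nt if it is densely
populated. The PAC's representative coordinate (its *summit*) is the
position with the highest tag count; ties break toward the 3'-most position
on the PAC's strand, a deterministic rule that reflects the distal bias of
cleavage heterogeneity. Both choices are parameters/documented because the
source material defines neither a representative coordinate nor a tie
rule.

## Gene models, AMB regions and 3' extension

`read_annotation()` + `build_gene_models()` merge all transcripts of a gene
into one model at single-nucleotide resolution: positions labelled
identically in every covering transcript keep that label
(5UTR/CDS/intron/3UTR); positions with conflicting labels become **AMB**
(ambiguous), then runs of equal labels are coalesced into maximal segments.

`extend_models()` appends the 3' search space in which poly(A) sites of
incompletely annotated genes are expected: genes **with** an annotated
3'-UTR are extended 200 nt (Medicago-like profile) or 120 nt
(Arabidopsis-like); genes **without** one, 400 or 338 nt respectively.
Extensions are clipped at chromosome edges and truncated where they would
enter a downstream same-strand gene body. That truncation policy is this
package's choice (the source material is silent): it prevents sense
misassignment between tandem genes while deliberately *allowing* overlap
with opposite-strand genes, which is exactly the convergent-overlap
configuration that produces antisense cases 1 and 2. The promoter window is
the 2000 nt upstream of the 5'-most transcribed coordinate, falling back to
the gene-body start for genes without an annotated 5'-UTR.

## Region assignment and antisense cases

`assign_pacs()` resolves each PAC **at its summit only**; span-based
assignment would double-count PACs straddling segment boundaries and
inflate AMB. Same-strand precedence is gene body > extension > promoter,
then nearest gene 3' end, then lexicographic gene id. PACs covered by
nothing on their own strand are promoter (if in a window) or intergenic.

A PAC whose summit falls in the *annotated body* of an opposite-strand gene
is antisense to that gene and receives an attribution case by searching for
a same-strand gene that could explain it as transcriptional read-through:

| case | configuration |
|------|---------------|
| 1 | summit inside a same-strand gene's annotated or extended 3'-UTR |
| 2 | summit inside any other part of a same-strand gene body (CDS/5'-UTR; intron and AMB are folded in as the same phenomenon) |
| 3 | no covering same-strand gene, but one whose annotated 3' end lies within 500 nt upstream of the summit (convergent configuration) |
| 4 | orphan: no plausible convergent source |

The 500-nt "nearby" distance for case 3 is a package default, surfaced as
`nearby_antisense_distance`: it exceeds both extension rules, and measuring
from the *annotated* gene end makes the case boundaries fall exactly at the
extension length (1 → 3) and at the nearby distance (3 → 4). A PAC that is
antisense to gene A while lying sense inside gene B (overlapping convergent
genes) keeps both attributions and appears in both the sense and antisense
tabulations.

## Nucleotide profiles

`composition_profile()` tallies per-position base fractions in a window
(default −300/+100 nt; the upstream reach is generous because functional
elements occur out to ~100 nt upstream, and a wider window costs nothing)
around summits, on the site's sense strand, with position 0 at the cleavage
site; T is reported as U. Sites whose window would cross a chromosome edge
are dropped and counted. Genuine plant poly(A) sites show a tripartite
signal — far-upstream U-rich element, A-rich element near −20, U-rich
cleavage region with a YA dinucleotide — whereas randomly placed sites give
a flat profile at 0.25, which is exactly how the tests discriminate signal
from artifact. `stratified_profiles()` keys profiles by region class
(3'-UTR/intron/CDS/intergenic and the three antisense classes
overlap/nearby/orphan) crossed with single-PAT/multi-PAT support.

## Conservation statistics

`utr_lengths_per_gene()` measures, per gene with 3'-UTR PACs, the distance
from the annotated CDS 3' end to a representative poly(A) coordinate. The
representative is genuinely underdetermined in the source material, so
three modes are provided — tag-weighted mean (default), most distal summit,
median summit — and the mode is recorded in the result's metadata.

`compare_utr_lengths()` reports Wilcoxon rank-sum tests of orthologous vs
non-orthologous gene lengths per species, the Pearson correlation over
ortholog pairs, and the correlation over randomly assembled pairs as the
null control (seeded).

`feature_conservation_test()` is the randomization design used for
intronic, CDS and antisense APA conservation: with species-B feature genes
mapped into a pool of species-A orthologs, it draws `n_random_trials`
(default 1000) random samples of the same size from the pool *without
replacement* and compares the observed number of feature-sharing orthologs
against the randomization mean with a two-cell chi-square goodness of fit.
The chi-square construction is this package's concrete reading of the
published "chi-square test"; since a single random draw is a hypergeometric
sample, the closed-form hypergeometric expectation
`sample_size * K / N` is computed alongside, and the randomization mean
converges to it. The chi-square uses the binomial variance at the expected
proportion, which slightly *understates* significance relative to the
hypergeometric variance — a conservative choice. Gene-level counting
deduplicates many-to-many ortholog tables to unique species-B genes,
counting a feature as shared if **any** ortholog partner carries it.
Degenerate cases: an empty sample is flagged untestable; expected counts
are clamped away from 0 and the sample size before division; an exact match
of observed and expected gives a statistic of 0.

`est_validation()` counts EST-derived poly(A) sites with a same-strand PAC
summit within 50 nt; the window is inclusive at the boundary (a site
exactly 50 nt away validates).

## The synthetic-data generator

`simulate_genome()` / `simulate_tags()` / `simulate_orthologs()` define the
study conditions under which every stage is tested, with fully known ground
truth:

* Chromosomes are uniform-composition random sequence (2 × 100 kb by
  default) carrying 40 genes, placed singly or as convergent pairs (30% of
  placement units) whose inter-gene gaps span the antisense case regimes.
* 60% of genes get an annotated 3'-UTR, exercising the 200 vs 400 nt
  extension rule; 70% get an annotated 5'-UTR, exercising the promoter
  fallback.
* Per-gene planted site counts follow the reported gene-level APA spectrum
  (probabilities 0.36/0.24/0.16/0.10/0.14 for 1–5 sites, i.e. 64% of genes
  with more than one site), and the region mix (3'-UTR 0.71, intron 0.07,
  CDS 0.12, antisense 0.10) mirrors the reported genomic distribution of
  sense PACs with an antisense component.
* Cleavage jitter is a discrete truncated normal (default sd 3 nt,
  truncated at ±11 nt) so that all tags of one site stay pairwise closer
  than the 24-nt gap; planted sites on one strand are kept ≥50 nt apart so
  sites remain recoverable one-to-one under jitter.
* Internal-priming decoys are genomic A-tracts (≥6 A, 0.5/kb) planted ≥60 nt
  from any site; artifact tags (5% of tags) sit immediately upstream of a
  tract. The 10 nt downstream of every *genuine* site (over the whole ±11 nt
  jitter range) are scrubbed of accidental A-runs, so the artifact ground
  truth is exact: the internal-priming filter must recover the planted
  artifact set with sensitivity and specificity 1.
* Ortholog tables plant marginal and joint feature rates; joint = product
  of marginals plants the null, larger joints plant conservation
  enrichment. `simulate_utr_lengths()` plants a bivariate-normal length
  correlation (defaults centred on the reported medians, 180 vs 169 nt).

What the generator does **not** emulate: sequencing errors and the
alignment step (the pipeline starts from mapped coordinates), non-uniform
genomic base composition, the genuine tripartite poly(A) signal around
planted sites (planted sites are signal-free by construction, except where
a test plants an A-rich element deliberately), transposon-rich intergenic
space, and expression-level variation between samples. Passing tests
therefore demonstrate the correctness of the *computational* rules — the
filters, the clustering, interval logic and the statistics — not that the
pipeline's defaults are optimal for any particular real genome.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout, matching GFF3 and the
  Bioconductor ranges stack the package is built on.
* All randomness flows from explicit integer seeds; fixed seed means
  byte-identical FASTA/GFF3/BED/JSON outputs and identical statistics.
* Determinism rules: summit ties break 3'-most; aggregated tag records take
  the lexicographically smallest tag id; randomization trials use
  `sample.int` without replacement on the sorted pool.
* Problem sizes in the test-suite and in `scripts/acceptance.R` are scaled
  to the synthetic study (tens of genes, hundreds of tags, thousands of
  ortholog pairs; 100-seed calibration runs use 300 randomization trials) —
  chosen so the whole suite exercises every rule in minutes while keeping
  Monte-Carlo standard errors well inside the asserted tolerances.
* The conservation test's null calibration is checked empirically: with a
  planted-null ortholog table the test must be non-significant at
  `alpha = 0.05` in ≥90% of seeds, and with 3× planted enrichment
  significant at 0.01 in ≥90% — both hold with margin because the
  chi-square construction is conservative.

## Known limitations

* The pipeline starts from mapped cleavage coordinates; alignment,
  barcode handling and adapter chemistry are out of scope.
* Expression normalisation between samples and differential PAC-usage
  testing are not implemented (not part of this design).
* Attribution of intergenic PACs to novel transcription units is reported
  only as distance statistics, not as gene calls.
* The antisense "nearby" distance (case 3) and the internal-priming window
  are package defaults, not published values; both are parameters and are
  recorded in every run manifest.

## A worked miniature

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- simulate_genome(cfg)
tags <- simulate_tags(sim)
run <- run_pipeline(sim$genome, sim$features, tags, seed = 1)
run
run$region_table
tidy(run$gene_pacs)
autoplot(run$profiles)
```
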