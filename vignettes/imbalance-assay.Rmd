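---
title: "Inferring gene fusions from 5'/3' expression imbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene fusions from 5'/3' expression imbalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusimba)
```

## The problem

Clinical fusion detection from whole-transcriptome sequencing (WTS) of
FFPE tumor tissue relies on split reads and discordant mate pairs. Both
kinds of evidence degrade with FFPE fragmentation and low tumor cell
content (TCC), so therapeutically critical fusions — EML4::ALK being the
canonical case — can be missed even when the fusion transcript is clearly
expressed. The rescue signal exploited here is *expression imbalance*: a
fusion places the retained portion of the target gene (for ALK, the exons
coding the kinase domain, downstream of the recurrent breakpoint after
exon 19) under the partner's promoter. In a gene that is otherwise silent
in adult tissue, this produces strong coverage on one side of the
breakpoint and essentially none on the other — detectable without any
junction-spanning read. A flagged gene is *not* a fusion call: the partner
remains unknown, and the recommendation attached to every flag is
orthogonal confirmation (targeted panel, FISH or CISH).

## The imbalance statistic

For a gene with exons numbered in transcription order and a breakpoint
between exons $k$ and $k+1$, let $\bar d_5$ and $\bar d_3$ be the
length-weighted mean *sense-strand* read depths over the 5' exons
$\{1..k\}$ and the 3' exons $\{k+1..n\}$. The statistic is

$$ \mathrm{FC} = \frac{\bar d_\mathrm{retained} + \varepsilon}
                      {\bar d_\mathrm{other} + \varepsilon}, $$

with pseudocount $\varepsilon = 0.05\times$ by default. The pseudocount is
not cosmetic: the non-retained side of a silent fused gene is frequently
exactly $0\times$, and the ratio must remain finite and comparable across
genes. With example means of $0.03\times$ and $7.37\times$ this
definition gives $7.42/0.08 = 92.75$; note that ratios of rounded means
are very sensitive to the denominator, so small differences in the
pseudocount convention change the headline number substantially
($7.37/0.03 \approx 246$ with no pseudocount at all). The formula above,
with its explicit $\varepsilon$, is therefore stated as *the* definition
used throughout this package, and $\varepsilon$ is exposed in
`imbalanceThresholds()`.

Whether the per-side mean should be length-weighted across exons or a
plain mean of per-exon means is a genuine design choice; we default to
length-weighting (a mean over transcript bases) and expose
`lengthWeighted = FALSE` for the alternative.

### Why strandedness is essential

Coverage on the *antisense* strand must never enter the statistic. The
motivating failure mode is unspliced pre-mRNA of a neighboring gene
transcribed on the opposite strand (for ALK, CLIP4 pre-mRNA reaching into
the kinase-domain exons): in an unstranded pileup this inflates the
retained-side mean and fabricates imbalance. `strandedExonCoverage()`
therefore assigns every read a transcript strand from its pair flags under
the declared library orientation (`RF`, the TruSeq-stranded convention, by
default; `FR` supported) and reports sense and antisense tracks
separately. The antisense track is kept visible in the output precisely so
the confounder can be inspected, but neither it nor antisense spliced
reads contribute to any reported number — a property the test suite
asserts by injecting heavy antisense contamination and requiring the
report to be bit-identical.

### Junction evidence

Spliced reads (alignments with an N gap) on the gene strand are counted
for each side of the boundary; a junction crossing the boundary is
*spanning* and counted separately, because a canonical exon $k$ to
$k+1$ junction is wild-type evidence against a breakpoint there, not for
it. The junction classification point is the midpoint of the intron
between exons $k$ and $k+1$, so the canonical crossing junction always
classifies as spanning regardless of exon geometry.

### The flagging rule

A gene/breakpoint is flagged when all three hold:

| parameter | default | unit | role |
|---|---|---|---|
| `minFoldChange` | 10 | — | imbalance strength |
| `minRetainedDepth` | 2.0 | x coverage | absolute expression floor |
| `minJunctionDelta` | 5 | reads | independent splice-level evidence |
| `pseudocount` | 0.05 | x coverage | fold-change regularization |

The conjunction matters: a fold change of 50 on a gene whose retained
side is at $0.5\times$ is noise, not signal. These defaults are package
decisions validated by simulation (the TCC power curve below), not
published constants; all are exposed in `imbalanceThresholds()`.

## Automatic breakpoint determination

When no recurrent breakpoint is configured, `autoBreakpoint()` fits a
piecewise-constant two-mean step model to $y_i = \log_2(d_i +
\varepsilon)$ over the exon index and returns the boundary minimising

$$ \mathrm{RSS}(k) = \sum_{i \le k} (y_i - \bar y_{1..k})^2 +
   \sum_{i > k} (y_i - \bar y_{k+1..n})^2 . $$

Two deliberate choices: the fit is on log depth because coverage noise is
multiplicative, and the minimisation is an exhaustive scan over all
$n - 1$ candidate boundaries rather than an iterative segmented-regression
fitter. For a single changepoint over a gene-sized number of exons
($\le$ ~100) the exhaustive scan is exact, deterministic and effectively
free, so it strictly dominates iterative approximations; the test suite
holds it to agreement with an independent brute-force implementation on
1,000 random profiles. Ties break toward the smallest $k$; at least 4
exons are required for a meaningful two-mean fit. The step (level-shift)
reading, rather than a broken-slope model, is the natural model for an
expression jump at a fusion breakpoint.

## The QC gate and routing

Four criteria gate a sample into WTS; any failure routes it to a targeted
panel as fallback:

| criterion | threshold | source |
|---|---|---|
| tumor cell content | >= 40 % | pathologist metadata |
| RNA input | >= 50 ng | lab metadata |
| unique fragments after collapsing | >= 50 million | computed from BAM |
| median insert size | >= 100 bp | computed from BAM |

All four comparisons are inclusive (`>=`). Clinical descriptions of such
gates mix "at least", "or more", "more than" and "above" phrasing for the
same thresholds; a single inclusive convention is used here and boundary
behaviour is pinned by tests. Insert size is used as the FFPE quality
proxy instead of RIN deliberately — it is a post-sequencing property of
the actual library. TCC and RNA input are *never* imputed from sequence
data; a missing value is an error, not a pass.

Two metric definitions are under-determined and fixed as follows:
"unique reads after collapsing" is computed as distinct fragment
coordinate keys (contig, fragment start, fragment end, orientation of the
leftmost mate) among primary proper pairs — no UMIs exist in this
protocol, so coordinate collapsing is the only available definition; a
`asReads = TRUE` flag doubles the tally for sites that count reads rather
than fragments. The median insert is the lower median over pairs, so the
reported value is always an actually observed template length.

## The simulator

`simulateSample()` generates stranded paired-end alignments with known
truth so that every stage above is testable without external data. It
emulates exactly the features the assay consumes, and nothing else:

- **Transcript classes.** A *fusion* transcript covering only the exons on
  the retained side of the breakpoint (the partner gene is deliberately
  not simulated — the assay's premise is that the partner is unknown); a
  full-length *wild-type* transcript; and optional *antisense* unspliced
  contamination spanning the gene, mimicking neighboring-gene pre-mRNA.
- **Counts.** Fragment counts are Poisson with expectation
  $d \cdot L / (2R)$ for target depth $d$, transcript length $L$ and read
  length $R$ — the simplest count model consistent with a coverage target.
  Fusion depth is scaled by $\mathrm{TCC}/100$; the wild-type background
  is present in all cells and is not scaled.
- **Inserts.** Fragment lengths are log-normal (median 129 bp, spread
  8 bp by default, FFPE-like), discretized and clamped to
  $[R, \min(L, 3 \cdot \mathrm{median})]$. The SAM template-length field
  records the sequenced fragment length; for spliced fragments the genomic
  mate span would include introns and is not the insert the QC metric
  estimates.
- **Strands and flags.** RF chemistry is baked in: the second-in-pair
  mate aligns on the transcript strand. Alignments are splice-consistent
  (M/N CIGARs across exon junctions), properly paired, MAPQ 60.
- **Truth.** `SimTruth` carries realized per-class fragment counts and
  the *analytic* expected sense depth per exon, computed in closed form by
  marginalising over the fragment-length pmf and the uniform placement —
  including the depth depression near transcript ends, so the
  expectation-match test needs no fudge tolerance beyond sampling error.
- **Determinism.** The seed is part of the config; identical configs give
  byte-identical SAM.

What it does *not* model — base-call errors, soft clips, mismatched
alignments, chimeric split reads, partner-gene sequence — is omitted
because the assay consumes alignments, not base calls, and none of those
features exercise any code path here. Consequently, passing simulation
tests demonstrates correctness of the counting, strand logic and decision
arithmetic under the stated generative model; it does not demonstrate
robustness to alignment artifacts in real FFPE libraries, which must come
from validation on real samples.

## Cohort summaries

`summarizeCohort()` reduces a per-sample ledger to the headline
statistics of a diagnostic cohort: detection rate among fusion-positive
samples, sample-level concordance (detected positives plus confirmed
negatives — the only reading under which a cohort with only false
negatives has concordance `(n - misses)/n`), fusion-level call rate
(fusions and samples are tallied separately because multi-fusion samples
make the two differ), the per-criterion QC failure breakdown, concordance
restricted to QC-passing samples, and fallback routing tallies.
Percentages are rounded half-up to one decimal (half-up, not banker's
rounding, so printed report values are stable); small-cohort detection
rates can be printed as integer percents via `integerPct = TRUE`.

## A worked example at desk scale

```{r example}
st <- seq(1000, by = 1000, length.out = 34)
alk <- geneModel("ALK", "chr2", "-", cbind(st, st + 149))
bp  <- breakpointSpec("ALK", 19, "3prime", gene = alk)
sim <- simulateSample(simConfig(alk, bp, tcc = 100,
    fusionExpression = 7.34, wildtypeExpression = 0.03, seed = 2024))
res <- runImbalanceAssay(sim, alk, bp)[[1]]
res
```

The simulated gene reproduces the canonical pattern: near-zero coverage
over exons 1–19, several-fold coverage over exons 20–34, spliced reads
almost exclusively 3' of the boundary, and a flag with an
orthogonal-confirmation recommendation.

## Numerical and scale choices

Exon intervals are stored as 1-based closed `IRanges`; all interval
arithmetic (union-merge of transcript exons, per-exon coverage views) is
delegated to IRanges/GenomicAlignments rather than re-implemented. GTF
input/output is via rtracklayer, with a light pre-scan so malformed lines
fail with a line number. Multi-transcript genes are collapsed to the exon
union of all transcripts — no canonical-transcript selection is
attempted, since breakpoint exon numbering is defined on the merged model.

Test and acceptance problem sizes are chosen to make the statistical
checks sharp at desk scale: 1,000 random profiles for changepoint
exactness, 200 replicates per point for the noisy-step recovery rate and
the TCC power curve (TCC in {10, 20, 30, 40, 60, 100}), 100 replicates
for the expectation-match check, and a single-exon 10 kb transcript with
more than 2,000 fragments for insert-median fidelity.

## Known limitations

- The assay infers *imbalance*, not fusions: promoter-driven
  overexpression without rearrangement, internal deletions, or assembly
  artifacts can flag; every flag requires orthogonal confirmation.
- Genes with substantial wild-type expression dilute the fold change; the
  assay is most sensitive for genes silent in the tissue of origin.
- Recurrent-breakpoint tables and diagnostic gene sets are site
  configuration; the files shipped under `inst/extdata/` are synthetic
  illustrations of the schema, not clinical content.
- The flagging thresholds were tuned on simulated data under the
  generative model above; sites should re-validate them on their own
  panel-confirmed samples before clinical use.
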