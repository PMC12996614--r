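# fusimba

Expression-imbalance fusion inference and QC gating for clinical RNA-seq.

## What problem this solves

Diagnostic labs detect gene fusions from whole-transcriptome sequencing
(WTS) of FFPE tumor samples with split-read/discordant-mate callers
(ARRIBA, DRAGEN, CTAT-Splicing). On fragmented FFPE libraries with low
tumor cell content those reads are often simply absent, and actionable
fusions — EML4::ALK above all — get missed even though the fusion
transcript is expressed. `fusimba` implements the computational safety
net around that failure mode, for molecular pathology pipelines:

- **5'/3' expression-imbalance assay.** A fusion puts the retained part
  of a target gene under a foreign promoter. For a gene that is silent in
  the tissue (ALK in adult tissue), coverage appearing only downstream of
  a recurrent breakpoint is strong indirect fusion evidence. The assay
  computes strand-aware per-exon mean depth, the pseudocounted fold
  change

  `FC = (mean_retained + eps) / (mean_other + eps)`,   `eps = 0.05x`,

  strand-aware spliced-read counts on each side of the boundary, and a
  flag that triggers a recommendation for orthogonal confirmation.
  Strandedness is load-bearing: unspliced antisense pre-mRNA of a
  neighboring gene (CLIP4 over ALK's kinase-domain exons) would otherwise
  fabricate the signal.
- **Automatic breakpoint determination.** An exact exhaustive
  single-changepoint step-model fit on log2 per-exon depth
  (`autoBreakpoint()`), for genes without a configured recurrent
  breakpoint.
- **Four-criterion QC gate with fallback routing.** TCC >= 40 %, RNA
  input >= 50 ng, >= 50 M unique fragments after coordinate duplicate
  collapsing, median insert size >= 100 bp; any failure routes the sample
  to a targeted panel (`evaluateQC()`, `routeSamples()`).
- **Fusion-call filtering and harmonization.** ARRIBA-style and generic
  caller tables, read-support + gene-set filters (minimum support 1 for a
  validated diagnostic set, 10 for an expanded exploratory list),
  multi-caller merging with a ±10 bp breakpoint tolerance, and
  truth-matching against panel results (`parseFusionTable()`,
  `applyFilters()`, `mergeCallers()`, `matchToTruth()`).
- **A deterministic stranded read simulator** with analytic truth
  (`simulateSample()`, `simulateCohort()`) and **cohort summaries**
  (`summarizeCohort()`) so the entire workflow is testable without
  external data.

## Worked example

A simulated ALK-like case: 34 exons on the minus strand, fusion
expression starting after exon 19, faint wild-type background.

```r
library(fusimba)

st  <- seq(1000, by = 1000, length.out = 34)
alk <- geneModel("ALK", "chr2", "-", cbind(st, st + 149))
bp  <- breakpointSpec("ALK", 19, "3prime", gene = alk)

sim <- simulateSample(simConfig(alk, bp, tcc = 100,
    fusionExpression = 7.34, wildtypeExpression = 0.03, seed = 2024))
runImbalanceAssay(sim, alk, bp)[[1]]
#> ImbalanceResult ALK (boundary exon 19, retained 3prime)
#>   mean5 = 0.035x, mean3 = 7.911x, fold change = 93.56
#>   junctions: 5' = 1 , 3' = 111 , spanning = 0
#>   flagged: TRUE -> orthogonal_confirmation
```

Reading the output: exons 1–19 are essentially uncovered (0.035x) while
exons 20–34 sit at ~7.9x on the gene-specific strand; the pseudocounted
fold change is 93.6; 111 spliced reads lie 3' of the boundary versus 1 on
the 5' side, and none span it. All three flag criteria (fold change >= 10,
retained depth >= 2x, junction difference >= 5) are met, so the gene is
flagged for orthogonal confirmation — the assay deliberately stops short
of naming a fusion partner. `runImbalanceAssay()` accepts an indexed BAM
(or SAM) path in place of the simulator output for real data.

The QC gate works the same way on real or ledger metadata:

```r
evaluateQC(qcMetrics("S1", tcc = 50, rnaInput = 120,
                     uniqueReads = 6.2e7, medianInsert = 128))
#> QCDecision S1: PASS -> WTS
#>   tcc_ok=TRUE input_ok=TRUE reads_ok=TRUE insert_ok=TRUE
```

A thin CLI over the same functions is installed at
`exec/fusimba` (subcommands `imbalance`, `qc`, `filter`, `cohort`,
`simulate`); invoke it as
`Rscript $(Rscript -e 'cat(system.file("exec", "fusimba", package = "fusimba"))') <subcommand> ...`.

See `vignettes/imbalance-assay.Rmd` for the model, the parameter
defaults and their rationale, and known limitations.

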