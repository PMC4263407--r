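---
title: "Methylome reprogramming analysis: models, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome reprogramming analysis: models, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methreprog)
library(data.table)
```

## The problem

After fertilization the mammalian embryo erases most gametic DNA
methylation and re-establishes it after implantation. The two parental
genomes behave differently: the paternal (sperm-derived) genome is
demethylated rapidly and almost completely, while the fate of the
maternal (oocyte-derived) genome differs between species. In mouse,
maternal methylation is largely lost passively — each DNA replication
without maintenance methylation halves the methylation of the maternal
chromatids. Whether human embryos do the same is a quantitative
question: under one replication-dependent dilution event, a region
fully methylated on the maternal allele and unmethylated on the
paternal allele can retain at most

$$\frac{m_\mathrm{mat}\cdot 2^{-k} + m_\mathrm{pat}}{2}
  \;=\; \frac{1 \cdot 0.5 + 0}{2} \;=\; 25\%$$

of its methylation in the diploid embryo (`passive_demethylation_expectation()`).
Observed blastocyst levels of oocyte-specific methylated regions well
above this bound argue for retention of the maternal methylome rather
than passive dilution. This package implements the full downstream
analysis needed to make that argument from whole-genome bisulfite
sequencing (WGBS) data — and a synthetic-methylome generator that
encodes both competing models so every analysis stage can be verified
against planted truth.

## Data model and coverage conventions

A sample is a `MethylomeTrack`: per-cytosine methylated/total read
counts keyed by (chromosome, 0-based position, context). Bisulfite
sequencing cannot distinguish 5mC from 5hmC, so "methylation" here is
their sum. CpG dyads are palindromic; `merge_cpg_strands()` sums the
two strands into one call at the forward-strand C. Depth filtering
follows the asymmetric convention of low-input oocyte libraries:
CpGs with ≥3 reads are analysed for oocytes, ≥5 for all other samples
(`filter_depth()`); replicates are pooled by summing counts *before*
filtering (`pool_tracks()`), and the bisulfite conversion rate is
estimated from an unmethylated spike-in contig
(`estimate_conversion_rate()`). Region and window means are unweighted
averages of per-CpG levels — each covered CpG counts once regardless
of its depth — because deep positions would otherwise dominate
low-input samples; read-weighted means are available behind a flag.

## Sliding-window analysis

Windows contain a fixed number of CpGs (20, stepping by 10) taken from
a reference CpG map rather than from per-sample covered positions, so
a window denotes the same genomic entity in every sample. A window is
testable in a sample when ≥10 of its CpGs pass that sample's depth
filter. Between two samples, `classify_window_changes()` calls a
window **increasing** when its mean rises by >20 percentage points and
the per-CpG levels differ significantly (Student's unpaired
equal-variance t-test, Benjamini–Hochberg adjusted q < 0.05),
**decreasing** for the mirror image, and **stable** otherwise.

Three conventions deserve comment:

* **Unpaired versus paired.** "Student's t-test" is read literally as
  the unpaired equal-variance test; a paired mode (per-CpG pairing on
  jointly covered CpGs) is available via `mode = "paired"` since
  either reading is defensible.
* **BH family.** Adjustment is per pairwise comparison, not pooled
  across comparisons — each comparison is one experiment. Untestable
  windows are excluded before adjustment so they do not dilute it.
* **Degenerate windows.** Fully methylated versus fully unmethylated
  windows have zero variance in both groups; the t statistic diverges
  and the window is assigned p = 0 with a `zero_variance` flag rather
  than propagating `NaN`. Note that BH-adjusted q-values are *not* a
  fixed point of re-adjustment (step-up adjustment applied to its own
  output generally inflates it); the tests therefore verify the
  adjustment against an independently written step-up implementation
  and the true invariants (q ≥ p, q ≤ 1, sorted monotonicity,
  threshold consistency with the step-up rejection rule).

Thresholds used throughout, with their glyph conventions:
hypermethylated means **≥80%**, hypomethylated **≤20%** (both
inclusive); the blastocyst demethylation-protection screen is strictly
**>70%**; ES-cell gDMR hypermethylation loss is strictly **>75%**; the
somatic maintenance interval for gDMRs in blood is the closed interval
**[35, 65]%**.

## Gamete-specific regions and the imprinted-DMR taxonomy

`categorize_gamete_windows()` / `categorize_gamete_regions()` label
windows, CGIs and promoters as oocyte-specific (oocyte ≥80, sperm
≤20), sperm-specific, both-hyper, both-hypo or other. An imprinted-DMR
catalogue is classified by `classify_dmr()`:

1. a record hypermethylated in one gamete and hypomethylated in the
   other is a **germline DMR** (gDMR), maternal or paternal by the
   hypermethylated gamete;
2. a gDMR with blood methylation inside [35, 65]% is a somatically
   maintained **M-gDMR** / **P-gDMR**;
3. a maternal gDMR outside that interval whose catalogue entry is
   flagged placenta-maintained is a **placenta-specific M-gDMR** (the
   flag is catalogue metadata — no placenta methylome is inferred);
4. everything else is a **secondary DMR** (sDMR).

A gDMR with blood outside the interval and no placenta flag — a
combination the rule set does not otherwise cover — falls back to
M-gDMR/P-gDMR by gamete origin. `es_stability_summary()` counts
maintained gDMRs whose ES-cell mean exceeds 75% (hypermethylation-type
loss of imprint balance), and `persistence_comparison()` contrasts
blastocyst levels of gDMRs against oocyte-specific methylated CGIs —
the central retention-versus-dilution readout — with medians,
quartiles and a Mann–Whitney test, optionally splitting CGIs into
autosomal and X-linked (pooled blastocysts carry an excess of maternal
X).

## Repeats, VNTRs and demethylation protection

Repeat-family methylation (`family_methylation()`) pools CpGs over all
copies of a repeat name — not per-copy averages — so CpG-rich copies
weigh more, matching how family-level levels are usually reported.
The protection screen (`screen_windows_above()` at >70% in blastocyst,
then `protection_screen()`) ranks repeat names by the fraction of
their copies overlapping protected windows, excluding names with ≤100
genomic copies. Overlap everywhere means ≥1 bp intersection.

Variable-number tandem repeats enter either from Tandem Repeats Finder
`.dat` output (period ≤ 500 bp, alignment score ≥ 150, alignment
parameters 2, 5, 7 — `read_regions(..., "trf")` + `admit_vntrs()`) or,
for self-contained synthetic sequence, from
`detect_tandem_repeats_naive()`, a periodicity scan for exact tandem
arrays scored at 2 per array base (so a perfect array of *c* copies of
a *p*-mer scores *2pc*, consistent with a match weight of 2). The
naive detector exists so the synthetic pipeline needs no external
tool; real genomes should use parsed TRF output. Downstream,
`vntr_enrichment()` tests whether a region group (e.g. maternal gDMRs)
contains VNTRs more often than a background (all CGIs) by Pearson
chi-square without continuity correction — the uncorrected convention
reproduces the printed reference p-value for the 11/44 versus
1763/27718 table to within rounding — and `cgi_protection_by_vntr()`
tests whether VNTR-bearing CGIs hypermethylated in both gametes
preferentially stay >70% methylated in blastocysts.
`compare_vntr_features()` compares period size, copy number and
alignment score of the representative (highest-scoring) VNTR per CGI
between protected and unprotected groups by Mann–Whitney tests, which
are exact (full enumeration) for group sizes ≤20 without ties and
tie-corrected normal approximations otherwise.

## Gene bodies and expression

Promoters are TSS ± 1 kb per transcript (clipped at contig boundaries
rather than dropped); gene bodies are the merged transcribed span of a
gene minus its promoters, with genes under 300 bp excluded
(`define_promoters()`, `define_gene_bodies()`). For the
methylation–transcription relationship only genes with >5 kb of body
are joined to RPKM values floored at 0.01
(`genebody_expression_join()`, `load_expression()`); genes are called
transcriptionally active above a species boundary of log2(RPKM) = −5
(human oocytes) or 0 (mouse), the troughs of the respective bimodal
expression distributions. Cross-species gene-body classes reuse the
global ≥80/≤20 thresholds, as no gene-body-specific cutoff is defined;
this is configurable.

## The synthetic generator

`build_reference()` lays out a miniature genome — by default three
2-Mb chromosomes, the last named `chrX` — with background CpGs every
~100 bp and CpG-rich features (one CpG per 10 bp): 60 CGIs per
chromosome split across planted gamete categories (20 both-hypo, 16
oocyte-specific, 8 sperm-specific, 16 both-hyper), an imprinted-DMR
catalogue mirroring the published census (29 maintained M-gDMRs, 2
P-gDMRs, 15 placenta-specific M-gDMRs, 21 sDMRs), a VNTR-bearing
SVA-like repeat family and an Alu-like control family (120 and 150
copies genome-wide, both above the 100-copy ranking floor), and genes
of 8–16 kb whose oocyte gene-body methylation is coupled to a planted
active/inactive expression class. Baseline true methylation is 0.55
(oocyte), 0.85 (sperm), 0.80 (blood, ES), chosen to match the global
levels these cell types show; planted gamete-specific regions use
0.90/0.05.

`simulate_methylomes()` draws per-CpG read depth as Poisson (defaults
oocyte 7, sperm/blastocyst 24, blood/ES 16 — the study's coverage
structure scaled down) and methylated reads as Binomial(depth, p),
plus a bisulfite non-conversion floor (0.005), oocyte-only CpA-like
non-CpG methylation (~5.6%) and an unmethylated lambda-like spike
contig. The blastocyst truth is computed from the gametic truth by one
of two models:

* **human_retention** — maternal methylation multiplied by a retention
  factor (0.85), paternal by a residual (0.1), *uniformly*: maternal
  gDMRs receive no special maintenance. This is deliberate — the
  observed near-equality of gDMR and oocyte-specific CGI blastocyst
  medians is reproducible only if imprinted and non-imprinted maternal
  methylation persist alike. The retention factor 0.85 places planted
  oocyte-specific regions (gametic level 0.90) near 38% in the
  blastocyst, the scale the retained-methylome data show.
* **mouse_passive** — maternal methylation halved per replication
  round (default one round), with maternal gDMRs exempt (the imprint
  maintenance machinery protects the methylated allele); this yields
  the characteristic gap of ≥10 points between CGIs (~23%) and gDMRs
  (~46%).

Paternal gDMRs keep their sperm-derived methylation under both models.
On `chrX` the maternal contribution is weighted 3:1 (pooled
blastocysts: the single X of male embryos is maternal).
Demethylation-protected CpGs — the SVA-like family and VNTR-bearing
both-hyper CGIs — retain their gametic level in the blastocyst.

What the generator does **not** emulate: realistic chromosome
composition and repeat sequence, read-level error and mapping bias,
allele-resolved (SNP-phased) methylation, cell-type heterogeneity
within a blastocyst pool, and correlated noise between neighbouring
CpGs. Recovery tests passing on this generator therefore demonstrate
the correctness of the *computation* — window calling, classification
rules, screens — under binomial sampling noise, not robustness to
every artefact of real WGBS data.

One known tension at desk scale: because the miniature genome is
deliberately enriched for interesting CGI categories (VNTR-bearing
both-hyper CGIs for the protection analysis), the genome-wide VNTR
rate of its CGIs (~17%) sits closer to the maternal-gDMR rate (25%)
than the genome-wide rates in real data; the VNTR-enrichment test is
therefore demonstrated at the realistic sample sizes (44 versus
27,718) by exact planting, while the miniature genome demonstrates the
counting machinery.

## Numerical choices and problem sizes

All simulation entry points take an explicit seed, and identical
seed + parameters give byte-identical outputs. The test suite runs the
generator at 0.5–2 Mb per chromosome; the window-recovery calibration
uses 1,000 windows with 100 planted +50-point shifts at depth 30
(`simulate_window_shift_scenario()`, with planted blocks aligned to
window boundaries so that planted and pure-null windows are cleanly
separable in the overlapping-window geometry); DMR recovery uses the
full 67-record catalogue at depth 20. These sizes keep the complete
suite under a minute while leaving every planted effect far above the
sampling noise floor.

Tie-breaks and degenerate inputs: `select_top_vntr()` breaks score
ties by array length then leftmost position; duplicate homolog pairs
keep the first occurrence; duplicate positions in input files are an
error (they usually indicate concatenated files), whereas orphan
reverse-strand calls are retained and counted. Zero-coverage CpGs are
parsed and retained; filters drop them. Contingency tables with a zero
margin report cleanly instead of testing.

## Limitations

The package consumes methylation call summaries; alignment,
deduplication and methylation calling are upstream. RPKM tables are
consumed, not computed. GO enrichment and motif discovery are out of
scope (gene lists and VNTR consensus patterns are exported for
external tools). The placenta-specific DMR class depends on catalogue
metadata. X-linked analyses model only the pooled-blastocyst maternal
excess, not X inactivation.
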