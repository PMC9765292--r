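---
title: "Methods: genome-wide CRISPRi competence screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide CRISPRi competence screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispriscreen)
```

# The screening problem

CRISPR interference turns a pooled gRNA library plus an inducible dCas9 into
a conditional knockdown library covering a whole bacterial genome, including
essential genes. Grown competitively for a known number of generations, the
relative abundance of each guide reports the fitness cost of silencing its
target. Run under three conditions — no induction (mock), library induction
(Ci), and library plus competence induction (Ci+C) — the screen can separate
the *generic* cost of silencing a gene from the cost that appears only when
the competence program fires. Genes in the second class are candidate
competence regulators: silencing a competence *antagonist* lets the costly
competence program over-fire, depleting its guides specifically under
induction.

This package implements that computational pipeline end to end, plus two
companion readouts: a luciferase reporter screen that measures each
candidate guide's effect on the activity of the promoter of the competence
sigma-factor gene, and a transformation-rate calculation; hits from all
screens are profiled by COG functional category weighted by genome
composition.

# Library design

## Model

A candidate is every position, on either strand, where 20 nt are
immediately followed (3', same strand) by an NGG PAM. For a CDS on strand
$\sigma$, interference blocks transcription efficiently only when the
spacer base-pairs with the coding (nontemplate) strand, which is equivalent
to the protospacer lying on the strand opposite $\sigma$; that operational
form is what the designer applies, and the test suite verifies the
equivalence by explicit base-pairing. Candidates wholly outside annotated
features are intergenic and retained on both strands (promoter-blocking
interference is orientation-insensitive). A candidate overlapping features
but passing for none is rejected.

## Choices made where the design was open

* **Overlap rule.** A candidate is judged against every feature it overlaps
  by at least one protospacer base and is retained if it passes for any of
  them, recorded per feature. Published designs rarely state a rule for
  overlapping genes; the permissive choice maximizes coverage and keeps the
  per-gene index explicit.
* **rRNA/tRNA loci.** Whether structural-RNA genes should follow the CDS
  strand rule is undocumented in screens of this type (interference in them
  is dominated by multi-copy mapping anyway). Exposed as
  `rna_rule = c("cds", "both_strands")`, default `"cds"` (strand rule
  applies), on the argument that transcribed loci behave like CDSs for
  elongation blocking.
* **Multi-target spacers** (identical sequence at several loci) are kept in
  the library file — they exist physically — but flagged and excluded from
  every gene-level statistic, since their counts cannot be attributed to one
  locus.
* **Ambiguous bases.** Any `N` in spacer or PAM aborts the candidate: such
  an oligo cannot be synthesized as designed.
* **Coordinates.** Internally 0-based half-open on the + strand; GFF3 I/O
  converts. A guide's `start` is the genome coordinate of the protospacer's
  5'-most base *on its own strand*, so reading 23 nt 5'→3' from `start`
  always reproduces spacer+PAM — the invariant `extract_protospacer()`
  checks. Circular genomes include origin-spanning windows and features
  wrapping the origin are stored as two sub-intervals sharing a locus tag.
* **Determinism.** Libraries are sorted by (strand, start, spacer).
* Median guides-per-CDS uses `stats::median()` (midpoint for even counts)
  with zero-guide CDSs included; mean spacing is
  `round(genome length / n_guides)`.

# Counting and normalization

Spacers are recovered from reads by locating the upstream constant anchor
exactly, requiring the downstream anchor exactly 20 nt further on, and
retrying on the reverse-complemented read. Exact matching keeps counting
deterministic and unbiased; a `max_mismatch = 1` switch exists for lower
quality chemistry. Failures and off-library spacers count as unassigned, so
assigned + unassigned always equals reads processed.

Replicates are pooled by raw-count summation *before* normalization —
matching the screen protocol of pooling replicate reads per condition —
and pooled conditions are normalized by median ratios: with
$g_i$ the geometric mean of guide $i$ across samples (over guides nonzero
everywhere), size factor $s_j = \operatorname{median}_i (c_{ij}/g_i)$ and
normalized counts $c_{ij}/s_j$. One property deserves a note: scaling one
of $m$ samples by $k$ rescales *every* normalized column by the common
factor $k^{1/m}$ because the geometric-mean reference moves; all
between-sample ratios — the only quantities the downstream contrasts use —
are exactly invariant, and the test suite asserts that exact form.

# Gene-level depletion statistics

Per guide, $\mathrm{lfc} = \log_2\frac{n_t + c}{n_c + c}$ on normalized
counts with pseudocount $c = 1$ (bounds the statistic at zero counts).
Guides flagged multi-target, and guides targeting intergenic regions, are
excluded; ranks use average tie handling over the included guides.

The signed **gene score** is the median of the gene's guide lfc values — a
robust location summary chosen because the external tool that inspired this
layer does not document its plotted score; the definition is recorded in
the output header so downstream consumers are never guessing.

**Significance** uses robust rank aggregation rather than a parametric
guide-level test: with the gene's sorted rank percentiles
$u_{(1)} \le \dots \le u_{(k)}$,

$$\rho = \min_{j:\, u_{(j)} \le \alpha} P\!\left(\mathrm{Beta}(j,\,k-j+1) \le u_{(j)}\right),$$

i.e. how surprisingly small the $j$-th of $k$ uniform order statistics is,
restricted to the top $\alpha$ fraction ($\alpha = 0.25$ by default —
guides in the bottom three quarters carry no evidence and only add noise);
$\rho = 1$ when no percentile is below $\alpha$. Because $\rho$ depends on
percentiles only, it is invariant under any monotone transform of the lfc.
P-values come from re-drawing each gene's percentile slots without
replacement from the pooled percentiles (null shared across genes with the
same $k$; $(1 + \#\{\rho_{perm} \le \rho_{obs}\})/(N+1)$ with $N = 10{,}000$
by default), the enrichment tail repeats the construction on reversed
percentiles, and FDR is Benjamini–Hochberg within each tail. The
permutation seed is part of the contrast configuration and is written into
output headers.

# Residual outlier calling

Gene scores of the competence-induced contrast ($y$) are regressed on the
library-only contrast ($x$) by OLS (genes matched by inner join; genes in
only one contrast are reported, never imputed). Shared fitness effects —
essential genes are costly in both — put most genes on the line; the
competence-specific signal is the residual. Residuals are standardized as

$$r_i = \frac{e_i}{\hat\sigma\sqrt{1 - h_i}}, \qquad
h_i = \frac1n + \frac{(x_i - \bar x)^2}{\sum_j (x_j - \bar x)^2},$$

the internally studentized form. The leverage correction is statistical
convention (it is what R's own diagnostics compute); the plain
$e_i/\hat\sigma$ form is available via `residual_type = "simple"`, and at
genome scale ($n$ in the thousands, $h_i \approx 1/n$) the two are
indistinguishable. A numerically perfect fit returns all-zero residuals
rather than 0/0. Calls use strict cutoffs at $\pm 2.5$ (ties are neutral),
and `confirm_direct()` checks each call's matching tail in the direct
treatment-vs-treatment contrast at FDR $\le 0.05$.

# Reporter screen

Specific Lux activity is $\sum_t \mathrm{RLU}_t/\mathrm{OD600}_t$ over all
provided timepoints; an OD floor of 0.01 excludes near-blank early wells
where the ratio explodes (cultures start at OD 0.05, so the floor rarely
triggers), and no blank subtraction is applied by default because the assay
protocol does not describe one. Per gene, the evidence combines the mean
log2 fold change over the gene's *distinct* selected spacers (re-isolated
clones of the same spacer are averaged first — the screen counts guides,
not colonies) with the normalized count: distinct selected spacers divided
by the gene's library guide count, correcting the gene-size bias. The
antagonist call requires normalized count > 0.02 *and* mean log2FC > 0.5
(both strict; the 0.02 follows the primary description of the cutoff — a
footnoted 0.01 variant exists in the source literature, and the parameter
is exposed). The agonist class mirrors the rule at mean log2FC < −0.5; it
is an extension beyond the published antagonist cutoff and is identifiable
as such by its class label.

Transformation rates are
$(\mathrm{CFU}_{sel} \cdot d_{sel})/(\mathrm{CFU}_{tot} \cdot d_{tot})$;
zero selective colonies report `NA` with `detected = FALSE` ("not
detected"), zero total colonies are an error.

# COG profiles

Each gene carries at most one category (highest-scoring assignment,
computed externally and consumed as a table). A screen's profile is, per
category, $100 \cdot \text{hits}/\text{genome total}$ — weighting by genome
composition so a 20-gene category with 10 hits outranks a 200-gene category
with 20. Hits without an assignment appear in an explicit `unassigned`
bucket (percentage `NA`, never silently dropped); a combined
union-of-screens profile is always emitted.

# The synthetic world

`simulate_*` generate every input the pipeline consumes, with exported
truth. The stated world: ~24 guides per gene (Poisson), $G = 12$
generations of growth, 4 technical replicates, $10^7$ reads per replicate,
negative-binomial sequencing dispersion 0.01 (0 degrades to multinomial),
log-normal initial abundance spread $\sigma = 0.5$ (library cloning is
uneven at roughly that scale), guide-efficacy noise $\sigma_g = 0.02$ per
generation, luciferase noise 5%, and a genome of GC 0.36 with ~900-bp CDSs
on alternating strands separated by ~120-bp gaps — all typical
streptococcal magnitudes, fixed once.

Selection is parameterized per generation: guide $i$ of gene $g$ grows as
$a_i \, 2^{G(1 + s_g(\text{cond}) + \varepsilon_i)}$, so a planted
$s$ maps linearly onto an expected lfc of $G \cdot s$ against mock
(a competence-specific penalty of $-0.25$/generation is an lfc shift of
$-3$). The efficacy noise $\varepsilon_i$ is drawn once per guide and
applied in the dCas9-induced conditions only: it models how well that guide
silences its target, which is a property of the guide — absent without
dCas9, and identical between Ci and Ci+C. (Applying it in all conditions,
as a fully literal reading of the growth expression would, makes it cancel
from every contrast and turns the parameter into a no-op.) Because
selection acts on *relative* abundance, a penalty shared by every gene is
invisible; planted effects are only observable against a majority of
unaffected guides, which the generator's class fractions guarantee.

Planted classes: `neutral`; `essential` (equal cost in both induced
conditions — these land *on* the regression line and exercise the
separation between generic and competence-specific cost); and
`competence_costly` ($s_{Ci} \approx 0$, $s_{Ci+C} < 0$; reporter factor 2,
since silencing an antagonist derepresses the reporter promoter). An
optional `competence_required` class carries a fratricide-style penalty
($s_{Ci+C} < 0$ despite being an activator) to reproduce the
counterintuitive depletion of competence-activator operons that
immunity loss causes in the real screen, with reporter factor 0.5.

What the generator does **not** emulate: PCR chimeras and amplification
bias, PhiX spike-ins and unmappable reads beyond a composition residual,
position-dependent guide efficacy within a gene, polarity of interference
on downstream operon genes, bacteriocin killing dynamics in space, or
plate-colony sampling noise. A green recovery test therefore establishes
that the statistical pipeline recovers planted condition-specific fitness
effects at realistic depth and noise — not that any particular biological
screen is free of those artifacts.

# Numerical policies

* Pseudocount 1 applied after normalization; permutation p-values floored
  at $1/(N+1)$.
* Median-ratio normalization errors (with guidance) when no guide is
  nonzero in every sample; empty libraries error on spacing (explicit
  division-by-zero signal).
* Classification ties at exactly $\pm$cutoff are neutral in the residual
  screen; reporter cutoffs are strict inequalities.
* All randomized stages take explicit seeds, restore the caller's RNG
  state, and record the seed in file headers; identical configuration and
  seed reproduce every file byte-identically.
* `run_pipeline()` derives stage seeds from the master seed, writes a
  manifest with a configuration hash, and is the package's one-command
  demonstration; `scripts/acceptance.R` wraps it.

# Known limitations

The RRA permutation null is shared across genes with equal guide counts,
which is what makes genome-scale permutation affordable but induces weak
dependence between their p-values (marginally they remain uniform; the
test suite checks Kolmogorov–Smirnov distance on a neutral simulation).
The designer's duplicate detection is exact-sequence only — near-identical
spacers (one mismatch) are not collapsed, mirroring the screen's own
analysis choice. Reporter scoring sums whatever timepoints are provided;
assays of different durations are comparable only through the fold change
against a reference measured on the same schedule.
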