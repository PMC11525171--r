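---
title: "Integrative prioritization of GWAS risk variants: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative prioritization of GWAS risk variants: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vartier)
```

## The problem

Genome-wide association studies identify risk loci, but linkage
disequilibrium (LD) leaves the functional variant at each locus — and the
gene it regulates — unresolved. `vartier` implements an integrative
prioritization scheme: every tested variant receives a small integer score
(0 = no hit, 1 = hit, 2 = strong hit) from each of several orthogonal
annotation layers (reporter-assay allelic activity, statistical
fine-mapping, chromatin state, open chromatin, CTCF binding, long-range
chromatin contacts, predicted 3D-structure disruption, and
expression-based Mendelian randomization in normal and tumor tissue).
Per-layer scores are collapsed across cell lines, summed, and the summed
scores are banded into tiers. Tier 1 variants then nominate effector
genes wherever at least two independent gene-level evidence sources
agree.

## Locus definition and variant selection

Risk loci are defined by greedy clumping: variants with association
$P < 5\times10^{-8}$ are taken best-first, and a variant founds a new
locus only if it lies at least 500 kb from every accepted lead on its
chromosome. Each locus spans the lead $\pm 250$ kb. Variants enter
functional testing if either

* their $P$ is within three orders of magnitude of the lead's
  ($P \le 1000 \times P_\mathrm{lead}$, boundary inclusive — "within"
  conventionally includes the boundary, and the bound is configurable), or
* $-\log_{10} P > 0.7 \times (-\log_{10} P_\mathrm{lead})$ with
  $r^2 > 0.2$ to the lead and $P < 10^{-5}$ (a rescue rule for loci with
  extremely strong leads).

Credible sets collect variants with posterior inclusion probability
(PIP) $> 0.001$, in descending PIP order, until the cumulative PIP
reaches 0.95 (the crossing variant is included). PIP ties break by
variant id so the set is deterministic.

## Annotation scores

| term | 2 | 1 |
|---|---|---|
| MPRA (per cell line) | FDR $\le 10^{-3}$ | FDR $\le 0.05$ |
| fine-mapping | PIP $> 0.5$ | in a credible set |
| chromatin state | promoter/enhancer state | weak state |
| ATAC peak | overlap | — |
| CTCF peak | overlap | — |
| SMR (normal; tumor) | passing association | — |
| 3D disruption | $>25\%$ of $\pm100$ bp in top 10% | top 20% |
| chromatin contact | distal anchor holds a TSS | distal anchor in a gene body |

Decisions worth spelling out:

* **Fine-mapping score 1.** The scoring rule's literal wording ("PIP
  greater than zero") and its own gloss ("part of a credible set") differ:
  every variant has PIP numerically above zero, so the literal reading
  degenerates. We score 1 on credible-set membership;
  `scoring_config(finemap_literal_pip = TRUE)` restores the literal
  reading (with `pip > 0`) for comparison.
* **"Top 10%" is inclusive**: a score exactly at the 90th-percentile value
  counts. This is the conventional reading and matters for tied scores.
* **The disruption window** is $\pm100$ bp inclusive, and the denominator
  is the number of scored positions actually present in the window, so
  track gaps shrink the window instead of diluting the fraction. An empty
  window scores 0 with a warning, never an error.
* **TSS containment** is a point-in-interval test (`tss_pad`, default 0,
  widens it); gene-body overlap is ordinary interval intersection.
* **Coordinates.** Interval tracks are 0-based half-open; variants and
  TSS positions are 1-based points; the single bridge is
  `pos - 1 ∈ [start, end)`. Note `[100, 200)` therefore contains
  1-based positions 101..200 — position 200 is inside, 201 is not.
  Chromosome names are compared verbatim: silent "chr" normalization
  hides input errors.

## Consensus across cell lines

Cell-line-resolved terms (ATAC, CTCF, chromatin state, chromatin
contacts) are collapsed by a strict, level-wise majority: level
$L \in \{2, 1\}$ is retained iff strictly more than half of the cell
lines *with data for that assay* score $\ge L$; the consensus is the
highest retained level. Level-wise counting means a variant that is
strong in half the lines and weak in the rest still keeps a weak
consensus — the least lossy reading consistent with "present in more than
50% of the cell lines". Cell lines without data leave the denominator;
the panel roster is data-driven, never a fixed list (the assays in the
motivating study ran on overlapping but unequal cell-line sets).

ABC enhancer–gene scores and TF motif-match scores are continuous, so
their consensus is a binomial test: within each cell line an item is
flagged iff its best score reaches that cell line's 90th percentile
(computed over all items the cell line scored); with $k$ flags out of $n$
informative cell lines, the upper tail $P = \Pr(X \ge k)$,
$X \sim \mathrm{Bin}(n, 0.1)$, gives score 2 if $P < 0.01$, 1 if
$P < 0.05$. $k = 0$ short-circuits to 0 — no evidence cannot signal
enrichment. The reference population for the percentile (all scored
items per cell line) is a configuration choice; the null rate `p0`
(default 0.10) matches the flag definition.

## Tiers

Summed scores are ranked **globally** over all tested variants: the top
20% of positions are Tier 1, the bottom 50% Tier 3, the rest Tier 2.
Global ranking follows the scheme's definition ("top 20% of all
scores"); the alternative per-locus reading is available as
`run_pipeline(per_locus_tiers = TRUE)` for comparison — under per-locus
ranking every locus trivially owns a Tier 1 variant, which contradicts
the possibility of loci lacking Tier 1 variants. Boundary positions are
`ceiling(0.2 N)` and `N - floor(0.5 N)`; a score tied across a boundary
promotes its whole block to the better tier, so the tier is a function of
the score alone, order-independent, with $|T_1| \ge \lceil 0.2N \rceil$
and $|T_3| \le \lfloor 0.5N \rfloor$; any excess over the exact quantile
is tie-driven. With heavily tied score distributions (e.g. mostly-zero
backgrounds) the promotion rule can empty Tier 3 entirely; that is the
rule working as specified, not a defect.

## Gene nomination

Per locus, evidence from four sources — SMR normal, SMR tumor, ABC, and
chromatin contact onto a TSS — is unioned per gene across the locus's
Tier 1 variants; two or more distinct sources make a strong link.
Requiring the two sources on one single variant is stricter than the
per-locus union; the union matches nominating genes from a locus's Tier 1
set collectively. Fallbacks fire strictly in order and only if the
previous stage produced nothing at that locus: (1) gene-body chromatin
contacts of Tier 1 variants (weak, `microc_body`); (2) no Tier 1 variants
at all: rerun on Tier 2, all links weak (`tier2`); (3) a considered
variant inside a gene body (weak, `intronic` — without an exon table
"intronic" degrades to gene-body containment, and the link table records
which fallback applied). A locus can legitimately end with no link.

SMR records pass when `p_smr * n_genes(locus) < 0.05` (Bonferroni by the
number of genes at the locus) and `p_heidi > 0.05` (heterogeneity test
does not indicate linkage). This per-locus correction is deliberately a
separate operation from the global Bonferroni eQTL threshold
`eqtl_bonferroni_threshold(n_genes)` (e.g. $0.05/665 = 7.51\times10^{-5}$
for 665 genes): conflating the two changes results. Direction
concordance between reporter-assay and eQTL effects compares the signs of
the two effects after harmonizing both to the alternative allele
(`harmonize_effect` flips the eQTL beta when its effect allele is the
reference allele); a zero effect is non-concordant by definition, with a
warning.

## Permutation enrichment

The associated variant set (AVS) of a locus holds the lead plus all
members with $r^2 \ge 0.8$ **and** $D' \ge 0.8$. Enrichment of AVS
positions in a peak track is measured by the tally of AVS with at least
one overlapping member (the variant-set-enrichment convention;
`tally = "variants"` counts overlapping members instead). Null tallies
come from size-matched draws from a background variant pool — matching on
set size is a documented proxy for "same LD characteristics", which would
require genotypes the pipeline does not consume. The TF-count test
recounts bound TF sites in windows of the observed sizes centred on null
variants with association $P > 0.95$.

The empirical $P$ is the plain proportion of permutations with null
tally $\ge$ observed — deliberately without the $+1$ pseudocount, to
match the proportion definition; `smooth = TRUE` gives $(b+1)/(n+1)$ for
users who need a nonzero $P$. The default is 50,000 permutations; tests
calibrate at 500–2,000. Each call seeds R's RNG once from its `seed`
argument and draws sequentially, so a fixed seed gives bit-identical
null tallies; per-permutation substreams (useful for parallel execution)
are not implemented. Each permutation makes one global
without-replacement draw split into per-AVS groups, which is exchangeable
with the observed construction and hence calibration-exact.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` writes real files in the declared formats (BED,
BEDPE-like, TSV) so every test exercises the I/O paths. Its stated world:
10 loci of 40 candidate variants (the motivating study tested a median of
39 variants per locus), six chromatin cell lines, five chromatin-contact
lines, three reporter-assay lines, three genes per locus; leads at
$-\log_{10}P \sim U(9, 15)$ with members 0.2–3.5 orders of magnitude
above the lead so most qualify for testing; $r^2$ decays exponentially
with distance (scale 25 kb) with jitter and $D' \ge r$ — sufficient for
the selection and AVS rules without simulating genotypes. One causal
variant is planted per selected locus (PIP mass must concentrate on a
single variant for the strong fine-mapping score to be attainable — the
generator errors if asked for more causals than loci). Each supporting
annotation is planted independently with probability `signal_strength`
on causal variants and `background_rate` elsewhere; a planted annotation
is emitted consistently across the relevant cell-line panel.

Deterministic recovery at the limit (`signal_strength = 1`,
`background_rate = 0`: every causal variant reaches the maximal total of
26 = 3 MPRA lines × 2 + 10 terms × 2, every non-causal variant totals 0)
required two stylizations: variants sit on a ≥1.1 kb lattice so planted
peaks, state segments and contact anchors never leak onto a neighbour;
and the disruption track uses a fixed 21-position per-window pattern (16
low values, five at exactly 0.9) whose windows sit below the $>25\%$
exceedance rule for any global threshold the planted highs induce. Real
data have none of this regularity — a green recovery test establishes
that the scoring machinery is faithful to its rules, not that the rules
are powerful on real epigenomes. The generator also does not emulate real
human LD panels, allele frequencies, overlapping loci on multiple
chromosomes, or assay-specific noise; the ABC/TF score tables carry
uniform filler items only so that the 90th-percentile flag has a
realistic reference distribution.

## Numerical choices

* Quantiles use R's default type-7 interpolation; all threshold
  comparisons at quantiles are inclusive (`>=`).
* The 3-OOM selection boundary is compared with a $10^{-12}$ relative
  tolerance so the inclusive boundary survives binary rounding.
* Ties: PIP ties break by variant id; tier ties promote; lead-P ties in
  clumping break by variant id; all outputs are sorted with stable radix
  ordering. Fixed inputs give byte-identical outputs.
* Empty inputs are legitimate everywhere downstream of locus definition
  (empty credible set, zero links, empty tracks score 0); only an empty
  GWAS qualifying set aborts the pipeline, by design.

## Known limitations

* Scores are unweighted sums; no learned combination or per-ancestry
  stratification.
* The intronic fallback cannot distinguish exonic from intronic
  positions without an exon table.
* LD matching in the enrichment null is by set size only.
* The CLI exposes `simulate`, `define-loci`, `select-variants`,
  `credible-sets`, `run-all`, `enrich` and `report`; the scoring,
  tiering and linking stages run inside `run-all` and are available as R
  functions with TSV intermediates rather than as separate subcommands.
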