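---
title: "Methods: screen statistics and m6A site analysis in plasmascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen statistics and m6A site analysis in plasmascreen}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmascreen)
library(dplyr)
```

plasmascreen implements the computational arm of an RNA-binding-protein
(RBP) targeted CRISPR knockout screen for plasma-cell (CD138+)
accumulation, together with the companion m6A-eCLIP crosslink-site
analysis. This vignette is the package's account of the underlying
models, the tunable parameters, the numerical choices, and what the
synthetic-data tests do and do not establish about real data.

## The screen design and its data

Activated B cells carrying a pooled sgRNA library are sampled at day 4
and day 8 of culture (the *expansion* comparison, capturing
proliferation and survival effects), and the day-8 culture is sorted
into CD138− and CD138+ fractions (the *accumulation* comparison,
capturing effects on plasma-cell emergence). The library encodes 10
sgRNAs per gene against 1213 RBPs and 72 positive-control genes, plus
500 non-targeting (NT) control guides — 13,350 guides in all, with the
plasmid pool tightly distributed (>98.8% of guides within a 16-fold
abundance range).

Reads carry the 19-nt protospacer immediately 5' of the constant
scaffold `GTTTAAGAGCTAT`. Quantification locates the first occurrence
of that anchor in each read, takes the 19 preceding bases, and assigns
them to a guide by exact string equality — zero mismatches, no
alignment. Reads with no anchor, fewer than 19 preceding bases, an `N`
in the extracted 19-mer, or a 19-mer absent from the library are left
unassigned; each read counts toward at most one guide. First-occurrence
anchoring is our convention for the rare reads in which the anchor
appears twice; it is deterministic and matches the single-pass
trimming the design implies.

## Screen inference

The inference chain is NT-anchored throughout: the non-targeting guides
are the designated null set, and every null quantity is estimated from
them.

**Normalization.** Size factors are median-of-ratios restricted to NT
guides: for each NT guide with a nonzero geometric mean across samples,
the ratio of its count to that geometric mean is formed, and the
per-sample factor is the median ratio. Restricting to NT guides keeps
true-positive depletion or enrichment of targeting guides from biasing
the factors. At least 20 usable NT guides are required (configurable).

**Mean-variance null.** For a sample pair, each NT guide contributes a
pair mean $\mu = (x_1 + x_2)/2$ and a paired variance proxy
$v = (x_1 - x_2)^2/2$ of normalized counts. Guides are grouped into
equal-occupancy bins of $\mu$ (up to 20 bins, at least 5 guides each)
and $\log_2\max(\bar v - \bar\mu, \text{floor})$ is regressed on
$\log_2\bar\mu$, giving the null variance model
$\sigma^2(\mu) = \mu + k\,\mu^b$ — Poisson sampling plus a power-law
overdispersion term, the standard pooled-screen form. The floor
(default 0.01) keeps the regression defined when the data are
essentially Poisson; the paired proxy works without replicates, which
is what the single-pass screen design provides.

**sgRNA tests.** Per guide, the LFC is
$\log_2\big((t + c_0)/(c + c_0)\big)$ on normalized counts with
pseudocount $c_0 = 0.5$ (symmetric, conventional). Enrichment and
depletion tails are taken under a negative binomial with mean equal to
the normalized control count (floored at the pseudocount) and variance
from the model, collapsing to exact Poisson tails when the modelled
variance does not exceed the mean:
$p_\text{enrich} = P(X \ge \lfloor t \rceil)$,
$p_\text{deplete} = P(X \le \lfloor t \rceil)$. Guides are ranked
ascending by p within each direction, ties broken by decreasing |LFC|
then guide id so that all downstream ranks are deterministic.

**Gene scores: alpha-RRA.** Guides with a direction p below
`alpha_select` (default 0.05, matching the significance convention used
throughout) are *selected*. With $m$ guides for a gene and selected
normalized ranks $u_{(1)} \le \dots \le u_{(j)}$ among the $N$ ranked
guides, the gene score is

$$\rho = \min_{k \le j} P\!\big(\mathrm{Beta}(k,\, m-k+1) \le u_{(k)}\big),$$

the probability that the $k$-th best of $m$ uniform ranks would be this
extreme; a gene with no selected guide scores 1. Gene p-values come
from permutation: the sgRNA-to-gene allocation is randomized by drawing
random sets of $m$ targeting guides, `n_permutations` times (default
10,000) per gene-size class, with draws pooled across genes of equal
size; $p = (1 + \#\{\rho_\text{null} \le \rho\}) / (1 + n)$, which
floors p at $1/(n+1)$. Both directions are scored independently,
Benjamini–Hochberg adjustment is applied within direction, and each
gene keeps its better direction — smaller permutation p, then smaller
RRA score, then positive; the final tie-break is arbitrary but
deterministic and, in practice, unreachable.

**Gene LFC, z, and the hit rule.** The gene LFC is the median LFC of
its guides whose sign matches the chosen direction, and the z-score
expresses that median in standard deviations of the NT LFC
distribution. The reference distribution is guide-level NT LFCs by
default; because the median of 10 guides is less dispersed than a
single guide, these z-scores are conservative in magnitude for null
genes. A pseudo-gene reference (median LFCs of random groups of 10 NT
guides) is available via `nt_reference = "pseudo_gene"` for exact
calibration. A gene is a hit when $|z| \ge 2$ (boundary inclusive) and
FDR-adjusted p < 0.05.

**Two-screen classification.** With accumulation LFC defined as CD138+
over CD138−, knocking out a differentiation *promoter* depletes its
guides from the CD138+ gate, so accumulation-only hits with
$z \le -2$ are classed `accumulation_promote` and those with
$z \ge +2$ `accumulation_limit`; genes hitting only the expansion
screen are `expansion_only`, genes hitting both are `both`. The axis
orientation is inferred from the biology (guides against known
differentiation drivers must deplete from CD138+); `flip_sign` inverts
it if a dataset uses the opposite ratio.

## m6A crosslink-site analysis

**Hierarchical feature assignment.** Transcript models are parsed from
an Ensembl-dialect GTF; UTRs are derived as exonic sequence outside the
CDS (5' vs 3' by strand) and introns as inter-exon gaps. A site is
matched against all same-strand feature intervals it overlaps
(strandedness is required because eCLIP is strand-specific; clusters
are matched by any overlap), and candidates are ordered
lexicographically: protein-coding isoforms first; then transcript
support level (TSL) < 4 — an absent TSL is conservatively treated as
not < 4; then the feature hierarchy CDS > 3'UTR > 5'UTR > intron >
non-coding exon > non-coding intron; then lower TSL (absent last), then
CCDS-flagged, and finally transcript id ascending so the order is
total and input-order invariant. The feature hierarchy is applied
before the fine-grained confidence tie-break: confidence only
disambiguates isoforms offering the same feature class, it never
promotes a lower-ranked feature.

**Motif z-scores.** The 5 bases centred on each site (position −2..+2,
the only symmetric reading), reverse-complemented on minus-strand
sites, form the observed k-mer set. Control sets — 100 by default —
redraw each site uniformly by length within the pooled same-feature
territory of the genes that contain at least one observed site, so
every control set reproduces the observed feature distribution
exactly. Territory is the per-gene reduced union over isoforms;
sampling is length-weighted uniform, the least-informative choice given
that the background is defined only as "randomised across genes".
Control sites keep their by-construction feature label, preserving the
tally per set; a feature with no territory among site-bearing genes
falls back to all genes (logged), and intergenic observed sites — not a
case the feature-matched background defines — are redrawn uniformly
over the genome. Per 5-mer,
$z = (\text{obs} - \overline{\text{ctrl}})/\mathrm{sd}(\text{ctrl})$
with the sample (n−1) sd over sets; a zero sd yields z = 0 when the
observed count equals the control mean and a flagged ±Inf sentinel
otherwise. An alternative preserving per-gene site counts (rather than
only feature proportions) would be stricter; feature-proportion
preservation is what the stated background requires, so it is the
default and only mode.

**Metagene profiles.** One representative transcript per gene — the
longest total CDS, ties by transcript id, so no gene is double-counted —
contributes its genomic CDS span scaled into 100 body bins, flanked by
1 kb of fixed 10-bp bins on each side, oriented 5'→3'. A bin scores 1
if any same-strand cluster overlaps it (the maximum of an indicator,
zeros included), and the profile is the per-bin mean across genes: the
fraction of genes with a cluster in that bin, bounded in [0, 1]. Body
bin count and flank bin width are configurable; the defaults are the
common scale-regions settings of coverage-matrix tools.

## The synthetic data generator

The generator emulates the statistical structure the analysis assumes,
at desk scale:

* **Library**: the stated composition (1213 + 72 genes × 10 guides +
  500 NT = 13,350) with random distinct 19-mers.
* **Plasmid distribution**: log-normal with `plasmid_sigma = 0.75`
  log2 units. The design QC requires at least 98.8% of guides within a
  16-fold range; 0.75 gives 99.2% central mass, so a realized library
  clears the bound at any seed (a sigma putting the expectation exactly
  at 98.8% would fail half of realizations). The QC statistic is
  measured as the densest 16-fold window, matching "within *a* 16-fold
  range".
* **Counts**: negative binomial around `depth × abundance` with a
  single dispersion (default 0.05, a moderate pooled-screen value; the
  fitted mean-variance model recovers it). Day 4 and day 8 share one
  baseline per guide — the paired structure the variance proxy
  assumes. The day-8 expectation multiplies effect carriers by
  $2^{\text{expansion effect}}$; CD138− inherits the day-8 expectation
  and CD138+ multiplies it by $2^{\text{accumulation effect}}$, so the
  planted accumulation LFC equals the effect exactly. Default depth is
  500 reads per guide, a deliberate scale-down of the screen's >1000×
  representation that leaves all calibration and power properties
  testable in seconds.
* **Reads**: 50-nt reads with a 0–6-nt random prefix, the protospacer,
  the scaffold anchor, and random suffix, shuffled — the exact inverse
  of extraction, so counting round-trips exactly.
* **Toy transcriptomes**: 2–5-exon genes on both strands, coding genes
  with UTRs and in-frame CDS, varying TSL and CCDS flags, non-coding
  genes, serialized to an Ensembl-dialect GTF that the parser
  round-trips. Chromosome sequences are uniform random ACGT; no
  sequence composition structure is needed for any tested property.
* **Planted sites**: a configurable fraction of sites gets the genome
  edited so the centred 5-mer spells a DRACH instance (GGACT) in
  transcript orientation; a configurable fraction is placed within
  100 nt of stop codons; clusters are ±20-nt windows. Overlapping edit
  windows are resampled so planted motifs never corrupt each other.

What passing these tests shows — and does not. The synthetic screens
have exchangeable guides, a single dispersion, no PCR jackpotting, no
guide-efficiency variation beyond penetrance, and no correlation
between populations beyond the shared baseline; real screens violate
all of these to some degree, so passing null calibration here bounds
algorithmic false positives, not biological ones. Likewise the toy
transcriptome has no overlapping genes (a separate hand-built locus
exercises the hierarchy) and uniform base composition, so motif power
on it does not predict power against real UTR sequence bias.

## Problem sizes and determinism

Test and verification runs use 5,000-guide screens (450 genes plus 500
NT) at depth 500 with 10,000 permutations, 30–50-gene toy
transcriptomes with 150–200 sites, and 100 control sets — sizes chosen
so the full suite completes in well under a minute per property while
leaving each check statistically sharp. All stochastic steps flow from
explicit integer seeds; identical configuration and seed give
byte-identical outputs everywhere, including the control-site sets and
FASTQ simulation.

## Known limitations

* The screen inference follows the standard alpha-RRA approach to
  pooled-screen scoring (the MAGeCK family of methods) but is an
  independent implementation; permutation counts, normalization
  details and tie-breaking differ between implementations, so
  bit-identical agreement with other tools on real data is not
  expected.
* Degenerate direction ties (equal permutation p and RRA score in both
  directions) are resolved deterministically but arbitrarily.
* The NB tail uses a continuous-variance plug-in with a rounded
  treatment count; for very low means the discreteness of the rounding
  dominates the tail accuracy.
* Intergenic site backgrounds are genome-uniform, which is only a
  placeholder; the feature-matched background is defined for genic
  sites.
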