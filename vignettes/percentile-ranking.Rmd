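---
title: "Percentile-ranking analysis of bottlenecked in vivo CRISPRa screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percentile-ranking analysis of bottlenecked in vivo CRISPRa screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prscreen)
```

## The problem

In a pooled in vivo CRISPR activation (CRISPRa) screen read out through a
spontaneous-metastasis assay, tumor cells carrying a guide library are
injected subcutaneously, a primary tumor grows, and the few clones that
complete the metastatic cascade are recovered from the lungs. The
guide-level readout is dominated by a severe clonal bottleneck: of the
hundreds of thousands of injected cells, only a handful of clones seed each
lung, so per-animal count vectors are extremely sparse and heavy-tailed,
and the identity of the surviving clones varies from animal to animal.

Conventional screen statistics that average over replicates are poorly
suited to this regime — a genuine driver may dominate one lung completely
and be absent from the next. The percentile-ranking approach implemented
here asks a different question: *in how many animals does a guide reach the
top of that animal's own abundance distribution?* Rank aggregation across
animals, rather than averaging of abundances, is what gives the statistic
its robustness to single-animal jackpots.

## The statistic

Counts are first filtered on the two "0-hour" baseline replicates (the
transduced population sampled at injection time): a guide is kept only if
every baseline replicate carries at least 30 reads for it — guides with
exactly 30 reads survive, since only counts *below* the threshold are
removed. Samples are then total-normalized: each sample's counts are
divided by its size factor, the sample total over the grand mean of all
sample totals, so every normalized column sums to the grand mean depth.
Guides with no reads in any sample are dropped after normalization.

For each guide the package reports, over the lung samples:

* **n** (`n_present`) — the number of animals in which the guide is
  detected (nonzero normalized count);
* **m** (`count_mean`) — the mean normalized count over those n animals;
* **SD** — the sample standard deviation over the same animals (n − 1
  denominator; 0 by convention when n = 1);
* **SEM** = SD / √n;
* **z** = (m − mean of the guide's normalized baseline counts) / SEM,
  reported as missing when n ≤ 1 or SD = 0;
* **n_NEP** — the number of animals in which the guide lies within the
  98th percentile of that animal's guide abundances.

Membership is decided per animal: the 0.98 quantile *T* of the normalized
abundances of the guides *detected in that animal* is computed by linear
interpolation between sorted order statistics (R's `quantile` type 7), and
a detected guide is a member iff its abundance is ≥ *T* — ties at the
threshold are included, and a guide with zero reads in an animal is never a
member there. Guides are ranked by descending n_NEP, ties broken by
descending z (missing z below any finite z), then by guide id so the
ranking is deterministic. The hit filter is strict: a guide is a hit iff
n_NEP/n_mice > 30%, so at a 40-animal cohort 12/40 (exactly 30%) fails and
13/40 (32.5%) passes.

Gene aggregation is reporting, not testing: guides of one gene target
different transcription start sites and are deliberately analysed
individually; a gene inherits its best guide's statistics and is a hit iff
any of its guides is. Nontargeting controls are pooled under the reserved
`"non-targeting"` label and listed separately.

## Design choices in the open points

**Quantile convention.** "98th percentile" does not pin an interpolation
rule. The package declares linear interpolation between order statistics
(type 7) in `rank_params()` and records it in provenance; on 100 distinct
values 1..100 the threshold is 98.02 and exactly the top two values are
members.

**Zeros and the percentile pool.** The per-animal quantile is computed over
detected guides only. Bottlenecked lungs carry reads for well under 1% of
the library; pooling thousands of structural zeros would drive the 98th
percentile to zero and mark every detected guide a member, destroying the
statistic. A zero-read guide contributes no reads to the animal's relative
abundances, so it is excluded from the pool and from membership. A
sensitivity flag (`include_zeros` in `rank_params()`) restores the pooled
behavior for comparison.

**z-score reading.** "Normalized count minus the mean of the control
counts, over the group SEM" is read with m as the normalized count, the
guide's own mean normalized 0-hour value as the control mean, and the SEM
over the animals where the guide is present as the group SEM — the only
reading that reuses the already-defined m and SEM. The presence count n
uses nonzero normalized values, which coincides with nonzero raw reads
under positive size factors.

**Degenerate guides.** n = 1 gives SD = 0 and an undefined z; so does a
guide with identical values in all animals. Undefined z sorts below every
finite z, and a final lexicographic tie-break keeps the output stable
across platforms.

## The simulator

`simulate_screen()` generates the full study design so that every stage of
the analysis can be verified against ground truth:

1. **Library** — `n_genes` × `guides_per_gene` targeting guides plus
   `n_controls` nontargeting controls (defaults 2195 × 5 + 250 = 11,225),
   protospacers drawn uniformly over fixed-length DNA and
   rejection-sampled to uniqueness.
2. **Plasmid representation** — log-normal abundance per guide
   (`plasmid_lognormal_sigma`, default 0.5, a typical post-amplification
   skew). Transduction and antibiotic selection are absorbed here: they
   precede the 0-hour reference and are not separately identifiable.
3. **Baseline** — two replicates, each an independent multinomial draw at
   `baseline_depth`; column sums equal the depth exactly.
4. **Each lung** — three conditionally multinomial stages: injection
   (`injection_cells`, default 5.5e5, a 50× library coverage), metastatic
   seeding of `met_bottleneck` clones with per-guide weight
   `injected × (1 + s)`, and outgrowth in which every seeded clone's mass
   is scaled by an independent lognormal factor
   (`clone_expansion_sigma`, default 1) before `lung_depth` reads are
   drawn. Selection acts at seeding — the assay reads out lung
   colonization against day 0, not primary-tumor growth.

Per-animal independence with exact reproducibility comes from a substream
scheme: the master seed seeds the RNG once and a vector of 31-bit
substream seeds is drawn, one per stage and animal.

Defaults are the study conditions. `met_bottleneck = 100` produces the
extreme sparsity the statistic exploits (≤ 100 detected guides per lung
from an 11,225-guide library). The default driver advantage
`selection_s = 99` (a hundredfold seeding weight) encodes what the
observed hit strength implies: for a single guide to reach the top 2% of a
bottlenecked lung in a third of a cohort, its seeding probability must be
of the order of several percent per clone, i.e. roughly two orders of
magnitude above a neutral guide's ~1/11,225 × coverage share.

What the simulator does *not* model: PCR chimeras and sequencing errors,
cohort batch effects, tumor growth dynamics, censoring/ulceration, or
immune interactions. Passing recovery tests on synthetic screens therefore
demonstrates correctness of the statistical machinery under the stated
sampling model, not robustness to every artifact of real libraries.

### A structural property of the membership count

One simulator-derived fact is worth recording because it constrains what
any recovery experiment can show. With a bottleneck of *B* clones, a lung
detects at most *B* guides; for pool sizes between 51 and 151 the
type-7 98th percentile admits exactly the top two detected guides as
members. A 40-animal cohort therefore yields at most ~80 membership events,
which all strongly selected guides must share. Five equally strong drivers
can average no more than n_NEP = 16 each, and the allocation is
multinomial — so demanding four of five drivers simultaneously at
n_NEP ≥ 13 fails in an appreciable fraction of simulated cohorts no matter
how strong the selection, and persistent representation differences
between driver guides (plasmid skew) concentrate the membership events on
whichever driver is best represented. In real screens the effective number
of detected guides per lung is larger (background reads, larger effective
bottlenecks), which widens the membership tail. The recovery test suite
asserts both the attainable property (driver guides in the top 1% of the
ranking) and the stricter simultaneous-hit property, and the latter is
expected to fail under the bottleneck-100 conditions for the structural
reason above.

## Quantification

Reads are single-end with the protospacer at a fixed offset behind a known
primer/adapter prefix; `trim_read()` takes the `protospacer_length` bases
after the anchored prefix and `quantify_fastq()` counts exact matches —
no mismatches, no indels, forward orientation only, as a bespoke
sequencing primer fixes the geometry. The adapter is user-configurable
(`read_layout()`) rather than hard-coded, since amplicon designs differ;
an unanchored search is available behind a flag. Unmatched reads are
reported, never redistributed, and `matched + unmatched = total` always
holds. `emit_fastq()` writes synthetic reads (prefix + protospacer +
suffix, right-padded with `A` to 50 nt — padding sits 3′ of the
protospacer, so it can never affect matching) and is the quantifier's
round-trip oracle.

## Problem sizes in the test suite

The simulation-based suites run on a tenfold-scaled library — 215 genes ×
5 guides + 50 controls = 1,125 guides — with 40 animals, the default
injection size and bottleneck, and sequencing depths of 2×10^5 (baseline)
and 1×10^5 (lung), keeping baseline coverage near 180 reads/guide. Null
calibration uses 100 seeded neutral screens and compares control versus
targeting n_NEP distributions with a rank-sum test; driver recovery uses
25 seeded screens with five planted drivers. Library-composition checks
run at the full 11,225-guide scale, where generation takes about a second.

## Limitations

* The percentile statistic carries no error model; the z-score is a
  tie-break, not a calibrated test, and no gene-level p-values or FDR are
  produced — by design, matching the per-guide analysis philosophy.
* Total normalization assumes depth differences are compositionally
  neutral; with one clone occupying most of a lung this is wrong in the
  absolute sense but harmless here because membership is scale-invariant
  within each animal.
* The baseline filter interacts with library skew: at low baseline depth
  poorly represented guides are removed before they can ever be scored.
* `met_bottleneck` is not calibrated to the observed frequency of
  macroscopic metastases; users simulating specific designs should set it
  from their own colonization data.
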