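---
title: "Prioritizing candidate genes in severe spermatogenic failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing candidate genes in severe spermatogenic failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haystackr)
```

## The problem

The Sertoli cell-only (SCO) phenotype is a form of non-obstructive
azoospermia in which seminiferous tubules contain no germ cells at all.
It is genetically heterogeneous: in exome cohorts, most implicated genes
carry a qualifying loss-of-function (LoF) allele in a single patient, so
simple recurrence cannot separate causal genes from background. The
strategy implemented here is instead a cascade of orthogonal filters:
keep only variants that plausibly destroy the protein, are essentially
absent from the general population, are confidently called, sit in genes
expressed predominantly in testis, and — critically — are never seen as
LoF in men with intact spermatogenesis.

`haystackr` provides that cascade with a complete audit trail, plus the
statistical and assay-level calculators that accompany this kind of
study: an allele-level LoF burden test against a reference population,
an inheritance-aware screen of known infertility genes, and calculators
for CRISPR growth-competition and dye-dilution proliferation readouts.

## The filtering cascade

A cohort is a variant table (one row per alternate allele, annotated
with gene, consequence and optional CADD score) plus a long table of
genotype calls (`GT`, `DP`, `AD`). Multi-allelic VCF records are split
before any filtering, because every threshold below is per allele.
Consequence terms are classified into `lof` — exactly stop-gained,
frameshift, splice-acceptor and splice-donor — `missense`, and `other`;
a synonym map absorbs annotation dialects, and unknown terms fall into
`other` rather than erroring.

The five stages, in fixed order:

1. **Effect and rarity.** Keep LoF variants with population MAF
   $\le$ 0.01. A variant absent from the frequency table is treated as
   novel (MAF 0); population databases list genuinely novel alleles by
   omission, so treating absence as missing data would discard exactly
   the variants of interest.
2. **Call quality.** A call survives if read depth $\ge$ 10, alternate
   depth $\ge$ 4 and variant allele fraction $\ge$ 40%, all inclusive.
   The VAF gate is applied to every genotype, not only heterozygotes —
   it is a confidence heuristic, not a genotype model.
3. **Genotype-stratified frequency.** Autosomal homozygotes tolerate
   MAF $\le$ 0.01; heterozygous and X-linked variants $\le$ 0.001,
   reflecting the different population frequencies compatible with a
   recessive versus dominant/hemizygous architecture.
4. **Testis-biased expression.** Keep genes whose testis expression is
   strictly above 50% of their maximum across all provided tissues
   (testis participates in the maximum, so a testis-maximal gene scores
   1). "Above" is read literally: a gene at exactly 0.5 fails. Genes
   missing from the expression table are removed with an explicit
   `no profile` reason rather than silently passed — conservative and
   auditable. The tissue denominator is whatever columns the input
   table provides; no fixed atlas is assumed.
5. **Control exclusion.** Remove any gene in which a control with
   intact spermatogenesis carries a LoF call. The control evidence must
   itself pass the stage-2 quality gate (a DP-5 control call is noise,
   not exculpatory evidence), but no MAF gate is applied: any credible
   LoF allele in a fertile man disqualifies the gene regardless of its
   frequency.

The audit records gene-level in/out counts per stage — counts are
monotone non-increasing and chained — and each removed gene with its
reason. Candidate genes are then summarized by recurrence: the number of
distinct patients carrying at least one qualifying variant, with
percentages of the candidate total.

All thresholds live in a single `filter_config()` object; nothing is
duplicated in command code. One known tension in the source material is
surfaced rather than resolved: the published variant table labels a MAF
of 0.0047 as "rare (MAF $\le$ 0.001)" while the methods state the 0.001
heterozygous cutoff. The cascade and the panel screen use the stated
cutoffs; a run with `filter_config(het_maf_max = 0.005)` shows the
sensitivity of results to that choice.

## The burden test

For a single gene, carriers are expanded to allele counts (a
heterozygote contributes one affected allele, a homozygote two, every
individual two in total for autosomes), giving a 2×2 table of affected
and unaffected alleles in cohort versus reference. The p-value is the
exact conditional two-sided Fisher test: with both margins fixed, sum
the hypergeometric point probabilities of all tables no more probable
than the observed one. The implementation enumerates the support with
`lchoose`-based log probabilities; a relative tolerance of $10^{-7}$ on
the point-probability comparison guards floating-point ties. Degenerate
margins return p = 1 by convention, flagged. Tests verify agreement with
an independent `dhyper`-based enumeration for every table with total
$N \le 60$ and with `stats::fisher.test` on random tables.

The odds-ratio interval is the Woolf logit interval,
$\exp(\log \mathrm{OR} \pm z \cdot \mathrm{SE})$ with
$\mathrm{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}$. Any zero cell triggers the
Haldane–Anscombe correction (+0.5 to all four cells) before both the
odds ratio and the interval — the standard companion to the Woolf
method. With single-carrier tables the interval is wide and the odds
ratio is dominated by the correction; the p-value, not the interval, is
the inferential quantity.

Allele basis: for the cohorts of interest both the allele-based
(2N) and individual-based constructions give p-values identical to well
below the printed precision (a regression test bounds the difference at
$5\times10^{-5}$); the package uses alleles, with an optional
`ref_allele_number` override because population databases can report
fewer than 2N called alleles at a site.

## The panel screen

Known infertility genes are screened per patient: a variant qualifies if
it is LoF, or missense with CADD $\ge$ 20 (missense without a CADD score
never qualifies, and is thereby logged out of the screen), and is rare
(MAF $\le$ 0.01 homozygous, $\le$ 0.001 heterozygous, missing MAF → 0).
Non-recessive genes are hit by any qualifying variant. Recessive genes
require a homozygous qualifying variant or a *likely*
compound-heterozygous state, implemented — phase being unknown in
exome singletons — as at least two distinct qualifying variants in the
same gene in the same patient. Hits carry their rationale (`lof`,
`missense_cadd`, `homozygous`, `compound_het`); ranking hits against
each other is deliberately out of scope, since no principled weighting
of a heterozygous missense hit against a LoF hit exists without
functional data.

## Assay calculators

**Growth competition.** Amplicon reads from an edited/wild-type cell
mixture are classified per read by the net signed indel length inside a
quantification window (default ±10 bp around the cut site, half-open,
0-based): no indel → wild type, net length ≡ 0 (mod 3) → in-frame,
otherwise frameshift. Substitution-only reads count as wild type: frame
is defined by indel length, and the three reported categories leave
substitutions no other home. Fold changes of class frequencies between
timepoints are reported as ratio plus nearest-integer fold. Production
input is pre-called indel tables; a naive global aligner (match 2,
mismatch −1, affine gaps: 6 for the first gapped base, 1 per additional
base) is bundled for building small fixtures only, and its event
positions can legitimately slide within homopolymers.

**Dye dilution.** Assuming median fluorescence intensity halves per
division, the division number is
$\log_2[(\mathrm{MFI}_{d0} - \mathrm{MFI}_{us}) /
(\mathrm{MFI}_{end} - \mathrm{MFI}_{us})]$
and the mean cycle duration is elapsed time over divisions. The
estimator is invariant to uniform gain rescaling of all three MFIs. A
final MFI at or below background is an error, not a zero. The published
downstream step from cycle prolongation to a "percent reduction in
proliferation" follows from no stated formula with a shared wild-type
baseline, so it is intentionally not implemented.

## Synthetic data and what passing tests mean

Because the patient exomes are access-restricted, every claim the test
suite makes is grounded in seeded generators with planted truth.

The cohort generator emulates the study conditions: 247 cases and 89
fertile controls by default, a gene universe (default 160 genes) in
which planted causal genes carry novel LoF variants passing every
filter; each decoy gene family violates exactly one designed filter
(common MAF, low call quality, heterozygous-MAF excess, low testis
fraction, or a quality-passing control LoF); background genes carry
missense/synonymous variants with a Beta(0.3, 30) MAF spectrum. Planted
recurrence is drawn from 1–4 patients with probabilities (0.90, 0.06,
0.03, 0.01), mirroring the long-tailed recurrence such cohorts show and
the observed ceiling of four. Depths are Poisson around 40×. Generators
are pure functions of their config: identical seeds give byte-identical
emitted files (minimal VCF 4.2, contigs 1–22 and X so X-linked logic is
exercised).

The competition generator grows classes exponentially,
$n_x(t) = p_x \cdot 2^{t/T_x}$, with a 1:1 wild-type:mutant mix whose
mutant pool splits 0.175/0.325 into in-frame/frameshift (roughly the
1:2 split typical of editing outcomes), class cycle times of 24, 25.7
and 27.9 h (wild type plus prolongations of the magnitude measured for
the NHL-domain mutant), sampling 20,000 reads multinomially per
timepoint at days 0, 3, 7, 14, 21. The dye generator applies
multiplicative log-normal noise to the background-subtracted
exponential decay; noiseless output inverts to the true cycle time at
machine precision.

What the generators do **not** emulate: real exome error profiles,
batch and capture-kit effects, annotation disagreement between
transcript sets, population stratification of allele frequencies, or
PCR/sequencing bias in amplicon read-outs. A green suite therefore
shows the filters implement their stated rules exactly and recover
planted structure; it does not certify performance on real cohorts.

Problem sizes used in the checks were chosen to keep full runs
comfortable on a laptop: the cascade property runs 20 seeded cohorts at
the default 247/89 scale; the exact-test oracle comparison enumerates
all 635,376 tables with $N \le 60$; dye recovery uses 200 replicates at
5% noise.

## Numerical choices and edge cases

* Inclusive thresholds throughout except the expression gate, which is
  strict; a call at DP 10 / AD 4 / VAF 0.40 passes, a gene at testis
  fraction exactly 0.5 fails.
* Missing data: absent MAF → 0 (novel); missing DP/AD → call fails
  quality; missing CADD → missense never qualifies in the panel screen;
  gene without expression profile → removed with reason.
* `fisher_two_sided` works in log space; the $10^{-7}$ relative
  tolerance makes the minimum-likelihood rule robust to ties such as
  perfectly symmetric tables.
* Ordering: all stage outputs and summaries are sorted, so results are
  invariant to input row order (tested by permutation).
* Seeds: every generator takes an explicit seed and touches the RNG
  only through it.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_prioritization_cohort(cohort_sim_config(seed = 7))
res <- run_cascade(sim$cases, sim$controls, sim$frequency, sim$expression)
res$audit
recurrence_histogram(res)

lof_burden_test(247, 1, 0, 125748, 1, 0)
frequency_fold_change(32.46, 2.53)
```

## Limitations

The cascade consumes annotations; it performs no consequence prediction
or transcript selection of its own, and gene-level collapsing uses the
most severe class across records. The burden test covers a single gene
(no multiple-testing machinery, by design). The panel screen reports
hits with rationale but does not classify variants clinically. The
upstream platform that produced the first filter's inputs in the
original study is unpublished; only the printed criteria are
implemented, so absolute gene counts from real data are not expected to
be reproduced, and the corresponding guarantees here are the
property-based ones above.
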