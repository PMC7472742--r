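---
title: "Mapping a sex-determining region from full-sib families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a sex-determining region from full-sib families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrmap)
```

## The inference problem

In species without sexual dimorphism or heteromorphic sex chromosomes,
the sex-determining region (SDR) cannot be mapped by contrasting
phenotyped males and females at the stage of interest: larvae cannot be
sexed at all. `sdrmap` implements a chain of inferences that substitutes
pedigree structure for phenotype. Its assumptions are those of a
single-locus XY system in a full-sib design:

* sex is determined by the genotype at a single locus inside a candidate
  interval on one linkage group; the sire is heterozygous (X/Y) across
  the markers spanning it;
* families are true full-sib families (verified by parentage testing,
  not assumed);
* marker order and physical positions come from an orthologous reference
  map (positions in Mbp; the species itself need not have an assembly);
* recombination within the marker panel is rare enough that an
  individual carries at most one paternal crossover there.

## Parentage by exclusion

A candidate parent is excluded at a marker when no combination of one of
its alleles with one allele of the other (known) parent reproduces the
offspring's genotype; missing calls never contribute. The default
`threshold = 1` mismatching marker is the strict exclusion principle.
Because one mismatch can also be a genotyping error, `exclusion_counts()`
exposes the threshold: raising it to 2 tolerates single-marker errors at
the cost of exclusion power. Pairs sharing no genotyped marker are
reported `"untestable"`, never `"compatible"`.

## Phasing and sex-group assignment

For each parent, every marker at which that parent is heterozygous can
reveal which of its two alleles an offspring received, if the other
parent's genotype makes the transmission unambiguous. `phase_family()`
seeds at the most informative marker (parent heterozygous, co-parent
homozygous, most offspring resolved), orients every other marker by
majority co-segregation with the seed partition, and smooths each
offspring's haplotype path: a switch of haplotype (candidate crossover)
is accepted only when at least `min_run` consecutive resolved markers
support the alternative. `min_run = 3` is the default throughout — the
shortest discordant run we treat as a real crossover rather than
genotyping noise; shorter blips are kept on the current haplotype.

`assign_sex_groups()` turns the phase into putative sex-groups:

* **paternal** (XY model): group = paternal haplotype carried across the
  SDR interval. The SDR allele, not the chromosome-wide majority,
  determines sex, so a recombinant is grouped by the haplotype it
  carries *at the interval*; if its crossover falls inside the interval
  the larva is unassignable and is dropped downstream (with a logged
  count).
* **maternal** (ZW model): same logic on the dam's haplotypes.
* **random** (negative control): a seeded label permutation over the
  paternally assignable larvae that preserves the paternal group sizes.
  A permutation, rather than i.i.d. coin flips, keeps the control's
  power comparable to the tested scenarios.

Group labels A/B are arbitrary (no phenotype anchors them); any
comparison with external labels must be invariant to the A/B swap.

## SDR refinement from recombinants

In families with phenotyped individuals, `build_consensus()` computes
the modal genotype per family, marker and sex; a marker is
sex-informative where the two modal genotypes are defined (at least one
non-missing call per sex) and differ, with ties marked uninformative.
`detect_recombinants()` scans each individual for maximal runs of
adjacent sex-informative markers at which it matches the *opposite*
sex's consensus. Missing ("ND") and uninformative markers neither
extend nor break a run — real genotype matrices have ND cells inside
otherwise clean runs — while a call matching neither consensus breaks
it; a run's length counts only informative discordant calls.

Each accepted run implies a crossover in the gap between the run and the
flanking concordant marker, and restricts the SDR to the concordant
side. The crossover's exact position inside that gap is unknowable, so
`refine_interval()` bounds the interval **conservatively at the outer
margin of the gap** (the outermost discordant marker's position): a
correctly inferred event can then never exclude the true locus. We
initially considered closing at the first concordant marker instead
(which yields a narrower, more optimistic interval) but rejected it:
when a crossover lands in the same inter-marker gap as the causal locus,
that convention excludes the truth — in simulation this occurred in
roughly one replicate in ten. Consensus is per family and events are
never pooled across families except through the final interval
intersection; an empty intersection signals inconsistent events
(phenotype or genotype error) rather than returning a guess.

## Differential expression

Expression input is a genes × samples matrix of non-negative integer
counts; genes with pooled count below `min_total = 10` are excluded and
reported as filtered. The default test in `test_de()` is an **exact
conditional negative-binomial test**: counts are scaled to the geometric
mean library size, a common NB dispersion is estimated by the median
method-of-moments across genes, and each gene's two group sums are
compared conditionally on their total, the two-sided p-value summing the
probability of every outcome no more likely than the observed one.
Significance follows the raw p-value at `alpha = 0.01` (Benjamini–
Hochberg FDR is reported alongside).

A simpler exact conditional *binomial* test (`method = "binomial"`) — a
pure library-size-share test on pooled counts — is also provided. It is
the no-dispersion limit of the default and we do **not** recommend it
for biological replicates: ignoring overdispersion understates the null
variance by a factor of roughly `1 + phi * mu`, and on a simulated NB
null with dispersion 0.05 its empirical type-I error at nominal 0.01
exceeds 0.3, while the NB-conditional default stays near 0.013. The
numerical evaluation of the conditional distribution is windowed to
±20 conditional standard deviations (truncation error < 1e-40) and
normalised within the window; observed-probability comparisons use a
1e-10 relative tolerance so that symmetric outcomes sum to exactly 1.

Sex-specific genes (`tag_sex_specific()`) satisfy an all-or-nothing
rule: count ≥ `min_expr` (default 1) in *every* sample of one group and
exactly 0 in every sample of the other. Transcript-level results
collapse to genes by minimum p-value, with exact ties broken by
lexicographic transcript id for determinism; transcripts missing from
the annotation pass through flagged unannotated.

## Relative abundance and scenario comparison

For linkage group *i*, `RA_i = DE_i G_t / (DE_t G_i)` compares the
linkage group's share of sex-biased genes with its share of all genes;
1 means no enrichment. Genes absent from the orthology map are counted
unmapped and excluded from `DE_t`, mirroring how unannotated contigs are
dropped before such tabulations. The weighted identity
`sum_i RA_i G_i / G_t = 1` (all-mapped case) is asserted on every
summary to 1e-12. Percentages on the SD linkage group are rounded to
integers and scenario ratios to one decimal, matching how such tables
are conventionally printed.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the target study design: 2 full-sib
families × 45 larvae; 12 SDR markers spanning 0.27–3.40 Mbp with the
causal interval at 0.96–1.85 Mbp; at most one crossover per meiosis at
rate 0.1 (the observed data show single recombinants in roughly one
individual in ten; no per-meiosis rate is published, so this is a
placeholder, not an estimate); a parentage panel of 6 markers with 4
alleles (the published panels have 3–4) and 3 candidate sires; 2000
genes over 23 linkage groups with 107 truly sex-biased genes, 48% of
them on the SD linkage group and 23 of them sex-specific; |log2FC| = 2;
NB dispersion 0.05 (a plausible biological-replicate value for full-sib
fish larvae); library sizes 5e5 ± 20%.

Specific generator choices worth knowing:

* The sire carries the classic sex-associated pattern (X haplotype
  allele 1, Y allele 2 at every marker — males "12", females "11" when
  the dam is homozygous). The dam's minor allele is **3**, distinct from
  the sire's alleles, at a `dam_het_prob` fraction of haplotype
  positions. With a purely biallelic design the dam's informative
  transmissions would coincide with the paternal ones (maternal
  resolution only at offspring homozygotes), making the phased maternal
  partition spuriously identical to the paternal one; a
  maternal-specific allele — the behaviour of the multi-allelic
  microsatellites that flank real SDR panels — restores the
  independence the ZW control scenario needs.
* Sex-specific genes are simulated with expectation exactly zero in one
  group (not thresholded low expression), so the all-or-nothing
  definition is exactly recoverable. With `effect_log2fc = 0` the truth
  labels are kept but **all** genes share one distribution — a pure
  null matrix for type-I error measurement.
* The parentage generator's default `informative = TRUE` redraws an
  unrelated candidate's genotypes until the realized panel excludes it
  for every offspring, emulating the fully informative panels reported
  in practice (both non-sires excluded for every larva). With plain
  population draws (`informative = FALSE`) roughly half of 6-marker ×
  4-allele panels leave some unrelated candidate compatible with some
  larva by chance; the truth metadata flags such low-power panels.
* Crossovers are placed uniformly over inter-marker gaps, at most one
  per meiosis; `planted_crossovers` lets tests position them
  deterministically.

Features of real data the generator does **not** emulate: genotyping
error, per-gene dispersion variation, GC/length biases, batch effects,
partially sexed families, and multi-generation pedigrees. Passing tests
therefore demonstrate the correctness of the inference chain under the
stated model, not robustness to those artefacts.

## Known limitations

* **Scenario leakage.** The maternal and random scenarios regroup the
  same samples, so chance imbalance of the true groups leaks genuine
  sex-biased signal into them — with a 4-fold effect, even a 60/40
  split of true groups across a scenario's two sides makes the
  best-expressed sex-biased genes significant. The discriminating
  statistics are the paternal scenario's larger *total* and its
  enrichment relative to the analytic null share, not a zero count in
  the controls; enrichment of the maternal scenario's genes on the SD
  linkage group can match or exceed the paternal percentage, as
  published scenario tables themselves show.
* **Consensus false runs.** Maternal haplotype variation can make a
  non-recombinant individual match the opposite sex's consensus over a
  run of markers, producing a spurious middle-of-chromosome event;
  `min_run = 3` suppresses most of these, and genuinely contradictory
  events abort interval refinement rather than silently narrowing it.
* **Dispersion is common, not gene-wise.** The DE test estimates one
  dispersion for all genes; strongly variable genes are
  anti-conservative relative to a gene-wise model. The empirical
  type-I error at alpha 0.01 on the default null is ~0.013.
* The maternal (ZW) scenario is only available where the dam is
  informative inside the SDR interval; larvae unresolvable there are
  dropped with a logged count.

## Problem sizes in the test suite

The suite simulates at the design scale where the property demands it
(45-larva families for parentage and assignment; a 2000-gene null and
a 2000-gene powered matrix at n = 8 per group for DE calibration; 200
replicates for relative-abundance argmax recovery; 25 randomized small
families for the brute-force equivalence of recombinant detection) and
at reduced scale (300–800 genes, 4–8 linkage groups) for the remaining
unit checks, keeping the default run around twenty seconds.
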