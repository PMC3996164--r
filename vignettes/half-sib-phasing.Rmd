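---
title: "Half-sib phasing from opposing homozygotes: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-sib phasing from opposing homozygotes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibphase)
```

## The problem

In livestock breeding, SNP array genotypes are routinely collected on groups
of paternal half-sibs: many offspring of one sire, each out of a different,
usually unrelated and ungenotyped dam. Unphased genotypes (0/1/2 counts of an
arbitrary allele) hide which allele each offspring inherited from the sire.
Recovering that information — the *paternal haplotype* and the block structure
of sire strands it is built from — enables detection of the sire's
recombination events, imputation of an ungenotyped sire, phasing of every
offspring, and quality control of pedigrees.

The key observation is the **opposing homozygote**: if one half-sib is
homozygous 0 and another homozygous 2 at the same biallelic marker, the two
paternal alleles differ, so the sire must be heterozygous there, and every
*homozygous* offspring's paternal allele at that marker is known exactly.
Such markers are called *informative*. Between two informative loci, a pair
of half-sibs whose four homozygous codes sum to 2 or 6 opposes at exactly one
of the loci, which implies a recombination in one of the two meioses
(`pair_recombination()`).

## The block-partition walk

`block_partition()` reconstructs, for each offspring, which of the sire's two
strands (arbitrarily labelled P and M per chromosome) each chromosome segment
came from.

1. **Seeding.** At the first informative locus, homozygous-0 offspring are
   labelled P, homozygous-2 offspring M, heterozygous or missing offspring
   unknown (U). The labels are arbitrary: every downstream statistic treats
   P/M as exchangeable.
2. **Forward memory vector (FMV).** The running per-offspring label is
   carried marker by marker. Non-informative markers inherit it unchanged.
3. **Orientation choice.** Each informative locus admits two complementary
   assignments of its homozygous offspring (which strand carries allele 0).
   The walk keeps the candidate whose cost — switches against the FMV plus
   the switches a greedy continuation would be forced into over the next
   `lookahead` informative loci (default 10) — is smaller. The lookahead
   matters: a purely local count will happily take a "free" orientation that
   strands the walk on the wrong side of a crossover it has not seen yet.
   Remaining ties go to the candidate agreeing with the most recently updated
   offspring label (the offspring with the shortest uninformative stretch is
   the least likely to have recombined in it), then deterministically to the
   orientation labelling 0-homozygotes P.
4. **Validation.** Genotyping errors masquerade as strand switches. Every
   implied switch is therefore checked against up to `window` (default 30)
   downstream informative loci at which the switching offspring is
   homozygous: `confirm` (default 3) loci assigning it the new strand accept
   the switch as a recombination event; `confirm` loci assigning the old
   strand — or exhaustion of the scan — reject it and flag the discordant
   genotype as a suspected error. Two details are load-bearing:
   * the scanning FMV only ever *fills in* unknown labels, never overwrites
     known ones, so other unvalidated switches cannot smuggle themselves into
     the evidence; and
   * the focal offspring is excluded from each scanned locus's orientation
     choice — its own pending switch must not vote for itself. Loci whose
     orientation is ambiguous without the focal offspring are skipped rather
     than counted as coin flips.
5. **Rejection leaves uncertainty.** A rejected switch keeps the old code at
   the flagged cell in the block matrix, but the running label becomes U:
   the offspring re-anchors at its next homozygous informative locus. If it
   re-anchors on the *opposite* strand (validated again), the change is
   recorded as a recombination event across the unknown gap. Keeping a hard
   old label instead turns one doubtful call into a systematically wrong
   voter, which at small family sizes can cascade into a whole-family label
   flip.
6. **Anchor correction.** When a switch is accepted but the *old* strand had
   fewer than `confirm` supporting loci since the offspring's previous block
   boundary, the old supporting cells (for example a mistyped genotype at the
   seed locus) are reclassified as suspected errors and the block is
   rewritten instead of recording an event.
7. **Output conventions.** Markers before the first informative locus take
   the seed assignment; markers strictly inside an accepted event's flanking
   interval are unknown — the crossover cannot be localised there, and these
   gaps are exactly the unassigned bands visible in block images at
   recombination break points. `fill_uncertain_codes()` later fills unknown
   runs whose flanks agree (and single-flank runs at chromosome ends when
   `end_fill = TRUE`); runs with disagreeing flanks are recombination gaps
   and stay unknown.

In families of ten or more offspring the walk additionally requires at least
two offspring in *each* homozygote class before treating a locus as
informative: with 1% genotyping errors and forty offspring, a lone opposing
homozygote is far more likely to be a mistyped genotype at a sire-homozygous
marker than evidence of sire heterozygosity, and such false loci would
otherwise mislabel half the family in one step. Small families cannot afford
the stricter rule, and single errors there are still caught by validation.

Setting `window = 0` disables validation and the uncertainty/anchor handling;
the walk then reduces to pure greedy switch minimisation, which on error-free
families reproduces the exhaustive minimum-switch solution (the test suite
checks this against a full enumeration oracle on small families).

## Sire imputation

For each marker and strand, the offspring assigned to that strand vote for
the strand's allele. The package's default (`method = "hom"`) lets only
offspring *homozygous* at the marker vote — their paternal allele is
unambiguous — and takes the rounded mean of the votes; a strand with no
homozygous voter, or an exactly tied vote, stays missing. The alternative
(`method = "mean"`) averages the raw genotype codes of all offspring on the
strand and thresholds the mean at 0.5 (clipping means above 1), which matches
a simple description of genotype averaging but mis-calls the allele wherever
the strand carries allele 0 and the dam-population frequency exceeds 0.5: the
strand mean is then roughly the dam allele frequency, which crosses the 0.5
threshold regardless of the sire's allele. Under uniform allele frequencies
this affects a substantial fraction of markers — enough that the averaging
rule cannot reach the near-perfect large-family sire accuracies that the
homozygote-vote rule attains; the homozygote vote is therefore the default,
and its yield (the fraction of markers where both strands can be imputed)
naturally reproduces the steep rise with family size, from roughly half the
markers in families of four towards all markers at forty.

Two consistency checks run on top of the vote: a strand whose voters contain
both homozygote codes is reported as low-confidence, and a locus that
opposing homozygotes prove sire-heterozygous but whose two imputed alleles
agree is reported as a conflict and set missing. The imputed sire genotype is
the sum of the two strand alleles where both are known.

## Phasing

`phase_family()` replaces each offspring's block code by the corresponding
sire strand allele (after gap filling), giving the paternal haplotype; the
maternal haplotype is the genotype minus the paternal allele. A difference
outside {0, 1} is impossible and marks a genotyping error or a wrong block;
the cell is left missing and reported. Wherever both alleles are known,
paternal + maternal equals the genotype by construction — the test suite
asserts this conservation on every simulation it runs.

## Evaluation metrics

All accuracy statistics respect the arbitrariness of strand labels:

* `r2_haplotypes()` — squared product-moment correlation between the
  concatenated predicted and true haplotype pair, maximised over the two
  pairings; positions missing in the prediction are omitted first.
* `block_r2()` — strands coded 0/1, unknown cells omitted, squared
  correlation over all retained family cells (a family shares one sire
  orientation; the square makes it relabelling-invariant).
* `switch_error_rate()` — relative-phase flips between adjacent usable
  heterozygous sites divided by (usable sites − 1); flip counting is
  orientation-free.
* `percent_het_phased()` / `percent_het_correct()` — yield and per-site
  concordance at truth-heterozygous sites, concordance after per-individual
  orientation matching.
* `random_phase_baseline()` — coin-flip phasing of heterozygous sites. Its
  expectation is governed by the heterozygous fraction *h* of the genotypes:
  homozygous sites are phased for free, so the haplotype correlation is
  roughly 1 − *h* and the baseline R² roughly (1 − *h*)². This makes the
  baseline a sensitive readout of the simulated allele-frequency spectrum.

## The simulator and what it does (not) emulate

`sim_population()` is a truth-tracked forward simulator of a livestock-style
design: founder haplotypes drawn independently at per-marker allele
frequencies, discrete generations of random mating (sires drawn uniformly,
dams without replacement), and a final generation of exact half-sib families,
with every paternal gamete's strand-of-origin vector and crossover positions
recorded. Crossover counts are Poisson with mean equal to the map length in
Morgans (Haldane, no interference) by default; a bounded-uniform count model
(uniform on 0..6) is available for high-density runtime-style datasets.
Genotyping errors rewrite a fixed fraction of cells to a uniformly chosen
different code. Everything is reproducible from one seed.

Default study conditions used by the acceptance script and the heavier tests,
chosen once:

* one chromosome of 500 cM with evenly spaced markers (1250 or 10 000: 2.5 or
  20 markers per cM);
* founder allele frequencies uniform on (0.3, 0.7). Commercial SNP panels
  are ascertained for common, segregating variants, and simulated livestock
  populations are typically initialised near frequency 0.5; the resulting
  offspring heterozygosity (≈0.45 after ten generations of drift) also
  reproduces the published random-phasing baseline, which pins down the
  spectrum via the (1 − *h*)² relationship above;
* 10 generations of random mating with 20 sires and 800 dams per generation
  (a desk-scale reduction of a 16-generation, 120-family design), families
  of 40 in the final generation; family sizes 4 and 8 are evaluated on
  subsets of the same families, mirroring the robustness design of varying
  the number of individuals per family;
* genotyping-error rate 0 or 1%.

What the simulator does **not** emulate: linkage disequilibrium from a deep
historical population (founders are in linkage equilibrium; only the recorded
generations build LD), mutation, selection, non-uniform marker spacing,
crossover interference, and sex chromosomes. Experiments adding a small
historical burn-in population showed it mainly adds drift-driven long
homozygous tracts without improving block accuracy, so it is available
(`hist_generations`) but off by default. Consequently, passing tests show the
method's behaviour under idealised family structure and marker ascertainment;
real data adds LD, pedigree errors and heterogeneous marker quality that the
diagnostics (`recombination_counts()`, `flag_recombination_outliers()`,
`render_block_image()`) are designed to surface rather than the simulator to
reproduce.

## Known limitations

* **Small families.** With four offspring there are on average only two
  informative homozygotes per locus, and whenever two offspring recombine in
  overlapping uncertainty intervals the two family-wide label assignments
  are exactly equally parsimonious; no forward walk can break such ties
  better than chance, so whole-family label flips are intrinsic at this
  size. Flips do not affect label-free quantities (sire genotype, phased
  haplotypes, switch error), but they cap the strand-assignment R² well
  below its large-family values; our implementation's residual flip rate at
  size 4 remains somewhat above what the published block accuracies imply,
  which is discussed with the acceptance results.
* **Unvalidated tails.** A true crossover within `confirm` informative loci
  of the chromosome end cannot be confirmed and is conservatively rejected.
* **Double crossovers** inside one uninformative gap are invisible, as in any
  opposing-homozygote method.
* **Multi-allelic markers** are out of scope; inputs are biallelic 0/1/2.

## Numerical and interface conventions

Genotypes are integer matrices (individuals × markers) with `NA` for missing
(9 in text formats); block matrices use 0/1/2 for U/P/M internally and
U/P/M letters in CSV exports. Map positions are centimorgan and/or base pairs,
non-decreasing within a chromosome; recombination events are half-open
intervals between flanking informative markers. Multi-chromosome inputs are
processed per chromosome and stitched back in input order by `hs_phase()`.
PLINK PED/MAP input collapses allele pairs to counts of the lexicographically
larger observed allele unless an explicit allele key is supplied; the
algorithms are invariant to that polarity. All random draws go through R's
RNG, so a single `set.seed()` reproduces any simulation or baseline exactly.
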