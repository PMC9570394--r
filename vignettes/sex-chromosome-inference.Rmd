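---
title: "Inferring sex-linked markers, sex-chromosome identity, and turnover from tag-based genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sex-linked markers, sex-chromosome identity, and turnover from tag-based genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sexlinkr` implements a complete inference chain for sex-chromosome
evolution in species with homomorphic sex chromosomes, starting from
multi-individual reduced-representation genotype catalogs (GBS or RAD-seq
tags) and ending with counts of sex-chromosome turnovers on a species
phylogeny. This vignette is the package's account of the underlying
models, its tunable parameters, the synthetic data that backs the test
suite, and the numerical and design decisions that were genuinely open.

## The inference problem

In a male-heterogametic (XY) species, a SNP inside the non-recombining
sex-determining region is carried by all males in heterozygous form (one
X allele, one Y allele) and by all females in homozygous form; a tag
inserted on the Y alone is present in males and absent in females. A
female-heterogametic (ZW) species shows the mirror image. With tens of
individuals of each sex per species, these patterns are detectable from
genotype tables alone — but at catalog scale (10^5–10^7 loci) chance
heterozygosity patterns and assembly artifacts vastly outnumber true
signal, so a screening stage must be followed by an independent
sequence-level validation and a statistical call of the system.

Once per-species sets of confirmed sex-linked markers exist, two
higher-level questions follow. First, are the sex chromosomes of related
species homologous? That is answered by mapping markers onto a common
reference genome and comparing the chromosomes they concentrate on, and
summarized by small-parsimony counting of identity changes on the species
tree. Second, for species sharing a homologous pair: does X–Y
recombination continue outside the sex-determining region? The
diagnostic is the topology of multispecies gene trees of sex-linked loci:
without recombination, Y alleles of different species are each other's
closest relatives (gametolog clustering); with ongoing recombination, X
and Y alleles of the same species cluster together (species clustering).

## Screening rules and their parameters

The three screens (`screen_heterozygosity()`, `screen_allele_frequency()`,
`screen_sex_limited()`) are threshold rules, not association tests; the
thresholds live in `screen_thresholds()`:

* `min_frac_het_heterogametic = 1/3`, `min_frac_hom_homogametic = 1/3` —
  a site qualifies when at least one third of the genotyped
  heterogametic-sex individuals are heterozygous *and* at least one third
  of the genotyped homogametic-sex individuals are homozygous. Boundaries
  are inclusive ("at least"). The deliberately loose 1/3 keeps recall
  high in the presence of genotyping error and missing data; the
  validation stage, not the screen, carries the specificity burden.
* `min_frac_present_heterogametic = 1/2`,
  `max_present_homogametic = 0` — a sex-limited tag must be completely
  absent in the homogametic sex and present in at least half of the
  heterogametic sex.
* `min_genotyped_per_sex = 3` — fractions are computed over genotyped
  (non-missing) individuals, and sites with fewer genotyped individuals
  of either sex are skipped (logged, never errored). The source rules are
  silent on missing data; computing fractions over genotyped individuals
  with a small floor is this package's choice.

Two design points were genuinely open:

* **How strategy (i) differs from strategy (ii).** Both share the
  one-third heterozygosity conditions. We interpret the
  *allele-frequency* screen as additionally requiring an allele with zero
  copies in the homogametic sex (a strictly sex-limited allele, recorded
  as `sex_specific_allele`), which makes it a strict subset of the
  heterozygosity screen — frequencies must constrain alleles, not
  genotype classes, to add anything. A frequency-difference alternative
  (`allele_freq_diff_cutoff`) is provided for users who prefer a softer
  predicate.
* **Sites passing both the XY and the ZW expectation.** The mirrored
  predicates are not mutually exclusive: with 4/12 males heterozygous and
  4/12 females homozygous, the complementary classes (8/12 males
  homozygous, 8/12 females heterozygous) satisfy the ZW rule too. Rather
  than suppressing such sites or inventing a tie-break, the screens emit
  one candidate row per system and `combine_candidates()` flags the pair
  (`system_conflict`); the validation stage and the per-species system
  call are the right places to resolve the ambiguity, mirroring the
  workflow in which ZW-expected markers are excluded only after
  validation.

`combine_candidates()` deduplicates candidates across strategies and
assembly parameterizations on (consensus sequence, SNP column,
sex-specific allele, system), concatenating strategy and dataset
provenance. A strategy that records no sex-specific allele merges with
one that does when the recorded alleles agree.

## In-silico validation

Opposite-sex verification asks whether the sex-specific signal survives
contact with the actual reads of the homogametic sex. For SNP markers the
built-in check aligns every same-length pool read end-to-end against the
locus consensus (both strands) and reads off the base at the variable
column: one qualifying female-pool read carrying the sex-specific allele
rejects the marker; at least one male-pool read carrying it (and none in
females) confirms it. The E ≤ 1e-20 cutoff is applied to a documented
Karlin–Altschul-style approximation, `E = m · n · 2^(−bits)` with
`bits = 2·matches − 3·mismatches`; the approximation exists so cutoffs
are exercisable with the built-in matcher and is *not* calibrated against
any external search tool — externally computed 12-column hit tables are
accepted verbatim for real data, with the cutoff applied to their
E-values as printed.

Sex-limited tags are verified by the simpler rule: exact, full-length
substring occurrence in zero homogametic reads and at least one
heterogametic read. The check is strand-aware by default (a
reverse-complement occurrence counts as an occurrence); a literal
forward-strand mode (`strand_aware = FALSE`) reproduces a plain `grep`.
The minimum number of supporting heterogametic occurrences defaults to 1,
the weakest defensible requirement, and is configurable
(`min_het_occurrences`).

`call_system()` operationalizes "differed from random expectations" as an
exact two-sided binomial test of the confirmed XY count against
p = 0.5 — the simplest null under which XY- and ZW-patterned false
positives are equally likely. The majority system is called when
p < `alpha` (default 0.05); minority markers are counted in
`n_excluded`, never silently dropped; a species with no confirmed marker
is `undetermined` with no p-value.

## Chromosome assignment and concentration

`assign_direct()` applies two rules from the mapping procedure: hits
qualify at E ≤ `evalue_cutoff` (1e-20), and the best hit wins only when
it is the sole qualifying hit or lies at least `best_hit_gap_orders`
(5) orders of magnitude below the runner-up. Gaps are computed in log10
with E = 0 floored at 1e-308 so that "orders of magnitude" stays finite.
Ties and sub-gap runners-up are reported as `ambiguous_gap`, hits above
the cutoff as `fails_evalue`, absent queries as `no_hit` — every marker
yields a record. Assignment is invariant to hit-row order (hits are
sorted internally with deterministic tie-breaks).

`assign_indirect()` implements the two-step route for distant references:
markers are placed on a bridge assembly, each hit is extended by
`flank_length` (2 kb) of scaffold sequence per side
(`extract_flanks()`, clipped at scaffold ends with the clipping
recorded), and the extended fragment is re-mapped to the target genome.
Whether the five-orders gap rule applies at the bridge step was not
resolvable from the source; by default it applies at the target step
only, with `gap_at_bridge = TRUE` to enable it at both.

Chromosomal concentration is this package's operationalization of a
claim usually made by eye: per chromosome, a one-sided exact binomial
test of the assigned count against the length-proportional expectation,
Holm-adjusted across chromosomes. Because the binomial is discrete and
Holm controls the family-wise error, the procedure is conservative; the
Monte-Carlo calibration in the test suite (1000 proportional-scatter
replicates, 60 markers, 6 chromosomes) observes a family-wise type-I
error of about 0.03 at nominal 0.05.

## Gene trees

`k2p_distance()` is the closed form
d = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q) with pairwise deletion of
non-ACGT sites; arguments outside the logarithms' domain raise a
saturation error rather than returning NaN. `nj_tree()` is standard
Saitou–Nei agglomeration with three documented numerical choices:

* ties in the Q criterion are broken first toward the closest pair, then
  by lexicographic label order — identical within-species haplotypes
  therefore coalesce before anything attaches between them, and results
  are reproducible across platforms;
* negative branch lengths are clamped to zero with the deficit moved to
  the sister edge (path lengths between the joined neighbors are
  preserved); cluster-reduction can still leave tiny negative edges,
  which are floored at zero;
* internal edges of exactly zero length are collapsed, so an all-zero
  matrix yields a star tree and unsupported resolutions are not
  pretended.

`bootstrap_supports()` resamples alignment columns with replacement and
reports, for each internal bipartition of the point tree, the percentage
of replicate trees containing it. Bipartitions are canonically encoded
(the side not containing the alphabetically first taxon), making supports
invariant to taxon input order; the default engine reuses precomputed
per-pair site classifications so a replicate costs one matrix product.
Replicates in which a distance saturates are dropped and counted
(`n_failed`); an alignment without a single variable site is flagged
`zero_information`.

`classify_topology()` works on the unrooted tree — the figures in this
literature are drawn rooted, but no rooting rule is stated, so monophyly
is evaluated as bipartition membership. *Gametolog-clustered*: the
Y-class tips, spanning at least two species, form one side of a
bipartition with support at or above `support_threshold` (50 by
default, the conventional "shown when above 50%" line).
*Species-clustered*: every species' tip set is such a bipartition and at
least one species contributes both X and Y tips. Trivial splits (single
tips and their complements) count as fully supported. The two patterns
are mutually incompatible on one tree (their defining bipartitions
conflict), which the code asserts. Unphased tips — haplotypes of species
where the locus is not confirmed sex-linked — can satisfy species
clustering but never gametolog clustering; the Y label is assigned only
to the male haplotype carrying the validated sex-specific allele
(`retrieve_homologs()`, with optional per-species phasing for
trans-species markers). We do not require the focal species' X and Y to
separate for the species-clustered call; the default rule asks only for
species monophyly.

Homolog retrieval assumes equal-length catalog loci (fixed-length tags)
and refuses length-variable input rather than aligning silently;
multiple sequence alignment is out of scope. Externally estimated trees
(e.g. GTR+Γ maximum likelihood from another program) enter through
`method = "external"` with supports as node labels; re-implementing ML
estimation would be out of proportion to its role, since the
classification logic is the contribution. Multi-locus analyses
concatenate per-locus alignments over the shared label set; with one
locus the concatenated path reduces to the single-locus path exactly.

## Turnover counting

`fitch_min_changes()` counts minimum state changes by dynamic programming
(Sankoff with unit costs) on the unrooted tree, so counts are invariant
to rerooting and tip order; multifurcations are handled natively. Tips
with unknown state are wildcards — compatible with every state, never
forcing a change — rather than excluded taxa; an identity that is known
to be *different* (the "not chromosome-5" case) should be encoded as a
distinct concrete state, with unknown available where that is too
strong. A second pass computes, per branch, the minimum cost with the
branch forced change-free and forced change-bearing, separating branches
where every most-parsimonious reconstruction places a change
(`change_branches`) from merely possible placements
(`possible_branches`). `heterogamety_shifts()` is the same machinery
restricted to the XY/ZW character; `count_identities()` counts distinct
non-missing identity labels. The species tree is input data and is never
re-estimated.

## The synthetic-data generator

`simulate_catalog()` emulates the statistical structure the analysis
assumes, not any particular sequencing run: per species, autosomal
background loci with genotypes drawn at `minor_allele_freq` (0.2)
independently of sex; `xy_snp` loci with every heterogametic-sex
individual heterozygous for a sex-limited allele and every
homogametic-sex individual homozygous; `y_limited` tags present only in
the heterogametic sex; and optional `ancestral_sdr` loci shared across a
configured species subset, whose X and Y haplotypes split on a stem
branch twice the subtree height and then evolve independently. ZW
species are the exact sex-mirror through one code path. Every locus
consensus is embedded at a recorded position on its true chromosome of a
generated reference genome, so mapping can be tested end-to-end. The
generator is deterministic given `seed` (all randomness flows through
R's generator under a fixed seed).

Default study design: nine species on a two-clade ultrametric tree of
depth 1 (one species alone in its clade), ten males and ten females per
species, 150 bp tags, 200 autosomal / 40 sex-linked SNP / 15 sex-limited
loci per species. Noise knobs are free parameters, not estimates:
`genotyping_error_rate = 0.01` replaces a called genotype with one of
the other two genotype classes at the site (so with error rate e the
probability a planted locus keeps its perfect pattern across n
individuals is exactly (1−e)^n, which the test suite checks against the
binomial expectation), and `locus_dropout_rate = 0.05` removes a locus
from an individual (presence FALSE, genotypes missing).

Substitutions follow Kimura's two-parameter process — Poisson(rate ×
length × branch) events, transitions with probability κ/(κ+2), κ = 2 by
default — so the downstream K2P distances are estimating the model that
generated the data. The default `mutation_rate = 0.15` per site per
branch unit makes the deepest inter-species divergence roughly 25–30%
and, more importantly, puts several diagnostic substitutions on every
terminal branch of the default tree: a species whose stem happens to
carry zero substitutions is genuinely unresolvable in a single-locus
gene tree, and a generator that produced such loci routinely would be
testing the classifier against noise rather than against its decision
rule. "Ongoing recombination" is modelled as complete homogenization of
Y with X within species (every haplotype descends from the species' tip
sequence, with a short `within_species_branch = 0.02` of private
variation); partial suppression gradients are a non-goal.

What the generator does *not* emulate — read-level sequencing error,
coalescent demography and incomplete lineage sorting, restriction-site
dropout correlated with divergence, library-size effects, and
paralogy — bounds what passing tests show: the pipeline is correct with
respect to its own assumptions, not robust to every pathology of real
reduced-representation data.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, chosen so
the full chain is exercised on a laptop: screens are cross-checked
against a brute-force predicate evaluation on 200 random catalogs of up
to 8 loci × 12 individuals; noiseless recovery uses two species (one XY,
one ZW) with 10+10 individuals and 88 loci each; scenario classification
uses 50 loci per scenario, eight species (ongoing recombination) or two
(ancestral suppression), 100 bootstrap replicates at threshold 50;
neighbor joining is checked against exhaustive least-squares topology
selection on all 4- and 5-taxon topologies and against an independent NJ
implementation up to 8 taxa; parsimony against exhaustive enumeration up
to 6 tips and an independent implementation up to 16; concentration
calibration uses 1000 Monte-Carlo replicates. Every stochastic step takes
an explicit seed, and `run_pipeline()` stamps each output file with the
configuration hash and seed that produced it.

## Known limitations

* The built-in matcher handles exact and equal-length ungapped matches
  only; anything subtler (indels, partial tags, paralog discrimination)
  must come from an external search tool via hit tables.
* Haplotype phase across multiple SNP columns of one locus is taken as
  stored in the catalog (allele1 with allele1); only the validated
  sex-specific column is actively phased. Multi-SNP loci with unknown
  phase can therefore understate X–Y divergence.
* The system call treats markers as independent; linked markers on one
  sex chromosome violate that assumption in the direction of
  anti-conservative p-values. The call is a screen, not a hypothesis
  test of record.
* Parsimony counts are minimum-change counts; no attempt is made to
  model turnover rates or to date events.
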