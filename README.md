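# sexlinkr

Sex-linked marker discovery and sex-chromosome evolution inference from
reduced-representation (GBS / RAD-seq) genotype catalogs.

Many fishes, amphibians, and non-avian reptiles carry *homomorphic* sex
chromosomes: X and Y (or Z and W) look alike and can only be told apart
genetically. Two forces can keep them that way — recurrent **turnover**
(a new chromosome pair takes over sex determination) and ongoing **X–Y
recombination** (exchange outside the sex-determining region erases
divergence). Distinguishing the two requires a chain of analyses that
usually lives in one-off scripts: screen thousands of multi-individual tag
loci for sex-linked signatures, weed out false positives, call the
heterogametic system, place markers on a reference genome, test gene-tree
topologies, and count turnovers on the species phylogeny. `sexlinkr`
packages that chain as tested, composable R functions for population
geneticists working on non-model species with homomorphic sex chromosomes.

## What it computes

**Screens** (per species, over a locus catalog and a sample–sex registry;
run under both the XY and the sex-mirrored ZW expectation):

1. *Heterozygosity*: a SNP site is a candidate when it is heterozygous in
   at least 1/3 of genotyped males and homozygous in at least 1/3 of
   genotyped females (inclusive boundaries, fractions over non-missing
   genotypes).
2. *Allele frequency*: additionally requires an allele with zero copies in
   females and at least one copy in males — the putative Y allele.
3. *Sex-limited tags*: a whole locus present in zero females and at least
   half of the males — putative Y-specific sequence.

**In-silico validation** (opposite-sex verification): a SNP candidate is
confirmed only if no female-pool sequence aligns (E ≤ 1e-20) over the
variable base carrying the sex-specific allele while male-pool sequences
do; sex-limited tags must occur verbatim (either strand) in zero female
reads and at least one male read. Confirmed XY versus ZW counts are then
tested per species against the random-expectation null with an exact
binomial test (p = 0.5) to call the system.

**Chromosome assignment**: hits qualify at E ≤ 1e-20 and a marker is
assigned only when its best hit beats the runner-up by ≥ 5 orders of
magnitude; the two-step indirect mode maps markers to a bridge assembly,
extends each hit by 2 kb of scaffold on both sides, and re-maps the
extended fragment to the target genome. Per-chromosome concentration is
tested with one-sided exact binomial tests against length-proportional
expectations, Holm-adjusted.

**Gene trees**: homologs of a sex-linked locus are gathered across
species, pairwise distances use Kimura's two-parameter model,

  d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q),

with P and Q the transition and transversion proportions; trees are built
with in-house Saitou–Nei neighbor joining, supports by column-resampling
bootstrap, and each genealogy is classified as **gametolog-clustered**
(Y alleles of ≥ 2 species form one supported bipartition — recombination
stopped before speciation) or **species-clustered** (every species
monophyletic, some species contributing both X and Y — recombination is
ongoing). Externally estimated trees (e.g. maximum likelihood) are
accepted with their own supports.

**Turnovers**: per-species sex-chromosome identities and heterogamety are
placed on a fixed species phylogeny and the minimum number of changes is
counted by small parsimony (Fitch/Sankoff, unrooted, unknown tips as
wildcards), with mandatory-change branches reported.

A seeded synthetic-data generator (`simulate_catalog()`,
`simulate_reads()`, `simulate_gene_history()`) produces multi-species
catalogs with planted sex-linked loci, per-sex read pools, and allele
histories under both gene-history scenarios, so the entire pipeline is
testable without sequencing data.

## Worked example

Nine torrent-frog species on their two-clade phylogeny, eight with
chromosome-5-homologous sex-linked markers and one (the only eastern-clade
species) with a non-homologous pair:

```r
library(sexlinkr)

ex  <- amolops_example()
fit <- fitch_min_changes(ex$tree, ex$identities)
fit
#> <parsimony_fit> 1 change(s), states: chr5-homologous, other
#> mandatory change on branch(es):
#>   { A_wuyiensis }
count_identities(ex$identities)
#> [1] 2
heterogamety_shifts(ex$tree, ex$heterogamety)$min_changes
#> [1] 0
```

One turnover, sitting exactly on the branch separating the eastern from
the western clade; two distinct sex-chromosome pairs; no change of
heterogamety. On synthetic data the full marker chain reads:

```r
library(dplyr)
sim <- simulate_catalog(sim_config(
  species = c("a", "b"), n_males = 10, n_females = 10,
  n_autosomal_loci = 100, n_xy_snp_loci = 25, n_y_limited_loci = 10,
  species_tree = "(a:1,b:1);", seed = 42))

cand  <- screen_all(sim$catalogs$a, sim$registry)
pools <- simulate_reads(sim$catalogs$a, sim$registry)
ver   <- verify_markers(combine_candidates(gbs = cand),
                        pools$male, pools$female,
                        catalog = sim$catalogs$a)
count(ver, status)
#>   status                            n
#> 1 confirmed                        32
#> 2 rejected_homogametic_evidence   114

ver |>
  filter(status == "confirmed") |>
  mutate(species_id = "a") |>
  call_system()
#>   species_id n_confirmed_xy n_confirmed_zw  p_value call  n_excluded
#> 1 a                      32              0 4.66e-10 XY             0
```

The screens deliberately over-call (114 chance heterozygosity patterns
pass the 1/3-thresholds here) and the opposite-sex verification removes
them; the 32 survivors are overwhelmingly XY-patterned, so the species is
called XY. Fitted objects come with `tidy()`, `glance()`, `autoplot()`
(concentration reports) and `plot()` (gene trees, parsimony fits);
`run_pipeline()` chains every stage from one declarative config into a run
directory with per-stage TSV/FASTA/Newick outputs and a `summary.json`.

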