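# trpa1evo

Comparative molecular-evolution tools for the vertebrate thermosensor
channel **TRPA1**, for researchers asking how thermal sensing evolved as
integumentary insulation (fur, feathers, blubber) replaced skin-level
thermoregulation.

TRPA1 is a heat sensor in ectotherms, a cold sensor in some rodents, and
thermally insensitive in primates, lagomorphs and squirrels. Two
comparative signals capture this history, and this package implements
both as a tested pipeline:

- **Domain-partitioned rate ratios.** For each protein region *R*
  (amino-terminal ankyrin repeats ARD1–9, the ARD10–16 + linker block,
  the transmembrane S1–S6 + carboxy tail) and each taxonomic clade
  group *g*, the statistic is

  ratio(g, R) = mean phylogenetic distance of *g* in *R* / mean
  phylogenetic distance of *g* in the full-length protein,

  with distances in expected substitutions per site from
  maximum-likelihood trees under the JTT amino-acid model
  (Q<sub>ij</sub> = S<sub>ij</sub>·π<sub>j</sub>, normalized to unit
  expected rate). Elevated sensor-region ratios in blubber-insulated
  marine lineages are read as relaxed selection on the thermosensor.
- **The S5 diagnostic residue.** The scan maps human TRPA1 position 878
  onto any alignment via the ungapped-reference column map and
  tabulates each taxon's V/G state against curated thermal-sensitivity
  labels per clade group.

A clade-structured sequence simulator (JTT evolution along a tree, with
per-clade per-region rate multipliers and a plantable diagnostic column)
provides ground truth for every stage; all validation is offline.

## Worked example

```r
library(trpa1evo)

## climate fixture: the temperature range behind the experimental design
climate_summary(read_climate_table(trpa1evo_extdata("climate_table1.tsv")))
#> mean_daily_min    cold_nights mean_daily_max       hot_days
#>           20.3           15.2           33.2           38.5

## marine fixture: 16 taxa, 4 clade groups, sensor region x3 in group 14
fx <- make_marine_fixture(seed = 1)
rep <- rate_ratio_report(fx$alignment, fx$domain_map, fx$clade_groups,
                         jtt_model(),
                         rate_config(regions = c("sensor", "middle", "pore"),
                                     scheme = "mean_pairwise_within_group"))
subset(as.data.frame(rep), region %in% c("full_length", "sensor"))
#>   group_id        group_name      region n  mean     sd ratio
#> 1       14           Sirenia full_length 4 0.423 0.1092  1.00
#> 2       15       Proboscidea full_length 4 0.263 0.0417  1.00
#> 3       16 Afroinsectiphilia full_length 4 0.292 0.0252  1.00
#> 4       17           Cetacea full_length 4 0.284 0.0581  1.00
#> 5       14           Sirenia      sensor 4 0.788 0.2102  1.86
#> 6       15       Proboscidea      sensor 4 0.245 0.0469  0.93
#> 7       16 Afroinsectiphilia      sensor 4 0.312 0.0213  1.07
#> 8       17           Cetacea      sensor 4 0.296 0.0636  1.04
```

`full_length` ratios are 1 by construction. The "aquatic" group (14)
carries a ×3 rate multiplier on the 300-site sensor region; its measured
sensor ratio of 1.86 matches the expected value under dilution by the
full-length denominator, 3·L/(3·L<sub>s</sub> + L − L<sub>s</sub>) = 1.8
for L<sub>s</sub> = L/3, while the terrestrial groups sit near 1. The
vignette derives this algebra and why the within-group pairwise scheme is
used for clade contrasts.

```r
## residue fixture: V/G planted per group at the 878-like position
rf <- make_residue_fixture(seed = 1)
calls <- call_reference_residue(rf$alignment, "human_TRPA1", rf$truth$position)
tabulate_by_clade(calls, rf$clade_groups, rf$thermal_labels)
#>   group_id        group_name n_V n_G n_other n_gap n_total thermal_label
#> 1       23 Sciuromorpha_like   3   0       0     0       3   insensitive
#> 2       24        Lagomorpha   3   0       0     0       3   insensitive
#> 3       25         Myomorpha   0   3       0     0       3          cold
#> 4       26          Primates   3   0       0     0       3   insensitive
```

Cold-labeled groups are all G, insensitive-labeled all V — the
concordance pattern the scan is built to expose (descriptive only; V/G
is necessary but not sufficient for the thermal phenotype).

For real data, supply your own aligned FASTA (the pipeline consumes
pre-aligned sequences), the packaged 26-group clade table
(`trpa1evo_extdata("clade_groups.tsv")`) extended with your taxa, and the
packaged human domain map (`trpa1evo_extdata("domain_map.yaml")`) with
interval boundaries reviewed — the shipped ones are marked illustrative.

## Command line

```sh
Rscript -e 'trpa1evo::trpa1evo_cli()' simulate --fixture marine --seed 1 --out fix/
Rscript -e 'trpa1evo::trpa1evo_cli()' domain-rates --alignment msa.fasta \
    --groups groups.tsv --domains domains.yaml \
    --regions ARD1_9,ARD10_16_linker,S1_S6_COOH \
    --scheme root_to_tip --deletion complete --out out/
Rscript -e 'trpa1evo::trpa1evo_cli()' residue-scan --alignment msa.fasta \
    --groups groups.tsv --domains domains.yaml --position 878 --out out/
Rscript -e 'trpa1evo::trpa1evo_cli()' climate --table table1.tsv
```

(`exec/trpa1evo` is the same entry point as an installed script.)

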