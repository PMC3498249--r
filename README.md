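# bcri — forest recovery assessment with the Tanner (Bray-Curtis) recovery index

How well has a disturbed forest patch recovered? Count-based similarity
indices routinely over-answer: a stand whose stems are all back but still
thin scores as "recovered", and proportionate indices (Morisita-Horn,
abundance-based Chao-Jaccard) cannot even distinguish a plot from one with
twice as many trees of every species. `bcri` is an R package for ecologists
monitoring permanent plots through disturbance — experimental gaps, felling,
hurricanes — who need a recovery measure that is sensitive to both *how
many* stems came back and *how big* they are.

## The index

For abundance vectors of two censuses *j*, *k* over species *i*, the
quantitative Bray-Curtis similarity is

    BC_jk = 2 Σᵢ min(Y_ij, Y_ik) / (Σᵢ Y_ij + Σᵢ Y_ik)

The **Tanner recovery index** is the mean of this similarity computed on
per-species stem densities and on per-species basal areas:

    BC_RI = (BC_density + BC_ba) / 2

Because Bray-Curtis is not proportionate, BC(x, 2x) = 2/3 < 1, and because
basal area enters with equal weight, a stand of numerous thin recruits
cannot masquerade as recovered old growth.

Recovery is never reported as raw similarity: undisturbed plots drift apart
over time and differ in space, so the package normalizes by the
**maximum attainable similarity** of the design —

* temporal: sim(pre-gap, post-gap) / sim(pre-control, post-control)
* spatial (space-for-time): sim(post-gap, post-control) / sim(pre-gap, pre-control)

— as a ratio of means across plot pairs, with a two-tailed paired t-test of
observed vs maximum.

Around the core index: comparator indices ([Morisita-Horn and
abundance-based Chao-Jaccard](R/similarity.R)), importance values, paired
change tests with per-hectare basal-area conversion, individual-based
rarefaction, Dufrêne-Legendre indicator species analysis with Monte Carlo
(or exhaustive) permutation, baseline inter-plot variability, and a seeded
generator of paired gap/control censuses for testing pipelines without
field data.

## Worked example

```r
library(bcri)

coll <- simulate_censuses(sim_config(seed = 1))  # 4 pairs + 1 unpaired gap
coll
#> census_collection: 18 censuses, 9 plots, 33 species
#>   treatments: control=4, gap=5

assess_recovery(coll, "temporal", "tanner")
#> Recovery assessment (temporal, tanner)
#>   observed  = 0.45 (mean of 5 comparisons)
#>   maximum   = 0.87 (mean of 4 comparisons)
#>   recovery  = 52% of maximum
#>   paired t  = -10.264 on 3 df, two-tailed p = 0.0020 (significant at alpha = 0.05)
```

Reading: 24–35 simulated years after gaps lost 30% of their stems (largest
first) and an alien invader moved in, each gap plot's composition resembles
its own pre-disturbance state with Tanner similarity 0.45, while undisturbed
controls resemble *their* past at 0.87 — so the gaps sit at 52% of
attainable recovery, significantly short of it. Splitting the index shows
why density-only assessments flatter the stand:

```r
assess_recovery(coll, "temporal", "bray_curtis_density")$percent_of_maximum
#> [1] 66.15767   # stems largely back...
assess_recovery(coll, "temporal", "bray_curtis_ba")$percent_of_maximum
#> [1] 36.90823   # ...basal area is not
```

The same pipeline runs from the shell:

```sh
exec/bcri simulate --seed 1 --out-prefix sim
exec/bcri assess --census-table sim_census.csv --meta-table sim_meta.csv \
  --mode both --index tanner --out recovery.csv
exec/bcri indval --census-table sim_census.csv --meta-table sim_meta.csv \
  --census post --permutations 999 --seed 1 --out indicators.csv
```

Subcommands: `similarity`, `assess`, `baseline`, `iv`, `change-tests`,
`rarefy`, `indval`, `simulate`. Exit codes: 0 ok, 1 data/validation error,
2 usage error. Output CSVs carry header comments with the tool version,
seed and input checksums.

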