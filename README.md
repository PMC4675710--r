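# metacosm

Quantitative analysis of time-course shotgun metagenomes from disturbed
soil microcosms — for microbial ecologists asking how a community's
taxa, gene pools and phages respond to, and recover from, a chemical
disturbance such as aromatic-pollutant amendment.

The package takes per-sample feature count tables (OTU / genus / KO /
gene / contig) and BLAST tabular hit files produced upstream, and
implements:

* **Genome-equivalent normalization.** KO abundances are read counts
  divided by median protein length; each sample is then divided by its
  *genome equivalents* — the mean length-normalized abundance of a
  36-gene single-copy marker set (gyrB + 35 universal single-copy
  genes) — so abundances become per-genome frequencies, invariant to
  sequencing depth and community size.
* **Pathway dynamics.** Per-pathway variation scores
  `V_p(t) = log2(K_p(t) / K_p(t−1))` over consecutive sampled time
  points, k-means clustering of the score vectors with the
  Calinski–Harabasz index `CH(k) = [B/(k−1)] / [W/(n−k)]` selecting k,
  and labelling of the constant vs disturbance-responsive clusters.
* **Community structure.** Shannon–Wiener diversity
  `H' = −Σ p_i ln p_i`, 1 − Pearson correlation distances between
  samples, complete-linkage dendrograms, and co-occurrence clustering
  of the most abundant genus time profiles.
* **Gene-pool distance.** The all-against-all D2 distance
  `D2(A,B) = 1 − (S(A→B) + S(B→A)) / (S(A→A) + S(B→B))` from sums of
  per-read best-hit bit scores (121 ordered pairs for 11 samples).
* **Phage–host asynchrony.** Four-criteria classification of putative
  phage-genome contigs (>2 kb, phage-related, ≥40 % ortholog identity,
  ≥1 phage-region call) and a kill-the-winner detector that flags a
  phage-contig bloom lagging and suppressing its host's bloom.
* **Synthetic data.** Generators that plant all of the above structure
  (constant/oscillating pathway groups, marker counts with known genome
  equivalents, host/phage blooms, filter fixtures, bit-score
  summaries) with truth labels, so the whole pipeline is testable
  without any external database.

## Worked example

Simulate the default study conditions — 11 samples (baseline week 0,
control and polluted arms at weeks 1, 3, 6, 12, 24), 100 constant plus
46 disturbance-responsive pathways — then cluster the polluted-arm
variation profiles:

```r
library(metacosm)
sim  <- simulate_pathway_tables(seed = 1)
poll <- arm_series(default_design(), "polluted")
v    <- variation_scores(sim$abundance[, poll$sample_id], weeks = poll$week)
res  <- cluster_variation_profiles(v, seed = 1)
res
#> pathway clustering: k = 2 (CH-selected), sizes 100/46
table(label_clusters(res)[res$labels])
#>   constant responsive
#>        100         46
round(res$centroids, 2)
#>     V_1   V_3   V_6  V_12 V_24
#> 1 -0.01  0.02 -0.01 -0.01 0.00
#> 2  2.99 -2.99  1.00  0.01 0.02
```

The CH index selects two clusters; the cluster with near-zero centroid
(no systematic log2 change at any step) is the constant core of the
community's functional repertoire, while the responsive cluster shows
the planted bloom-and-bust signature: a sharp rise into week 1
(V ≈ +3), collapse by week 3 (V ≈ −3) and a slight re-rise at week 6.

The phage module detects host→phage bloom asynchrony on the planted
bloom (host genus peaking 23-fold at week 1, a 44.5-kb phage contig
peaking 17000-fold at week 6):

```r
bl <- simulate_phage_bloom()
ge <- setNames(rep(1, 11), default_design()$sample_id)
ph <- contig_abundance_series(bl$phage, setNames(44500, "contig70_3"), ge)
hs <- normalize_per_genome(bl$host, ge)
detect_bloom_asynchrony(
  setNames(unclass(hs)[1, poll$sample_id], poll$week),
  setNames(unclass(ph)[1, poll$sample_id], poll$week))
#>   host_peak_week phage_peak_week lag_weeks host_fold_rise phage_fold_rise
#> 1              1               6         5             23           17000
#>   host_decline_after_phage_rise ktw_flag
#> 1                            23     TRUE
```

A positive 5-week lag, a massive phage rise and a host decline after
its peak together raise the kill-the-winner flag.

## Command line

A thin wrapper over the same functions lives at `inst/cli/metacosm.R`:

```sh
Rscript inst/cli/metacosm.R simulate --preset m1m2 --seed 42 --out sim/
Rscript inst/cli/metacosm.R dynamics --table sim/pathway_abundance_polluted.tsv \
    --seed 1 --out dyn/
```

Subcommands: `simulate`, `normalize`, `dynamics`, `community`,
`genepool`, `phage`. Identical arguments and seed give byte-identical
outputs.

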