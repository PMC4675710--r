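---
title: "Methods: quantifying time-course metagenome dynamics with metacosm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying time-course metagenome dynamics with metacosm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacosm)
```

## The setting

metacosm analyses shotgun-metagenome time courses from closed soil
microcosms subjected to a chemical disturbance (e.g. amendment with
aromatic pollutants). The canonical design has 11 samples: one baseline
at week 0 and two parallel arms — an undisturbed control and a polluted
arm — each sampled at weeks 1, 3, 6, 12 and 24
(`default_design()`). The pipeline starts from feature count tables
(OTU, genus, KO, gene or contig read counts per sample) and BLAST
tabular hit files; read QC, assembly and alignment are upstream of the
package.

## Genome-equivalent normalization

Read counts confound a feature's true per-genome frequency with
sequencing depth and community size. The package removes both in two
steps:

1. **Length normalization.** A KO's abundance is its read count divided
   by the median protein length of the KO (amino acids); contig hits
   are divided by contig length in bp (`length_normalize()`).
2. **Per-genome normalization.** Each sample's abundances are divided
   by that sample's *genome equivalents*: the arithmetic mean of the
   length-normalized abundances of a fixed 36-gene marker set — gyrB
   plus 35 universal single-copy genes, each carried once by nearly
   every prokaryotic genome (`estimate_genome_equivalents()`,
   `normalize_per_genome()`).

Two choices here were genuinely open:

* **Absent markers count as zero inside the mean** (the divisor is
  always the full set size). The alternative — averaging only detected
  markers — would inflate genome estimates in shallow samples exactly
  where depth correction matters most. The choice is pinned by a test.
* **The marker identities** ship as a documented placeholder (gyrB
  K02470 plus 35 ribosomal-protein/tRNA-ligase KOs,
  `default_marker_set()`); any single-copy set present in the catalog
  can be substituted via `marker_set()`. Results depend on the set only
  through a per-sample scale factor, which cancels in all fold-change
  and correlation analyses.

The resulting unit is reads per residue (or per bp) per genome
equivalent. Pathway abundance is the sum of member-KO abundances, a KO
in several pathways contributing to each (`pathway_abundance()`).

## Pathway variation profiles and clustering

Pathways are filtered before dynamics analysis (`filter_pathways()`):
a pathway is kept when it occurs in prokaryotes, its normalized
abundance reaches at least `1e-4` at some time point, and it is never
exactly zero in an analysed sample. The zero rule is applied per
*any* analysed sample, because the log2 ratio below is undefined at a
zero; imputing a pseudo-count instead would silently reshape the
cluster structure, so zeros are a hard error downstream of the filter.

For each retained pathway p the variation score into time point t is

$$V_p(t) = \log_2 \frac{K_p(t)}{K_p(t-1)},$$

where $K_p(t)$ is the normalized pathway abundance and $t-1$ the
previous *sampled* time point regardless of week spacing — six sampled
points give five scores per pathway (`variation_scores()`). Control
and polluted arms are scored and clustered independently.

Score vectors are clustered by Euclidean k-means (best of 100 random
starts, fixed seed, `stats::kmeans`) for every k in 2–10, and the
cluster count is chosen by the Calinski–Harabasz index

$$\mathrm{CH}(k) = \frac{B/(k-1)}{W/(n-k)},$$

with B and W the between- and within-cluster sums of squared Euclidean
distances (`ch_index()`, `cluster_variation_profiles()`). CH is
undefined at k = 1 and 146 profiles bound any sensible upper k, hence
the 2–10 default range. When W = 0 (perfectly separated duplicate
profiles) CH is $+\infty$ and ties resolve to the smallest k. The
cluster whose centroid is nearest the origin — no systematic change at
any step — is labelled *constant*, all others *responsive*
(`label_clusters()`), with centroid-norm ties going to the lowest
cluster index. All tie-breaks exist purely for determinism.

## Community structure

`relative_abundance()` converts counts to per-sample proportions;
`shannon_index()` computes the Shannon–Wiener diversity
$H' = -\sum_i p_i \ln p_i$ in natural-log units (the Shannon–Wiener
convention; no log base is canonical and the base only rescales
comparisons). Sample similarity uses the 1 − Pearson correlation
distance over feature abundances (`correlation_distance()`), clustered
with complete linkage (`hclust_complete()`, `stats::hclust`).

Genus co-occurrence clustering (`cooccurrence_clusters()`) takes the
top 30 genera ranked by *maximum* relative abundance across samples —
maximum rather than mean so that transient bloomers, the ecologically
interesting genera in a disturbance study, are not averaged away — and
clusters their time profiles with the same 1 − Pearson/complete-linkage
machinery, cut at k = 4 by default. The cut count is an explicit
parameter because no criterion for it is canonical here.

## Gene-pool distance

For the all-against-all gene-pool comparison, `summarize_bitscores()`
reduces each ordered sample pair (A, B) to
$S(A \to B) = \sum_{\text{reads } r \in A} \max \text{bitscore}(r, B)$
after an e-value ≤ 0.01 filter; 11 samples give 121 ordered pairs. The
distance is

$$D_2(A,B) = 1 - \frac{S(A\to B) + S(B\to A)}{S(A\to A) + S(B\to B)},$$

clamped to [0, 1]: 0 for identical pools, 1 for pools with no
cross-similarity, normalized by the self-comparison scores so that
sequencing-effort differences cancel. The symmetric self-normalized
form is this module's single point of interpretive freedom; it is
isolated in `d2_matrix()` so an alternative can be swapped in, and its
required properties (identity, symmetry, bounds, monotonicity in the
cross-scores) are asserted as tests.

## Read assignment filters

Taxonomic and functional assignment keeps the highest-bit-score hit
per read among hits with identity ≥ 70 and bit score ≥ 40
(`filter_hits()`, `best_hit()`); bit-score ties break to the
lexicographically smallest subject. The curated-database ("in-house")
workflow adds two stages: reference sequences qualify for the DB at
identity ≥ 90 with query and subject coverage ≥ 70
(`db_build_filter()`; coverage arrives as input columns because the
pipeline never sees raw sequences), and a candidate assignment is
confirmed only if the read's best hit against the comprehensive DB is
itself an in-house sequence (`confirm_inhouse()`). A read with *no*
comprehensive-DB hit keeps its in-house assignment — the in-house hit
is then trivially the best known hit; this unspecified corner is a
documented choice, pinned by a test.

## Phage–host asynchrony (kill-the-winner)

Candidate phage contigs are accepted when all four criteria hold:
length strictly greater than 2 kb, membership in the phage
genome-related contig set, at least one CDS with amino-acid identity
≥ 40% against a phage-ortholog database, and at least one
phage-derived region call (`classify_phage_contigs()`). Contig
abundance series reuse the two-step normalization (hits / contig bp /
genome equivalents, `contig_abundance_series()`).

`detect_bloom_asynchrony()` operationalizes the kill-the-winner
pattern — a phage bloom that lags and then suppresses its host's
bloom — as three configurable conditions on a shared week grid:
positive lag between the host-abundance peak and the phage-contig
peak, a phage fold rise of at least 100 over its baseline week, and a
host decline of at least 2-fold between the host peak and the phage
peak. Peak ties resolve to the earliest week. Fold baselines default
to each series' earliest sampled week but are parameters, since a
contig absent at week 0 forces a later comparison week. The defaults
are deliberately permissive: a genuine predation signal in this regime
is orders of magnitude above both thresholds (host blooms of ~20-fold,
phage rises of 10^3–10^4), while the thresholds still reject flat or
host-leading series. The flag is a screen, not a hypothesis test — no
p-value accompanies it.

## The synthetic-data generators

Every analysis stage is exercised against generated inputs with
planted truth (`simulate_pathway_tables()`,
`simulate_marker_and_ko_counts()`, `simulate_phage_bloom()`,
`make_filter_fixture()`, `simulate_blast_summaries()`; bundled
defaults via `simulate_preset()`). Design choices:

* **Noise model.** Multiplicative lognormal noise on abundances
  (Gaussian in log2 space, applied per time step, so a pathway's
  variation score is exactly its planted shift plus one Gaussian term)
  and Poisson noise on read counts — the simplest models consistent
  with positive abundances and count data.
* **Study conditions as defaults.** The pathway generator plants 100
  constant and 46 responsive pathways (146 after filtering) over the
  11-sample design with step noise sd 0.1 in log2 units; the
  responsive archetype uses log2 shifts (+3, −3, +1, 0, 0) over weeks
  1–24 — a bloom-and-bust magnitude chosen once to be well separated
  from that noise, since no quantitative oscillation size is canonical.
  The bloom generator plants a 23-fold host peak at week 1 and a
  17000-fold rise of a 44.5-kb phage contig at week 6, in the polluted
  arm only. The filter fixture plants 160 pathways of which 8 are
  non-prokaryotic, 4 sub-cutoff and 2 zero-containing, leaving 146.
* **Truth labels are always returned** (and written as `truth.tsv` by
  the presets) so recovery tests can score against the planted
  partition.

What the generators deliberately do *not* emulate: compositional
coupling between features, phylogenetic correlation, overdispersion
beyond Poisson, chimeric contigs, or any sequence-level structure.
Passing recovery tests therefore demonstrates that the estimators
invert their stated generative models — not that real soil
metagenomes satisfy those models.

## Numerical choices and degenerate inputs

* Zero abundances: hard errors in `variation_scores()` (filter first)
  and in genome-equivalent estimation (a zero estimate makes
  normalization impossible).
* Constant sample profiles make the Pearson distance undefined and are
  an error naming the sample, not an NA.
* Cross-pair bit scores exceeding self-scores (possible with heuristic
  alignment) clamp D2 at 0 rather than going negative.
* All stochastic steps (generators, k-means restarts) are pure
  functions of their seed; identical invocations are byte-identical.

## Problem sizes

The bundled simulations run at the study's own scale — 11 samples,
6 time points, 146 pathways, k searched over 2–10 with 100 restarts —
which completes in seconds; the test suite's Monte-Carlo check of the
Poisson marker model uses 200 replicate draws of a 36-marker sample.

## Reproducing the headline quantities

```r
sim  <- simulate_pathway_tables(seed = 1)
poll <- arm_series(default_design(), "polluted")
v    <- variation_scores(sim$abundance[, poll$sample_id], weeks = poll$week)
res  <- cluster_variation_profiles(v, seed = 1)
res$k_selected                 # 2
table(label_clusters(res)[res$labels])  # constant 100, responsive 46
```

`scripts/acceptance.R` wraps exactly this computation and writes the
two cluster sizes as JSON.
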