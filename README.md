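# bifpopgen

Population genomics of gut *Bifidobacterium longum* cohorts: core-genome
SNP calling, co-ancestry-based population structure, fixation indices,
population- and phenotype-associated variant discovery, clonal-group
transmission inference, and host-covariate attribution of microbiota
composition — plus a synthetic cohort generator that plants every signal
the pipeline is designed to detect, so the whole analysis is testable
end-to-end without external sequence data.

## Who this is for

Researchers analyzing collections of closely related bacterial isolates
(here modeled on *B. longum*, a core human gut commensal) who want to ask:
how many differentiated gene pools does the species form, which genes and
SNPs define them, which strains are recent transmission partners, and
which host factors (geography, age, sex, longevous-district residence)
shape strain genotypes and community composition.

## The methods in brief

* **Core SNPs.** From reference-coordinate genome alignments, a column is
  *core* when the fraction of unambiguous calls is ≥ `core_fraction`
  (default 1); variable core columns with exactly two observed bases
  become sites. Pairwise distances d(i,j) count differing non-missing
  calls (pairwise deletion); all thresholds below are absolute SNP counts.
* **Clonal pruning.** Single-linkage clusters at d < 300 are collapsed to
  one random representative each, removing clonal signal before structure
  inference.
* **Chromosome painting (simplified).** Sites are cut into windows of 100
  SNP columns; in each window every recipient donates one chunk to its
  nearest non-self donor(s) (ties split equally), giving a recipient ×
  donor co-ancestry matrix whose rows sum to the window count exactly.
  Average-linkage clustering of row-normalized profiles with
  silhouette-selected K yields populations; palettes give each strain's
  per-population chunk fractions.
* **Fixation index.** Haploid Weir–Cockerham estimator,
  θ = Σa / Σ(a+b) over polymorphic loci, overall and per population pair.
* **Population-specific variants.** Three one-vs-rest scans (two-sided
  Fisher exact, variants at 5–95% carriage, Bonferroni 0.05/m), merged;
  COG/KEGG enrichment by one-sided Fisher at the strict threshold
  0.01/220 ≈ 4.55 × 10⁻⁵.
* **Phenotype GWAS.** MinHash (Mash-type) sketch distances
  (d = −(1/k)·ln(2j/(1+j)), k = 21, s = 1000) → classical MDS axes as
  structure covariates → fixed-effect regression (OLS for continuous
  phenotypes, logistic with Firth fallback for binary), variants at 1–99%
  carriage, Bonferroni 0.05/m; RDA and PERMANOVA quantify each
  covariate's share of overall genomic variation.
* **Transmission.** Semi-clonal groups (SCG) at d < 2500 with per-group
  SNP re-calling; windowed Poisson outlier masking of recombination
  imports against the group consensus; clonal groups (CG) at post-masking
  d < 10; each CG classified to the most specific shared metadata stratum
  (host → family → community → city → province → country).
* **Community statistics.** Dataset-wide 0.005% abundance filter,
  Hellinger transformation, tb-RDA and Euclidean PERMANOVA effect sizes
  with 1000-permutation tests, Kruskal–Wallis plus pairwise Mann–Whitney
  tests across age bins (0–17, 18–45, 46–65, >65) with compact letter
  displays.

## Worked example

```r
library(bifpopgen)

cfg <- sim_config(seed = 1, clone_groups = list(c(2, 8), c(2, 8)))
cohort <- simulate_cohort(cfg)

snps <- call_core_snps(cohort$genomes)
snps
#> snp_matrix: 60 strains x 16902 bi-allelic core sites (reference reference , 50000 bp)

d <- pairwise_snp_distances(snps)
pruned <- prune_clonal(d, threshold = 300, seed = 1)
painting <- paint_chromosomes(subset_snps(snps, pruned$representatives))
pops <- cluster_populations(painting, k_range = 2:6)
pops
#> pop_assignment: K = 3 populations, sizes 19/19/20

adjusted_rand_index(pops$labels, cohort$truth$population_of[pruned$representatives])
#> [1] 1

weir_cockerham_fst(snps, cohort$truth$population_of)[1, ]
#>   pop1 pop2     theta n_loci
#> 1  all  all 0.6734122  16902
```

The simulated cohort plants three populations of 20 strains on a 50 kb
core; the pipeline prunes the two planted clone pairs, re-identifies
K = 3 populations perfectly (adjusted Rand index 1 against the planted
labels), and the fixation index ≈ 0.67 reflects the planted
between-population divergence (twice the tip branch length).

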