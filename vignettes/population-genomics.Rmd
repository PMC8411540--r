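---
title: "Methods: population genomics, transmission and host association for gut Bifidobacterium cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics, transmission and host association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifpopgen)
```

# Scope and data model

`bifpopgen` implements a complete strain-level analysis chain for
collections of closely related bacterial genomes — modeled on gut
*Bifidobacterium longum* cohorts — under one simplifying premise: genomes
arrive **already in reference coordinates** (equal-length alignments, one
record per strain plus the reference). Whole-genome alignment and
assembly are upstream concerns; everything downstream of the alignment —
SNP calling, structure, transmission, association, community statistics —
is computed here and is fully testable against planted ground truth from
the built-in cohort generator.

Five inputs, all plain text, flow through the pipeline: the aligned
multi-FASTA; a strain metadata table (country/province/city,
community/family, host species, age, sex, longevous-district flag); a
gene presence/absence matrix in the Roary Rtab dialect; a gene→COG/KEGG
annotation table; and a sample×taxon abundance table. Interchange formats
are VCF 4.2 with haploid genotypes, Newick, BED, and TSV. All internal
coordinates are 1-based inclusive; the 0-based half-open convention of
BED is applied only at the writer/reader boundary.

# Core SNPs and distances

A column is *core* when the fraction of records with an unambiguous
`A/C/G/T` call is at least `core_fraction` (default 1, the strict core).
Among core columns, variable columns with exactly two observed bases
become bi-allelic sites; columns with three or more observed bases are
dropped outright, and residual `N`/`-` calls at retained sites become
missing genotypes. The `core_fraction` knob exists because the core — and
therefore the SNP set — shrinks as cohorts grow, so sub-analyses (each
semi-clonal group, each GWAS panel) re-call SNPs on their own strain
subset.

Pairwise distances count sites where both calls are present and differ
(**pairwise deletion**). We deliberately do not normalize to a rate:
every operative threshold in the pipeline (300 for clonal pruning, 2500
for semi-clonal groups, 10 for clonal groups) is an absolute SNP count,
so the distance must stay on the count scale. Pairwise deletion (rather
than complete-case restriction) keeps each pair's distance on the largest
usable site set; the alternative would couple every distance to the
cohort's worst strain.

Neighbor-joining trees use the Saitou–Nei agglomeration via `ape::nj`.
The estimator can produce negative branch lengths on non-additive inputs;
we clamp them to zero and shift the deficit onto the sibling branch so
path lengths through the parent node are preserved. On additive matrices
the input distances are reproduced exactly (this is a tested invariant).

# Population structure

## Clonal pruning

Clonal relationships distort co-ancestry-based structure inference, so
strains at pairwise distance < 300 are grouped by single linkage and each
group is collapsed to one uniformly random representative. Single linkage
is the right closure here because "A within 300 of B within 300 of C"
already chains the clonal signal even if d(A,C) ≥ 300. After an initial
clustering, populations smaller than `min_size = 4` are treated as
residual clonal signal (they typically comprise two or three strains),
collapsed to one representative each, and painting and clustering are
re-run — the same two-pass scheme used in practice with co-ancestry
clustering tools.

## Simplified chromosome painting

The canonical approach paints each recipient's genome as a mosaic of
donor segments with a hidden-Markov copying model and clusters the
resulting co-ancestry matrix by MCMC. We implement a deliberately
simplified, deterministic analogue and document it as such:

* sites are partitioned into consecutive windows of `window_snps = 100`
  SNP columns (a trailing partial window survives on its own if it spans
  at least half a window, otherwise it merges into the previous one);
* in each window, every recipient assigns one chunk to the non-self
  donor(s) at minimal Hamming distance, ties splitting the chunk equally;
* the co-ancestry matrix accumulates chunks, so each row sums exactly to
  the window count — a conservation law the tests assert on tie-heavy
  inputs.

Under a uniform recombination rate the dominant copying signal is
window-local nearest-relative copying, which this scheme captures while
remaining exactly testable (every chunk is attributable by hand). The
trade-off: no per-site switching within windows, no donor-specific
emission model, and window width fixes the resolution; fine-scale mosaic
boundaries are out of reach.

Populations come from average-linkage hierarchical clustering of
row-normalized co-ancestry profiles (Euclidean distance), with K chosen
to maximize the mean silhouette width over `k_range` (smallest K on
ties). This replaces the MCMC with a deterministic procedure: same input,
same answer. When even the best silhouette stays below 0.25 the
assignment is flagged `weak_structure`. Palettes — each strain's chunk
fractions received from donors of each population — are row-normalized
aggregations of the co-ancestry matrix and sum to one by construction.

## Fixation index

Differentiation is summarized by the haploid Weir–Cockerham estimator.
Per polymorphic locus the among-population component
$a = (\mathrm{MSP} - \mathrm{MSG})/n_c$ and within component
$b = \mathrm{MSG}$ are accumulated (heterozygote terms vanish for
haploids), and the multi-locus estimate is
$\theta = \sum a / \sum (a+b)$, reported overall and per population pair.
Monomorphic loci and loci unobserved in some population are skipped; the
estimator may go slightly negative in the no-differentiation limit, which
is expected finite-sample behavior, not an error.

# Association analyses

## Population-specific variants

Markers that *define* populations would be absorbed by any structure
correction, so the one-vs-rest scans deliberately use none: for each
variant (SNP alt-carriage or accessory gene presence) at 5–95% cohort
carriage, a **two-sided Fisher exact test** compares carriage in the
target population against all others, with Bonferroni significance at
0.05/m. The exact test is the defensible choice for a binary phenotype,
binary genotype and no covariates, and it is verifiable against
hypergeometric enumeration (a tested invariant at 1e-12). The three scan
hit sets are merged into one variant list tagged by contributing
population(s).

Functional enrichment of hit genes uses the one-sided (greater) Fisher
exact test per COG category and KEGG pathway against the reference
genome's gene complement, with the strict Bonferroni threshold
$0.01/220 = 4.55\times10^{-5}$ (20 COG categories + 200 pathway terms —
one family across both term types).

## Phenotype GWAS

Population structure for the phenotype scans comes from
assembly-sketch distances: canonical k-mers (k = 21) are hashed by a
universal affine map modulo $2^{31}-1$, each genome keeps its bottom-1000
sketch, and the pairwise Jaccard estimate $j$ from the merged bottom
sketch is converted to $d = -\tfrac{1}{k}\ln\frac{2j}{1+j}$ (capped at 1
when $j = 0$). With a sketch at least as large as the k-mer universe the
estimate equals the exact Jaccard — the tested oracle route. k and s are
the sketching tool's customary defaults; nothing in the pipeline is
sensitive to them at the planted effect sizes.

Classical (Torgerson) MDS of that distance matrix supplies the structure
covariates: axes with positive eigenvalues are retained until 80% of the
positive-eigenvalue mass is covered, capped at 10 axes, each axis
sign-fixed by making its largest-magnitude loading positive (so the
covariate matrix is reproducible across runs and machine orders). The
retention rule is a package choice — any rule that captures the leading
structure axes works; 80%/10 keeps the design matrix small relative to
typical panel sizes.

The association model is a fixed-effect regression of the phenotype on
each variant plus the MDS covariates, over variants at 1–99% carriage:
ordinary least squares with the Wald t-test for continuous phenotypes
(computed by Frisch–Waugh residualization, algebraically identical to the
full regression and fast enough to vectorize over thousands of variants),
and logistic regression for binary phenotypes with a Firth-penalized
fallback when separation is detected. Missing phenotypes are dropped
casewise per phenotype; significance is Bonferroni 0.05/m. SNP-based and
gene-based scans form separate Bonferroni families (each scan tests its
own variant set).

To attribute overall genomic variation to covariates, the binary genotype
matrix is treated as a multivariate response and passed to the community
module's RDA and PERMANOVA (below); strains missing any covariate are
excluded, since shares are only comparable on a common strain set.

# Transmission inference

The chain runs at three scales, all strict inequalities ("less than"):

1. **Semi-clonal groups**: single-linkage components at whole-cohort
   distance < 2500, at least two members; SNPs are re-called on each
   group's own core, since the core grows as the strain set shrinks.
2. **Recombination masking**: for each member, sites differing from the
   group's majority consensus are scanned in sliding 1 kb windows (200 bp
   step). A window is flagged when its SNP count exceeds the upper
   $10^{-4}$ tail of a Poisson with mean (strain-wide SNP rate × window
   length); flagged windows are merged and each merged run is trimmed to
   the strain's SNP extent inside it (which keeps the masked interval
   tight around the dense tract rather than bleeding a window-width into
   the flanks). Masked sites become missing for that strain, so under
   pairwise deletion masking can only decrease distances — a tested
   invariant. This windowed Poisson outlier scan stands in for a full
   branch-wise recombination model: it is transparent, has a closed-form
   false-positive calculation, and serves exactly the thresholding role
   the chain needs. Externally produced masks can be substituted by
   applying any BED of intervals via the same masking path.
3. **Clonal groups**: single-linkage components at post-masking distance
   < 10. A pair at exactly 10 is *not* clonal.

Each clonal group is classified to the most specific metadata stratum
shared (with a non-missing, equal value) by all members — host, family,
community, city, province — then `inter-province` within a country and
`inter-country` otherwise. Groups confined to one host are reported as
single-colonization evidence, not transmission; `cross_host_species`
flags groups spanning host species. The within-host summary pools
post-masking distances among same-host isolate pairs and reports their
median.

# Community statistics

Taxa below 0.005% dataset-wide relative abundance (taxon total over grand
total) are removed; a per-sample variant of the filter is available
behind a flag. The Hellinger transformation
$y' = \sqrt{y/\text{row total}}$ gives every sample unit sum of squares,
making Euclidean machinery valid for zero-inflated compositional data.

Effect sizes come by two routes that agree when the distance is Euclidean
on the same response (a tested identity):

* **tb-RDA**: least-squares projection of the column-centered response on
  dummy-coded covariates; the full-model $R^2$ plus each covariate's
  individual (single-term) $R^2$, with permutation p-values
  $(\#\{stat_{perm} \ge stat_{obs}\}+1)/(B+1)$ under row permutation.
  Individual single-covariate shares are reported (rather than drop-one
  shares) because the question is each host factor's own explanatory
  weight; the shares may therefore sum to more than the full-model $R^2$
  when covariates are correlated.
* **PERMANOVA**: sequential (Type-I) partitioning via traces of
  hat-matrix increments on the Gower-centered inner-product matrix,
  pseudo-F against the residual mean square, p by permuting sample
  identities. Terms are added in the order supplied (province, age,
  longevous district, sex, matching the covariate panel order); on a
  1-dimensional response the pseudo-F reduces exactly to the one-way
  ANOVA F.

Per-taxon group comparisons use the tie-corrected Kruskal–Wallis omnibus
test and all pairwise two-sided Mann–Whitney U tests (exact enumeration
when both groups have ≤ 8 samples and no ties; normal approximation with
continuity correction otherwise), summarized by a compact letter display:
groups share a letter iff no pairwise p < 0.05 separates them. Host ages
bin into 0–17, 18–45, 46–65, > 65.

# The synthetic cohort generator

The generator plants every signal the pipeline detects, with defaults
that *are* the study conditions of the test-suite:

* **Genomes**: star-like evolution — one random 50 kb reference, one
  ancestor per population at `pop_divergence` expected substitutions/site
  (default 2 × `mutation_scale`), independent tip branches at
  `mutation_scale = 0.008`. These values put within-population pairwise
  distances near 800 SNPs (clearly above the 300-SNP pruning threshold,
  as in real cohorts of this species) and between-population distances
  about three times the within-population ones. A full coalescent is
  unnecessary: the pipeline consumes distances and window-local
  similarity, which the star model already provides.
* **Clonal expansions**: each group replaces members by near-copies of a
  shared founder, every member at most ⌊max/2⌋ private mutations, so the
  planted pairwise cap holds by construction.
* **Imports** are *elevated-density mutation tracts* — extra mutations at
  `mutation_scale × (multiplier − 1)` per site inside a random interval —
  not donor-sequence copying, because density is precisely what the
  masking stage detects. Tracts land on clone-group members first
  (cyclically), emulating imports overlaying recent clones; remaining
  tracts go to random strains.
* **Metadata**: age = baseline + effect × causal-allele + Gaussian noise
  (effect 40 years per allele, noise sd 5 — a deliberately strong planted
  signal for power measurement); the causal triplet is three perfectly
  linked alt alleles forced onto a random ~40% carrier subset after all
  other mutations, so the contrast is exactly bi-allelic. Provinces
  follow populations up to a 5% leakage; clone groups share community
  (and, for the first group, family) so planted transmission is
  classifiable.
* **Gene content**: core genes everywhere; population-specific genes at
  98%/2% expected carriage with hard caps guaranteeing the ≥ 95% / ≤ 5%
  contrast; unstructured noise genes at random frequencies.
* **Abundances**: Dirichlet-multinomial counts; the focal taxon's
  Dirichlet weight declines log-linearly in age (slope −0.03/year),
  provinces shift the background composition.

What the generator does **not** emulate: indels and rearrangements, real
linkage structure within populations, donor-identifiable recombination,
assembly/mapping artifacts, compositional sequencing biases beyond the
Dirichlet-multinomial. Passing tests therefore demonstrate correctness of
the inference machinery under the planted model, not robustness to every
artifact of real data.

# Numerical choices and degenerate inputs

* Tie-breaks are explicit everywhere randomness or order could leak in:
  painting ties split chunk mass equally; clustering is deterministic;
  MDS axes are sign-fixed; representative draws take an explicit seed.
* Fisher p-values are capped at 1; log-odds use the Haldane ½ correction
  for display only.
* The Poisson mask threshold uses the strain's own genome-wide SNP rate
  (imports included), making the scan conservative; a strain identical to
  its group consensus is never masked.
* Degenerate inputs fail loudly with typed errors naming the offending
  field, record or strain: unequal FASTA records, non-binary Rtab cells,
  duplicate strain ids, negative ages, all-zero abundance rows, sequences
  shorter than k, distance matrices with no positive MDS eigenvalue.
* Monomorphic loci contribute nothing to θ; populations under two members
  are excluded from Fst with a warning; covariates with zero variance or
  collinear dummy columns are dropped with a message/warning.

# Problem sizes in the simulation studies

The bundled studies run at the sizes the package treats as its standard
evidence: population recovery on 20 cohorts of 3 × 20 strains × 50 kb
(with two planted clone pairs); transmission recovery on 50 cohorts with
two planted clone trios (≤ 8 SNPs) each carrying a 5 kb import at 20× the
background density; GWAS calibration on 200 null and 50 planted-effect
replicates of 150 strains × 1000 variants. These sizes give stable rate
estimates (binomial standard errors of a few percent) while keeping a
full run in the minutes range on one CPU.

# Known limitations

* The painting is window-local nearest-donor copying; it recovers
  population-scale structure but not fine recombination mosaics, and its
  resolution is the window width.
* Silhouette-selected K can under-split nested or unbalanced populations;
  the `weak_structure` flag reports when no K is convincing.
* The mask detects density outliers only: imports at modest multipliers
  or shorter than ~a window go unnoticed; imports from *closer* donors
  that do not raise density are invisible by design.
* The haploid Weir–Cockerham estimator assumes independent loci when
  interpreted inferentially; we report it descriptively.
* r/m-style recombination-to-mutation rate estimation and
  maximum-likelihood phylogenies are out of scope; the package consumes
  or emulates their roles where needed.
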