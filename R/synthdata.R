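## Synthetic cohort generator: genomes with planted population structure,
## clonal expansions and recombination-like imports; metadata with an
## age-associated SNP triplet; pan-genome gene content with
## population-specific genes; covariate-driven abundance tables.

#' Configuration for synthetic cohort simulation
#'
#' Bundles every tunable of the generator. The defaults are the study
#' conditions used throughout the test-suite and the simulation studies:
#' a 50 kb core alignment, three populations of 20 strains, tip branches of
#' 0.008 expected substitutions/site (within-population pairwise distances
#' around 800 SNPs, well above the 300-SNP clonal-pruning threshold) and
#' population ancestors at twice the tip branch length so between-population
#' pairwise distances are about three times the within-population ones.
#'
#' @param seed Integer seed; fixes every output bit-for-bit.
#' @param genome_length Reference length in bp (>= 1000).
#' @param n_populations Number of divergent populations.
#' @param strains_per_population Strains sampled per population.
#' @param mutation_scale Expected substitutions per site on each tip branch.
#' @param pop_divergence Expected substitutions per site on the branch from
#'   the reference ancestor to each population ancestor; default
#'   `2 * mutation_scale`.
#' @param clone_groups List of `c(size, max_pairwise_snps)` pairs; each
#'   plants a clonal expansion whose members differ by at most
#'   `max_pairwise_snps` positions. Groups are placed in populations
#'   round-robin.
#' @param import_tracts List of `c(length_bp, density_multiplier)` pairs.
#'   Each tract adds mutations inside a random interval so the local SNP
#'   density becomes `density_multiplier` times the background
#'   (`mutation_scale`). Tracts are assigned cyclically to clone-group
#'   members first (emulating imports overlaying recent clones), then to
#'   random strains.
#' @param causal_snp_effect Phenotype (age, years) shift per alt allele at
#'   the planted causal triplet.
#' @param causal_carrier_frac Fraction of strains carrying the causal
#'   alt allele triplet.
#' @param age_baseline,age_noise_sd Baseline host age and Gaussian noise sd
#'   (years).
#' @param pop_specific_genes Accessory genes planted per population
#'   (carried by >= 95% of that population, <= 5% elsewhere).
#' @param n_core_genes,n_noise_genes Core genes (present everywhere) and
#'   unstructured accessory genes at random frequencies.
#' @param province_leakage Probability a strain's province is drawn from a
#'   different population's province.
#' @param abundance_effects Named list: `age` (slope of the focal taxon's
#'   log concentration per year; negative means the focal taxon declines
#'   with age) and `province` (sd of province-specific log-abundance
#'   offsets applied to non-focal taxa).
#' @param n_taxa Number of taxa in the abundance table.
#' @param reads_per_sample Sequencing depth for the Dirichlet-multinomial
#'   abundance draw.
#' @param dirichlet_conc Total Dirichlet concentration (controls
#'   overdispersion).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 50000L,
                       n_populations = 3L,
                       strains_per_population = 20L,
                       mutation_scale = 0.008,
                       pop_divergence = NULL,
                       clone_groups = list(),
                       import_tracts = list(),
                       causal_snp_effect = 40,
                       causal_carrier_frac = 0.4,
                       age_baseline = 30,
                       age_noise_sd = 5,
                       pop_specific_genes = 5L,
                       n_core_genes = 100L,
                       n_noise_genes = 50L,
                       province_leakage = 0.05,
                       abundance_effects = list(age = -0.03, province = 0.5),
                       n_taxa = 20L,
                       reads_per_sample = 50000L,
                       dirichlet_conc = 200) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_populations = as.integer(n_populations),
              strains_per_population = as.integer(strains_per_population),
              mutation_scale = mutation_scale,
              pop_divergence = pop_divergence %||% (2 * mutation_scale),
              clone_groups = clone_groups, import_tracts = import_tracts,
              causal_snp_effect = causal_snp_effect,
              causal_carrier_frac = causal_carrier_frac,
              age_baseline = age_baseline, age_noise_sd = age_noise_sd,
              pop_specific_genes = as.integer(pop_specific_genes),
              n_core_genes = as.integer(n_core_genes),
              n_noise_genes = as.integer(n_noise_genes),
              province_leakage = province_leakage,
              abundance_effects = abundance_effects,
              n_taxa = as.integer(n_taxa),
              reads_per_sample = as.integer(reads_per_sample),
              dirichlet_conc = dirichlet_conc)
  if (cfg$genome_length < 1000L) stop_config("genome_length", "must be >= 1000")
  if (cfg$n_populations < 1L) stop_config("n_populations", "must be >= 1")
  if (cfg$strains_per_population < 1L)
    stop_config("strains_per_population", "must be >= 1")
  if (cfg$mutation_scale < 0) stop_config("mutation_scale", "must be >= 0")
  if (cfg$pop_divergence < 0) stop_config("pop_divergence", "must be >= 0")
  for (g in cfg$clone_groups) {
    if (length(g) != 2L || g[1L] < 2L || g[2L] < 0)
      stop_config("clone_groups", "each entry must be c(size >= 2, max_snps >= 0)")
    if (g[1L] > cfg$strains_per_population)
      stop_config("clone_groups", "clone size ", g[1L],
                  " exceeds strains_per_population ", cfg$strains_per_population)
  }
  for (tr in cfg$import_tracts) {
    if (length(tr) != 2L || tr[1L] < 1 || tr[2L] < 1)
      stop_config("import_tracts",
                  "each entry must be c(length_bp >= 1, multiplier >= 1)")
    if (tr[1L] > cfg$genome_length)
      stop_config("import_tracts", "tract longer than genome")
  }
  if (cfg$province_leakage < 0 || cfg$province_leakage > 1)
    stop_config("province_leakage", "must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

## mutate `m` random positions of an integer-coded genome (values 1..4)
mutate_genome <- function(g, m) {
  L <- length(g)
  m <- min(m, L)
  if (m == 0L) return(g)
  pos <- sample.int(L, m)
  g[pos] <- ((g[pos] - 1L + sample(1:3, m, replace = TRUE)) %% 4L) + 1L
  g
}

#' Simulate reference-coordinate genomes with planted structure
#'
#' Evolution is star-like: a random reference ancestor spawns one ancestor
#' per population (branch length `pop_divergence`), and each strain hangs
#' off its population ancestor by an independent tip branch
#' (`mutation_scale`). Clonal expansions replace selected strains by
#' near-copies of a shared founder; import tracts overlay extra mutations
#' at `mutation_scale * (multiplier - 1)` per site inside a random
#' interval; a causal triplet of perfectly linked alt alleles is planted in
#' a random subset of strains (the carriers).
#'
#' @param config A [sim_config()].
#' @return A list with elements `genomes` (an `aligned_genomes` object,
#'   reference row included) and `truth` (a `sim_truth` list with
#'   `population_of`, `clone_group_of`, `import_intervals` (0-based
#'   half-open bp), `causal_sites`, `causal_carriers`,
#'   `covariate_effects`).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  npop <- config$n_populations
  nper <- config$strains_per_population

  ref <- sample.int(4L, L, replace = TRUE)
  strain_ids <- as.vector(t(outer(seq_len(npop), seq_len(nper),
                                  function(p, s) sprintf("P%dS%02d", p, s))))
  pop_of <- rep(paste0("pop", seq_len(npop)), each = nper)
  names(pop_of) <- strain_ids

  ancestors <- lapply(seq_len(npop), function(p)
    mutate_genome(ref, stats::rpois(1L, config$pop_divergence * L)))

  genomes <- matrix(0L, nrow = length(strain_ids), ncol = L,
                    dimnames = list(strain_ids, NULL))
  for (i in seq_along(strain_ids)) {
    p <- (i - 1L) %/% nper + 1L
    genomes[i, ] <- mutate_genome(ancestors[[p]],
                                  stats::rpois(1L, config$mutation_scale * L))
  }

  ## clonal expansions: groups placed in populations round-robin, members
  ## overwrite the first not-yet-clonal strains of that population
  clone_of <- stats::setNames(rep(NA_character_, length(strain_ids)), strain_ids)
  if (length(config$clone_groups) > 0L) {
    for (gi in seq_along(config$clone_groups)) {
      size <- as.integer(config$clone_groups[[gi]][1L])
      maxsnp <- as.integer(config$clone_groups[[gi]][2L])
      p <- (gi - 1L) %% npop + 1L
      pool <- which(pop_of == paste0("pop", p) & is.na(clone_of))
      if (length(pool) < size)
        stop_config("clone_groups", "population ", p,
                    " has too few free strains for a clone group of size ", size)
      members <- pool[seq_len(size)]
      founder <- mutate_genome(ancestors[[p]],
                               stats::rpois(1L, config$mutation_scale * L))
      half <- maxsnp %/% 2L
      for (m in members)
        genomes[m, ] <- mutate_genome(founder, sample.int(half + 1L, 1L) - 1L)
      clone_of[members] <- paste0("CG", gi)
    }
  }

  ## imports: elevated-density mutation tracts; clone members first
  imports <- stats::setNames(vector("list", length(strain_ids)), strain_ids)
  if (length(config$import_tracts) > 0L) {
    clone_members <- which(!is.na(clone_of))
    others <- setdiff(seq_along(strain_ids), clone_members)
    targets <- integer(length(config$import_tracts))
    for (ti in seq_along(config$import_tracts)) {
      targets[ti] <- if (ti <= length(clone_members)) clone_members[ti]
                     else sample_one(others)
    }
    for (ti in seq_along(config$import_tracts)) {
      len <- as.integer(config$import_tracts[[ti]][1L])
      mult <- config$import_tracts[[ti]][2L]
      s <- targets[ti]
      start <- sample.int(L - len + 1L, 1L)             # 1-based start
      extra <- stats::rpois(1L, len * config$mutation_scale * (mult - 1))
      if (extra > 0L) {
        pos <- start - 1L + sample.int(len, min(extra, len))
        genomes[s, pos] <- ((genomes[s, pos] - 1L +
                             sample(1:3, length(pos), replace = TRUE)) %% 4L) + 1L
      }
      imports[[s]] <- rbind(imports[[s]],
                            c(start - 1L, start - 1L + len))  # 0-based half-open
    }
  }

  ## causal triplet: force ref allele everywhere, alt in carriers, done last
  ## so no other mutation can disturb the bi-allelic contrast
  causal_sites <- integer(0)
  carriers <- character(0)
  if (config$causal_snp_effect != 0 || config$causal_carrier_frac > 0) {
    causal_sites <- sort(sample.int(L, 3L))
    n_car <- max(1L, round(config$causal_carrier_frac * length(strain_ids)))
    carriers <- sort(sample(strain_ids, min(n_car, length(strain_ids) - 1L)))
    for (pos in causal_sites) {
      refb <- ref[pos]
      altb <- (refb %% 4L) + 1L
      genomes[, pos] <- refb
      genomes[carriers, pos] <- altb
    }
  }

  mat <- rbind(matrix(DNA_BASES[ref], nrow = 1L,
                      dimnames = list("reference", NULL)),
               matrix(DNA_BASES[genomes], nrow = nrow(genomes),
                      dimnames = list(strain_ids, NULL)))
  truth <- structure(list(
    population_of = pop_of,
    clone_group_of = clone_of,
    import_intervals = imports[!vapply(imports, is.null, logical(1))],
    causal_sites = causal_sites,
    causal_carriers = carriers,
    gene_population_map = NULL,
    covariate_effects = list(age = config$causal_snp_effect)),
    class = "sim_truth")
  list(genomes = aligned_genomes(mat, ref_id = "reference"), truth = truth)
}

#' Simulate strain metadata and accessory gene content
#'
#' Host age is `age_baseline + causal_snp_effect * carrier + N(0,
#' age_noise_sd)`, truncated at 0; province (and city) follow the strain's
#' population up to `province_leakage`; clone-group members share a
#' community (and, for the first group, a family) to make planted
#' transmission classifiable. Gene content is core genes everywhere,
#' population-specific genes at 98%/2% carriage in/outside their
#' population, plus unstructured noise genes; each gene gets a COG letter,
#' a KEGG pathway and a reference interval for SNP annotation.
#'
#' @param truth `sim_truth` from [simulate_genomes()].
#' @param config The same [sim_config()].
#' @return List with `metadata` (data.frame, one row per strain),
#'   `genes` (gene x strain 0/1 matrix), `annotation` (data.frame:
#'   gene_id, cog, kegg, start, end) and the updated `truth`
#'   (gene_population_map filled in).
#' @export
simulate_metadata_and_genes <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  ids <- names(truth$population_of)
  n <- length(ids)
  npop <- config$n_populations
  pops <- paste0("pop", seq_len(npop))

  carrier <- as.integer(ids %in% truth$causal_carriers)
  age <- config$age_baseline + config$causal_snp_effect * carrier +
    stats::rnorm(n, 0, config$age_noise_sd)
  age <- pmax(age, 0)

  provinces <- paste0("province", seq_len(npop))
  own <- match(truth$population_of, pops)
  leak <- stats::runif(n) < config$province_leakage & npop > 1L
  prov_idx <- own
  if (any(leak)) prov_idx[leak] <- vapply(own[leak], function(p)
    sample_one(setdiff(seq_len(npop), p)), integer(1))
  province <- provinces[prov_idx]
  city <- paste0(province, "_city", 1L + (seq_len(n) %% 2L))

  community <- rep(NA_character_, n)
  family <- rep(NA_character_, n)
  host_species <- rep("human", n)
  cg <- truth$clone_group_of
  for (g in unique(stats::na.omit(cg))) {
    m <- which(!is.na(cg) & cg == g)
    community[m] <- paste0("community_", g)
    city[m] <- city[m[1L]]
    province[m] <- province[m[1L]]
    if (g == "CG1" && length(m) > 1L) family[m] <- paste0("family_", g)
  }

  metadata <- data.frame(
    strain_id = ids,
    sample_id = paste0("sample_", ids),
    country = "China",
    province = province,
    city = city,
    community_id = community,
    family_id = family,
    host_species = host_species,
    age = round(age, 2),
    sex = sample(c("male", "female"), n, replace = TRUE),
    longevous_district = stats::runif(n) < 0.3,
    stringsAsFactors = FALSE)

  ## pan-genome
  core_ids <- sprintf("core_%04d", seq_len(config$n_core_genes))
  ps_ids <- character(0)
  gene_pop <- character(0)
  rows <- list()
  for (gid in core_ids) rows[[gid]] <- rep(1L, n)
  for (p in seq_len(npop)) {
    for (k in seq_len(config$pop_specific_genes)) {
      gid <- sprintf("popgene_p%d_%02d", p, k)
      ps_ids <- c(ps_ids, gid)
      gene_pop <- c(gene_pop, pops[p])
      inpop <- truth$population_of == pops[p]
      n_in <- sum(inpop); n_out <- sum(!inpop)
      pres <- integer(n)
      ## carriage 98%/2% in expectation, hard-capped so the >= 95% /
      ## <= 5% contrast holds by construction
      k_absent <- min(stats::rbinom(1L, n_in, 0.02), floor(0.05 * n_in))
      k_stray <- min(stats::rbinom(1L, n_out, 0.02), floor(0.05 * n_out))
      pres[inpop] <- 1L
      if (k_absent > 0L)
        pres[which(inpop)[sample.int(n_in, k_absent)]] <- 0L
      if (k_stray > 0L)
        pres[which(!inpop)[sample.int(n_out, k_stray)]] <- 1L
      rows[[gid]] <- pres
    }
  }
  noise_ids <- sprintf("noise_%04d", seq_len(config$n_noise_genes))
  for (gid in noise_ids)
    rows[[gid]] <- stats::rbinom(n, 1L, stats::runif(1L, 0.1, 0.9))
  genes <- do.call(rbind, rows)
  colnames(genes) <- ids
  storage.mode(genes) <- "integer"

  all_ids <- rownames(genes)
  glen <- max(1L, config$genome_length %/% length(all_ids))
  starts <- (seq_along(all_ids) - 1L) * glen + 1L
  annotation <- data.frame(
    gene_id = all_ids,
    cog = sample(cog_categories(), length(all_ids), replace = TRUE),
    kegg = sprintf("ko%05d", sample.int(200L, length(all_ids), replace = TRUE)),
    start = starts,
    end = pmin(starts + glen - 1L, config$genome_length),
    stringsAsFactors = FALSE)

  truth$gene_population_map <- stats::setNames(gene_pop, ps_ids)
  list(metadata = metadata, genes = genes, annotation = annotation,
       truth = truth)
}

## one Dirichlet draw per row of an alpha matrix
rdirichlet_rows <- function(alpha) {
  x <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow = nrow(alpha))
  x / rowSums(x)
}

#' Simulate a sample x taxon abundance table
#'
#' Dirichlet-multinomial counts for one focal taxon (whose expected relative
#' abundance declines monotonically with host age at the configured log-slope)
#' plus unstructured background taxa whose baselines shift by province.
#'
#' @param config A [sim_config()].
#' @param metadata Metadata with `sample_id`, `age` and `province` columns
#'   (from [simulate_metadata_and_genes()]).
#' @return List with `counts` (sample x taxon integer matrix, rownames =
#'   sample ids; first column `focal_taxon`) and `relative` (rows summing
#'   to 1).
#' @export
simulate_abundance <- function(config, metadata) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("sample_id", "age", "province") %in% names(metadata)))
    stop_param("metadata must have sample_id, age and province columns")
  set.seed(config$seed + 2000L)
  n <- nrow(metadata)
  K <- max(1L, config$n_taxa)
  age_slope <- config$abundance_effects$age %||% 0
  prov_sd <- config$abundance_effects$province %||% 0

  provs <- unique(metadata$province)
  prov_off <- matrix(stats::rnorm(length(provs) * (K - 1L), 0, prov_sd),
                     nrow = length(provs),
                     dimnames = list(provs, NULL))
  base <- matrix(rep(stats::runif(K - 1L, 0.5, 1.5), each = n), nrow = n)
  logalpha_bg <- log(base) + prov_off[metadata$province, , drop = FALSE]
  age_c <- metadata$age - mean(metadata$age)
  logalpha_focal <- log(1.5) + age_slope * age_c
  alpha <- cbind(exp(logalpha_focal), exp(logalpha_bg))
  alpha <- alpha / rowSums(alpha) * config$dirichlet_conc

  pr <- rdirichlet_rows(alpha)
  counts <- t(vapply(seq_len(n), function(i)
    stats::rmultinom(1L, config$reads_per_sample, pr[i, ])[, 1L],
    integer(K)))
  taxa <- c("focal_taxon", sprintf("taxon_%02d", seq_len(K - 1L)))
  dimnames(counts) <- list(metadata$sample_id, taxa)
  list(counts = counts, relative = counts / rowSums(counts))
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [simulate_genomes()],
#' [simulate_metadata_and_genes()] and [simulate_abundance()].
#'
#' @param config A [sim_config()].
#' @return List: `genomes`, `metadata`, `genes`, `annotation`, `abundance`,
#'   `truth`.
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genomes(config)
  mg <- simulate_metadata_and_genes(g$truth, config)
  ab <- simulate_abundance(config, mg$metadata)
  list(genomes = g$genomes, metadata = mg$metadata, genes = mg$genes,
       annotation = mg$annotation, abundance = ab, truth = mg$truth)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes the aligned FASTA, metadata TSV, gene presence/absence Rtab,
#' annotation TSV, abundance TSV and a JSON ground-truth record.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genomes = file.path(dir, "genomes.fasta"),
             metadata = file.path(dir, "metadata.tsv"),
             genes = file.path(dir, "gene_presence_absence.Rtab"),
             annotation = file.path(dir, "annotation.tsv"),
             abundance = file.path(dir, "abundance.tsv"),
             truth = file.path(dir, "truth.json"))
  write_aligned_fasta(cohort$genomes, paths[["genomes"]])
  write_metadata(cohort$metadata, paths[["metadata"]])
  write_rtab(cohort$genes, paths[["genes"]])
  utils::write.table(cohort$annotation, paths[["annotation"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_abundance(cohort$abundance$relative, paths[["abundance"]])
  truth <- unclass(cohort$truth)
  truth$import_intervals <- lapply(truth$import_intervals, function(m)
    unname(as.data.frame(m)))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(paths)
}
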