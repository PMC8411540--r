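## Simulation studies: end-to-end recovery and calibration experiments run
## on the synthetic cohort generator. Each returns per-replicate
## measurements so callers can summarize rates however they need.

#' Population-recovery study: prune, paint, cluster vs planted truth
#'
#' For each seed, simulates the standard cohort (three populations of 20
#' strains on 50 kb with two planted clone pairs), calls core SNPs, prunes
#' clonal pairs at < 300 SNPs, paints the pruned set, clusters the
#' co-ancestry matrix, and scores the adjusted Rand index of the inferred
#' populations against the planted labels of the retained
#' representatives.
#'
#' @param n_seeds Number of replicate cohorts (default 20).
#' @param base_seed First seed (replicate i uses `base_seed + i - 1`).
#' @param window_snps Painting window (default 100 SNP columns).
#' @param k_range Candidate population counts (default 2:6).
#' @return data.frame: `seed`, `n_representatives`, `K`, `ari`.
#' @export
sim_study_population_recovery <- function(n_seeds = 20L, base_seed = 1L,
                                          window_snps = 100L,
                                          k_range = 2:6) {
  out <- lapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(seed = base_seed + i - 1L,
                      clone_groups = list(c(2L, 8L), c(2L, 8L)))
    sim <- simulate_genomes(cfg)
    snps <- call_core_snps(sim$genomes)
    d <- pairwise_snp_distances(snps)
    pruned <- prune_clonal(d, threshold = 300L, seed = cfg$seed)
    reps <- pruned$representatives
    painting <- paint_chromosomes(subset_snps(snps, reps), window_snps)
    assignment <- cluster_populations(painting, k_range)
    ari <- adjusted_rand_index(assignment$labels[reps],
                               sim$truth$population_of[reps])
    data.frame(seed = cfg$seed, n_representatives = length(reps),
               K = assignment$K, ari = ari)
  })
  do.call(rbind, out)
}

## mask truth comparison: returns cohort-level base counts
mask_confusion <- function(scgs, truth, genome_length) {
  tp <- fp <- tract_bases <- nontract_bases <- 0
  strains <- unlist(lapply(scgs, function(s) s$members))
  for (s in strains) {
    tr <- truth$import_intervals[[s]]
    tr1 <- if (is.null(tr)) NULL else
      cbind(tr[, 1L] + 1L, tr[, 2L])               # to 1-based inclusive
    tb <- interval_bases(tr1)
    tract_bases <- tract_bases + tb
    nontract_bases <- nontract_bases + genome_length - tb
    mk <- NULL
    for (scg in scgs) if (s %in% scg$members)
      mk <- scg$mask_intervals[[s]]
    if (is.null(mk)) next
    covered <- logical(genome_length)
    for (r in seq_len(nrow(mk))) covered[mk[r, 1L]:mk[r, 2L]] <- TRUE
    in_tract <- logical(genome_length)
    if (!is.null(tr1)) for (r in seq_len(nrow(tr1)))
      in_tract[tr1[r, 1L]:tr1[r, 2L]] <- TRUE
    tp <- tp + sum(covered & in_tract)
    fp <- fp + sum(covered & !in_tract)
  }
  c(tp = tp, fp = fp, tract = tract_bases, nontract = nontract_bases)
}

#' Transmission-recovery study: SCG, masking, CG vs planted clones
#'
#' For each seed, simulates the standard cohort with two planted clone
#' trios (max 8 pairwise SNPs) whose members each carry a 5 kb import at
#' 20x the background SNP density, then runs the chain: whole-cohort
#' distances, SCGs (< 2500) with per-group SNP re-calling, windowed
#' Poisson recombination masking, CGs (< 10). Scores exact recovery of
#' the planted clone membership plus base-level masking sensitivity and
#' false-positive rate against the planted tracts.
#'
#' @param n_seeds Number of replicate cohorts (default 50).
#' @param base_seed First seed.
#' @return data.frame: `seed`, `exact` (planted clone groups recovered
#'   exactly, as sets), `sensitivity`, `fpr`.
#' @export
sim_study_transmission_recovery <- function(n_seeds = 50L, base_seed = 1L) {
  out <- lapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(seed = base_seed + i - 1L,
                      clone_groups = list(c(3L, 8L), c(3L, 8L)),
                      import_tracts = rep(list(c(5000, 20)), 6L))
    sim <- simulate_genomes(cfg)
    snps <- call_core_snps(sim$genomes)
    d <- pairwise_snp_distances(snps)
    scgs <- find_scgs(d, threshold = 2500L, genomes = sim$genomes)
    scgs <- lapply(scgs, mask_recombination)
    cgs <- unlist(lapply(scgs, find_cgs), recursive = FALSE)
    found <- lapply(cgs, function(cg) sort(cg$members))
    planted <- split(names(sim$truth$clone_group_of),
                     sim$truth$clone_group_of)
    planted <- lapply(planted, sort)
    exact <- length(found) == length(planted) &&
      all(vapply(planted, function(p)
        any(vapply(found, identical, logical(1), y = p)), logical(1)))
    conf <- mask_confusion(scgs, sim$truth, cfg$genome_length)
    data.frame(seed = cfg$seed, exact = exact,
               sensitivity = unname(conf["tp"] / conf["tract"]),
               fpr = unname(conf["fp"] / conf["nontract"]))
  })
  do.call(rbind, out)
}

#' GWAS calibration study: family-wise error and power
#'
#' Null replicates draw `n_variants` independent binary variants (carriage
#' 5-50%) and an independent Gaussian phenotype, run the fixed-effect scan
#' and record whether any variant clears the Bonferroni threshold
#' (family-wise error). Power replicates add one causal variant shifting
#' the phenotype by `effect` per allele over Gaussian noise `noise_sd` and
#' record whether that variant is recovered.
#'
#' @param n_null Null replicates (default 200).
#' @param n_power Power replicates (default 50).
#' @param n Strains per replicate (default 150).
#' @param n_variants Variants per replicate (default 1000).
#' @param effect Planted phenotype shift (default 40).
#' @param noise_sd Phenotype noise sd (default 5).
#' @param base_seed First seed.
#' @return List: `fwer`, `power`, `n_null`, `n_power`.
#' @export
sim_study_gwas_calibration <- function(n_null = 200L, n_power = 50L,
                                       n = 150L, n_variants = 1000L,
                                       effect = 40, noise_sd = 5,
                                       base_seed = 1L) {
  draw_variants <- function(n, m) {
    af <- stats::runif(m, 0.05, 0.5)
    v <- matrix(stats::rbinom(n * m, 1L, rep(af, each = n)), nrow = n,
                dimnames = list(paste0("s", seq_len(n)),
                                paste0("v", seq_len(m))))
    filter_variants(v, 0.01, 0.99)
  }
  null_hit <- logical(n_null)
  for (b in seq_len(n_null)) {
    set.seed(base_seed + b - 1L)
    v <- draw_variants(n, n_variants)
    y <- stats::rnorm(n, 30, 10)
    names(y) <- rownames(v)
    res <- phenotype_gwas(v, y)
    null_hit[b] <- any(res$significant, na.rm = TRUE)
  }
  power_hit <- logical(n_power)
  for (b in seq_len(n_power)) {
    set.seed(base_seed + 100000L + b)
    v <- draw_variants(n, n_variants)
    causal <- stats::rbinom(n, 1L, 0.4)
    v <- cbind(v, causal = causal)
    y <- 20 + effect * causal + stats::rnorm(n, 0, noise_sd)
    names(y) <- rownames(v)
    res <- phenotype_gwas(v, y)
    power_hit[b] <- res$significant[res$variant == "causal"]
  }
  list(fwer = mean(null_hit), power = mean(power_hit),
       n_null = n_null, n_power = n_power)
}
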