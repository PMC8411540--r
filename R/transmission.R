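## Transmission inference: semi-clonal groups (SCG, single linkage at
## < 2500 core SNPs) with per-group SNP re-calling, windowed Poisson
## recombination masking against the group consensus, clonal groups (CG,
## post-masking distance < 10) and metadata-level transmission
## classification.

single_linkage_groups <- function(d, threshold) {
  adj <- as.matrix(d) < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(rownames(as.matrix(d)), comp)
  Filter(function(m) length(m) >= 2L, unname(groups))
}

#' Find semi-clonal groups (SCGs)
#'
#' Single-linkage connected components of the graph joining strains at
#' pairwise SNP distance strictly below `threshold`; components of at
#' least two members become SCGs. When the genome set is supplied, SNPs
#' are re-called on each group's own core (the core grows as the strain
#' set shrinks, so group-internal distances are computed on the group's
#' own site set).
#'
#' @param d Whole-cohort pairwise SNP distance matrix.
#' @param threshold SCG distance threshold (default 2500, strict `<`).
#' @param genomes Optional `aligned_genomes` for per-group SNP re-calling.
#' @param core_fraction Core fraction for the re-call (default 1).
#' @return List of `scg` objects: `id`, `members`, `snps` (re-called
#'   `snp_matrix`, or `NULL` when no genomes given), `distances`.
#' @export
find_scgs <- function(d, threshold = 2500L, genomes = NULL,
                      core_fraction = 1.0) {
  groups <- single_linkage_groups(d, threshold)
  out <- lapply(seq_along(groups), function(i) {
    members <- groups[[i]]
    snps <- NULL
    dist_sub <- as.matrix(d)[members, members, drop = FALSE]
    if (!is.null(genomes)) {
      snps <- call_core_snps(subset_genomes(genomes, members),
                             core_fraction = core_fraction)
      dist_sub <- pairwise_snp_distances(snps)
    }
    structure(list(id = paste0("SCG", i), members = members, snps = snps,
                   distances = dist_sub, mask_intervals = NULL,
                   masked_snps = NULL),
              class = "scg")
  })
  out
}

#' @export
print.scg <- function(x, ...) {
  cat(x$id, ":", length(x$members), "members,",
      if (is.null(x$snps)) "no re-called SNPs" else
        paste(length(x$snps$pos), "re-called sites"),
      if (is.null(x$mask_intervals)) "" else "(masked)", "\n")
  invisible(x)
}

## majority-call consensus genotype (ties -> reference allele 0)
scg_consensus <- function(geno) {
  ones <- colSums(geno == 1L, na.rm = TRUE)
  zeros <- colSums(geno == 0L, na.rm = TRUE)
  as.integer(ones > zeros)
}

#' Mask putative recombination imports within an SCG
#'
#' For every member strain, the sites where it differs from the group
#' consensus are scanned in sliding windows of `window_bp` (step
#' `step_bp`); windows whose SNP count exceeds the upper `tail_p` tail of
#' a Poisson with mean `strain-wide SNP rate x window_bp` are flagged,
#' overlapping flagged windows are merged, and each merged run is trimmed
#' to the strain's SNP extent inside it. Masked sites are set to missing
#' for that strain, so (under pairwise deletion) no pairwise distance can
#' increase.
#'
#' @param scg An `scg` with re-called SNPs (>= 2 members).
#' @param window_bp Window width in bp (default 1000).
#' @param step_bp Window step in bp (default 200).
#' @param tail_p Poisson upper-tail level (default 1e-4).
#' @return The `scg` with `masked_snps` (a `snp_matrix`) and
#'   `mask_intervals` (named per-strain list of 1-based inclusive
#'   `[start, end]` matrices) filled in, and `distances` recomputed on the
#'   masked matrix.
#' @export
mask_recombination <- function(scg, window_bp = 1000L, step_bp = 200L,
                               tail_p = 1e-4) {
  stopifnot(inherits(scg, "scg"))
  if (length(scg$members) < 2L) stop_param("SCG must have >= 2 members")
  if (is.null(scg$snps))
    stop_param("SCG has no re-called SNPs; run find_scgs() with genomes")
  snps <- scg$snps
  L <- snps$genome_length
  cons <- scg_consensus(snps$geno)
  geno <- snps$geno
  starts <- unique(c(seq.int(1L, max(1L, L - window_bp + 1L), by = step_bp),
                     max(1L, L - window_bp + 1L)))
  masks <- stats::setNames(vector("list", nrow(geno)), rownames(geno))
  for (s in rownames(geno)) {
    diffs <- snps$pos[which(geno[s, ] != cons & !is.na(geno[s, ]))]
    if (length(diffs) == 0L) { masks[[s]] <- NULL; next }
    lambda <- length(diffs) / L * window_bp
    cutoff <- stats::qpois(1 - tail_p, lambda)
    sorted <- sort(diffs)
    counts <- findInterval(starts + window_bp - 1L, sorted) -
      findInterval(starts - 1L, sorted)
    hot <- which(counts > cutoff)
    if (length(hot) == 0L) { masks[[s]] <- NULL; next }
    iv <- merge_intervals(cbind(starts[hot],
                                pmin(starts[hot] + window_bp - 1L, L)))
    ## trim each run to the strain's SNP extent inside it
    for (r in seq_len(nrow(iv))) {
      inside <- sorted[sorted >= iv[r, 1L] & sorted <= iv[r, 2L]]
      iv[r, ] <- c(min(inside), max(inside))
    }
    colnames(iv) <- c("start", "end")
    masks[[s]] <- iv
    for (r in seq_len(nrow(iv)))
      geno[s, snps$pos >= iv[r, 1L] & snps$pos <= iv[r, 2L]] <- NA_integer_
  }
  scg$masked_snps <- new_snp_matrix(snps$pos, snps$ref, snps$alt, geno,
                                    snps$ref_id, L)
  scg$mask_intervals <- masks[!vapply(masks, is.null, logical(1))]
  scg$distances <- pairwise_snp_distances(scg$masked_snps)
  scg
}

#' Find clonal groups (CGs) within a masked SCG
#'
#' Single-linkage components at post-masking pairwise distance strictly
#' below `threshold` (a pair at exactly the threshold is not clonal).
#'
#' @param scg An `scg`, typically after [mask_recombination()] (falls back
#'   to unmasked distances otherwise).
#' @param threshold CG distance threshold (default 10, strict `<`).
#' @return List of `clonal_group` objects: `id`, `scg_id`, `members`,
#'   `max_distance`, `distances`.
#' @export
find_cgs <- function(scg, threshold = 10L) {
  stopifnot(inherits(scg, "scg"))
  d <- scg$distances
  groups <- single_linkage_groups(d, threshold)
  lapply(seq_along(groups), function(i) {
    m <- groups[[i]]
    structure(list(id = paste0(scg$id, "_CG", i), scg_id = scg$id,
                   members = m,
                   max_distance = max(d[m, m]),
                   distances = d[m, m, drop = FALSE]),
              class = "clonal_group")
  })
}

#' @export
print.clonal_group <- function(x, ...) {
  cat(x$id, ":", length(x$members),
      "members, max post-masking distance", x$max_distance, "\n")
  invisible(x)
}

## metadata strata from most to least specific
transmission_strata <- c(host = "sample_id", family = "family_id",
                         community = "community_id", city = "city",
                         province = "province")

#' Classify the transmission level of a clonal group
#'
#' The level is the most specific metadata stratum (host, family,
#' community, city, province, country) shared -- with a non-missing equal
#' value -- by all members. A CG confined to one host is reported as
#' single-colonization evidence (`is_transmission = FALSE`), not a
#' transmission event. `cross_host_species` is TRUE iff members span host
#' species.
#'
#' @param cg A `clonal_group`.
#' @param metadata Metadata data.frame covering all members.
#' @return data.frame row: `cg`, `level`, `n_members`,
#'   `cross_host_species`, `is_transmission`.
#' @export
classify_transmission <- function(cg, metadata) {
  stopifnot(inherits(cg, "clonal_group"))
  missing <- setdiff(cg$members, metadata$strain_id)
  if (length(missing) > 0L)
    stop_param("member(s) missing from metadata: ",
               paste(missing, collapse = ", "))
  md <- metadata[match(cg$members, metadata$strain_id), , drop = FALSE]
  shared <- function(col) {
    v <- md[[col]]
    !is.null(v) && !anyNA(v) && length(unique(v)) == 1L
  }
  level <- "inter-country"
  for (nm in names(transmission_strata)) {
    col <- transmission_strata[[nm]]
    if (col %in% names(md) && shared(col)) {
      level <- paste0("intra-", nm)
      break
    }
  }
  if (level == "inter-country" && "country" %in% names(md) &&
      shared("country"))
    level <- "inter-province"
  data.frame(cg = cg$id, level = level, n_members = length(cg$members),
             cross_host_species = length(unique(md$host_species)) > 1L,
             is_transmission = level != "intra-host")
}

#' Median within-host pairwise distance across clonal groups
#'
#' Pools, over all clonal groups, the post-masking pairwise distances
#' among isolate pairs that share a host (sample), and summarizes them.
#'
#' @param cgs List of `clonal_group` objects.
#' @param metadata Metadata with `strain_id` and `sample_id`.
#' @return List: `n_pairs`, `median` (NA when no multi-isolate host).
#' @export
intra_host_summary <- function(cgs, metadata) {
  vals <- numeric(0)
  for (cg in cgs) {
    md <- metadata[match(cg$members, metadata$strain_id), , drop = FALSE]
    for (smp in unique(md$sample_id)) {
      m <- cg$members[md$sample_id == smp]
      if (length(m) >= 2L) {
        sub <- cg$distances[m, m, drop = FALSE]
        vals <- c(vals, sub[lower.tri(sub)])
      }
    }
  }
  list(n_pairs = length(vals),
       median = if (length(vals) > 0L) stats::median(vals) else NA_real_)
}
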