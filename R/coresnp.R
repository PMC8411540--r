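## Bi-allelic core SNP calling from reference-coordinate genomes, pairwise
## SNP distances with pairwise deletion of missing calls, per-group
## diversity summaries and neighbor-joining trees.

new_snp_matrix <- function(pos, ref, alt, geno, ref_id, genome_length) {
  stopifnot(length(pos) == ncol(geno), length(ref) == length(pos),
            length(alt) == length(pos))
  if (is.unsorted(pos, strictly = TRUE) && length(pos) > 1L)
    stop_param("SNP positions must be strictly increasing")
  structure(list(pos = as.integer(pos), ref = as.character(ref),
                 alt = as.character(alt), geno = geno,
                 ref_id = ref_id, genome_length = as.integer(genome_length)),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat("snp_matrix:", nrow(x$geno), "strains x", length(x$pos),
      "bi-allelic core sites (reference", x$ref_id, ",",
      x$genome_length, "bp)\n")
  invisible(x)
}

#' Subset a SNP matrix by strain
#' @param snps A `snp_matrix`.
#' @param strains Strain ids to keep.
#' @return A `snp_matrix` restricted to those strains (site set unchanged).
#' @export
subset_snps <- function(snps, strains) {
  missing <- setdiff(strains, rownames(snps$geno))
  if (length(missing) > 0L)
    stop_param("unknown strain(s): ", paste(missing, collapse = ", "))
  new_snp_matrix(snps$pos, snps$ref, snps$alt,
                 snps$geno[strains, , drop = FALSE],
                 snps$ref_id, snps$genome_length)
}

#' Call bi-allelic core SNPs
#'
#' A column belongs to the core iff the fraction of records (strains plus
#' reference) with an unambiguous `A/C/G/T` base is at least
#' `core_fraction`. Among core columns, variable columns with exactly two
#' observed bases become sites (columns with three or more observed bases
#' are dropped); remaining `N`/`-` calls at retained sites become missing.
#' Allele 0 is the reference base, allele 1 the alternative.
#'
#' @param genomes An `aligned_genomes` object with at least two
#'   non-reference strains.
#' @param core_fraction Minimum fraction of unambiguous calls for a column
#'   to be core, in (0, 1]; default 1 (strict core).
#' @return A `snp_matrix`: positions (1-based), ref/alt alleles, and a
#'   strains x sites genotype matrix over `0` (ref), `1` (alt), `NA`.
#' @export
call_core_snps <- function(genomes, core_fraction = 1.0) {
  stopifnot(inherits(genomes, "aligned_genomes"))
  if (core_fraction <= 0 || core_fraction > 1)
    stop_param("core_fraction must be in (0, 1]")
  ids <- strain_ids(genomes)
  if (length(ids) < 2L) stop_param("need at least 2 non-reference strains")
  code <- matrix(match(genomes$mat, DNA_BASES), nrow = nrow(genomes$mat),
                 dimnames = dimnames(genomes$mat))
  obs_frac <- colMeans(!is.na(code))
  counts <- vapply(1:4, function(b) colSums(code == b, na.rm = TRUE),
                   numeric(ncol(code)))          # L x 4
  nbases <- rowSums(counts > 0L)
  core <- obs_frac >= core_fraction - 1e-12
  sites <- which(core & nbases == 2L)
  refcode <- code[genomes$ref_id, ]
  keep <- logical(length(sites))
  alt <- integer(length(sites))
  if (length(sites) > 0L) {
    present <- counts[sites, , drop = FALSE] > 0L
    for (k in seq_along(sites)) {
      pair <- which(present[k, ])
      ## reference base must be one of the two observed bases (otherwise
      ## the column carries three alleles relative to the reference)
      if (refcode[sites[k]] %in% pair) {
        keep[k] <- TRUE
        alt[k] <- setdiff(pair, refcode[sites[k]])
      }
    }
  }
  sites <- sites[keep]
  alt <- alt[keep]
  sub <- code[ids, sites, drop = FALSE]
  geno <- matrix(NA_integer_, nrow = length(ids), ncol = length(sites),
                 dimnames = list(ids, NULL))
  geno[sub == rep(refcode[sites], each = length(ids))] <- 0L
  geno[sub == rep(alt, each = length(ids))] <- 1L
  new_snp_matrix(pos = sites, ref = DNA_BASES[refcode[sites]],
                 alt = DNA_BASES[alt], geno = geno,
                 ref_id = genomes$ref_id, genome_length = ncol(genomes$mat))
}

## pairwise mismatch counts between rows of a 0/1/NA matrix
## (missing sites excluded pairwise)
hamming_pairwise <- function(geno) {
  A <- geno == 1L; A[is.na(A)] <- FALSE; storage.mode(A) <- "double"
  B <- geno == 0L; B[is.na(B)] <- FALSE; storage.mode(B) <- "double"
  d <- tcrossprod(A, B)
  d <- d + t(d)
  dimnames(d) <- list(rownames(geno), rownames(geno))
  d
}

#' Pairwise SNP distances
#'
#' `d(i, j)` counts the sites where both strains have a non-missing call
#' and the calls differ; sites missing in either member of a pair are
#' excluded for that pair (pairwise deletion). All downstream thresholds
#' (300, 2500, 10) are absolute counts on this scale.
#'
#' @param snps A `snp_matrix` with at least two strains.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = strain
#'   ids.
#' @export
pairwise_snp_distances <- function(snps) {
  stopifnot(inherits(snps, "snp_matrix"))
  if (nrow(snps$geno) < 2L) stop_param("need at least 2 strains")
  hamming_pairwise(snps$geno)
}

#' Within-group pairwise distance summaries
#'
#' @param d Symmetric distance matrix with strain dimnames.
#' @param groups Named vector strain -> group label.
#' @return data.frame: `group`, `n` (strains), `n_pairs`, `median`, `q25`,
#'   `q75`, `iqr` of within-group pairwise distances; groups of size < 2
#'   get `NA` statistics.
#' @export
diversity_by_group <- function(d, groups) {
  ids <- intersect(rownames(d), names(groups))
  groups <- groups[ids]
  out <- lapply(sort(unique(groups)), function(g) {
    m <- ids[groups == g]
    if (length(m) < 2L)
      return(data.frame(group = g, n = length(m), n_pairs = 0L,
                        median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                        iqr = NA_real_))
    v <- d[m, m][lower.tri(matrix(0, length(m), length(m)))]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(m), n_pairs = length(v),
               median = q[2L], q25 = q[1L], q75 = q[3L], iqr = q[3L] - q[1L])
  })
  do.call(rbind, out)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler criterion (via
#' [ape::nj()]); negative branch-length estimates are clamped to zero with
#' the deficit shifted onto the sibling branch so path lengths through the
#' parent are preserved.
#'
#' @param d Symmetric distance matrix (>= 3 strains) with dimnames.
#' @return An unrooted `ape::phylo` tree with non-negative branch lengths.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop_param("neighbor joining needs >= 3 strains")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sibs) > 0L)
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr
}
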