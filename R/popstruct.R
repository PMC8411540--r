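## Population structure: iterative clonal pruning, simplified chromosome
## painting into a co-ancestry matrix, hierarchical population clustering
## with silhouette-selected K, palettes, and the haploid Weir-Cockerham
## fixation index.
##
## The painting is a per-window nearest-donor assignment, a transparent
## simplification of the ChromoPainter/fineSTRUCTURE copying model: under a
## uniform recombination rate the dominant signal is window-local copying
## from the closest relative, which this scheme captures exactly and
## testably. Clustering is deterministic (average linkage + silhouette)
## rather than MCMC.

#' Iterative clonal pruning of a distance matrix
#'
#' Clonal clusters are the single-linkage connected components of the graph
#' joining strains at distance strictly below `threshold`; one
#' representative per cluster is retained, chosen uniformly at random.
#' Among representatives, all pairwise distances are >= `threshold`.
#'
#' @param d Symmetric integer SNP-distance matrix with strain dimnames.
#' @param threshold Clonal distance threshold (default 300 SNPs).
#' @param seed Optional integer seed for the representative draw.
#' @return List: `representatives` (character vector) and `clusters`
#'   (list of member-id vectors, singletons included).
#' @export
prune_clonal <- function(d, threshold = 300L, seed = NULL) {
  d <- as.matrix(d)
  if (!is.null(seed)) set.seed(seed)
  adj <- d < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- split(rownames(d), comp)
  names(clusters) <- NULL
  reps <- vapply(clusters, function(m) sample_one(m), character(1))
  list(representatives = reps, clusters = clusters)
}

#' Simplified chromosome painting into a co-ancestry matrix
#'
#' Sites are partitioned into consecutive windows of `window_snps` columns
#' (a trailing partial window is kept as its own window if it spans at
#' least half of `window_snps` sites, otherwise it is merged into the
#' previous window). For each recipient and window, the non-self donor(s)
#' at minimal Hamming distance receive equal shares of one chunk, so every
#' row of the co-ancestry matrix sums exactly to the window count.
#'
#' @param snps A `snp_matrix` with >= 3 strains and >= 1 full window.
#' @param window_snps Window width in SNP columns (default 100).
#' @return An object of class `coancestry`: `matrix` (recipient x donor
#'   chunk counts, zero diagonal), `n_windows`, `window_snps`, `windows`
#'   (2-column matrix of column ranges).
#' @export
paint_chromosomes <- function(snps, window_snps = 100L) {
  stopifnot(inherits(snps, "snp_matrix"))
  n <- nrow(snps$geno)
  S <- ncol(snps$geno)
  if (n < 3L) stop_param("painting needs >= 3 strains")
  nfull <- S %/% window_snps
  if (nfull < 1L) stop_param("fewer SNP columns (", S,
                             ") than one window (", window_snps, ")")
  starts <- seq.int(1L, by = window_snps, length.out = nfull)
  ends <- starts + window_snps - 1L
  rem <- S - nfull * window_snps
  if (rem >= ceiling(window_snps / 2)) {
    starts <- c(starts, nfull * window_snps + 1L)
    ends <- c(ends, S)
  } else {
    ends[length(ends)] <- S
  }
  W <- length(starts)
  ca <- matrix(0, n, n, dimnames = list(rownames(snps$geno),
                                        rownames(snps$geno)))
  for (w in seq_len(W)) {
    dw <- hamming_pairwise(snps$geno[, starts[w]:ends[w], drop = FALSE])
    diag(dw) <- Inf
    mins <- apply(dw, 1L, min)
    share <- (dw == mins) / rowSums(dw == mins)
    ca <- ca + share
  }
  structure(list(matrix = ca, n_windows = W, window_snps = window_snps,
                 windows = cbind(start = starts, end = ends)),
            class = "coancestry")
}

#' @export
print.coancestry <- function(x, ...) {
  cat("coancestry:", nrow(x$matrix), "strains,", x$n_windows,
      "windows of", x$window_snps, "SNPs\n")
  invisible(x)
}

#' Cluster strains into populations from a co-ancestry matrix
#'
#' Row-normalized co-ancestry profiles are clustered by average-linkage
#' hierarchical clustering on Euclidean distances; the number of
#' populations K is chosen as the maximal mean silhouette width over
#' `k_range` (smallest K on ties). Deterministic given its input.
#'
#' @param ca A `coancestry` object (or plain recipient x donor matrix).
#' @param k_range Candidate K values, within `[2, n - 1]`.
#' @param weak_silhouette Mean-silhouette level below which the result is
#'   flagged as weak structure (default 0.25).
#' @return An object of class `pop_assignment`: `labels` (named integer
#'   vector strain -> population), `K`, `silhouette` (per candidate K),
#'   `weak_structure` flag.
#' @export
cluster_populations <- function(ca, k_range = 2:10, weak_silhouette = 0.25) {
  m <- if (inherits(ca, "coancestry")) ca$matrix else as.matrix(ca)
  n <- nrow(m)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > n - 1L)
    stop_param("k_range must lie within [2, ", n - 1L, "]")
  prof <- m / rowSums(m)
  dd <- as.matrix(stats::dist(prof))
  hc <- stats::hclust(stats::as.dist(dd), method = "average")
  sil <- vapply(k_range, function(k)
    mean_silhouette(dd, stats::cutree(hc, k)), numeric(1))
  names(sil) <- k_range
  K <- k_range[which.max(sil)]
  labels <- stats::cutree(hc, K)
  structure(list(labels = labels, K = K, silhouette = sil,
                 weak_structure = max(sil) < weak_silhouette),
            class = "pop_assignment")
}

#' @export
print.pop_assignment <- function(x, ...) {
  cat("pop_assignment: K =", x$K, "populations, sizes",
      paste(table(x$labels), collapse = "/"),
      if (x$weak_structure) "(weak structure)" else "", "\n")
  invisible(x)
}

#' Collapse small clusters and re-run painting and clustering
#'
#' Clusters smaller than `min_size` are treated as residual clonal signal:
#' each is collapsed to one randomly chosen representative, and painting
#' plus clustering are repeated on the reduced strain set.
#'
#' @param assignment A `pop_assignment` from [cluster_populations()].
#' @param snps The `snp_matrix` the painting was computed from.
#' @param min_size Minimum cluster size to survive (default 4).
#' @param window_snps,k_range Passed through to the rerun.
#' @param seed Optional seed for the representative draws.
#' @return A `pop_assignment` on the retained strains (unchanged input if
#'   no cluster falls below `min_size`).
#' @export
small_cluster_rerun <- function(assignment, snps, min_size = 4L,
                                window_snps = 100L, k_range = 2:10,
                                seed = NULL) {
  stopifnot(inherits(assignment, "pop_assignment"))
  sizes <- table(assignment$labels)
  small <- names(sizes)[sizes < min_size]
  if (length(small) == 0L) return(assignment)
  if (!is.null(seed)) set.seed(seed)
  drop <- character(0)
  for (cl in small) {
    members <- names(assignment$labels)[assignment$labels == as.integer(cl)]
    keep <- sample_one(members)
    drop <- c(drop, setdiff(members, keep))
  }
  retained <- setdiff(names(assignment$labels), drop)
  painting <- paint_chromosomes(subset_snps(snps, retained), window_snps)
  cluster_populations(painting, k_range)
}

#' Per-strain population palettes from a painting
#'
#' For each recipient, the fraction of its chunk mass received from donors
#' of each population; rows sum to 1.
#'
#' @param painting A `coancestry` object.
#' @param assignment A `pop_assignment` (or named label vector) covering
#'   the painted strains.
#' @return Numeric strain x population matrix with rows summing to 1.
#' @export
compute_palettes <- function(painting, assignment) {
  ca <- painting$matrix
  labels <- if (inherits(assignment, "pop_assignment")) assignment$labels
            else assignment
  if (!all(rownames(ca) %in% names(labels)))
    stop_param("assignment does not cover all painted strains")
  donor_pop <- factor(labels[colnames(ca)])
  mass <- t(rowsum(t(ca), donor_pop))
  colnames(mass) <- levels(donor_pop)
  mass / rowSums(ca)
}

## haploid Weir-Cockerham variance components for one set of populations;
## returns c(sum_a, sum_ab, n_loci)
wc_components <- function(geno, labels) {
  pops <- sort(unique(labels))
  r <- length(pops)
  ni <- vapply(pops, function(p)
    colSums(!is.na(geno[labels == p, , drop = FALSE])), numeric(ncol(geno)))
  pi <- vapply(pops, function(p)
    colMeans(geno[labels == p, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(geno)))
  if (ncol(geno) == 1L) { ni <- matrix(ni, nrow = 1L); pi <- matrix(pi, nrow = 1L) }
  N <- rowSums(ni)
  ok <- rowSums(ni > 0L) == r & N > r              # every pop observed
  pbar <- rowSums(ni * pi) / N
  poly <- ok & pbar > 0 & pbar < 1
  if (!any(poly)) return(c(a = 0, ab = 0, n_loci = 0L))
  ni <- ni[poly, , drop = FALSE]; pi <- pi[poly, , drop = FALSE]
  N <- N[poly]; pbar <- pbar[poly]
  nc <- (N - rowSums(ni^2) / N) / (r - 1)
  msp <- rowSums(ni * (pi - pbar)^2) / (r - 1)
  msg <- rowSums(ni * pi * (1 - pi)) / (N - r)
  a <- (msp - msg) / nc
  b <- msg
  c(a = sum(a), ab = sum(a + b), n_loci = sum(poly))
}

#' Haploid Weir-Cockerham fixation index
#'
#' Multi-locus Weir-Cockerham theta for haploid data: per polymorphic
#' locus the among-population variance component `a` and within component
#' `b` (heterozygote terms vanish for haploids) are accumulated and
#' `theta = sum(a) / sum(a + b)`. Monomorphic loci and loci unobserved in
#' some population are skipped. Reported for the full population set and
#' for every population pair.
#'
#' @param snps A `snp_matrix`.
#' @param assignment A `pop_assignment` or named label vector.
#' @return data.frame: `pop1`, `pop2` (equal to pop1 and to "all" for the
#'   overall row), `theta`, `n_loci`.
#' @export
weir_cockerham_fst <- function(snps, assignment) {
  stopifnot(inherits(snps, "snp_matrix"))
  labels <- if (inherits(assignment, "pop_assignment")) assignment$labels
            else assignment
  ids <- intersect(rownames(snps$geno), names(labels))
  labels <- labels[ids]
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    warning("excluding population(s) with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !labels %in% small
    ids <- ids[keep]; labels <- labels[keep]
  }
  pops <- sort(unique(labels))
  if (length(pops) < 2L) stop_param("need >= 2 populations with >= 2 members")
  geno <- snps$geno[ids, , drop = FALSE]
  rows <- list()
  comp <- wc_components(geno, labels)
  rows[[1L]] <- data.frame(pop1 = "all", pop2 = "all",
                           theta = unname(comp["a"] / comp["ab"]),
                           n_loci = unname(comp["n_loci"]))
  if (length(pops) > 2L) {
    for (i in seq_len(length(pops) - 1L)) for (j in (i + 1L):length(pops)) {
      sel <- labels %in% pops[c(i, j)]
      comp <- wc_components(geno[sel, , drop = FALSE], labels[sel])
      rows[[length(rows) + 1L]] <-
        data.frame(pop1 = as.character(pops[i]), pop2 = as.character(pops[j]),
                   theta = unname(comp["a"] / comp["ab"]),
                   n_loci = unname(comp["n_loci"]))
    }
  }
  do.call(rbind, rows)
}
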