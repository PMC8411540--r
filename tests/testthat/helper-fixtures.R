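## In-code fixtures shared across test files.

## aligned_genomes from per-record strings (first record is the reference)
make_alignment <- function(...) {
  recs <- list(...)
  mat <- do.call(rbind, lapply(recs, function(s)
    strsplit(s, "", fixed = TRUE)[[1L]]))
  rownames(mat) <- names(recs)
  aligned_genomes(mat, ref_id = names(recs)[1L])
}

## snp_matrix straight from a genotype matrix
make_snps <- function(geno, pos = NULL, genome_length = NULL) {
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("s", seq_len(nrow(geno)))
  pos <- pos %||% seq_len(ncol(geno))
  bifpopgen:::new_snp_matrix(
    pos = pos, ref = rep("A", ncol(geno)), alt = rep("C", ncol(geno)),
    geno = geno, ref_id = "ref",
    genome_length = genome_length %||% (max(pos) + 10L))
}

## named distance matrix from upper-triangle values in row-major pair
## order: (1,2), (1,3), ..., (1,n), (2,3), ...
make_dist <- function(ids, values) {
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  d[lower.tri(d)] <- values
  d[upper.tri(d)] <- t(d)[upper.tri(d)]
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## exact jaccard between canonical k-mer sets, brute force
exact_canonical_jaccard <- function(s1, s2, k) {
  revcomp <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
  }
  kmers <- function(s) {
    ks <- substring(s, seq_len(nchar(s) - k + 1L), k:nchar(s))
    unique(pmin(ks, vapply(ks, revcomp, character(1))))
  }
  a <- kmers(s1); b <- kmers(s2)
  length(intersect(a, b)) / length(union(a, b))
}

## two-sided Fisher exact p by hypergeometric enumeration (the
## probability-ordering definition, with fisher.test's relative tolerance)
fisher_enum_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
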