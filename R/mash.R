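## Native MinHash (Mash-type) sketch distances: canonical 2-bit k-mer
## codes, a universal affine hash modulo the Mersenne prime 2^31 - 1, and
## bottom-s sketches. With a sketch at least as large as the number of
## distinct k-mers the Jaccard estimate is exact.

MERSENNE31 <- 2147483647

## (a * x + b) mod p for doubles, exact: a is split into 16-bit halves so
## every intermediate product stays below 2^53
affine_mod31 <- function(x, a, b) {
  a_hi <- a %/% 65536
  a_lo <- a %% 65536
  (((a_hi * x) %% MERSENNE31) * 65536 + a_lo * x + b) %% MERSENNE31
}

## canonical (strand-independent) k-mer codes of one sequence; NA windows
## (containing non-ACGT) are dropped
canonical_kmer_codes <- function(seq_chars, k) {
  x <- match(seq_chars, DNA_BASES) - 1
  L <- length(x)
  n <- L - k + 1L
  if (n < 1L) return(numeric(0))
  fwd <- numeric(n)
  rev <- numeric(n)
  idx <- seq_len(n)
  for (j in seq_len(k)) {
    fwd <- fwd * 4 + x[idx + j - 1L]
    rev <- rev * 4 + (3 - x[idx + k - j])
  }
  codes <- pmin(fwd, rev)
  codes[!is.na(codes)]
}

#' Sketch configuration for MinHash distances
#'
#' @param k K-mer length; odd, between 11 and 31 (odd so no k-mer is its
#'   own reverse complement). Default 21.
#' @param sketch_size Bottom-sketch size s (default 1000).
#' @param hash_seed Integer seed for the affine hash (default 42).
#' @return A `sketch_config` list.
#' @export
sketch_config <- function(k = 21L, sketch_size = 1000L, hash_seed = 42L) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L || k > 31L)
    stop_param("k must be odd and within [11, 31]")
  if (sketch_size < 1L) stop_param("sketch_size must be >= 1")
  structure(list(k = k, sketch_size = as.integer(sketch_size),
                 hash_seed = as.integer(hash_seed)),
            class = "sketch_config")
}

## bottom-s sketch (sorted distinct hash values) of one sequence
minhash_sketch <- function(seq_chars, cfg) {
  codes <- canonical_kmer_codes(seq_chars, cfg$k)
  if (length(codes) == 0L) return(numeric(0))
  a <- (abs(cfg$hash_seed) * 2654435761) %% (MERSENNE31 - 1) + 1
  b <- (abs(cfg$hash_seed) * 40503 + 12345) %% MERSENNE31
  h <- affine_mod31(codes %% MERSENNE31, a, b)
  h <- sort(unique(h))
  h[seq_len(min(cfg$sketch_size, length(h)))]
}

## Mash distance from two bottom sketches
mash_from_sketches <- function(sa, sb, cfg) {
  u <- sort(unique(c(sa, sb)))
  x <- u[seq_len(min(cfg$sketch_size, length(u)))]
  j <- sum(x %in% sa & x %in% sb) / length(x)
  if (j <= 0) return(1)
  min(1, -(1 / cfg$k) * log(2 * j / (1 + j)))
}

#' MinHash (Mash-type) sketch distances between genomes
#'
#' Each genome is reduced to the bottom-`s` sketch of the hashes of its
#' canonical k-mers (gaps and ambiguous bases are stripped before
#' k-merization). For a pair, the Jaccard similarity j is estimated from
#' the merged bottom-`s` sketch and converted to the mutation-distance
#' scale `d = -(1/k) * log(2j / (1 + j))`; `j = 0` is reported as the cap
#' `d = 1`. When `sketch_size` is at least the number of distinct k-mers,
#' the estimate equals the exact Jaccard.
#'
#' @param genomes An `aligned_genomes` object, or a named character vector
#'   / list of sequences.
#' @param cfg A [sketch_config()].
#' @param include_reference Keep the reference record of an
#'   `aligned_genomes` input (default FALSE).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
mash_distance <- function(genomes, cfg = sketch_config(),
                          include_reference = FALSE) {
  stopifnot(inherits(cfg, "sketch_config"))
  if (inherits(genomes, "aligned_genomes")) {
    ids <- if (include_reference) rownames(genomes$mat) else
      strain_ids(genomes)
    seqs <- lapply(ids, function(s) {
      v <- genomes$mat[s, ]
      v[v %in% DNA_BASES]
    })
  } else {
    ids <- names(genomes) %||% paste0("seq", seq_along(genomes))
    seqs <- lapply(genomes, function(s) {
      v <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
      v[v %in% DNA_BASES]
    })
  }
  names(seqs) <- ids
  short <- ids[vapply(seqs, length, integer(1)) < cfg$k]
  if (length(short) > 0L)
    stop_param("sequence shorter than k after stripping gaps: ",
               paste(short, collapse = ", "))
  sketches <- lapply(seqs, minhash_sketch, cfg = cfg)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- mash_from_sketches(sketches[[i]], sketches[[j]], cfg)
  }
  d
}
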