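#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' COG functional category letters used for enrichment
#'
#' The 20 single-letter cluster-of-orthologous-groups categories over which
#' functional enrichment of population-specific variants is evaluated.
#'
#' @return Character vector of 20 category letters.
#' @export
cog_categories <- function() {
  c("C", "D", "E", "F", "G", "H", "I", "J", "K", "L",
    "M", "N", "O", "P", "Q", "T", "U", "V", "S", "R")
}

stop_param <- function(...) {
  stop(structure(class = c("bifpopgen_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("bifpopgen_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(field, ...) {
  stop(structure(class = c("bifpopgen_config_error", "error", "condition"),
                 list(message = paste0("invalid configuration field '", field,
                                       "': ", ...),
                      call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index comparing two partitions of the same
#' strains; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length (names are ignored; order pairs
#'   the elements).
#' @return A number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_param("labelings differ in length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxidx <- (ai + bj) / 2
  if (abs(maxidx - expected) < .Machine$double.eps) return(1)
  (nij - expected) / (maxidx - expected)
}

## mean silhouette width of a labeling on a distance matrix;
## singleton clusters contribute 0 (standard convention)
mean_silhouette <- function(d, labels) {
  n <- nrow(d)
  labs <- unique(labels)
  if (length(labs) < 2L) return(0)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(labs[labs != labels[i]],
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

## sample() without the size-1 surprise
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

## merge a two-column matrix of [start, end] (1-based inclusive) intervals
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) for (r in 2L:nrow(iv)) {
    if (iv[r, 1L] <= out[nrow(out), 2L] + 1L) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], iv[r, 2L])
    } else {
      out <- rbind(out, iv[r, , drop = FALSE])
    }
  }
  out
}

## total length of [start, end] inclusive intervals
interval_bases <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(0L)
  sum(iv[, 2L] - iv[, 1L] + 1L)
}
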