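## Community statistics: dataset-wide low-abundance filtering, Hellinger
## transformation, transformation-based RDA effect partitioning, PERMANOVA
## on Euclidean distances, and per-taxon rank tests with compact letter
## displays.

#' Remove taxa below a dataset-wide relative abundance
#'
#' A taxon is removed when its dataset-wide relative abundance (taxon
#' total over grand total) falls below `min_frac`. The default 0.005%
#' mirrors the usual low-abundance OTU filter. A per-sample variant
#' (keep a taxon if it reaches `min_frac` in at least one sample) is
#' available behind `per_sample`.
#'
#' @param table Non-negative sample x taxon matrix (counts or
#'   proportions).
#' @param min_frac Threshold (default 5e-5, i.e. 0.005%).
#' @param per_sample Use the per-sample rule instead (default FALSE).
#' @return The filtered matrix.
#' @export
filter_low_abundance <- function(table, min_frac = 5e-5,
                                 per_sample = FALSE) {
  if (any(table < 0)) stop_format("negative abundance entries")
  if (per_sample) {
    rel <- table / rowSums(table)
    keep <- apply(rel, 2L, max) >= min_frac
  } else {
    keep <- colSums(table) / sum(table) >= min_frac
  }
  table[, keep, drop = FALSE]
}

#' Hellinger transformation
#'
#' `y' = sqrt(y / row_total)`; each transformed row has unit sum of
#' squares, which makes Euclidean distances on the result appropriate for
#' zero-inflated compositional data (and hence valid inputs for RDA).
#'
#' @param table Non-negative sample x taxon matrix with positive row sums.
#' @return The transformed matrix.
#' @export
hellinger <- function(table) {
  rs <- rowSums(table)
  if (any(rs <= 0)) {
    bad <- rownames(table)[which(rs <= 0)[1L]] %||% which(rs <= 0)[1L]
    stop_format("all-zero sample row: ", bad)
  }
  sqrt(table / rs)
}

## dummy-coded model matrix (no intercept column) for a covariate subset
covariate_mm <- function(covariates, cols) {
  df <- as.data.frame(covariates)[, cols, drop = FALSE]
  for (j in seq_along(df)) if (is.character(df[[j]]) || is.logical(df[[j]]))
    df[[j]] <- factor(df[[j]])
  stats::model.matrix(~ ., df)[, -1L, drop = FALSE]
}

## R-squared of column-centered Y on covariate columns (by QR projection)
rda_r2 <- function(Yc, mm) {
  X <- scale(mm, scale = FALSE)
  qx <- qr(X)
  sum(qr.fitted(qx, Yc)^2) / sum(Yc^2)
}

#' Redundancy-analysis effect sizes with permutation tests
#'
#' Constrained ordination by least squares of the (column-centered)
#' response on dummy-coded covariates. Reports the full-model
#' `R2 = SS_fitted / SS_total` plus each covariate's individual
#' (single-term) R2, with permutation p-values computed as
#' `(count(stat_perm >= stat_obs) + 1) / (permutations + 1)` under row
#' permutation of the response. For abundance data the response should be
#' Hellinger-transformed first (tb-RDA).
#'
#' @param response Numeric sample x variable matrix.
#' @param covariates data.frame of covariates (factors/characters are
#'   dummy-coded), rownames aligned with the response.
#' @param permutations Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return data.frame of class `covariate_effects`: `term` ("full" plus
#'   one row per covariate), `df`, `R2`, `R2_adj`, `p`, `method`.
#' @export
rda_effects <- function(response, covariates, permutations = 1000L,
                        seed = NULL) {
  Y <- as.matrix(response)
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  if (!is.null(seed)) set.seed(seed)
  cv <- as.data.frame(covariates)
  collinear <- logical(ncol(cv))
  mm_all <- covariate_mm(cv, seq_along(cv))
  qa <- qr(scale(mm_all, scale = FALSE))
  if (qa$rank < ncol(mm_all)) {
    dropped <- colnames(mm_all)[qa$pivot[(qa$rank + 1L):ncol(mm_all)]]
    warning("collinear covariate column(s) dropped: ",
            paste(dropped, collapse = ", "))
  }
  Yc <- scale(Y, scale = FALSE)
  sstot <- sum(Yc^2)

  eval_term <- function(cols, Ymat) {
    mm <- covariate_mm(cv, cols)
    X <- scale(mm, scale = FALSE)
    qx <- qr(X)
    sum(qr.fitted(qx, Ymat)^2) / sstot
  }
  terms <- names(cv)
  r2_full <- eval_term(seq_along(cv), Yc)
  r2_terms <- vapply(terms, function(tm) eval_term(tm, Yc), numeric(1))
  df_full <- qa$rank
  df_terms <- vapply(terms, function(tm)
    qr(scale(covariate_mm(cv, tm), scale = FALSE))$rank, numeric(1))

  perm_ge <- rep(0L, length(terms) + 1L)
  for (b in seq_len(permutations)) {
    Yp <- Yc[sample.int(n), , drop = FALSE]
    rp_full <- eval_term(seq_along(cv), Yp)
    rp_terms <- vapply(terms, function(tm) eval_term(tm, Yp), numeric(1))
    perm_ge <- perm_ge + (c(rp_full, rp_terms) >= c(r2_full, r2_terms) - 1e-12)
  }
  pvals <- (perm_ge + 1) / (permutations + 1)
  adj <- function(r2, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)
  out <- data.frame(term = c("full", terms),
                    df = c(df_full, df_terms),
                    R2 = c(r2_full, r2_terms),
                    R2_adj = c(adj(r2_full, df_full),
                               adj(r2_terms, df_terms)),
                    p = pvals, method = "RDA", row.names = NULL)
  class(out) <- c("covariate_effects", "data.frame")
  out
}

## Gower-centered inner-product matrix from a distance matrix
gower_center <- function(d) {
  A <- -0.5 * d^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' PERMANOVA with sequential (Type-I) partitioning
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' terms are added in the order given, sums of squares come from traces of
#' hat-matrix increments applied to the Gower-centered inner-product
#' matrix, pseudo-F uses the residual mean square, and p-values come from
#' permuting sample identities (`(count >= obs) + 1) / (permutations + 1)`).
#'
#' @param d Symmetric distance matrix (Euclidean for the classical
#'   variance interpretation).
#' @param covariates data.frame of covariates in the desired sequential
#'   order.
#' @param permutations Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return data.frame of class `covariate_effects`: one row per term plus
#'   `Residual` and `Total`; columns `term`, `df`, `SS`, `R2`, `F`, `p`,
#'   `method`.
#' @export
permanova <- function(d, covariates, permutations = 1000L, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop_param("PERMANOVA needs n >= 3")
  if (!is.null(seed)) set.seed(seed)
  cv <- as.data.frame(covariates)
  G <- gower_center(d)
  sstot <- sum(diag(G))
  terms <- names(cv)
  ## cumulative hat matrices (intercept first)
  hats <- vector("list", length(terms) + 1L)
  ones <- matrix(1, n, 1L)
  hats[[1L]] <- ones %*% t(ones) / n
  dfs <- numeric(length(terms))
  for (k in seq_along(terms)) {
    mm <- cbind(1, covariate_mm(cv, terms[seq_len(k)]))
    qx <- qr(mm)
    Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    hats[[k + 1L]] <- Q %*% t(Q)
    dfs[k] <- qx$rank - sum(dfs) - 1L
  }
  Hfull <- hats[[length(hats)]]
  df_res <- n - sum(dfs) - 1L
  if (df_res < 1L) stop_param("no residual degrees of freedom")

  ss_terms <- function(Gm) {
    ss <- numeric(length(terms))
    for (k in seq_along(terms))
      ss[k] <- sum((hats[[k + 1L]] - hats[[k]]) * Gm)
    ## exact within-group fits can leave a residual of -0 numerically
    c(ss, resid = max(sum((diag(n) - Hfull) * Gm), 0))
  }
  obs <- ss_terms(G)
  Fobs <- (obs[seq_along(terms)] / dfs) / (obs[length(obs)] / df_res)

  ge <- rep(0L, length(terms))
  for (b in seq_len(permutations)) {
    idx <- sample.int(n)
    ssp <- ss_terms(G[idx, idx])
    Fp <- (ssp[seq_along(terms)] / dfs) / (ssp[length(ssp)] / df_res)
    ge <- ge + (Fp >= Fobs - 1e-12)
  }
  pvals <- (ge + 1) / (permutations + 1)
  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(obs[seq_along(terms)], obs[length(obs)], sstot),
    R2 = c(obs[seq_along(terms)], obs[length(obs)], sstot) / sstot,
    F = c(Fobs, NA, NA),
    p = c(pvals, NA, NA),
    method = "PERMANOVA", row.names = NULL)
  class(out) <- c("covariate_effects", "data.frame")
  out
}

## compact letter display: groups share a letter iff no pairwise p < alpha
## separates them (insert-and-absorb)
letter_display <- function(groups, pmat, alpha = 0.05) {
  k <- length(groups)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
    newsets <- list()
    for (s in sets) {
      if (all(c(i, j) %in% s)) {
        newsets <- c(newsets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else newsets <- c(newsets, list(s))
    }
    ## absorb subsets
    keep <- rep(TRUE, length(newsets))
    for (u in seq_along(newsets)) for (v in seq_along(newsets)) {
      if (u != v && keep[u] && all(newsets[[u]] %in% newsets[[v]]) &&
          length(newsets[[u]]) < length(newsets[[v]]))
        keep[u] <- FALSE
    }
    sets <- unique(newsets[keep])
  }
  letters_out <- stats::setNames(rep("", k), groups)
  for (s in seq_along(sets))
    letters_out[sets[[s]]] <- paste0(letters_out[sets[[s]]], letters[s])
  letters_out
}

#' Bin ages into the standard host-age categories
#'
#' @param age Numeric ages in years.
#' @return Factor with levels `0-17`, `18-45`, `46-65`, `>65`.
#' @export
age_bin <- function(age) {
  cut(age, breaks = c(-Inf, 17, 45, 65, Inf),
      labels = c("0-17", "18-45", "46-65", ">65"))
}

#' Compare a taxon's relative abundance across groups
#'
#' Kruskal-Wallis omnibus test (tie-corrected) plus all pairwise
#' two-sided Mann-Whitney U tests (exact enumeration when both group
#' sizes are <= 8 and there are no ties, normal approximation with
#' continuity correction otherwise), summarized by a compact letter
#' display: groups share a letter iff no pairwise p below `alpha`
#' separates them.
#'
#' @param abundance Sample x taxon relative-abundance matrix.
#' @param taxon Column name of the focal taxon.
#' @param group Factor (e.g. [age_bin()] of host ages) aligned with rows;
#'   empty groups are dropped, groups of one sample excluded with a
#'   warning.
#' @param alpha Pairwise significance level for the letters (default
#'   0.05).
#' @return List: `omnibus_p`, `pairwise` (matrix of p-values), `letters`,
#'   `group_medians`.
#' @export
taxon_group_tests <- function(abundance, taxon, group, alpha = 0.05) {
  if (!taxon %in% colnames(abundance)) stop_param("unknown taxon: ", taxon)
  x <- abundance[, taxon]
  group <- droplevels(factor(group))
  sizes <- table(group)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    warning("excluding group(s) with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !group %in% small
    x <- x[keep]; group <- droplevels(group[keep])
  }
  if (nlevels(group) < 2L) stop_param("need >= 2 groups of >= 2 samples")
  kw <- stats::kruskal.test(x, group)
  levs <- levels(group)
  k <- length(levs)
  pmat <- matrix(NA_real_, k, k, dimnames = list(levs, levs))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    xi <- x[group == levs[i]]; xj <- x[group == levs[j]]
    exact <- length(xi) <= 8L && length(xj) <= 8L &&
      !anyDuplicated(c(xi, xj))
    wt <- stats::wilcox.test(xi, xj, exact = exact, correct = TRUE)
    pmat[i, j] <- pmat[j, i] <- wt$p.value
  }
  list(omnibus_p = kw$p.value,
       pairwise = pmat,
       letters = letter_display(levs, pmat, alpha),
       group_medians = tapply(x, group, stats::median))
}
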