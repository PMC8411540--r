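## Association analyses: carriage filtering, one-vs-rest population scans
## with exact tests, merging of scan hits, COG/KEGG enrichment, classical
## MDS covariates, and fixed-effect phenotype GWAS with Bonferroni control.

#' Filter variants by carriage fraction
#'
#' Keeps variants whose carriage fraction lies strictly inside
#' `(min_frac, max_frac)`. The population-specific scans use (0.05, 0.95);
#' the phenotype GWAS uses (0.01, 0.99).
#'
#' @param m Binary strains x variants matrix (SNP alt-carriage or gene
#'   presence), `NA` allowed.
#' @param min_frac,max_frac Exclusive carriage bounds.
#' @return The matrix restricted to passing variants.
#' @export
filter_variants <- function(m, min_frac = 0.05, max_frac = 0.95) {
  if (min_frac >= max_frac) stop_param("min_frac must be < max_frac")
  frac <- colMeans(m, na.rm = TRUE)
  m[, frac > min_frac & frac < max_frac, drop = FALSE]
}

## two-sided Fisher p and Haldane-corrected log-odds for vectors of 2x2
## counts (a = carrier&case, b = carrier&ctrl, c = noncarrier&case,
## d = noncarrier&ctrl)
fisher_scan <- function(a, b, c, d) {
  p <- vapply(seq_along(a), function(i)
    stats::fisher.test(matrix(c(a[i], b[i], c[i], d[i]), 2L))$p.value,
    numeric(1))
  lor <- log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)))
  list(p = pmin(p, 1), log_or = lor)
}

#' One-vs-rest population scan for population-specific variants
#'
#' For each variant, a two-sided Fisher exact test of carriage in the
#' target population versus all other populations combined; no structure
#' covariates by design (the scan looks for the markers that define the
#' structure). Significance at the Bonferroni level `0.05 / m` over the
#' `m` variants tested.
#'
#' @param variants Binary strains x variants matrix (pre-filtered, e.g. by
#'   [filter_variants()] at 5-95%).
#' @param assignment A `pop_assignment` or named label vector.
#' @param target_pop Label of the focal population.
#' @param alpha Family-wise error level (default 0.05).
#' @return data.frame: `variant`, `target_pop`, carriage counts
#'   (`carrier_in`, `n_in`, `carrier_out`, `n_out`), `log_or`, `p`,
#'   `threshold`, `significant`.
#' @export
population_scan <- function(variants, assignment, target_pop, alpha = 0.05) {
  labels <- if (inherits(assignment, "pop_assignment")) assignment$labels
            else assignment
  ids <- intersect(rownames(variants), names(labels))
  if (length(unique(labels[ids])) < 2L)
    stop_param("need >= 2 populations")
  if (!target_pop %in% labels[ids])
    stop_param("target population '", target_pop, "' not present")
  v <- variants[ids, , drop = FALSE]
  y <- labels[ids] == target_pop
  a <- colSums(v[y, , drop = FALSE], na.rm = TRUE)
  b <- colSums(v[!y, , drop = FALSE], na.rm = TRUE)
  n_in <- colSums(!is.na(v[y, , drop = FALSE]))
  n_out <- colSums(!is.na(v[!y, , drop = FALSE]))
  ft <- fisher_scan(a, n_in - a, b, n_out - b)
  m <- ncol(v)
  data.frame(variant = colnames(v) %||% as.character(seq_len(m)),
             target_pop = as.character(target_pop),
             carrier_in = a, n_in = n_in, carrier_out = b, n_out = n_out,
             log_or = ft$log_or, p = ft$p, threshold = alpha / m,
             significant = ft$p < alpha / m, row.names = NULL)
}

#' Merge population-scan hits
#'
#' Union of the significant variants across scans, each tagged with the
#' population(s) whose scan flagged it.
#'
#' @param results List of [population_scan()] results.
#' @return data.frame: `variant`, `populations` (comma-separated tags),
#'   `min_p`.
#' @export
merge_hits <- function(results) {
  hits <- do.call(rbind, lapply(results, function(r)
    r[r$significant, c("variant", "target_pop", "p"), drop = FALSE]))
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.frame(variant = character(0), populations = character(0),
                      min_p = numeric(0)))
  out <- do.call(rbind, lapply(split(hits, hits$variant), function(h)
    data.frame(variant = h$variant[1L],
               populations = paste(sort(unique(h$target_pop)),
                                   collapse = ","),
               min_p = min(h$p))))
  rownames(out) <- NULL
  out[order(out$min_p, out$variant), , drop = FALSE]
}

#' Functional enrichment of hit genes over COG/KEGG terms
#'
#' One-sided (greater) Fisher exact test per term on the 2x2 table of
#' hit/non-hit genes inside/outside the term, against the reference
#' background gene set; significant iff `p < alpha / n_terms` (defaults
#' give the strict Bonferroni threshold 0.01/220 = 4.55e-5).
#'
#' @param hits Character vector of hit gene ids (only those carried by the
#'   background count; hits whose terms are absent from the background are
#'   skipped with a warning).
#' @param annotation data.frame with `gene_id`, `cog`, `kegg` columns.
#' @param background Character vector of background (reference genome)
#'   gene ids.
#' @param alpha Base significance level (default 0.01).
#' @param n_terms Bonferroni family size (default 220 = 20 COG + 200 KEGG).
#' @return data.frame: `term`, `type` (COG/KEGG), `hits_in`, `hits_out`,
#'   `bg_in`, `bg_out`, `p`, `threshold`, `significant`.
#' @export
enrichment_test <- function(hits, annotation, background,
                            alpha = 0.01, n_terms = 220L) {
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  hit_bg <- intersect(hits, background)
  orphan_terms <- unique(unlist(
    annotation[annotation$gene_id %in% setdiff(hits, background),
               c("cog", "kegg")]))
  orphan_terms <- setdiff(orphan_terms, unique(unlist(ann[, c("cog", "kegg")])))
  if (length(orphan_terms) > 0L)
    warning("term(s) absent from background skipped: ",
            paste(orphan_terms, collapse = ", "))
  threshold <- alpha / n_terms
  term_rows <- function(col, type) {
    terms <- sort(unique(ann[[col]]))
    do.call(rbind, lapply(terms, function(tm) {
      in_term <- ann$gene_id[ann[[col]] == tm]
      hi <- sum(hit_bg %in% in_term)
      ho <- length(hit_bg) - hi
      bi <- length(setdiff(in_term, hit_bg))
      bo <- length(setdiff(background, hit_bg)) - bi
      p <- stats::fisher.test(matrix(c(hi, ho, bi, bo), 2L),
                              alternative = "greater")$p.value
      data.frame(term = tm, type = type, hits_in = hi, hits_out = ho,
                 bg_in = bi, bg_out = bo, p = p, threshold = threshold,
                 significant = p < threshold)
    }))
  }
  out <- rbind(term_rows("cog", "COG"), term_rows("kegg", "KEGG"))
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}

#' Classical MDS coordinates as population-structure covariates
#'
#' Torgerson MDS via double-centering of the squared distances; axes with
#' positive eigenvalues are retained until `var_frac` of the positive
#' eigenvalue mass is reached, capped at `max_dims`; each axis is
#' sign-fixed by making its largest-magnitude loading positive.
#'
#' @param d Symmetric distance matrix.
#' @param max_dims Maximum retained axes (default 10).
#' @param var_frac Positive-eigenvalue mass to cover (default 0.8).
#' @return Coordinate matrix (strains x retained axes) with an `eig`
#'   attribute holding all eigenvalues.
#' @export
mds_covariates <- function(d, max_dims = 10L, var_frac = 0.8) {
  d <- as.matrix(d)
  n <- nrow(d)
  ## k = n-1 axes are requested and screened by eigenvalue below, so
  ## cmdscale's "only k of first n" note is expected
  cm <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1L,
                                         eig = TRUE))
  ev <- cm$eig
  tol <- 1e-9 * max(abs(ev), 1)
  pos <- which(ev > tol)
  if (length(pos) == 0L) stop_param("degenerate distances: no positive eigenvalue")
  cum <- cumsum(ev[pos]) / sum(ev[pos])
  ndim <- min(max_dims, pos[which(cum >= var_frac - 1e-12)[1L]])
  coords <- cm$points[, seq_len(ndim), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    s <- sign(coords[which.max(abs(coords[, j])), j])
    if (s < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  attr(coords, "eig") <- ev
  coords
}

## Firth-penalized logistic regression (Newton iterations on the modified
## score); used as fallback on separation
firth_logistic <- function(X, y, maxit = 100L, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    XtW <- t(X * w)
    I <- XtW %*% X
    Iinv <- solve(I)
    h <- rowSums((X %*% Iinv) * (X * w))
    U <- drop(t(X) %*% (y - p + h * (0.5 - p)))
    step <- drop(Iinv %*% U)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(Iinv))
  list(coef = b, se = se)
}

#' Fixed-effect phenotype GWAS with MDS structure correction
#'
#' Continuous phenotypes: ordinary least squares
#' `phenotype ~ variant + covariates` with the Wald p-value on the variant
#' term (computed by Frisch-Waugh residualization, exactly equivalent to
#' the full regression). Binary phenotypes: logistic regression with the
#' same design, falling back to a Firth-penalized fit when separation is
#' detected. Strains with missing phenotype are dropped; rank-deficient
#' covariate columns are dropped with a warning; variants constant after
#' the drop are skipped (`NA` p). Bonferroni significance at
#' `alpha / m`.
#'
#' @param variants Binary strains x variants matrix, pre-filtered (the
#'   phenotype scans use [filter_variants()] at 1-99%).
#' @param phenotype Named numeric (continuous) or two-level vector.
#' @param covariates Optional numeric covariate matrix (e.g.
#'   [mds_covariates()]) with matching rownames.
#' @param alpha Family-wise error level (default 0.05).
#' @return data.frame: `variant`, `af`, `beta`, `se`, `p`, `threshold`,
#'   `significant`.
#' @export
phenotype_gwas <- function(variants, phenotype, covariates = NULL,
                           alpha = 0.05) {
  ids <- rownames(variants) %||% names(phenotype)
  if (is.null(names(phenotype))) names(phenotype) <- ids
  keep <- ids[!is.na(phenotype[ids])]
  v <- variants[keep, , drop = FALSE]
  y <- phenotype[keep]
  Z <- matrix(1, nrow = length(keep), ncol = 1L,
              dimnames = list(keep, "(Intercept)"))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)[keep, , drop = FALSE]
    Z <- cbind(Z, cv)
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) {
      drop_cols <- qz$pivot[(qz$rank + 1L):ncol(Z)]
      warning("dropping rank-deficient covariate(s): ",
              paste(colnames(Z)[drop_cols], collapse = ", "))
      Z <- Z[, -drop_cols, drop = FALSE]
    }
  }
  m <- ncol(v)
  threshold <- alpha / m
  af <- colMeans(v, na.rm = TRUE)
  binary <- length(unique(y)) == 2L
  if (binary) y <- as.numeric(factor(y)) - 1

  beta <- se <- p <- rep(NA_real_, m)
  constant <- apply(v, 2L, function(x) length(unique(x[!is.na(x)])) < 2L)
  if (!binary) {
    qz <- qr(Z)
    ry <- stats::resid(stats::lm.fit(Z, y))
    RX <- v
    RX[is.na(RX)] <- af[col(RX)][is.na(RX)]          # mean-impute rare NAs
    RX <- RX - qr.fitted(qz, RX)
    sxx <- colSums(RX^2)
    df <- length(y) - ncol(Z) - 1L
    usable <- !constant & sxx > 1e-12
    bhat <- colSums(RX * ry)[usable] / sxx[usable]
    rss <- pmax(sum(ry^2) - bhat^2 * sxx[usable], 0)
    sig2 <- rss / df
    sehat <- sqrt(sig2 / sxx[usable])
    tval <- bhat / sehat
    beta[usable] <- bhat
    se[usable] <- sehat
    p[usable] <- 2 * stats::pt(-abs(tval), df)
  } else {
    for (j in seq_len(m)) {
      if (constant[j]) next
      X <- cbind(Z, variant = v[, j])
      ok <- stats::complete.cases(X)
      sep <- FALSE
      fit <- withCallingHandlers(
        stats::glm.fit(X[ok, , drop = FALSE], y[ok],
                       family = stats::binomial()),
        warning = function(w) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        })
      cf <- fit$coefficients
      if (sep || !fit$converged || any(abs(cf) > 15)) {
        ff <- firth_logistic(X[ok, , drop = FALSE], y[ok])
        beta[j] <- ff$coef[ncol(X)]
        se[j] <- ff$se[ncol(X)]
      } else {
        I <- crossprod(X[ok, , drop = FALSE] * sqrt(fit$weights))
        sm <- solve(I)
        beta[j] <- cf[ncol(X)]
        se[j] <- sqrt(diag(sm))[ncol(X)]
      }
      p[j] <- 2 * stats::pnorm(-abs(beta[j] / se[j]))
    }
  }
  data.frame(variant = colnames(v) %||% as.character(seq_len(m)),
             af = af, beta = beta, se = se, p = p, threshold = threshold,
             significant = !is.na(p) & p < threshold, row.names = NULL)
}

#' Covariate effect sizes on a genotype matrix
#'
#' Treats the binary genotype matrix as a multivariate response and
#' delegates to [rda_effects()] and [permanova()] (on Euclidean distances
#' of the same matrix) to estimate each covariate's share of the overall
#' genomic variation with a permutation p-value. Strains with any missing
#' covariate are excluded (with a message); zero-variance covariates are
#' excluded likewise.
#'
#' @param variants Binary strains x variants matrix.
#' @param covariates data.frame of covariates, rownames = strain ids.
#' @param permutations Number of permutations (default 1000).
#' @param seed Optional seed for the permutations.
#' @return data.frame combining the RDA and PERMANOVA tables (`method`
#'   column).
#' @export
genotype_effectsizes <- function(variants, covariates, permutations = 1000L,
                                 seed = NULL) {
  ids <- intersect(rownames(variants), rownames(covariates))
  cv <- covariates[ids, , drop = FALSE]
  complete <- stats::complete.cases(cv)
  if (any(!complete))
    message("excluding ", sum(!complete), " strain(s) with missing covariates")
  ids <- ids[complete]
  cv <- cv[ids, , drop = FALSE]
  novar <- vapply(cv, function(x) length(unique(x)) < 2L, logical(1))
  if (any(novar)) {
    message("excluding zero-variance covariate(s): ",
            paste(names(cv)[novar], collapse = ", "))
    cv <- cv[, !novar, drop = FALSE]
  }
  v <- variants[ids, , drop = FALSE]
  storage.mode(v) <- "double"
  rda <- rda_effects(v, cv, permutations = permutations, seed = seed)
  pm <- permanova(as.matrix(stats::dist(v)), cv,
                  permutations = permutations, seed = seed)
  rda$method <- "RDA"
  pm$method <- "PERMANOVA"
  common <- c("term", "df", "R2", "p", "method")
  rbind(rda[, common], pm[, common])
}
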