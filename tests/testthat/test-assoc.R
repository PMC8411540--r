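test_that("carriage filter applies exclusive bounds", {
  m <- cbind(all = rep(1L, 100),
             ten = c(rep(1L, 10), rep(0L, 90)),
             five = c(rep(1L, 5), rep(0L, 95)),
             one = c(1L, rep(0L, 99)))
  rownames(m) <- paste0("s", 1:100)
  f <- filter_variants(m, 0.05, 0.95)
  expect_identical(colnames(f), "ten")      # 5% sits on the bound: excluded
  f2 <- filter_variants(m, 0.01, 0.99)
  expect_setequal(colnames(f2), c("ten", "five"))
  expect_error(filter_variants(m, 0.5, 0.5), "min_frac")
})

test_that("population scan matches the exact hypergeometric p", {
  v <- cbind(hit = c(rep(1L, 10), rep(0L, 10)),
             flat = rep(c(1L, 0L), 10))
  rownames(v) <- paste0("s", 1:20)
  labels <- setNames(rep(c("t", "o"), each = 10), rownames(v))
  res <- population_scan(v, labels, "t")
  expect_equal(res$p[res$variant == "hit"], 2 / choose(20, 10),
               tolerance = 1e-9)
  expect_equal(res$p[res$variant == "flat"], 1)
  expect_equal(res$threshold, rep(0.05 / 2, 2))
  expect_true(res$significant[res$variant == "hit"])

  ## strain order invariance and allele-label swap
  res2 <- population_scan(v[rev(rownames(v)), ], labels, "t")
  expect_equal(res2$p, res$p)
  res3 <- population_scan(1L - v, labels, "t")
  expect_equal(res3$p, res$p)
  expect_equal(res3$log_or[1], -res$log_or[1], tolerance = 1e-12)
  expect_error(population_scan(v, labels, "missing_pop"), "target")
})

test_that("scan hits merge into a union with population tags", {
  mk <- function(vars, pops, ps) {
    data.frame(variant = vars, target_pop = pops, p = ps,
               significant = rep(TRUE, length(vars)))
  }
  r1 <- mk(c("a", "b", "c"), "p1", c(1e-8, 1e-7, 1e-6))
  r2 <- mk(c("d", "e"), "p2", c(1e-9, 1e-5))
  r3 <- mk("a", "p3", 1e-4)
  merged <- merge_hits(list(r1, r2, r3))
  expect_equal(nrow(merged), 5L)
  expect_equal(merged$populations[merged$variant == "a"], "p1,p3")
  empty <- merge_hits(list(mk(character(0), character(0), numeric(0))))
  expect_equal(nrow(empty), 0L)
})

test_that("enrichment threshold and p-values are exact", {
  ann <- data.frame(gene_id = paste0("g", 1:100),
                    cog = c(rep("G", 5), rep("E", 95)),
                    kegg = rep("ko00010", 100))
  bg <- paste0("g", 1:100)
  hits <- paste0("g", 1:5)                 # all 5 hits in the 5-gene term
  en <- enrichment_test(hits, ann, bg)
  expect_equal(en$threshold[1], 0.01 / 220)
  expect_equal(signif(en$threshold[1], 3), 4.55e-5)
  pG <- en$p[en$term == "G"]
  expect_equal(pG, 1 / choose(100, 5), tolerance = 1e-9)
  expect_true(en$significant[en$term == "G"])
})

test_that("proportionally distributed hits are never enriched", {
  ann <- data.frame(gene_id = paste0("g", 1:100),
                    cog = rep(c("G", "E"), 50),
                    kegg = rep(c("ko00010", "ko00020"), each = 50))
  bg <- paste0("g", 1:100)
  hits <- paste0("g", 1:10)                # 5 G / 5 E, 10/0 by kegg? no: 1:10 all ko00010
  en <- enrichment_test(paste0("g", c(1:5, 51:55)), ann, bg)
  expect_false(any(en$significant))
})

test_that("mash distance equals the closed form on exact Jaccard", {
  set.seed(14)
  cfg <- sketch_config(k = 11, sketch_size = 100000)
  s1 <- random_dna(300)
  s2 <- random_dna(300)
  d <- mash_distance(c(a = s1, b = s2), cfg)
  j <- exact_canonical_jaccard(s1, s2, 11)
  expected <- if (j == 0) 1 else min(1, -(1 / 11) * log(2 * j / (1 + j)))
  expect_equal(unname(d["a", "b"]), expected, tolerance = 1e-12)

  expect_equal(unname(mash_distance(c(x = s1, y = s1), cfg)["x", "y"]), 0)
  ## disjoint k-mer sets -> capped at 1
  p1 <- paste(rep("ACCCTG", 10), collapse = "")
  p2 <- paste(rep("GATTAA", 10), collapse = "")
  expect_equal(unname(mash_distance(c(x = p1, y = p2), cfg)["x", "y"]), 1)
})

test_that("sketch parameters are validated and short sequences rejected", {
  expect_error(sketch_config(k = 12), "odd")
  expect_error(sketch_config(k = 9), "11")
  expect_error(sketch_config(sketch_size = 0), "sketch_size")
  expect_error(mash_distance(c(tiny = "ACGT"), sketch_config()), "tiny")
})

test_that("subsampled sketches still approximate the exact distance", {
  set.seed(15)
  base <- random_dna(2000)
  mut <- strsplit(base, "")[[1]]
  idx <- sample(2000, 40)
  mut[idx] <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
  s2 <- paste(mut, collapse = "")
  exact <- mash_distance(c(a = base, b = s2),
                         sketch_config(k = 15, sketch_size = 1e6))["a", "b"]
  approx <- mash_distance(c(a = base, b = s2),
                          sketch_config(k = 15, sketch_size = 300))["a", "b"]
  expect_lt(abs(exact - approx), 0.02)
})

test_that("MDS geometry behaves on canonical configurations", {
  ## equilateral triangle: two equal positive eigenvalues
  d <- make_dist(c("a", "b", "c"), c(1, 1, 1))
  co <- mds_covariates(d, var_frac = 0.99)
  ev <- attr(co, "eig")
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  expect_equal(ev[1], 0.5, tolerance = 1e-9)   # centered Gram eigenvalues
  expect_equal(ncol(co), 2L)

  ## collinear points: one axis reproduces the line up to reflection
  x <- c(0, 1, 3, 6)
  dl <- as.matrix(dist(x))
  dimnames(dl) <- list(paste0("p", 1:4), paste0("p", 1:4))
  col1 <- mds_covariates(dl, var_frac = 0.8)
  expect_equal(ncol(col1), 1L)
  expect_equal(unname(as.matrix(dist(col1[, 1]))), unname(dl),
               tolerance = 1e-9)

  ## Euclidean input: no meaningful negative eigenvalue
  set.seed(16)
  pts <- matrix(rnorm(30), 10)
  de <- as.matrix(dist(pts))
  evs <- attr(mds_covariates(de, var_frac = 0.5), "eig")
  expect_gt(min(evs), -1e-9 * max(evs))

  expect_error(mds_covariates(matrix(0, 3, 3)), "degenerate")
})

test_that("MDS axes are deterministic in sign", {
  set.seed(17)
  pts <- matrix(rnorm(24), 8)
  d <- as.matrix(dist(pts))
  a <- mds_covariates(d)
  b <- mds_covariates(d[rev(1:8), rev(1:8)])
  for (j in seq_len(ncol(a)))
    expect_gt(a[which.max(abs(a[, j])), j], 0)
})

test_that("continuous GWAS equals the full least-squares fit", {
  set.seed(18)
  n <- 80
  v <- matrix(rbinom(n * 5, 1, 0.3), n,
              dimnames = list(paste0("s", 1:n), paste0("v", 1:5)))
  cov <- matrix(rnorm(n * 2), n, dimnames = list(paste0("s", 1:n),
                                                 c("m1", "m2")))
  y <- setNames(10 + 3 * v[, 2] + cov[, 1] + rnorm(n), paste0("s", 1:n))
  res <- phenotype_gwas(v, y, covariates = cov)
  for (j in 1:5) {
    fit <- summary(lm(y ~ v[, j] + cov))$coefficients
    expect_equal(res$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(res$p[j], fit[2, 4], tolerance = 1e-10)
  }
  expect_equal(res$threshold, rep(0.05 / 5, 5))
})

test_that("binary GWAS matches glm and survives separation via Firth", {
  set.seed(19)
  n <- 60
  v <- matrix(rbinom(n * 3, 1, 0.4), n,
              dimnames = list(paste0("s", 1:n), paste0("v", 1:3)))
  y <- setNames(rbinom(n, 1, plogis(-0.5 + v[, 1])), paste0("s", 1:n))
  res <- phenotype_gwas(v, factor(y), covariates = NULL)
  fit <- summary(glm(y ~ v[, 1], family = binomial))$coefficients
  expect_equal(res$beta[1], fit[2, 1], tolerance = 1e-6)
  expect_equal(res$p[1], fit[2, 4], tolerance = 1e-6)

  ## perfect separation: plain ML diverges, Firth stays finite
  ysep <- setNames(v[, 2], rownames(v))
  res_sep <- phenotype_gwas(v[, 2, drop = FALSE], factor(ysep))
  expect_true(is.finite(res_sep$beta[1]))
  expect_true(is.finite(res_sep$p[1]))
  expect_lt(abs(res_sep$beta[1]), 15)
})

test_that("MDS covariates absorb planted population confounding", {
  set.seed(20)
  n <- 60
  pop <- rep(0:1, each = n / 2)
  ## variant tracks population; phenotype driven by population, not variant
  v <- matrix(rbinom(n, 1, ifelse(pop == 1, 0.9, 0.1)), n,
              dimnames = list(paste0("s", 1:n), "confounded"))
  y <- setNames(10 + 8 * pop + rnorm(n, 0, 1), paste0("s", 1:n))
  ## structure distances reflect population membership
  coords <- cbind(pop * 4 + rnorm(n, 0, 0.3), rnorm(n, 0, 0.3))
  d <- as.matrix(dist(coords))
  dimnames(d) <- list(names(y), names(y))
  mds <- mds_covariates(d)
  naive <- phenotype_gwas(v, y)
  corrected <- phenotype_gwas(v, y, covariates = mds)
  expect_true(naive$p[1] < 0.05)
  expect_gt(corrected$p[1], 0.05)
})

test_that("missing phenotypes are dropped casewise", {
  set.seed(21)
  v <- matrix(rbinom(40, 1, 0.5), 20,
              dimnames = list(paste0("s", 1:20), c("v1", "v2")))
  y <- setNames(rnorm(20), rownames(v))
  y[c(3, 7)] <- NA
  res <- phenotype_gwas(v, y)
  fit <- summary(lm(y ~ v[, 1]))$coefficients   # lm drops NAs too
  expect_equal(res$beta[1], fit[2, 1], tolerance = 1e-10)
})

test_that("genotype effect sizes saturate for a determined genotype", {
  set.seed(22)
  n <- 30
  g <- factor(rep(c("x", "y", "z"), each = 10))
  v <- cbind(a = as.integer(g == "x"), b = as.integer(g == "y"))
  rownames(v) <- paste0("s", 1:n)
  cv <- data.frame(g = g, const = rep(1, n),
                   row.names = paste0("s", 1:n))
  expect_message(out <- genotype_effectsizes(v, cv, permutations = 49,
                                             seed = 1),
                 "zero-variance")
  rda_full <- out$R2[out$method == "RDA" & out$term == "full"]
  expect_equal(rda_full, 1, tolerance = 1e-9)
  pm_g <- out$R2[out$method == "PERMANOVA" & out$term == "g"]
  expect_equal(pm_g, 1, tolerance = 1e-9)
})
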