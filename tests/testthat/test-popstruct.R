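test_that("clonal pruning keeps all strains when none are clonal", {
  d <- make_dist(c("a", "b", "c"), c(400, 500, 600))
  pr <- prune_clonal(d, 300)
  expect_setequal(pr$representatives, c("a", "b", "c"))
})

test_that("clonal clusters are single-linkage components", {
  d <- make_dist(c("A", "B", "C"), c(100, 250, 100))
  pr <- prune_clonal(d, 300, seed = 1)
  expect_length(pr$clusters, 1L)
  expect_setequal(pr$clusters[[1]], c("A", "B", "C"))
  expect_length(pr$representatives, 1L)
})

test_that("representatives are mutually non-clonal", {
  set.seed(4)
  for (rep in 1:5) {
    n <- 12
    d <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
    v <- sample(50:1000, n * (n - 1) / 2, replace = TRUE)
    d[upper.tri(d)] <- v
    d[lower.tri(d)] <- t(d)[lower.tri(d)]
    pr <- prune_clonal(d, 300, seed = rep)
    reps <- pr$representatives
    if (length(reps) > 1)
      expect_true(all(d[reps, reps][upper.tri(diag(length(reps)))] >= 300))
  }
})

test_that("painting puts all row mass on an identical donor", {
  geno <- rbind(r1 = rep(c(0L, 1L), 10),
                d1 = rep(c(0L, 1L), 10),
                d2 = rep(1L, 20),
                d3 = rep(0L, 20))
  p <- paint_chromosomes(make_snps(geno), window_snps = 10)
  expect_equal(p$n_windows, 2L)
  expect_equal(unname(p$matrix["r1", "d1"]), 2)
  expect_equal(sum(p$matrix["r1", ]), 2)
})

test_that("window-specific donors each earn their chunk", {
  ## recipient matches d1 exactly in window 1, d2 exactly in window 2
  geno <- rbind(rec = c(rep(0L, 10), rep(1L, 10)),
                d1  = c(rep(0L, 10), rep(0L, 10)),
                d2  = c(rep(1L, 10), rep(1L, 10)),
                far = rep(c(1L, 0L), 10))
  p <- paint_chromosomes(make_snps(geno), window_snps = 10)
  expect_equal(unname(p$matrix["rec", c("d1", "d2")]), c(1, 1))
})

test_that("donor ties split the chunk and conserve row mass", {
  geno <- rbind(rec = rep(0L, 10),
                t1 = rep(0L, 10),
                t2 = rep(0L, 10),
                far = rep(1L, 10))
  p <- paint_chromosomes(make_snps(geno), window_snps = 10)
  expect_equal(unname(p$matrix["rec", c("t1", "t2")]), c(0.5, 0.5))
  expect_equal(unname(rowSums(p$matrix)), rep(1, 4))
})

test_that("co-ancestry row sums equal the window count on noisy data", {
  set.seed(8)
  geno <- matrix(sample(c(0L, 1L), 8 * 57, replace = TRUE), nrow = 8)
  p <- paint_chromosomes(make_snps(geno), window_snps = 10)
  ## 5 full windows + trailing 7 >= half window -> 6 windows
  expect_equal(p$n_windows, 6L)
  expect_equal(unname(rowSums(p$matrix)), rep(6, 8), tolerance = 1e-12)
})

test_that("trailing windows below half size merge into the previous one", {
  geno <- matrix(sample(c(0L, 1L), 6 * 23, replace = TRUE), nrow = 6)
  p <- paint_chromosomes(make_snps(geno), window_snps = 10)
  expect_equal(p$n_windows, 2L)
  expect_equal(unname(p$windows[2, ]), c(11, 23))
})

test_that("block-diagonal co-ancestry recovers the planted K", {
  set.seed(5)
  mk <- function(sizes) {
    n <- sum(sizes)
    m <- matrix(1, n, n)
    off <- cumsum(c(0, sizes))
    for (b in seq_along(sizes)) {
      idx <- (off[b] + 1):off[b + 1]
      m[idx, idx] <- 20 + matrix(runif(length(idx)^2), length(idx))
    }
    diag(m) <- 0
    m <- m / rowSums(m) * 50           # row sums = W
    dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
    m
  }
  ca3 <- mk(c(6, 6, 6))
  a3 <- cluster_populations(ca3, 2:6)
  expect_equal(a3$K, 3L)
  planted <- rep(1:3, each = 6)
  expect_equal(adjusted_rand_index(a3$labels, planted), 1)
  expect_false(a3$weak_structure)

  ca2 <- mk(c(8, 8))
  a2 <- cluster_populations(ca2, 2:6)
  expect_equal(a2$K, 2L)
})

test_that("structureless co-ancestry is flagged weak", {
  set.seed(6)
  n <- 12
  m <- matrix(10 + runif(n * n), n, n)
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  a <- cluster_populations(m, 2:5)
  expect_true(a$weak_structure)
  expect_error(cluster_populations(m, 2:20), "k_range")
})

test_that("small-cluster rerun drops to representatives and repaints", {
  cfg <- sim_config(seed = 31, genome_length = 20000, n_populations = 2,
                    strains_per_population = 8, mutation_scale = 0.004)
  sim <- simulate_genomes(cfg)
  snps <- call_core_snps(sim$genomes)
  p <- paint_chromosomes(snps, 50)
  a <- cluster_populations(p, 2:6)
  ## force a fake small cluster by relabeling two strains
  forced <- a
  forced$labels[1:2] <- max(a$labels) + 1L
  out <- small_cluster_rerun(forced, snps, min_size = 4, window_snps = 50,
                             k_range = 2:6, seed = 1)
  expect_equal(length(out$labels), length(a$labels) - 1L)

  untouched <- small_cluster_rerun(a, snps, min_size = 2)
  expect_identical(untouched$labels, a$labels)
})

test_that("palettes aggregate donor mass by population and sum to 1", {
  ca <- structure(list(matrix = rbind(r = c(r = 0, a1 = 2, a2 = 1, b1 = 1),
                                      a1 = c(1, 0, 2, 1),
                                      a2 = c(1, 2, 0, 1),
                                      b1 = c(2, 1, 1, 0)),
                       n_windows = 4, window_snps = 10),
                  class = "coancestry")
  colnames(ca$matrix) <- rownames(ca$matrix)
  labels <- c(r = "A", a1 = "A", a2 = "A", b1 = "B")
  pal <- compute_palettes(ca, labels)
  expect_equal(unname(pal["r", ]), c(0.75, 0.25))
  expect_equal(unname(rowSums(pal)), rep(1, 4))
})

test_that("fixed differences give theta = 1 and label swap leaves it unchanged", {
  geno <- rbind(matrix(0L, 4, 6), matrix(1L, 4, 6))
  rownames(geno) <- paste0("s", 1:8)
  snps <- make_snps(geno)
  labels <- setNames(rep(c("p1", "p2"), each = 4), rownames(geno))
  fst <- weir_cockerham_fst(snps, labels)
  expect_equal(fst$theta[fst$pop1 == "all"], 1)

  swapped <- make_snps(1L - geno)
  fst2 <- weir_cockerham_fst(swapped, labels)
  expect_equal(fst2$theta, fst$theta, tolerance = 1e-12)
})

test_that("theta matches an independent ANOVA-based evaluation", {
  ## allele counts 8/2 vs 2/8, n = 10 each, plus randomized multi-locus sets
  wc_oracle <- function(geno, labels) {
    sum_a <- sum_ab <- 0
    r <- length(unique(labels))
    for (l in seq_len(ncol(geno))) {
      x <- geno[, l]; g <- factor(labels)
      if (anyNA(x) || length(unique(x)) < 2) next
      fit <- stats::anova(stats::lm(x ~ g))
      msp <- fit$`Mean Sq`[1]; msg <- fit$`Mean Sq`[2]
      ni <- tabulate(g)
      nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
      a <- (msp - msg) / nc
      sum_a <- sum_a + a; sum_ab <- sum_ab + a + msg
    }
    sum_a / sum_ab
  }
  geno <- cbind(c(rep(1L, 8), rep(0L, 2), rep(1L, 2), rep(0L, 8)))
  rownames(geno) <- paste0("s", 1:20)
  labels <- setNames(rep(c("p1", "p2"), each = 10), rownames(geno))
  fst <- weir_cockerham_fst(make_snps(geno), labels)
  expect_equal(fst$theta[1], wc_oracle(geno, labels), tolerance = 1e-12)

  set.seed(9)
  for (rep in 1:5) {
    geno <- matrix(rbinom(30 * 12, 1, runif(12, .1, .9)), nrow = 30,
                   byrow = TRUE)
    geno <- matrix(as.integer(geno), nrow = 30)
    rownames(geno) <- paste0("s", 1:30)
    labels <- setNames(rep(c("p1", "p2", "p3"), each = 10), rownames(geno))
    fst <- weir_cockerham_fst(make_snps(geno), labels)
    expect_equal(fst$theta[fst$pop1 == "all"], wc_oracle(geno, labels),
                 tolerance = 1e-12)
  }
})

test_that("identical allele frequencies give near-zero theta", {
  set.seed(10)
  thetas <- vapply(1:20, function(i) {
    geno <- matrix(rbinom(40 * 20, 1, rep(runif(20, .2, .8), each = 40)),
                   nrow = 40)
    geno <- matrix(as.integer(geno), nrow = 40)
    rownames(geno) <- paste0("s", 1:40)
    labels <- setNames(rep(c("p1", "p2"), 20), rownames(geno))
    weir_cockerham_fst(make_snps(geno), labels)$theta[1]
  }, numeric(1))
  expect_lt(abs(mean(thetas)), 0.05)
})

test_that("undersized populations are excluded with a warning", {
  geno <- matrix(rep(c(0L, 1L), each = 10), nrow = 5)
  rownames(geno) <- paste0("s", 1:5)
  labels <- setNames(c("p1", "p1", "p2", "p2", "p3"), rownames(geno))
  expect_warning(weir_cockerham_fst(make_snps(geno), labels), "p3")
})

test_that("adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(11)
  for (i in 1:5) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
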