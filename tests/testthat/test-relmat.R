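test_that("MRM equals an explicit step-by-step recomputation", {
  counts <- matrix(c(10, 0, 5,
                     2, 8, 1,
                     7, 7, 7,
                     0, 3, 12), 4, 3, byrow = TRUE,
                   dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  cohorts <- rep("c1", 4)
  m <- build_mrm(counts, cohorts)

  # independent arithmetic: pseudo-count, proportions, log10, per-cohort
  # z-score, pairwise Pearson correlation
  tot <- rowSums(counts)
  lp <- matrix(NA_real_, 4, 3)
  for (i in 1:4) for (j in 1:3) lp[i, j] <- log10((counts[i, j] + 1) / tot[i])
  z <- lp
  for (j in 1:3) z[, j] <- (lp[, j] - mean(lp[, j])) / sd(lp[, j])
  # within-cohort normalisation property
  expect_equal(colMeans(z), rep(0, 3), tolerance = 1e-8)
  expect_equal(apply(z, 2, sd), rep(1, 3), tolerance = 1e-8)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(m[i, j], cor(z[i, ], z[j, ]), tolerance = 1e-12)

  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(m, t(m))
})

test_that("MRM cohort normalisation zeroes out flat tags and needs cohorts >= 2", {
  counts <- matrix(c(5, 5, 1,
                     5, 5, 9,
                     5, 2, 4,
                     5, 1, 8), 4, 3, byrow = TRUE,
                   dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  m <- build_mrm(counts, c("a", "a", "b", "b"), total_reads = rep(10, 4))
  expect_true(all(is.finite(m)))
  expect_error(build_mrm(counts, c("a", "a", "b", "c")), "cohort")
})

test_that("MRM is equivariant under sample permutation and stable under depth scaling", {
  set.seed(6)
  counts <- matrix(rpois(12 * 40, 200), 12, 40,
                   dimnames = list(paste0("s", 1:12), paste0("t", 1:40)))
  cohorts <- rep(c("a", "b"), each = 6)
  m <- build_mrm(counts, cohorts)
  perm <- sample(12)
  m_p <- build_mrm(counts[perm, ], cohorts[perm])
  expect_equal(unname(m_p), unname(m[perm, perm]), tolerance = 1e-12,
               ignore_attr = TRUE)

  # exact count scaling acts only through depth; with the pseudo-count the
  # effect is a vanishing perturbation at these depths
  scaled <- counts
  scaled[3, ] <- scaled[3, ] * 7L
  m_s <- build_mrm(scaled, cohorts)
  expect_lt(max(abs(offdiag(m_s) - offdiag(m))), 0.02)
})

test_that("log10 and centred log-ratio MRMs agree closely on dense data", {
  set.seed(7)
  n <- 30; k <- 200
  lat <- matrix(rnorm(n * k, 5, 0.5), n, k) +
    outer(rnorm(n), rep(1, k))
  counts <- matrix(rpois(n * k, exp(lat)), n, k,
                   dimnames = list(paste0("s", 1:n), paste0("t", 1:k)))
  cohorts <- rep(c("a", "b", "c"), each = 10)
  m1 <- build_mrm(counts, cohorts, normalization = "cohort_log10")
  m2 <- build_mrm(counts, cohorts, normalization = "clr")
  expect_gt(cor(offdiag(m1), offdiag(m2)), 0.95)
})

test_that("GRM with complete data equals the dense VanRaden oracle", {
  set.seed(8)
  p <- runif(200, 0.05, 0.5)
  x <- matrix(rbinom(20 * 200, 2, rep(p, each = 20)), 20, 200,
              dimnames = list(paste0("a", 1:20), paste0("m", 1:200)))
  g <- build_grm(x, maf_min = 0, call_rate_min = 0)

  phat <- colMeans(x) / 2
  w <- sweep(x, 2, 2 * phat)
  oracle <- (w %*% t(w)) / sum(2 * phat * (1 - phat))
  expect_equal(unname(g), unname(oracle), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("GRM pairwise missing handling matches direct arithmetic", {
  x <- matrix(c(0, 1, 2, 1,
                2, NA, 1, 0,
                1, 1, 0, 2), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("m", 1:4)))
  g <- build_grm(x, maf_min = 0, call_rate_min = 0)

  p <- colMeans(x, na.rm = TRUE) / 2
  het <- 2 * p * (1 - p)
  for (i in 1:3) for (j in 1:3) {
    s <- which(!is.na(x[i, ]) & !is.na(x[j, ]))
    num <- sum((x[i, s] - 2 * p[s]) * (x[j, s] - 2 * p[s]))
    expect_equal(g[i, j], num / sum(het[s]), tolerance = 1e-12)
  }
})

test_that("GRM filters SNPs on MAF and call rate, and flags duplicates", {
  set.seed(9)
  p <- runif(50, 0.2, 0.5)
  x <- matrix(rbinom(10 * 50, 2, rep(p, each = 10)), 10, 50)
  x <- cbind(x, mono = 0L)                      # MAF 0 -> dropped
  low_cr <- rbinom(10, 2, 0.4); low_cr[1:5] <- NA
  x <- cbind(x, low_cr = low_cr)                # call rate 0.5 -> dropped
  rownames(x) <- paste0("a", 1:10)
  g <- build_grm(x, maf_min = 0.01, call_rate_min = 0.70)
  expect_equal(attr(g, "n_snps_used"), 50L)

  # duplicated animal: off-diagonal equals both self-relationships
  x2 <- x[c(1, 1, 2:10), ]
  rownames(x2) <- paste0("a", 1:11)
  g2 <- build_grm(x2, maf_min = 0.01, call_rate_min = 0.70)
  expect_equal(g2[1, 2], g2[1, 1])
  expect_equal(g2[1, 2], g2[2, 2])
})

test_that("relationship-matrix PCA behaves on rank-1 and structureless inputs", {
  v <- c(3, -1, 2, 0.5, -2)
  rel <- tcrossprod(v)
  res <- rm_pca(rel, 2)
  expect_equal(res$var_explained[1], 1)
  expect_equal(abs(cor(res$scores[, 1], v)), 1, tolerance = 1e-8)

  k <- rand_kernel(40, seed = 10)
  res2 <- rm_pca(k, 4)
  s <- crossprod(res2$scores)
  expect_equal(unname(s[upper.tri(s)]), rep(0, 6), tolerance = 1e-8)
  expect_error(rm_pca(k, 41), "n_components")

  # single synthetic population: first PC uncorrelated with random labels
  set.seed(11)
  cfg <- sim_config(n_animals = 60, n_snps = 20, n_tags = 300,
                    depth_log_mean = log(5000), seed = 11)
  pop <- simulate_population(cfg)
  counts <- simulate_metagenome(pop$truth, cfg)
  m <- build_mrm(counts, pop$phenotypes$cohort)
  pc1 <- rm_pca(m, 1)$scores[, 1]
  lab <- rbinom(60, 1, 0.5)
  expect_lt(abs(cor(pc1, lab)), 0.3)
})

test_that("kernel eigendecomposition rejects indefinite matrices", {
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(kernel_eigen(bad), "positive semi-definite")
  expect_error(kernel_eigen(matrix(c(1, 0.5, 0.4, 1), 2)), "symmetric")
})
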