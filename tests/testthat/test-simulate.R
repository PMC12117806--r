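test_that("simulation is a pure function of config and seed", {
  cfg <- sim_config(n_animals = 60, n_snps = 40, n_tags = 30,
                    depth_log_mean = log(500), seed = 7)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a, b)
  expect_identical(simulate_metagenome(a$truth, cfg),
                   simulate_metagenome(b$truth, cfg))
  cfg2 <- sim_config(n_animals = 60, n_snps = 40, n_tags = 30,
                     depth_log_mean = log(500), seed = 8)
  c2 <- simulate_population(cfg2)
  expect_false(isTRUE(all.equal(a$truth$lot_factors,
                                c2$truth$lot_factors)))
})

test_that("degenerate variance components behave as stated", {
  cfg0 <- sim_config(n_animals = 48, n_snps = 30, sigma2_g = 0, seed = 1)
  pop <- simulate_population(cfg0)
  expect_equal(var(pop$truth$true_g), 0)

  cfgm <- sim_config(n_animals = 48, n_snps = 30, sigma2_m = 0, seed = 1)
  expect_equal(unname(simulate_population(cfgm)$truth$true_m),
               rep(0, 48))

  cfg <- sim_config(n_animals = 48, n_snps = 30,
                    sigma2_g = 0.16, sigma2_m = 0, sigma2_e = 0.84)
  expect_equal(sim_truth <- simulate_population(cfg)$truth$true_h2, 0.16)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_animals = 10, lot_size = 12), "lot_size")
  expect_error(sim_config(sigma2_g = -0.1), "sigma2_g")
  expect_error(sim_config(rho_gm = 1.5), "rho_gm")
  expect_error(sim_config(n_tags = 0), "n_tags")
})

test_that("metagenome counts conserve the drawn sequencing depth", {
  cfg <- sim_config(n_animals = 24, n_snps = 20, n_tags = 200,
                    depth_log_mean = log(2000), seed = 3)
  pop <- simulate_population(cfg)
  counts <- simulate_metagenome(pop$truth, cfg)
  expect_equal(unname(rowSums(counts)),
               unname(as.numeric(attr(counts, "total_reads"))))
  expect_true(all(attr(counts, "total_reads") > 0))
  expect_true(all(nchar(colnames(counts)) == 65))
  expect_false(anyDuplicated(colnames(counts)) > 0)
})

test_that("animals with equal microbial values give near-unit MRM entries as noise vanishes", {
  # all within-cohort latent variation comes from the microbial values:
  # loadings on every tag, no batch shifts, vanishing latent noise, and a
  # deep fixed depth so multinomial noise is negligible
  cfg <- sim_config(n_animals = 4, n_snps = 10, n_tags = 300, lot_size = 2,
                    tag_noise_sd = 1e-8, batch_sd = 0, load_frac = 1,
                    load_sd = 1.5, depth_log_mean = log(2e6),
                    depth_log_sd = 0, seed = 5)
  truth <- list(true_m = c(a1 = 1, a2 = 1, a3 = -1, a4 = 0.3),
                cohort_labels = c(a1 = "c", a2 = "c", a3 = "c", a4 = "c"))
  counts <- simulate_metagenome(truth, cfg)
  m <- build_mrm(counts, truth$cohort_labels)
  expect_gt(m["a1", "a2"], 0.9)
  expect_gt(m["a1", "a2"], max(m["a1", "a3"], m["a1", "a4"]))
})

test_that("read simulation and tag extraction are inverse operations", {
  set.seed(11)
  n_s <- 10; n_t <- 50
  counts <- matrix(rpois(n_s * n_t, 3), n_s, n_t,
                   dimnames = list(paste0("s", 1:n_s), rand_seq(n_t)))
  storage.mode(counts) <- "integer"
  counts[2, ] <- 0L                       # empty sample
  dir <- tempfile("reads")
  paths <- simulate_reads(counts, dir, seed = 42)
  expect_equal(length(readLines(paths[2])), 0L)
  extr <- lapply(paths, extract_tags)
  back <- tag_count_matrix(extr, tag_ids = colnames(counts))
  expect_equal(unname(back), unname(counts), ignore_attr = TRUE)

  bad <- counts
  colnames(bad)[1] <- paste0(strrep("A", 64), "N")
  expect_error(simulate_reads(bad, tempfile()), "A, C, G, T")
})

test_that("realized variance ratio converges to the configured heritability", {
  cfg <- sim_config(n_animals = 5000, n_snps = 300, sigma2_g = 0.3,
                    sigma2_m = 0.2, sigma2_e = 0.5, rho_gm = 0,
                    seed = 9)
  tr <- simulate_population(cfg)$truth
  realized <- var(tr$true_g) / var(tr$true_g + tr$true_m + tr$true_e)
  expect_equal(realized, tr$true_h2, tolerance = 0.03 / tr$true_h2)
})

test_that("larger genetic variance raises the mean heritability estimate", {
  mean_h2 <- function(s2g, reps = 5) {
    mean(sapply(seq_len(reps), function(r) {
      cfg <- sim_config(n_animals = 300, n_snps = 800, sigma2_g = s2g,
                        sigma2_m = 0, sigma2_e = 1 - s2g, seed = 100 + r)
      pop <- simulate_population(cfg)
      G <- build_grm(pop$genotypes, maf_min = 0, call_rate_min = 0)
      scaled <- scale_by_lot(pop$phenotypes$y, pop$phenotypes$lot_id, 7.5)
      ys <- adjust_phenotype(scaled, build_design(pop$phenotypes))
      kreml(y ~ 1, data.frame(y = ys), G, se = FALSE)$ratio
    }))
  }
  expect_gt(mean_h2(0.5), mean_h2(0.05))
})
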