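test_that("forward splits train on the past and validate on the target year", {
  meta <- data.frame(animal_id = paste0("a", 1:9),
                     birth_year = rep(c(2019, 2020, 2021), each = 3))
  plan <- forward_split(meta, 2021)
  expect_equal(unname(plan$assignment),
               rep(c("train", "train", "validate"), each = 3))
  expect_error(forward_split(meta, 2023), "absent")
  expect_error(forward_split(data.frame(animal_id = "x", birth_year = 2021),
                             2021), "empty")
  expect_error(forward_split(meta, 2020), "after the validation year")
})

test_that("CV folds keep cohorts whole and partition all animals", {
  meta <- data.frame(animal_id = paste0("a", 1:66),
                     cohort = rep(paste0("c", 1:11), each = 6),
                     flock = rep(paste0("f", 1:4), length.out = 66))
  meta$flock <- rep(paste0("f", rep(1:4, c(3, 3, 3, 2))), each = 6)[1:66]
  plan <- cv_folds(meta, n_folds = 11, seed = 1)
  expect_equal(sort(unique(plan$assignment)), 1:11)
  expect_equal(as.numeric(table(plan$assignment)), rep(6, 11))  # one cohort each

  # hard constraint: no cohort in two folds
  ftab <- table(meta$cohort, plan$assignment)
  expect_true(all(rowSums(ftab > 0) == 1))
  expect_error(cv_folds(meta, n_folds = 20), "exceeds")
})

test_that("greedy packing balances realistic cohort sizes", {
  set.seed(50)
  sizes <- pmax(8, round(rnorm(38, 93, 60)))           # 38 uneven cohorts
  meta <- data.frame(
    animal_id = paste0("a", seq_len(sum(sizes))),
    cohort = rep(paste0("c", 1:38), sizes),
    flock = rep(paste0("f", sample(1:8, 38, replace = TRUE)), sizes))
  plan <- cv_folds(meta, n_folds = 11, seed = 3)
  expect_equal(sum(plan$fold_sizes), sum(sizes))
  expect_lt(max(plan$fold_sizes) / min(plan$fold_sizes), 1.65)
  # deterministic given the seed
  plan2 <- cv_folds(meta, n_folds = 11, seed = 3)
  expect_identical(plan$assignment, plan2$assignment)
})

test_that("prediction evaluation recovers perfect, inverted and null signals", {
  set.seed(51)
  g <- rep(paste0("g", 1:10), each = 100)
  y <- rnorm(1000)
  res <- evaluate_predictions(y, y, g)
  expect_equal(unname(res$summary["accuracy", "mean"]), 1)
  expect_equal(unname(res$summary["slope", "mean"]), 1)

  res_neg <- evaluate_predictions(-y, y, g)
  expect_equal(unname(res_neg$summary["accuracy", "mean"]), -1)
  expect_equal(unname(res_neg$summary["slope", "mean"]), -1)

  res_null <- evaluate_predictions(rnorm(1000), y, g)
  expect_lt(abs(res_null$summary["accuracy", "mean"]), 0.1)

  # small and degenerate groups are skipped
  expect_warning(
    evaluate_predictions(c(y, rep(1, 5)), c(y, rnorm(5)),
                         c(g, rep("flat", 5))),
    "zero-variance")
})

test_that("relative efficacy reproduces its defining arithmetic", {
  expect_equal(round(relative_efficacy(0.75, 0.21, 0.37)), 1)
  expect_equal(round(relative_efficacy(0.62, 0.14, 0.22), 2), 0.78)
  expect_equal(relative_efficacy(0, 0.2, 0.4), 0)
  # depends only on variance ratios, not trait scales
  expect_equal(relative_efficacy(0.5, 0.2, 0.3),
               0.5 * sqrt(0.3 / 0.2))
  expect_error(relative_efficacy(0.5, 0, 0.3), "positive")
  expect_error(relative_efficacy(1.2, 0.2, 0.3), "rho_g")
})

test_that("metagenome kernel out-predicts the genomic kernel when microbial variance dominates", {
  cfg <- sim_config(n_animals = 400, n_snps = 800, n_tags = 1000,
                    sigma2_g = 0.02, sigma2_m = 0.6, sigma2_e = 0.38,
                    rho_gm = 0, depth_log_mean = log(3e4),
                    lot_effect_sd = 0.1, seed = 52)
  pop <- simulate_population(cfg)
  counts <- simulate_metagenome(pop$truth, cfg)
  M <- build_mrm(counts, pop$phenotypes$cohort)
  G <- build_grm(pop$genotypes, maf_min = 0, call_rate_min = 0)
  scaled <- scale_by_lot(pop$phenotypes$y, pop$phenotypes$lot_id, 7.5)
  ys <- adjust_phenotype(scaled, build_design(pop$phenotypes))

  plan <- forward_split(pop$phenotypes, max(pop$phenotypes$birth_year))
  tr <- names(plan$assignment)[plan$assignment == "train"]
  va <- names(plan$assignment)[plan$assignment == "validate"]
  ids <- pop$phenotypes$animal_id
  acc <- sapply(list(M = M, G = G), function(K) {
    f <- kreml(y ~ 1, data.frame(y = ys[ids %in% tr]), K[tr, tr],
               se = FALSE)
    cor(blup_predict(f, K, tr, va), ys[ids %in% va])
  })
  expect_gt(acc["M"], acc["G"])
})
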