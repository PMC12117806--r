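#' Simulation configuration
#'
#' Bundles the data-generating assumptions for a synthetic sheep population
#' with host-genetic, microbial, cohort, lot and sequencing-depth structure.
#' The defaults are scaled-down but structurally faithful study conditions:
#' animals measured in lots of 12, cohorts defined by flowcell x flock x
#' birth-year x sex, a CH4-like trait with overall mean 7.5 g/day, and a
#' variance partition (sigma2_g = 0.16, sigma2_m = 0.54 of a unit total)
#' matching moderate heritability and high microbiability.
#'
#' @param n_animals number of animals.
#' @param n_snps number of biallelic SNPs.
#' @param n_tags number of 65-bp sequence tags in the metagenome profile.
#' @param n_flocks,n_years,n_flowcells cohort-structure dimensions.
#' @param lot_size animals measured simultaneously per lot (default 12).
#' @param sigma2_g additive-genetic variance of the latent trait.
#' @param sigma2_m microbial variance of the latent trait.
#' @param sigma2_e residual variance of the latent trait.
#' @param rho_gm correlation between the genetic and microbial drivers;
#'   induces a genetic covariance between a trait and its microbial proxy.
#' @param lot_effect_sd standard deviation of log multiplicative lot factors
#'   (time-off-feed scaling of gas emissions).
#' @param depth_log_mean,depth_log_sd meanlog/sdlog of the log-normal
#'   per-sample sequencing depth.
#' @param missing_rate probability that a genotype call is missing.
#' @param maf_range range from which per-SNP allele frequencies are drawn
#'   uniformly; the default keeps all SNPs past a 0.01 MAF filter, widen to
#'   c(0, 0.5) to stress-test filtering.
#' @param overall_mean population mean of the gas trait (g/day for CH4).
#' @param batch_sd sd of per-cohort-by-tag batch shifts on the latent
#'   log-abundance scale.
#' @param load_sd sd of per-tag loadings of the microbial value.
#' @param load_frac fraction of tags that respond to the microbial value.
#' @param tag_noise_sd sd of the per-animal-by-tag latent noise.
#' @param seed integer seed; all outputs are pure functions of the config.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_animals = 480, n_snps = 2000, n_tags = 5000,
                       n_flocks = 3, n_years = 2, n_flowcells = 2,
                       lot_size = 12,
                       sigma2_g = 0.16, sigma2_m = 0.54, sigma2_e = 0.30,
                       rho_gm = 0.5, lot_effect_sd = 0.2,
                       depth_log_mean = log(2e5), depth_log_sd = 0.3,
                       missing_rate = 0.02, maf_range = c(0.05, 0.5),
                       overall_mean = 7.5,
                       batch_sd = 0.7, load_sd = 0.5, load_frac = 0.3,
                       tag_noise_sd = 0.3, seed = 1L) {
  cfg <- list(n_animals = as.integer(n_animals), n_snps = as.integer(n_snps),
              n_tags = as.integer(n_tags), n_flocks = as.integer(n_flocks),
              n_years = as.integer(n_years), n_flowcells = as.integer(n_flowcells),
              lot_size = as.integer(lot_size),
              sigma2_g = sigma2_g, sigma2_m = sigma2_m, sigma2_e = sigma2_e,
              rho_gm = rho_gm, lot_effect_sd = lot_effect_sd,
              depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
              missing_rate = missing_rate, maf_range = maf_range,
              overall_mean = overall_mean,
              batch_sd = batch_sd, load_sd = load_sd, load_frac = load_frac,
              tag_noise_sd = tag_noise_sd, seed = as.integer(seed))
  counts <- c("n_animals", "n_snps", "n_tags", "n_flocks", "n_years",
              "n_flowcells")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("'", nm, "' must be a count >= 1")
  for (nm in c("sigma2_g", "sigma2_m", "sigma2_e"))
    if (cfg[[nm]] < 0) stop("'", nm, "' must be >= 0")
  if (abs(cfg$rho_gm) > 1) stop("'rho_gm' must lie in [-1, 1]")
  if (cfg$lot_size < 2L) stop("'lot_size' must be >= 2")
  if (cfg$lot_size > cfg$n_animals)
    stop("'lot_size' exceeds 'n_animals'")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("'missing_rate' must lie in [0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic population configuration\n")
  cat(sprintf("  %d animals, %d SNPs, %d tags; lots of %d\n",
              x$n_animals, x$n_snps, x$n_tags, x$lot_size))
  cat(sprintf("  cohorts: %d flocks x %d years x 2 sexes x %d flowcells\n",
              x$n_flocks, x$n_years, x$n_flowcells))
  tot <- x$sigma2_g + x$sigma2_m + x$sigma2_e
  cat(sprintf("  variances g/m/e: %.3g / %.3g / %.3g (h2 = %.3f, m2 = %.3f), rho_gm = %.2f\n",
              x$sigma2_g, x$sigma2_m, x$sigma2_e,
              if (tot > 0) x$sigma2_g / tot else NA_real_,
              if (tot > 0) x$sigma2_m / tot else NA_real_, x$rho_gm))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Simulate a SNP genotype matrix
#'
#' Allele frequencies are sampled uniformly from \code{maf_range}.  With
#' \code{family_size = NULL} animals are unrelated: genotypes are drawn per
#' SNP as Binomial(2, p_k).  With a family size, animals are grouped into
#' paternal half-sib families (the dominant relatedness structure of a
#' progeny-test sheep population): each family shares a simulated sire, and
#' every offspring receives one Mendelian gamete from the sire and one from
#' the base population.  Entries are set missing (NA) independently with
#' probability \code{missing_rate}.  Uses the current RNG state (call
#' \code{set.seed} beforehand for reproducibility).
#'
#' @param n_animals,n_snps dimensions.
#' @param maf_range allele-frequency sampling range.
#' @param missing_rate per-call missingness probability.
#' @param family_size half-sib family size, or NULL for unrelated animals.
#' @return list with \code{calls} (n_animals x n_snps integer matrix coded
#'   0/1/2/NA, dimnames set), \code{freqs} (the sampled frequencies) and
#'   \code{family} (family index per animal, or NULL).
#' @export
simulate_genotypes <- function(n_animals, n_snps, maf_range = c(0.05, 0.5),
                               missing_rate = 0, family_size = NULL) {
  p <- stats::runif(n_snps, maf_range[1], maf_range[2])
  family <- NULL
  if (is.null(family_size) || family_size <= 1) {
    calls <- matrix(stats::rbinom(n_animals * n_snps, 2L,
                                  rep(p, each = n_animals)),
                    nrow = n_animals, ncol = n_snps)
  } else {
    n_fam <- ceiling(n_animals / family_size)
    sire <- matrix(stats::rbinom(n_fam * n_snps, 2L, rep(p, each = n_fam)),
                   nrow = n_fam, ncol = n_snps)
    family <- rep(seq_len(n_fam), each = family_size,
                  length.out = n_animals)
    sire_gamete <- matrix(
      stats::rbinom(n_animals * n_snps, 1L,
                    sire[family, , drop = FALSE] / 2),
      nrow = n_animals, ncol = n_snps)
    dam_gamete <- matrix(stats::rbinom(n_animals * n_snps, 1L,
                                       rep(p, each = n_animals)),
                         nrow = n_animals, ncol = n_snps)
    calls <- sire_gamete + dam_gamete
  }
  if (missing_rate > 0) {
    miss <- stats::runif(n_animals * n_snps) < missing_rate
    calls[miss] <- NA_integer_
  }
  dimnames(calls) <- list(paste0("an", seq_len(n_animals)),
                          paste0("snp", seq_len(n_snps)))
  list(calls = calls, freqs = p, family = family)
}

#' Simulate a population with genetic, microbial, cohort and lot structure
#'
#' Generates genotypes, latent additive-genetic values \code{g} (built from
#' marker effects so that their covariance tracks the realized genomic
#' relationships), microbial values \code{m} correlated with \code{g} through
#' \code{rho_gm}, cohort metadata (flock x birth year x sex x flowcell),
#' sequential measurement lots of \code{lot_size}, multiplicative lot
#' factors, modest fixed effects (birth/rearing rank, age of dam, birthday
#' deviation, contemporary group) and the observed gas trait
#' \deqn{y = \mu \cdot lot\_factor \cdot (1 + (g + m + e + fixed)/\mu),}
#' so that lot scaling and fixed-effect adjustment are both exercised.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genotypes} (calls matrix with NAs),
#'   \code{phenotypes} (data.frame of ids, metadata, fixed-effect columns and
#'   the trait \code{y}), and \code{truth} (per-animal \code{true_g},
#'   \code{true_m}, lot factors, cohort/flowcell labels and the implied
#'   \code{true_h2}, \code{true_m2}, \code{true_rg}).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_animals

  geno <- simulate_genotypes(n, config$n_snps, config$maf_range,
                             missing_rate = 0)
  calls_full <- geno$calls

  # additive values from marker effects on centred genotypes, scaled so
  # var(g) targets sigma2_g under HWE
  if (config$sigma2_g > 0) {
    p <- geno$freqs
    denom <- sum(2 * p * (1 - p))
    a <- stats::rnorm(config$n_snps, 0, sqrt(config$sigma2_g / denom))
    g <- drop(sweep(calls_full, 2L, 2 * p) %*% a)
  } else {
    g <- numeric(n)
  }

  sd_g <- stats::sd(g)
  z_g <- if (sd_g > 0) (g - mean(g)) / sd_g else numeric(n)
  z_m <- stats::rnorm(n)
  m <- sqrt(config$sigma2_m) *
    (config$rho_gm * z_g + sqrt(1 - config$rho_gm^2) * z_m)
  e <- stats::rnorm(n, 0, sqrt(config$sigma2_e))

  # blocky cohort assignment: contiguous animals share flock/year/flowcell,
  # sexes alternate within blocks (cohorts stay >= 2 animals for usual sizes)
  flock <- rep(seq_len(config$n_flocks), each = ceiling(n / config$n_flocks),
               length.out = n)
  year_block <- ceiling(seq_len(n) / ceiling(n / (config$n_flocks * config$n_years)))
  birth_year <- 2020L + ((year_block - 1L) %% config$n_years)
  sex <- rep(c("F", "M"), length.out = n)
  flowcell <- paste0("fc", 1L + ((flock + birth_year) %% config$n_flowcells))
  cohort <- paste(flowcell, flock, birth_year, sex, sep = "_")

  lot_id <- ceiling(seq_len(n) / config$lot_size)
  n_lots <- max(lot_id)
  lot_factors <- exp(stats::rnorm(n_lots, 0, config$lot_effect_sd))

  # fixed effects entering the latent scale
  birth_rank <- sample(c("1", "2", "3"), n, replace = TRUE,
                       prob = c(0.3, 0.55, 0.15))
  age_of_dam <- sample(c("1", "2", "3+"), n, replace = TRUE,
                       prob = c(0.25, 0.35, 0.4))
  bdev <- round(stats::rnorm(n, 0, 8))
  br_eff <- c("1" = 0, "2" = -0.25, "3" = -0.45)[birth_rank]
  ad_eff <- c("1" = 0, "2" = 0.1, "3+" = 0.15)[age_of_dam]
  cg_levels <- unique(paste(flock, birth_year, sex, sep = "_"))
  cg <- paste(flock, birth_year, sex, sep = "_")
  cg_eff <- stats::setNames(stats::rnorm(length(cg_levels), 0, 0.3), cg_levels)[cg]
  fixed <- br_eff + ad_eff + 0.01 * bdev + cg_eff

  mu <- config$overall_mean
  y <- mu * lot_factors[lot_id] * (1 + (g + m + e + fixed) / mu)

  # genotype missingness applied after g is formed from the complete matrix
  calls <- calls_full
  if (config$missing_rate > 0) {
    miss <- stats::runif(n * config$n_snps) < config$missing_rate
    calls[miss] <- NA_integer_
  }

  tot <- config$sigma2_g + config$sigma2_m + config$sigma2_e
  truth <- list(true_g = stats::setNames(g, rownames(calls)),
                true_m = stats::setNames(m, rownames(calls)),
                true_e = stats::setNames(e, rownames(calls)),
                lot_factors = lot_factors,
                cohort_labels = stats::setNames(cohort, rownames(calls)),
                flowcell_labels = stats::setNames(flowcell, rownames(calls)),
                true_h2 = if (tot > 0) config$sigma2_g / tot else NA_real_,
                true_m2 = if (tot > 0) config$sigma2_m / tot else NA_real_,
                true_rg = config$rho_gm)

  phen <- data.frame(animal_id = rownames(calls), flock = factor(flock),
                     birth_year = birth_year, sex = factor(sex),
                     flowcell = factor(flowcell), cohort = cohort,
                     lot_id = lot_id, birth_rank = factor(birth_rank),
                     age_of_dam = factor(age_of_dam), bdev = bdev,
                     y = y, stringsAsFactors = FALSE)

  list(genotypes = calls, phenotypes = phen, truth = truth)
}

#' Simulate a cohort-structured tag-count matrix
#'
#' Latent per-animal tag log-abundances are the sum of a skewed tag baseline
#' (which yields sparse counts), a cohort batch shift, a tag loading times
#' the animal's microbial value, and noise.  Counts are drawn multinomially
#' per sample with a log-normal sequencing depth, so every row sum equals
#' the drawn depth.
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{simulate_population}}.
#' @param config the same \code{\link{sim_config}}.
#' @return integer matrix (samples x tags) with animal-id rownames,
#'   unique 65-bp tag sequences as colnames, and attribute
#'   \code{total_reads} (the drawn depths).
#' @export
simulate_metagenome <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(truth$true_m)
  set.seed(config$seed + 101L)
  k <- config$n_tags

  depth <- round(stats::rlnorm(n, config$depth_log_mean, config$depth_log_sd))
  if (any(depth <= 0)) stop("drawn sequencing depth must be positive")

  base <- stats::rnorm(k, 0, 2)                    # skewed baseline -> sparsity
  load <- stats::rnorm(k, 0, config$load_sd) *
    stats::rbinom(k, 1L, config$load_frac)         # only some tags respond
  cohorts <- factor(truth$cohort_labels)
  batch <- matrix(stats::rnorm(nlevels(cohorts) * k, 0, config$batch_sd),
                  nrow = nlevels(cohorts))

  lat <- matrix(base, n, k, byrow = TRUE) +
    batch[as.integer(cohorts), , drop = FALSE] +
    tcrossprod(truth$true_m, load) +
    matrix(stats::rnorm(n * k, 0, config$tag_noise_sd), n, k)
  pr <- exp(lat - apply(lat, 1L, max))
  pr <- pr / rowSums(pr)

  counts <- matrix(0L, n, k)
  for (i in seq_len(n))
    counts[i, ] <- stats::rmultinom(1L, depth[i], pr[i, ])[, 1L]

  tags <- random_tag_sequences(k, seed = config$seed + 202L)
  dimnames(counts) <- list(names(truth$true_m), tags)
  attr(counts, "total_reads") <- stats::setNames(depth, names(truth$true_m))
  counts
}

# unique random 65-mers over ACGT
random_tag_sequences <- function(k, width = 65L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    tags <- vapply(seq_len(k), function(i)
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = ""), character(1))
    if (!anyDuplicated(tags)) return(tags)
  }
}

#' Write per-sample FASTQ files realising a tag-count matrix
#'
#' Each tag sequence is emitted \code{count} times per sample (order
#' shuffled), with placeholder Phred-40 base qualities.  The tag pipeline
#' applied to the output reproduces the input counts exactly.
#'
#' @param counts samples x tags matrix; colnames must be unique sequences
#'   over A/C/G/T of a single width.
#' @param dir output directory (created if needed).
#' @param seed integer seed for the per-file read shuffles.
#' @param gzip compress output files.
#' @return named character vector of file paths (one per sample).
#' @export
simulate_reads <- function(counts, dir, seed = 1L, gzip = FALSE) {
  tags <- colnames(counts)
  if (is.null(tags) || anyDuplicated(tags))
    stop("'counts' must have unique tag sequences as colnames")
  if (any(!grepl("^[ACGT]+$", tags)))
    stop("tag sequences must contain only A, C, G, T")
  if (length(unique(nchar(tags))) != 1L)
    stop("tag sequences must all have the same length")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  samples <- rownames(counts)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(counts)))
  paths <- stats::setNames(
    file.path(dir, paste0(samples, ".fastq", if (gzip) ".gz" else "")),
    samples)
  for (i in seq_len(nrow(counts))) {
    ci <- counts[i, ]
    seqs <- rep(tags, ci)
    if (length(seqs)) seqs <- sample(seqs)
    write_fastq(seqs, paths[i], id_prefix = samples[i], gzip = gzip)
  }
  paths
}

write_fastq <- function(seqs, path, id_prefix = "read", gzip = FALSE) {
  n <- length(seqs)
  if (n == 0L) {
    file.create(path)
    return(invisible(path))
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- paste0(id_prefix, "_", seq_len(n))
  qual <- Biostrings::PhredQuality(
    vapply(Biostrings::width(dna),
           function(w) strrep("I", w), character(1)))  # Phred 40
  qs <- Biostrings::QualityScaledDNAStringSet(dna, qual)
  Biostrings::writeQualityScaledXStringSet(qs, path, compress = gzip)
  invisible(path)
}

#' Draw a trait from a kernel variance-component model
#'
#' Simulates \eqn{y = \mu + u + e} with \eqn{u \sim N(0, \sigma_u^2 K)} and
#' \eqn{e \sim N(0, \sigma_e^2 I)}, where the variance components are chosen
#' so that \eqn{\sigma_u^2/(\sigma_u^2+\sigma_e^2)} equals \code{ratio} and
#' the total is \code{var_total}.  Used for parameter-recovery studies.
#'
#' @param K relationship matrix, or its precomputed eigendecomposition as
#'   returned by \code{\link{kernel_eigen}}.
#' @param ratio true variance ratio (heritability or microbiability).
#' @param var_total total variance \eqn{\sigma_u^2+\sigma_e^2}.
#' @param mean trait mean.
#' @return list with \code{y}, \code{u}, \code{sigma2_u}, \code{sigma2_e}.
#' @export
simulate_kernel_trait <- function(K, ratio = 0.5, var_total = 1, mean = 0) {
  ek <- kernel_eigen(K)
  s2u <- ratio * var_total
  s2e <- (1 - ratio) * var_total
  n <- length(ek$values)
  u <- if (s2u > 0)
    drop(ek$vectors %*% (sqrt(pmax(ek$values, 0) * s2u) * stats::rnorm(n)))
  else numeric(n)
  y <- mean + u + stats::rnorm(n, 0, sqrt(s2e))
  list(y = y, u = u, sigma2_u = s2u, sigma2_e = s2e)
}

#' Draw a trait pair from the bivariate kernel model
#'
#' Simulates two traits whose paired random effects have covariance
#' \eqn{K \otimes B} and residuals \eqn{I \otimes C}.
#'
#' @param K relationship matrix or its \code{\link{kernel_eigen}}.
#' @param B 2x2 random-effect (genetic) covariance matrix.
#' @param C 2x2 residual covariance matrix.
#' @return list with vectors \code{y1}, \code{y2} and the random effects
#'   \code{u1}, \code{u2}.
#' @export
simulate_kernel_pair <- function(K, B, C) {
  stopifnot(all(dim(B) == 2L), all(dim(C) == 2L))
  ek <- kernel_eigen(K)
  n <- length(ek$values)
  Lb <- chol2x2(B)
  Lc <- chol2x2(C)
  zk <- matrix(stats::rnorm(2L * n), n, 2L)
  # u (rotated) has per-eigenvalue covariance d_k * B
  ur <- sqrt(pmax(ek$values, 0)) * (zk %*% t(Lb))
  u <- ek$vectors %*% ur
  e <- matrix(stats::rnorm(2L * n), n, 2L) %*% t(Lc)
  list(y1 = u[, 1L] + e[, 1L], y2 = u[, 2L] + e[, 2L],
       u1 = u[, 1L], u2 = u[, 2L])
}

# lower Cholesky of a 2x2 PSD matrix, tolerating zero variances
chol2x2 <- function(S) {
  l11 <- sqrt(max(S[1, 1], 0))
  l21 <- if (l11 > 0) S[2, 1] / l11 else 0
  l22 <- sqrt(max(S[2, 2] - l21^2, 0))
  matrix(c(l11, l21, 0, l22), 2L, 2L)
}
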