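#' Run the full proxy-trait analysis pipeline
#'
#' Orchestrates: (optional) simulation of inputs, sample QC, presence-based
#' tag filtering (training-set reference under forward prediction, all
#' samples under cross-validation), MRM and GRM construction, lot scaling
#' and fixed-effect adjustment, univariate REML (heritability and
#' microbiability), split-based BLUP prediction with per-group accuracy and
#' slope, the bivariate proxy-trait model on the validation animals, and
#' the relative efficacy of indirect selection.  All randomness derives
#' from the config seed, so reruns with the same config are identical.
#'
#' @param config a list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{seed}{root seed (default 1).}
#'     \item{simulate}{list of \code{\link{sim_config}} arguments; if
#'       present, inputs are simulated.}
#'     \item{inputs}{alternatively, paths: \code{genotypes},
#'       \code{tag_counts}, \code{phenotypes} (tab-delimited; phenotype
#'       table needs animal_id, flock, birth_year, sex, flowcell, cohort,
#'       lot_id, fixed-effect columns and the trait column).}
#'     \item{trait}{trait column name (default "y").}
#'     \item{overall_mean}{overall population mean for lot scaling
#'       (default 7.5).}
#'     \item{trait_multiplier}{scale factor applied to the adjusted trait
#'       before the bivariate fit (e.g. 100 for a ratio trait analysed as a
#'       percentage; default 1).}
#'     \item{qc}{list: min_reads (1e5), presence_threshold (0.25),
#'       maf_min (0.01), call_rate_min (0.70).}
#'     \item{scheme}{"FP" (default) or "CV".}
#'     \item{validation_year}{FP validation birth year (default: latest).}
#'     \item{n_folds}{CV fold count (default 11, capped at the number of
#'       cohorts).}
#'     \item{fixed}{list: class_effects, covariates, group_cols for
#'       \code{\link{build_design}}.}
#'     \item{out_dir}{if set, per-stage tables and a JSON report are
#'       written there.}
#'   }
#' @return (invisibly) the report: a list with qc, heritability,
#'   microbiability, prediction evaluations per kernel, the bivariate fit
#'   summary and the relative efficacy.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  seed <- cfg$seed %||% 1L
  qc <- utils::modifyList(list(min_reads = 1e5, presence_threshold = 0.25,
                               maf_min = 0.01, call_rate_min = 0.70),
                          cfg$qc %||% list())
  trait <- cfg$trait %||% "y"
  scheme <- cfg$scheme %||% "FP"
  mult <- cfg$trait_multiplier %||% 1
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- inputs ----
  dat <- stage("inputs", {
    if (!is.null(cfg$simulate)) {
      sc <- do.call(sim_config, utils::modifyList(cfg$simulate,
                                                  list(seed = seed)))
      pop <- simulate_population(sc)
      counts <- simulate_metagenome(pop$truth, sc)
      list(genotypes = pop$genotypes, counts = counts,
           phenotypes = pop$phenotypes, truth = pop$truth)
    } else if (!is.null(cfg$inputs)) {
      for (nm in c("genotypes", "tag_counts", "phenotypes")) {
        pth <- cfg$inputs[[nm]]
        if (is.null(pth)) stop("input path '", nm, "' missing from config")
        if (!file.exists(pth)) stop("input path does not exist: ", pth)
      }
      list(genotypes = read_matrix_tsv(cfg$inputs$genotypes),
           counts = read_matrix_tsv(cfg$inputs$tag_counts, integer = TRUE),
           phenotypes = utils::read.delim(cfg$inputs$phenotypes,
                                          stringsAsFactors = FALSE),
           truth = NULL)
    } else stop("config needs either a 'simulate' block or 'inputs' paths")
  })

  # ---- sample QC, alignment ----
  qcres <- stage("sample_qc",
                 sample_qc(dat$counts, min_reads = qc$min_reads))
  ids <- Reduce(intersect, list(rownames(qcres$counts),
                                rownames(dat$genotypes),
                                dat$phenotypes$animal_id))
  if (length(ids) < 20L) stop("pipeline stage 'sample_qc': fewer than 20 ",
                              "animals survive QC/alignment")
  counts <- qcres$counts[ids, , drop = FALSE]
  attr(counts, "total_reads") <- attr(qcres$counts, "total_reads")[ids]
  geno <- dat$genotypes[ids, , drop = FALSE]
  phen <- dat$phenotypes[match(ids, dat$phenotypes$animal_id), ]

  # ---- phenotype prep ----
  prep <- stage("phenotype_prep", {
    scaled <- scale_by_lot(phen[[trait]], phen$lot_id,
                           cfg$overall_mean %||% 7.5)
    fx <- cfg$fixed %||% list()
    design <- build_design(phen,
                           class_effects = fx$class_effects %||%
                             c("birth_rank", "age_of_dam"),
                           covariates = fx$covariates %||% "bdev",
                           group_cols = fx$group_cols %||%
                             c("flock", "birth_year", "sex"))
    list(scaled = scaled, design = design,
         y_star = adjust_phenotype(scaled, design) * mult)
  })

  # ---- split ----
  plan <- stage("split", {
    if (scheme == "FP") {
      forward_split(phen, cfg$validation_year %||% max(phen$birth_year))
    } else {
      nf <- min(cfg$n_folds %||% 11L, length(unique(phen$cohort)))
      cv_folds(phen, n_folds = nf, seed = seed)
    }
  })

  # ---- tag filter + relationship matrices ----
  reference <- if (scheme == "FP")
    ids[plan$assignment == "train"] else ids
  counts_f <- stage("filter_tags",
                    filter_tags(counts, reference,
                                qc$presence_threshold))
  M <- stage("build_mrm", build_mrm(counts_f, phen$cohort))
  G <- stage("build_grm", build_grm(geno, maf_min = qc$maf_min,
                                    call_rate_min = qc$call_rate_min))

  # ---- full-data variance ratios ----
  fitdat <- data.frame(phen, y_star = prep$y_star)
  fit_m <- stage("fit_microbiability",
                 kreml(y_star ~ 1, fitdat, M, kind = "M"))
  fit_g <- stage("fit_heritability",
                 kreml(y_star ~ 1, fitdat, G, kind = "G"))

  # ---- prediction ----
  predres <- stage("predict", {
    predict_scheme <- function(K) {
      pred <- stats::setNames(rep(NA_real_, length(ids)), ids)
      if (scheme == "FP") {
        tr <- ids[plan$assignment == "train"]
        va <- ids[plan$assignment == "validate"]
        f <- kreml(y_star ~ 1, fitdat[match(tr, ids), , drop = FALSE],
                   K[tr, tr], se = FALSE)
        pred[va] <- blup_predict(f, K, tr, va)
      } else {
        for (k in sort(unique(plan$assignment))) {
          va <- ids[plan$assignment == k]
          tr <- setdiff(ids, va)
          f <- kreml(y_star ~ 1, fitdat[match(tr, ids), , drop = FALSE],
                     K[tr, tr], se = FALSE)
          pred[va] <- blup_predict(f, K, tr, va)
        }
      }
      pred
    }
    groups <- if (scheme == "FP") stats::setNames(phen$cohort, ids)
              else plan$assignment
    val <- if (scheme == "FP") ids[plan$assignment == "validate"] else ids
    m_hat <- predict_scheme(M)
    g_hat <- predict_scheme(G)
    list(m_hat = m_hat, g_hat = g_hat, validation = val,
         eval_m = evaluate_predictions(m_hat[val], prep$y_star[match(val, ids)],
                                       groups[val]),
         eval_g = evaluate_predictions(g_hat[val], prep$y_star[match(val, ids)],
                                       groups[val]))
  })

  # ---- bivariate proxy model + relative efficacy ----
  bires <- stage("bivariate", {
    val <- predres$validation
    fit <- kreml_bi(prep$y_star[match(val, ids)], predres$m_hat[val],
                    G[val, val])
    eff <- relative_efficacy(fit$rho_g, fit$h2[1], fit$h2[2])
    list(fit = fit, efficacy = eff,
         efficacy_se = relative_efficacy_se(fit))
  })

  report <- list(
    n_animals = length(ids),
    n_tags_filtered = ncol(counts_f),
    n_snps_used = attr(G, "n_snps_used"),
    scheme = scheme,
    qc = qcres$report,
    heritability = c(estimate = fit_g$ratio, se = fit_g$se$ratio),
    microbiability = c(estimate = fit_m$ratio, se = fit_m$se$ratio),
    prediction = list(
      metagenome = predres$eval_m$summary,
      genomic = predres$eval_g$summary),
    bivariate = summary(bires$fit)$estimates,
    relative_efficacy = c(estimate = bires$efficacy,
                          se = bires$efficacy_se),
    seed = seed)

  if (!is.null(cfg$out_dir)) {
    od <- cfg$out_dir
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(qcres$report, file.path(od, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(round(M, 6), file.path(od, "mrm.tsv"))
    write_matrix_tsv(round(G, 6), file.path(od, "grm.tsv"))
    utils::write.table(
      data.frame(fitdat, scaled = prep$scaled,
                 assignment = plan$assignment,
                 m_hat = predres$m_hat, g_hat = predres$g_hat),
      file.path(od, "phenotypes_adjusted.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(od, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

# delta-method SE for rho_g * sqrt(h2_2 / h2_1) from a kreml_bi fit
relative_efficacy_se <- function(fit) {
  if (is.null(fit$vcov_vc)) return(NA_real_)
  B <- fit$B; C <- fit$C
  S11 <- B[1, 1] + C[1, 1]
  S22 <- B[2, 2] + C[2, 2]
  eff <- B[1, 2] * sqrt(S11) / (B[1, 1] * sqrt(S22))
  g <- c(eff * (1 / (2 * S11) - 1 / B[1, 1]),
         eff / B[1, 2],
         -eff / (2 * S22),
         eff / (2 * S11),
         0,
         -eff / (2 * S22))
  sqrt(drop(t(g) %*% fit$vcov_vc %*% g))
}
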