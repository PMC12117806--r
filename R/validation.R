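#' Forward-prediction split by birth year
#'
#' Training animals are those born before \code{validation_year}; validation
#' animals are those born in it.  Later birth years are an error (forward
#' prediction trains strictly on the past).
#'
#' @param meta data.frame with a \code{birth_year} column (and optionally
#'   \code{animal_id}).
#' @param validation_year the validation birth year.
#' @return object of class \code{split_plan} with \code{scheme = "FP"} and
#'   \code{assignment} ("train"/"validate" per animal).
#' @export
forward_split <- function(meta, validation_year) {
  by <- meta$birth_year
  if (is.null(by)) stop("'meta' needs a 'birth_year' column")
  if (!validation_year %in% by)
    stop("validation year ", validation_year, " absent from the data")
  if (any(by > validation_year))
    stop("animals born after the validation year are present")
  assignment <- ifelse(by == validation_year, "validate", "train")
  if (!any(assignment == "train")) stop("training set is empty")
  ids <- meta$animal_id %||% as.character(seq_len(nrow(meta)))
  structure(list(scheme = "FP",
                 assignment = stats::setNames(assignment, ids),
                 validation_year = validation_year),
            class = "split_plan")
}

#' Cohort-blocked cross-validation folds
#'
#' Packs whole cohorts into \code{n_folds} size-balanced folds, preferring
#' to co-locate cohorts from the same flock (so validation animals come
#' from farms/years unlike their training set).  Cohorts are never split
#' across folds.  Deterministic given the seed.
#'
#' @param meta data.frame with \code{cohort} and \code{flock} columns (and
#'   optionally \code{animal_id}).
#' @param n_folds number of folds (default 11); must not exceed the number
#'   of cohorts.
#' @param seed seed for tie-breaking in the packing order.
#' @return object of class \code{split_plan} with \code{scheme = "CV"},
#'   \code{assignment} (fold index per animal), \code{fold_cohorts} and
#'   \code{fold_sizes}.
#' @export
cv_folds <- function(meta, n_folds = 11L, seed = 1L) {
  if (is.null(meta$cohort)) stop("'meta' needs a 'cohort' column")
  if (is.null(meta$flock)) stop("'meta' needs a 'flock' column")
  cohorts <- as.character(meta$cohort)
  tab <- table(cohorts)
  if (n_folds > length(tab))
    stop("'n_folds' exceeds the number of cohorts")
  info <- data.frame(cohort = names(tab), size = as.integer(tab),
                     stringsAsFactors = FALSE)
  info$flock <- vapply(info$cohort, function(ch)
    as.character(meta$flock[match(ch, cohorts)]), character(1))

  set.seed(seed)
  info <- info[sample(nrow(info)), ]          # seed-determined tie order
  fl_size <- tapply(info$size, info$flock, sum)
  info <- info[order(-fl_size[info$flock], info$flock, -info$size), ]

  target <- sum(info$size) / n_folds
  fold_size <- numeric(n_folds)
  fold_flocks <- vector("list", n_folds)
  assignment_by_cohort <- stats::setNames(integer(nrow(info)), info$cohort)
  warn_big <- info$cohort[info$size > 2 * target]
  if (length(warn_big))
    warning("cohort(s) larger than twice the target fold size: ",
            paste(warn_big, collapse = ", "))
  bonus <- 0.25 * target
  for (i in seq_len(nrow(info))) {
    score <- fold_size -
      bonus * vapply(fold_flocks, function(f) info$flock[i] %in% f, logical(1))
    j <- which.min(score)
    fold_size[j] <- fold_size[j] + info$size[i]
    fold_flocks[[j]] <- union(fold_flocks[[j]], info$flock[i])
    assignment_by_cohort[info$cohort[i]] <- j
  }
  ids <- meta$animal_id %||% as.character(seq_len(nrow(meta)))
  structure(list(scheme = "CV",
                 assignment = stats::setNames(
                   as.integer(assignment_by_cohort[cohorts]), ids),
                 fold_cohorts = split(info$cohort,
                                      assignment_by_cohort[info$cohort]),
                 fold_sizes = fold_size),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  if (x$scheme == "FP") {
    cat("Forward-prediction split: ",
        sum(x$assignment == "train"), " training / ",
        sum(x$assignment == "validate"), " validation (born ",
        x$validation_year, ")\n", sep = "")
  } else {
    cat("Cohort-blocked CV: ", length(x$fold_sizes), " folds, sizes ",
        paste(x$fold_sizes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Prediction accuracy and slope by group
#'
#' Per group: the Pearson correlation (accuracy) between the predictions
#' and the adjusted phenotypes, and the least-squares slope of the adjusted
#' phenotypes regressed on the predictions.  The summary is the group-size
#' weighted mean, with a weighted standard error (weighted sd of the group
#' statistics divided by the square root of the effective number of
#' groups).
#'
#' @param pred per-animal predictions (\eqn{\hat g} or \eqn{\hat m}).
#' @param y_star per-animal adjusted phenotypes.
#' @param groups per-animal group labels (cohorts for FP, folds for CV).
#' @param min_group smallest group size for which a correlation is
#'   computed (default 3); groups below it, or with zero-variance
#'   predictions, are skipped with a warning.
#' @return list of class \code{prediction_eval}: \code{by_group}
#'   (data.frame group/n/accuracy/slope) and \code{summary} (weighted mean
#'   and SE of each).
#' @export
evaluate_predictions <- function(pred, y_star, groups, min_group = 3L) {
  stopifnot(length(pred) == length(y_star), length(pred) == length(groups))
  groups <- as.character(groups)
  out <- lapply(split(seq_along(pred), groups), function(idx) {
    if (length(idx) < min_group) return(NULL)
    if (stats::sd(pred[idx]) == 0) {
      warning("group with zero-variance predictions skipped")
      return(NULL)
    }
    data.frame(n = length(idx),
               accuracy = stats::cor(pred[idx], y_star[idx]),
               slope = stats::cov(y_star[idx], pred[idx]) /
                 stats::var(pred[idx]))
  })
  keep <- !vapply(out, is.null, logical(1))
  if (!any(keep)) stop("no group large enough to evaluate")
  by_group <- do.call(rbind, out[keep])
  by_group <- cbind(group = names(out)[keep], by_group)
  rownames(by_group) <- NULL

  wstat <- function(x, w) {
    wm <- sum(w * x) / sum(w)
    wsd <- sqrt(sum(w * (x - wm)^2) / sum(w))
    neff <- sum(w)^2 / sum(w^2)
    c(mean = wm, se = wsd / sqrt(neff))
  }
  w <- by_group$n
  structure(list(by_group = by_group,
                 summary = rbind(accuracy = wstat(by_group$accuracy, w),
                                 slope = wstat(by_group$slope, w))),
            class = "prediction_eval")
}

#' @export
print.prediction_eval <- function(x, ...) {
  cat("Prediction evaluation over", nrow(x$by_group), "groups\n")
  cat(sprintf("  accuracy: %.3f (SE %.3f)\n",
              x$summary["accuracy", "mean"], x$summary["accuracy", "se"]))
  cat(sprintf("  slope:    %.3f (SE %.3f)\n",
              x$summary["slope", "mean"], x$summary["slope", "se"]))
  invisible(x)
}

#' Relative efficacy of indirect selection on a proxy trait
#'
#' Expected selection response from indirect selection on the proxy,
#' relative to direct selection on the target trait:
#' \eqn{\rho_{u12}\sqrt{h^2_{proxy}}/\sqrt{h^2_{direct}}}.  Depends only on
#' the two heritabilities and their genetic correlation, so it is invariant
#' to the traits' measurement scales.
#'
#' @param rho_g genetic correlation between target and proxy.
#' @param h2_direct heritability of the directly measured trait (> 0).
#' @param h2_proxy heritability of the proxy trait (>= 0).
#' @return the relative efficacy (vectorised over its arguments).
#' @export
relative_efficacy <- function(rho_g, h2_direct, h2_proxy) {
  if (any(abs(rho_g) > 1)) stop("'rho_g' must lie in [-1, 1]")
  if (any(h2_direct <= 0)) stop("'h2_direct' must be positive")
  if (any(h2_proxy < 0)) stop("'h2_proxy' must be non-negative")
  rho_g * sqrt(h2_proxy) / sqrt(h2_direct)
}
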