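#' Scale a gas trait by measurement lot
#'
#' Each value is divided by the mean of its lot and multiplied by the
#' overall population mean (7.5 g/day for CH4, 623 g/day for CO2, 0.032 for
#' the CH4/(CO2+CH4) ratio), so the within-lot mean of the scaled trait
#' equals the overall mean exactly.  This removes between-lot level shifts
#' (mostly time off feed) and stabilises heterogeneous variance.
#'
#' NA values are excluded from the lot means and stay NA after scaling.
#'
#' @param values numeric trait values (g/day or ratio scale).
#' @param lot_ids per-value lot identifiers.
#' @param overall_mean the overall population mean to scale to.
#' @return numeric vector of scaled values.
#' @export
scale_by_lot <- function(values, lot_ids, overall_mean) {
  stopifnot(length(values) == length(lot_ids), length(overall_mean) == 1L)
  lot_ids <- as.character(lot_ids)
  if (anyNA(lot_ids)) stop("every value needs a lot id")
  lot_means <- tapply(values, lot_ids, mean, na.rm = TRUE)
  if (any(!is.finite(lot_means)) || any(lot_means <= 0))
    stop("every lot mean must be positive")
  sizes <- tapply(!is.na(values), lot_ids, sum)
  if (any(sizes == 1L))
    warning("singleton lot(s) present; their scaled values equal the overall mean")
  overall_mean * values / as.numeric(lot_means[lot_ids])
}

#' Build a fixed-effects design matrix
#'
#' Class effects are one-hot encoded with the first level dropped;
#' covariates enter as-is; a contemporary group is formed by concatenating
#' the \code{group_cols} (default: flock x birth year x sex, the grouping
#' used for gas traits).  Class columns with a single observed level are
#' dropped with a warning.
#'
#' @param data data.frame containing the listed columns.
#' @param class_effects character vector of class-effect column names.
#' @param covariates character vector of numeric covariate column names.
#' @param group_cols columns combined into the contemporary group, or NULL
#'   for none.
#' @return list of class \code{fixed_design} with \code{X} (the design
#'   matrix, including intercept) and \code{effects} (the term labels).
#' @export
build_design <- function(data,
                         class_effects = c("birth_rank", "age_of_dam"),
                         covariates = "bdev",
                         group_cols = c("flock", "birth_year", "sex")) {
  used <- c(class_effects, covariates, group_cols)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop("columns not found in 'data': ", paste(missing_cols, collapse = ", "))

  df <- data.frame(row.names = seq_len(nrow(data)))
  keep_class <- character(0)
  for (ce in class_effects) {
    f <- factor(data[[ce]])
    if (nlevels(f) < 2L) {
      warning("class effect '", ce, "' has a single level and was dropped")
      next
    }
    df[[ce]] <- f
    keep_class <- c(keep_class, ce)
  }
  for (cv in covariates) df[[cv]] <- as.numeric(data[[cv]])
  if (!is.null(group_cols) && length(group_cols)) {
    cg <- factor(do.call(paste, c(data[group_cols], sep = "_")))
    if (nlevels(cg) < 2L) {
      warning("contemporary group has a single level and was dropped")
    } else {
      df[["contemporary_group"]] <- cg
      keep_class <- c(keep_class, "contemporary_group")
    }
  }
  terms <- c(keep_class, covariates)
  form <- if (length(terms))
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  else ~1
  X <- stats::model.matrix(form, df)
  structure(list(X = X, effects = colnames(X)), class = "fixed_design")
}

#' Adjust a phenotype for fixed effects
#'
#' Returns the residuals \eqn{y^* = y - X\hat b} of the least-squares fit of
#' the trait on the fixed-effects design (rank-deficient designs are handled
#' by pivoting).  \eqn{y^*} is orthogonal to every column of X and the
#' operation is idempotent.
#'
#' @param y numeric trait values.
#' @param design a \code{\link{build_design}} result or a design matrix.
#' @return numeric vector of adjusted phenotypes.
#' @export
adjust_phenotype <- function(y, design) {
  X <- if (inherits(design, "fixed_design")) design$X else as.matrix(design)
  stopifnot(length(y) == nrow(X))
  if (nrow(X) <= ncol(X))
    stop("need more records than fixed-effect columns")
  fit <- stats::lm.fit(X, y)
  if (fit$rank == 0L) stop("design matrix has rank 0")
  as.numeric(fit$residuals)
}
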