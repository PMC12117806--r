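#' Build the metagenome relationship matrix (MRM)
#'
#' Four steps: (1) add a pseudo-count of 1 and divide by the per-sample read
#' total to get proportions; (2) log10-transform; (3) standardise each tag
#' column to mean 0 / sd 1 within each cohort; (4) the MRM entry for a pair
#' of samples is the Pearson correlation of their cohort-normalised profiles
#' across tags.  The diagonal is set to exactly 1.  The \code{clr} mode
#' replaces steps (1)-(2) with a centred log-ratio transform of the
#' pseudo-counted profile for comparison.
#'
#' Tags with zero variance within a cohort carry no information there and
#' are given normalised value 0 for that cohort (the tag set stays aligned
#' across cohorts); their count per cohort is reported in the
#' \code{zero_variance} attribute.  Standard deviations use the n-1
#' denominator.
#'
#' @param counts tag-count matrix (samples x tags).
#' @param cohorts per-sample cohort labels (flowcell x flock x birth-year x
#'   sex in the intended application); every cohort needs >= 2 samples.
#' @param normalization \code{"cohort_log10"} (default) or \code{"clr"}.
#' @param total_reads per-sample read totals for step (1); defaults to the
#'   matrix's \code{total_reads} attribute, else row sums.
#' @return symmetric n x n matrix with unit diagonal, sample ids as
#'   dimnames, and attributes \code{kind = "MRM"} and \code{zero_variance}.
#' @export
build_mrm <- function(counts, cohorts,
                      normalization = c("cohort_log10", "clr"),
                      total_reads = NULL) {
  normalization <- match.arg(normalization)
  n <- nrow(counts)
  stopifnot(length(cohorts) == n)
  cohorts <- factor(cohorts)
  sizes <- table(cohorts)
  if (any(sizes < 2L))
    stop("every cohort needs at least 2 samples; singletons: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))

  if (normalization == "cohort_log10") {
    if (is.null(total_reads)) total_reads <- attr(counts, "total_reads")
    if (is.null(total_reads)) total_reads <- rowSums(counts)
    lp <- log10((counts + 1) / as.numeric(total_reads))
  } else {
    lx <- log(counts + 1)
    lp <- lx - rowMeans(lx)
  }

  z <- lp
  zero_var <- stats::setNames(integer(nlevels(cohorts)), levels(cohorts))
  for (ch in levels(cohorts)) {
    idx <- which(cohorts == ch)
    sub <- lp[idx, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2L, stats::sd)
    bad <- sdv == 0
    zero_var[ch] <- sum(bad)
    sdv[bad] <- 1
    zc <- sweep(sweep(sub, 2L, mu), 2L, sdv, "/")
    zc[, bad] <- 0
    z[idx, ] <- zc
  }

  m <- stats::cor(t(z))
  diag(m) <- 1
  dimnames(m) <- list(rownames(counts), rownames(counts))
  attr(m, "kind") <- "MRM"
  attr(m, "zero_variance") <- zero_var
  m
}

#' Build the genomic relationship matrix (GRM), VanRaden method 1
#'
#' SNPs failing the minor-allele-frequency or call-rate filters are removed;
#' allele frequencies come from all non-missing calls of the retained SNPs.
#' For each pair of animals only SNPs non-missing in both are used:
#' \deqn{G_{ij} = \frac{\sum_{k \in S_{ij}} (x_{ik}-2p_k)(x_{jk}-2p_k)}
#'                     {\sum_{k \in S_{ij}} 2 p_k (1-p_k)},}
#' with the self-relationship using the animal's own non-missing set.
#'
#' @param geno animals x SNPs matrix coded 0/1/2 with NA for missing.
#' @param maf_min minimum minor allele frequency (default 0.01, exclusive).
#' @param call_rate_min minimum per-SNP call rate (default 0.70).
#' @param impute_zero if TRUE, a pair with no shared non-missing SNPs gets
#'   relationship 0 instead of an error.
#' @return symmetric matrix with animal ids as dimnames and attributes
#'   \code{kind = "GRM"} and \code{n_snps_used}.
#' @export
build_grm <- function(geno, maf_min = 0.01, call_rate_min = 0.70,
                      impute_zero = FALSE) {
  stopifnot(is.matrix(geno))
  storage.mode(geno) <- "double"
  bad_codes <- !(geno %in% c(0, 1, 2) | is.na(geno))
  if (any(bad_codes)) stop("genotype calls must be coded 0/1/2/NA")

  call_rate <- colMeans(!is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- call_rate >= call_rate_min & maf > maf_min & !is.na(maf)
  if (!any(keep)) stop("no SNPs pass the MAF/call-rate filters")
  x <- geno[, keep, drop = FALSE]
  p <- p[keep]
  het <- 2 * p * (1 - p)

  if (!anyNA(x)) {
    w <- sweep(x, 2L, 2 * p)
    g <- tcrossprod(w) / sum(het)
  } else {
    obs <- !is.na(x)
    w <- sweep(x, 2L, 2 * p)
    w[!obs] <- 0
    num <- tcrossprod(w)
    storage.mode(obs) <- "double"
    den <- tcrossprod(sweep(obs, 2L, het, "*"), obs)
    empty <- den == 0
    if (any(empty)) {
      if (!impute_zero)
        stop("some animal pairs share no non-missing SNPs; ",
             "set impute_zero = TRUE to assign them relationship 0")
      den[empty] <- 1
      num[empty] <- 0
    }
    g <- num / den
  }
  dimnames(g) <- list(rownames(geno), rownames(geno))
  attr(g, "kind") <- "GRM"
  attr(g, "n_snps_used") <- sum(keep)
  g
}

#' Principal components of a relationship matrix
#'
#' Eigendecomposition-based scores for structure diagnostics: component
#' \eqn{j} scores are \eqn{\sqrt{\lambda_j}\, u_j}, ordered by decreasing
#' eigenvalue; variance explained is relative to the sum of positive
#' eigenvalues.  Deterministic up to the sign of each component.
#'
#' @param rel symmetric relationship matrix.
#' @param n_components number of components (<= n).
#' @return list with \code{scores} (n x n_components), \code{values} and
#'   \code{var_explained}.
#' @export
rm_pca <- function(rel, n_components = 2L) {
  n <- nrow(rel)
  if (n_components > n) stop("'n_components' exceeds matrix dimension")
  if (max(abs(rel - t(rel))) > 1e-8) stop("'rel' must be symmetric")
  e <- eigen(rel, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  idx <- seq_len(n_components)
  scores <- e$vectors[, idx, drop = FALSE] %*% diag(sqrt(pos[idx]), n_components)
  dimnames(scores) <- list(rownames(rel), paste0("PC", idx))
  list(scores = scores, values = e$values[idx],
       var_explained = pos[idx] / sum(pos))
}

#' Eigendecomposition of a relationship matrix for reuse across fits
#'
#' Small negative eigenvalues are clamped to zero: correlation-type kernels
#' carry numerical noise, and a GRM computed with pairwise non-missing SNP
#' sets is only approximately positive semi-definite under missingness.
#' Spectra negative beyond the tolerance raise an error.
#'
#' @param K symmetric relationship matrix, or an existing
#'   \code{kernel_eigen} object (returned unchanged).
#' @param tol most-negative eigenvalue tolerated, relative to the largest.
#' @return object of class \code{kernel_eigen}: list with \code{values},
#'   \code{vectors}, \code{ids}.
#' @export
kernel_eigen <- function(K, tol = 0.02) {
  if (inherits(K, "kernel_eigen")) return(K)
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-8) stop("kernel must be symmetric")
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values), 1))
    stop("kernel is not positive semi-definite (most negative eigenvalue ",
         signif(min(e$values), 3), ")")
  structure(list(values = pmax(e$values, 0), vectors = e$vectors,
                 ids = rownames(K)),
            class = "kernel_eigen")
}
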