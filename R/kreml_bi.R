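#' Bivariate kernel REML: proxy-trait genetic and phenotypic correlations
#'
#' Fits the bivariate mixed model for a trait pair (an adjusted phenotype
#' \eqn{y^*} and its predicted microbial proxy \eqn{\hat m}) whose stacked
#' random effects have covariance \eqn{K \otimes B} and residuals
#' \eqn{I \otimes C}, with
#' \eqn{B = [[\sigma^2_{u1}, \sigma_{u12}], [\sigma_{u12}, \sigma^2_{u2}]]}
#' and \eqn{C} the residual analogue.  A per-trait general mean is fitted.
#' Outputs are the genetic correlation
#' \eqn{\rho_{u12} = \sigma_{u12}/\sqrt{\sigma^2_{u1}\sigma^2_{u2}}}, the
#' phenotypic correlation
#' \eqn{(\sigma_{u12}+\sigma_{e12})/\sqrt{\sigma^2_{p1}\sigma^2_{p2}}}, and
#' the per-trait heritabilities
#' \eqn{h_i^2 = \sigma^2_{ui}/(\sigma^2_{ui}+\sigma^2_{ei})}, with
#' delta-method standard errors from the numerical observed information in
#' the six variance parameters.
#'
#' Rotating both traits by the eigenvectors of \eqn{K} factorises the
#' restricted likelihood into n bivariate normal terms with 2x2 covariance
#' \eqn{d_k B + C}, so each evaluation is O(n).  \eqn{B} and \eqn{C} are
#' parameterised through their Cholesky factors (log-diagonals), which
#' enforces positive semi-definiteness; optimisation is quasi-Newton (BFGS)
#' from a zero-covariance start and an empirical-covariance start, keeping
#' the better optimum.
#'
#' @param y1,y2 the two trait vectors, observed on the same animals in the
#'   same order as \code{K}.
#' @param K relationship matrix (typically the GRM) or its
#'   \code{\link{kernel_eigen}}.
#' @param se compute delta-method standard errors (default TRUE).
#' @param maxit maximum BFGS iterations per start.
#' @return object of class \code{kreml_bi} with components \code{B},
#'   \code{C}, \code{rho_g}, \code{rho_p}, \code{h2} (length-2),
#'   \code{sigma2_p} (phenotypic variances), \code{beta} (per-trait means),
#'   \code{se} (list with rho_g, rho_p, h2_1, h2_2, sigma2_p), \code{logLik},
#'   \code{convergence}, \code{boundary}.
#' @seealso \code{\link{kreml}}, \code{\link{kreml_bi_loglik}},
#'   \code{\link{relative_efficacy}}
#' @export
kreml_bi <- function(y1, y2, K, se = TRUE, maxit = 200L) {
  stopifnot(length(y1) == length(y2))
  ek <- kernel_eigen(K)
  n <- length(y1)
  if (length(ek$values) != n) stop("kernel dimension mismatch")
  d <- ek$values
  yt1 <- drop(crossprod(ek$vectors, y1))
  yt2 <- drop(crossprod(ek$vectors, y2))
  xt <- drop(crossprod(ek$vectors, rep(1, n)))

  nll_theta <- function(theta) {
    if (any(!is.finite(theta))) return(1e10)
    BC <- theta_to_BC(theta)
    ll <- bi_loglik_rot(yt1, yt2, xt, d, BC$B, BC$C)
    if (!is.finite(ll)) 1e10 else -ll
  }

  # starts: univariate components with zero / empirical covariance split
  f1 <- kreml(y ~ 1, data.frame(y = y1), ek, se = FALSE)
  f2 <- kreml(y ~ 1, data.frame(y = y2), ek, se = FALSE)
  cov_emp <- stats::cov(y1, y2)
  starts <- list(
    BC_to_theta(diag(c(max(f1$sigma2_u, 1e-4), max(f2$sigma2_u, 1e-4))),
                diag(c(max(f1$sigma2_e, 1e-4), max(f2$sigma2_e, 1e-4)))),
    BC_to_theta(make_psd2(max(f1$sigma2_u, 1e-4), max(f2$sigma2_u, 1e-4),
                          cov_emp * f1$ratio),
                make_psd2(max(f1$sigma2_e, 1e-4), max(f2$sigma2_e, 1e-4),
                          cov_emp * (1 - f1$ratio))))
  best <- NULL
  for (th0 in starts) {
    opt <- stats::optim(th0, nll_theta, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # polish: a derivative-free pass guards against line-search blow-ups on
  # likelihood plateaus, then a final quasi-Newton refinement
  polish <- stats::optim(best$par, nll_theta, method = "Nelder-Mead",
                         control = list(maxit = 500, reltol = 1e-12))
  if (polish$value < best$value) best <- polish
  refine <- stats::optim(best$par, nll_theta, method = "BFGS",
                         control = list(maxit = maxit, reltol = 1e-12))
  if (refine$value < best$value) best <- refine
  BC <- theta_to_BC(best$par)
  B <- BC$B
  C <- BC$C
  ll <- -best$value
  fitq <- bi_gls(yt1, yt2, xt, d, B, C)

  rho_g <- B[1, 2] / sqrt(max(B[1, 1] * B[2, 2], .Machine$double.eps))
  S <- B + C
  rho_p <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  h2 <- c(B[1, 1] / S[1, 1], B[2, 2] / S[2, 2])
  boundary <- abs(rho_g) > 0.999 || any(diag(B) < 1e-8)
  if (boundary)
    warning("bivariate REML converged at or near the PSD boundary")

  ses <- list(rho_g = NA_real_, rho_p = NA_real_, h2_1 = NA_real_,
              h2_2 = NA_real_, sigma2_p = c(NA_real_, NA_real_))
  vcov_vc <- NULL
  if (se && !boundary) {
    v0 <- c(B[1, 1], B[1, 2], B[2, 2], C[1, 1], C[1, 2], C[2, 2])
    h <- numeric_hessian(function(v) {
      Bv <- matrix(c(v[1], v[2], v[2], v[3]), 2)
      Cv <- matrix(c(v[4], v[5], v[5], v[6]), 2)
      bi_loglik_rot(yt1, yt2, xt, d, Bv, Cv)
    }, v0)
    vc <- tryCatch(solve(-h), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) {
      vcov_vc <- vc
      grad_rho_g <- c(-0.5 * rho_g / B[1, 1], 1 / sqrt(B[1, 1] * B[2, 2]),
                      -0.5 * rho_g / B[2, 2], 0, 0, 0)
      g_p11 <- -0.5 * rho_p / S[1, 1]
      g_p12 <- 1 / sqrt(S[1, 1] * S[2, 2])
      g_p22 <- -0.5 * rho_p / S[2, 2]
      grad_rho_p <- c(g_p11, g_p12, g_p22, g_p11, g_p12, g_p22)
      grad_h1 <- c(C[1, 1] / S[1, 1]^2, 0, 0, -B[1, 1] / S[1, 1]^2, 0, 0)
      grad_h2 <- c(0, 0, C[2, 2] / S[2, 2]^2, 0, 0, -B[2, 2] / S[2, 2]^2)
      dm <- function(g) sqrt(drop(t(g) %*% vc %*% g))
      gp1 <- c(1, 0, 0, 1, 0, 0)
      gp2 <- c(0, 0, 1, 0, 0, 1)
      ses <- list(rho_g = dm(grad_rho_g), rho_p = dm(grad_rho_p),
                  h2_1 = dm(grad_h1), h2_2 = dm(grad_h2),
                  sigma2_p = c(dm(gp1), dm(gp2)))
    }
  }

  structure(list(B = B, C = C, rho_g = rho_g, rho_p = rho_p, h2 = h2,
                 sigma2_p = c(S[1, 1], S[2, 2]),
                 beta = fitq$beta, se = ses, vcov_vc = vcov_vc,
                 logLik = ll, n = n, convergence = best$convergence,
                 boundary = boundary, ids = ek$ids),
            class = "kreml_bi")
}

# rotated restricted log-likelihood; per-trait general mean design
bi_loglik_rot <- function(yt1, yt2, xt, d, B, C) {
  a <- d * B[1, 1] + C[1, 1]
  b <- d * B[1, 2] + C[1, 2]
  cc <- d * B[2, 2] + C[2, 2]
  det <- a * cc - b^2
  if (any(det <= 0) || any(a <= 0) || any(cc <= 0)) return(-Inf)
  w11 <- cc / det
  w12 <- -b / det
  w22 <- a / det
  x2 <- xt^2
  A11 <- sum(x2 * w11); A12 <- sum(x2 * w12); A22 <- sum(x2 * w22)
  detA <- A11 * A22 - A12^2
  if (detA <= 0) return(-Inf)
  r1 <- sum(xt * (w11 * yt1 + w12 * yt2))
  r2 <- sum(xt * (w12 * yt1 + w22 * yt2))
  beta1 <- (A22 * r1 - A12 * r2) / detA
  beta2 <- (A11 * r2 - A12 * r1) / detA
  e1 <- yt1 - xt * beta1
  e2 <- yt2 - xt * beta2
  quad <- sum(w11 * e1^2 + 2 * w12 * e1 * e2 + w22 * e2^2)
  n <- length(yt1)
  -0.5 * ((2 * n - 2) * log(2 * pi) + sum(log(det)) + log(detA) + quad)
}

bi_gls <- function(yt1, yt2, xt, d, B, C) {
  a <- d * B[1, 1] + C[1, 1]
  b <- d * B[1, 2] + C[1, 2]
  cc <- d * B[2, 2] + C[2, 2]
  det <- a * cc - b^2
  w11 <- cc / det; w12 <- -b / det; w22 <- a / det
  x2 <- xt^2
  A11 <- sum(x2 * w11); A12 <- sum(x2 * w12); A22 <- sum(x2 * w22)
  detA <- A11 * A22 - A12^2
  r1 <- sum(xt * (w11 * yt1 + w12 * yt2))
  r2 <- sum(xt * (w12 * yt1 + w22 * yt2))
  list(beta = c((A22 * r1 - A12 * r2) / detA, (A11 * r2 - A12 * r1) / detA))
}

theta_to_BC <- function(theta) {
  # log-diagonals clamped so extreme line-search steps cannot overflow
  ld <- pmin(pmax(theta[c(1, 3, 4, 6)], -15), 15)
  od <- pmin(pmax(theta[c(2, 5)], -1e4), 1e4)
  Lb <- matrix(c(exp(ld[1]), od[1], 0, exp(ld[2])), 2)
  Lc <- matrix(c(exp(ld[3]), od[2], 0, exp(ld[4])), 2)
  list(B = tcrossprod(Lb), C = tcrossprod(Lc))
}

BC_to_theta <- function(B, C) {
  Lb <- chol2x2(B)
  Lc <- chol2x2(C)
  c(log(max(Lb[1, 1], 1e-6)), Lb[2, 1], log(max(Lb[2, 2], 1e-6)),
    log(max(Lc[1, 1], 1e-6)), Lc[2, 1], log(max(Lc[2, 2], 1e-6)))
}

# 2x2 covariance with given variances and covariance shrunk into the PD cone
make_psd2 <- function(v1, v2, cv) {
  lim <- 0.95 * sqrt(v1 * v2)
  cv <- max(min(cv, lim), -lim)
  matrix(c(v1, cv, cv, v2), 2)
}

#' Restricted log-likelihood of the bivariate kernel model
#'
#' Evaluates the restricted log-likelihood of the stacked trait pair under
#' random-effect covariance \eqn{K \otimes B} and residual covariance
#' \eqn{I \otimes C}, with a per-trait general mean profiled out by GLS.
#'
#' @param y1,y2 trait vectors.
#' @param K relationship matrix or \code{\link{kernel_eigen}}.
#' @param B,C 2x2 covariance matrices.
#' @return the restricted log-likelihood (a scalar).
#' @export
kreml_bi_loglik <- function(y1, y2, K, B, C) {
  ek <- kernel_eigen(K)
  yt1 <- drop(crossprod(ek$vectors, y1))
  yt2 <- drop(crossprod(ek$vectors, y2))
  xt <- drop(crossprod(ek$vectors, rep(1, length(y1))))
  bi_loglik_rot(yt1, yt2, xt, ek$values, B, C)
}

#' @export
print.kreml_bi <- function(x, ...) {
  cat("Bivariate kernel REML fit (", x$n, " animals)\n", sep = "")
  cat(sprintf("  genetic correlation   rho_g = %.3f (SE %.3f)\n",
              x$rho_g, x$se$rho_g))
  cat(sprintf("  phenotypic correlation rho_p = %.3f (SE %.3f)\n",
              x$rho_p, x$se$rho_p))
  cat(sprintf("  h2 trait 1 = %.3f (SE %.3f);  h2 trait 2 = %.3f (SE %.3f)\n",
              x$h2[1], x$se$h2_1, x$h2[2], x$se$h2_2))
  cat(sprintf("  phenotypic variances: %.4f, %.4f\n",
              x$sigma2_p[1], x$sigma2_p[2]))
  cat(sprintf("  REML log-likelihood: %.3f\n", x$logLik))
  if (x$boundary) cat("  note: at/near the PSD boundary\n")
  invisible(x)
}

#' @export
summary.kreml_bi <- function(object, ...) {
  est <- data.frame(
    quantity = c("rho_g", "rho_p", "h2_1", "h2_2",
                 "sigma2_p1", "sigma2_p2"),
    estimate = c(object$rho_g, object$rho_p, object$h2,
                 object$sigma2_p),
    se = c(object$se$rho_g, object$se$rho_p, object$se$h2_1,
           object$se$h2_2, object$se$sigma2_p))
  out <- list(fit = object, estimates = est)
  class(out) <- "summary.kreml_bi"
  out
}

#' @export
print.summary.kreml_bi <- function(x, ...) {
  print(x$fit)
  cat("\nEstimates:\n")
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.kreml_bi <- function(object, ...) object$beta

#' @export
logLik.kreml_bi <- function(object, ...)
  structure(object$logLik, df = 8, class = "logLik")
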