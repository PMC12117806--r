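#' Univariate kernel REML mixed model
#'
#' Fits \eqn{y = Xb + u + e} with \eqn{u \sim N(0, \sigma_u^2 K)} and
#' \eqn{e \sim N(0, \sigma_e^2 I)} by restricted maximum likelihood, where
#' \eqn{K} is a relationship matrix: the GRM gives heritability
#' \eqn{h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)}, the MRM gives
#' microbiability \eqn{m^2 = \sigma_m^2/(\sigma_m^2+\sigma_e^2)}.
#'
#' The kernel is eigendecomposed once; rotating \eqn{y} and \eqn{X} by the
#' eigenvectors diagonalises the covariance so the restricted likelihood
#' profiles to a one-dimensional bounded search over
#' \eqn{\log\lambda, \lambda = \sigma_u^2/\sigma_e^2}.  Standard errors come
#' from the inverse observed information (central finite differences of the
#' restricted log-likelihood in \eqn{(\sigma_u^2, \sigma_e^2)}), with the
#' ratio's standard error by the delta method.  Random effects are BLUPs
#' \eqn{\hat u = \hat\sigma_u^2 K V^{-1} (y - X\hat b)}.
#'
#' @param formula model formula for the trait and fixed effects, e.g.
#'   \code{y ~ 1} or \code{y ~ birth_rank + bdev}.
#' @param data data.frame the formula is evaluated in; rows must align with
#'   \code{K}.
#' @param K relationship matrix (n x n), or a precomputed
#'   \code{\link{kernel_eigen}}.
#' @param se compute standard errors (default TRUE; skip for speed in
#'   simulation loops).
#' @param lambda_interval search interval for \eqn{\log \lambda}.
#' @param tol convergence tolerance of the profile search.
#' @param kind label for the kernel ("G" or "M"); defaults to the matrix's
#'   \code{kind} attribute when present.
#' @return object of class \code{kreml} with components \code{sigma2_u},
#'   \code{sigma2_e}, \code{ratio}, \code{se} (list: sigma2_u, sigma2_e,
#'   ratio), \code{beta}, \code{u} (BLUPs), \code{logLik}, \code{alpha}
#'   (\eqn{V^{-1}(y - X\hat b)}, used for out-of-sample BLUP), \code{ids}.
#' @seealso \code{\link{blup_predict}}, \code{\link{kreml_loglik}},
#'   \code{\link{kreml_bi}}
#' @export
kreml <- function(formula, data, K, se = TRUE,
                  lambda_interval = c(-16, 16), tol = 1e-10, kind = NULL) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (is.null(kind) && is.matrix(K)) kind <- attr(K, "kind")
  ek <- kernel_eigen(K)
  n <- length(y)
  if (length(ek$values) != n)
    stop("kernel dimension (", length(ek$values),
         ") does not match number of records (", n, ")")
  p <- qr(X)$rank
  if (p < ncol(X)) {
    # drop aliased columns for a well-defined GLS solve
    q <- qr(X)
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
    p <- ncol(X)
  }
  d <- ek$values
  yt <- drop(crossprod(ek$vectors, y))
  Xt <- crossprod(ek$vectors, X)

  prof <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    XtWX <- crossprod(Xt, Xt * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    b <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, yt * w)))
    r <- yt - drop(Xt %*% b)
    rwr <- sum(r^2 * w)
    s2e <- rwr / (n - p)
    0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2e) -
             sum(log(w)) + 2 * sum(log(diag(ch))) + (n - p))
  }
  opt <- stats::optimize(prof, lambda_interval, tol = tol)
  loglam <- opt$minimum
  boundary <- min(abs(loglam - lambda_interval)) < 1e-3

  lam <- exp(loglam)
  w <- 1 / (lam * d + 1)
  XtWX <- crossprod(Xt, Xt * w)
  b <- drop(solve(XtWX, crossprod(Xt, yt * w)))
  r <- yt - drop(Xt %*% b)
  s2e <- sum(r^2 * w) / (n - p)
  s2u <- lam * s2e
  ratio <- lam / (1 + lam)
  ll <- -opt$objective

  # BLUPs and V^{-1}(y - Xb) on the original scale
  alpha <- drop(ek$vectors %*% (w * r)) / s2e
  u <- drop(ek$vectors %*% (lam * d * w * r))

  ses <- list(sigma2_u = NA_real_, sigma2_e = NA_real_, ratio = NA_real_)
  vcov_vc <- NULL
  if (se) {
    h <- numeric_hessian(function(th)
      kreml_loglik_rot(yt, Xt, d, th[1], th[2]), c(s2u, s2e))
    vc <- tryCatch(solve(-h), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) {
      vcov_vc <- vc
      grad <- c(s2e, -s2u) / (s2u + s2e)^2
      ses <- list(sigma2_u = sqrt(vc[1, 1]), sigma2_e = sqrt(vc[2, 2]),
                  ratio = sqrt(drop(t(grad) %*% vc %*% grad)))
    }
  }

  structure(list(call = cl, kind = kind, n = n, p = p,
                 sigma2_u = s2u, sigma2_e = s2e, ratio = ratio,
                 se = ses, vcov_vc = vcov_vc,
                 beta = stats::setNames(b, colnames(X)),
                 u = stats::setNames(u, ek$ids),
                 alpha = alpha, logLik = ll, lambda = lam,
                 boundary = boundary,
                 y = y, X = X, eigenK = ek,
                 ids = ek$ids),
            class = "kreml")
}

# restricted log-likelihood in the rotated basis at fixed components
kreml_loglik_rot <- function(yt, Xt, d, sigma2_u, sigma2_e) {
  n <- length(yt)
  p <- ncol(Xt)
  v <- sigma2_u * d + sigma2_e
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  XtWX <- crossprod(Xt, Xt * w)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  b <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, yt * w)))
  r <- yt - drop(Xt %*% b)
  -0.5 * ((n - p) * log(2 * pi) + sum(log(v)) + 2 * sum(log(diag(ch))) +
            sum(r^2 * w))
}

#' Restricted log-likelihood of the univariate kernel model
#'
#' Evaluates \eqn{-\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| +
#' y'Py]} at fixed variance components, with
#' \eqn{V = \sigma_u^2 K + \sigma_e^2 I}.
#'
#' @param y trait values.
#' @param X design matrix (default: intercept only).
#' @param K relationship matrix or \code{\link{kernel_eigen}}.
#' @param sigma2_u,sigma2_e variance components.
#' @return the restricted log-likelihood (a scalar).
#' @export
kreml_loglik <- function(y, X = matrix(1, length(y), 1), K,
                         sigma2_u, sigma2_e) {
  ek <- kernel_eigen(K)
  yt <- drop(crossprod(ek$vectors, y))
  Xt <- crossprod(ek$vectors, as.matrix(X))
  kreml_loglik_rot(yt, Xt, ek$values, sigma2_u, sigma2_e)
}

# central-difference Hessian with relative step
numeric_hessian <- function(f, x, rel_step = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x), 1e-8) * rel_step
  H <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        H[i, i] <- (f(x + h * (seq_len(k) == i)) - 2 * f(x) +
                      f(x - h * (seq_len(k) == i))) / h[i]^2
      } else {
        ei <- h * (seq_len(k) == i)
        ej <- h * (seq_len(k) == j)
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' @export
print.kreml <- function(x, ...) {
  lab <- switch(x$kind %||% "K", G = "heritability (h2)",
                GRM = "heritability (h2)", M = "microbiability (m2)",
                MRM = "microbiability (m2)", "variance ratio")
  cat("Kernel REML fit (", x$n, " records)\n", sep = "")
  cat(sprintf("  sigma2_u = %.4f (SE %.4f), sigma2_e = %.4f (SE %.4f)\n",
              x$sigma2_u, x$se$sigma2_u, x$sigma2_e, x$se$sigma2_e))
  cat(sprintf("  %s = %.4f (SE %.4f)\n", lab, x$ratio, x$se$ratio))
  cat(sprintf("  REML log-likelihood: %.3f\n", x$logLik))
  if (x$boundary)
    cat("  note: variance ratio at the search boundary\n")
  invisible(x)
}

#' @export
summary.kreml <- function(object, ...) {
  out <- list(fit = object,
              components = data.frame(
                component = c("sigma2_u", "sigma2_e", "ratio"),
                estimate = c(object$sigma2_u, object$sigma2_e, object$ratio),
                se = c(object$se$sigma2_u, object$se$sigma2_e,
                       object$se$ratio)),
              beta = object$beta)
  class(out) <- "summary.kreml"
  out
}

#' @export
print.summary.kreml <- function(x, ...) {
  print(x$fit)
  cat("\nVariance components:\n")
  print(x$components, row.names = FALSE, digits = 4)
  cat("\nFixed effects:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.kreml <- function(object, ...) object$beta

#' @export
logLik.kreml <- function(object, ...) {
  structure(object$logLik, df = object$p + 2, class = "logLik")
}

#' @export
fitted.kreml <- function(object, ...)
  drop(object$X %*% object$beta) + object$u

#' @export
residuals.kreml <- function(object, ...) object$y - fitted(object)

#' Simulate responses from a fitted kernel model
#' @param object a \code{kreml} fit.
#' @param nsim number of response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame of simulated responses (one column per simulation).
#' @export
simulate.kreml <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ek <- object$eigenK
  n <- object$n
  mu <- drop(object$X %*% object$beta)
  out <- replicate(nsim, {
    u <- drop(ek$vectors %*%
                (sqrt(object$sigma2_u * ek$values) * stats::rnorm(n)))
    mu + u + stats::rnorm(n, 0, sqrt(object$sigma2_e))
  })
  as.data.frame(out)
}

#' BLUP prediction for animals outside the training set
#'
#' \deqn{\hat u_{target} = \hat\sigma_u^2 K_{target,train}
#'   (\hat\sigma_u^2 K_{train,train} + \hat\sigma_e^2 I)^{-1}
#'   (y_{train} - X_{train}\hat b),}
#' i.e. the conditional mean of the target random effects given the
#' training phenotypes at the estimated variance components.
#'
#' @param fit a \code{\link{kreml}} fit on the training animals.
#' @param K_full relationship matrix covering training and target animals
#'   (dimnames required).
#' @param training_ids,target_ids disjoint id sets present in
#'   \code{K_full}; \code{training_ids} must match the fit's animals in
#'   order.
#' @return named numeric vector of predicted random effects for the targets.
#' @export
blup_predict <- function(fit, K_full, training_ids, target_ids) {
  stopifnot(inherits(fit, "kreml"))
  if (length(intersect(training_ids, target_ids)))
    stop("training and target id sets overlap")
  if (is.null(rownames(K_full)))
    stop("'K_full' needs dimnames to locate animals")
  missing_ids <- setdiff(c(training_ids, target_ids), rownames(K_full))
  if (length(missing_ids))
    stop("ids absent from 'K_full': ", paste(utils::head(missing_ids), collapse = ", "))
  if (length(training_ids) != fit$n)
    stop("'training_ids' must cover the fitted records")
  ktt <- K_full[target_ids, training_ids, drop = FALSE]
  stats::setNames(drop(fit$sigma2_u * ktt %*% fit$alpha), target_ids)
}

#' @export
predict.kreml <- function(object, K_full = NULL, target_ids = NULL, ...) {
  if (is.null(K_full)) return(fitted(object))
  blup_predict(object, K_full, object$ids, target_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
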