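# shared test fixtures, built in code

# write a minimal FASTQ file from raw sequences (Phred-40 qualities)
make_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  lines <- unlist(lapply(seq_along(seqs), function(i)
    c(paste0("@r", i), seqs[i], "+", strrep("I", nchar(seqs[i])))))
  writeLines(lines, path)
  path
}

rand_seq <- function(n, width = 65L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = ""), character(1))
}

# a small GRM-like PSD kernel: rank-deficient (spectrum reaching zero) so
# the kernel and residual variance components are well identified
rand_kernel <- function(n, seed = 1) {
  set.seed(seed)
  p <- max(2L, floor(0.6 * n))
  w <- matrix(rnorm(n * p), n)
  k <- tcrossprod(w) / p
  k / mean(diag(k))
}

offdiag <- function(m) m[lower.tri(m)]

# dense REML restricted log-likelihood, the independent oracle
dense_reml_loglik <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XVX)$modulus) +
            drop(t(y) %*% P %*% y))
}
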