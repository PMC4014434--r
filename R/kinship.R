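#' Genome-averaged kinship between crosses
#'
#' At positions thinned to `grid_step_cM`, the probability that two crosses
#' share a founder identical by descent is computed from the haplotype
#' probability vectors and averaged over positions, with maternal and
#' paternal sides weighted equally:
#' `K_ij = mean_pos 0.5 * (sum_f a_if a_jf + sum_f b_if b_jf)`.
#'
#' @param crosses a `cross_genotypes`.
#' @param grid_step_cM spacing of the positions used (the scan grid is
#'   thinned to at most this resolution).
#' @return Symmetric `n x n` matrix of class `kinship_matrix`.
#' @export
kinship <- function(crosses, grid_step_cM = 0.025) {
  stopifnot(inherits(crosses, "cross_genotypes"))
  pos <- resample_grid_idx(crosses$map, grid_step_cM)
  n <- crosses$n
  K <- matrix(0, n, n)
  for (p in pos) {
    X <- cross_dosage(crosses, p)
    K <- K + tcrossprod(X[, 1:8]) + tcrossprod(X[, 9:16])
  }
  K <- K / (2 * length(pos))
  dimnames(K) <- list(crosses$cross_id, crosses$cross_id)
  class(K) <- c("kinship_matrix", "matrix")
  K
}

#' Narrow-sense heritability by REML with a kinship random effect
#'
#' Fits `y = mu + g + e` with `g ~ N(0, sigma_g^2 K)` by restricted maximum
#' likelihood.  The kinship matrix is eigendecomposed once (small negative
#' eigenvalues are clipped to zero) and the restricted log-likelihood is
#' profiled down to a one-dimensional optimization in
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`, bounded to [0, 1].
#'
#' @param y phenotype vector.
#' @param K kinship matrix from [kinship()], or its precomputed
#'   eigendecomposition (as returned by `eigen(..., symmetric = TRUE)`) for
#'   repeated calls.
#' @return List with `h2`, `sigma_g2`, `sigma_e2`, `loglik`, and `flag`
#'   (`"ok"`, `"boundary"`, or `"unidentifiable"`).
#' @export
heritability <- function(y, K) {
  n <- length(y)
  eK <- if (is.list(K) && !is.null(K$vectors)) K
        else eigen(unclass(K), symmetric = TRUE)
  lambda <- pmax(eK$values, 0)
  if (diff(range(lambda)) < 1e-10 * max(lambda, 1)) {
    # K proportional to I: sigma_g and sigma_e are not separable
    return(list(h2 = NA_real_, sigma_g2 = NA_real_, sigma_e2 = var(y),
                loglik = NA_real_, flag = "unidentifiable"))
  }
  yr <- crossprod(eK$vectors, y)         # rotated phenotype
  ones <- crossprod(eK$vectors, rep(1, n))
  # restricted log-likelihood at heritability h (profiled over total variance)
  rll <- function(h) {
    d <- h * lambda + (1 - h)            # eigenvalues of hK + (1-h)I
    w <- 1 / d
    mu <- sum(w * ones * yr) / sum(w * ones^2)
    r <- yr - mu * ones
    s2 <- sum(w * r^2) / (n - 1)         # REML variance estimate
    -0.5 * (sum(log(d)) + log(sum(w * ones^2)) + (n - 1) * (1 + log(s2)))
  }
  opt <- optimize(rll, c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-8)
  h2 <- opt$maximum
  flag <- "ok"
  if (h2 < 1e-4 || h2 > 1 - 1e-4) {
    flag <- "boundary"
    h2 <- max(0, min(1, h2))
  }
  d <- h2 * lambda + (1 - h2)
  w <- 1 / d
  mu <- sum(w * ones * yr) / sum(w * ones^2)
  s2 <- sum(w * (yr - mu * ones)^2) / (n - 1)
  list(h2 = h2, sigma_g2 = h2 * s2, sigma_e2 = (1 - h2) * s2,
       loglik = opt$objective, flag = flag)
}
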