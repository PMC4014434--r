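#' Genome scan by regression on founder haplotype probabilities
#'
#' At every grid position each phenotype is regressed on the 16 founder
#' probability columns (8 maternal pA + 8 paternal pB) plus an intercept.
#' Because each panel's probabilities sum to one, the design is
#' rank-deficient; the fit uses a QR with pivoting and the F test for the
#' joint genotype effect uses `rank(design) - 1` numerator degrees of
#' freedom (14 when both panels vary).  LOD = (n/2) log10(RSS0 / RSS1)
#' against the intercept-only null.
#'
#' @param y phenotype vector (length n) or expression matrix
#'   (transcripts x crosses).
#' @param crosses a `cross_genotypes`.
#' @param positions grid indices to scan; default the whole grid.
#' @return An object of class `scan_result`: `lod` (positions x transcripts),
#'   `grid` (scanned subset of the map grid), `df1` per position, `n`.
#' @export
lod_scan <- function(y, crosses, positions = NULL) {
  stopifnot(inherits(crosses, "cross_genotypes"))
  Y <- if (is.matrix(y)) t(y) else matrix(y, ncol = 1L)
  n <- crosses$n
  if (nrow(Y) != n) stop("phenotype length must equal the number of crosses")
  if (anyNA(Y)) stop("missing phenotype values are not supported")
  if (n < 20L) stop("fewer than 20 crosses: insufficient degrees of freedom")
  if (is.null(positions)) positions <- crosses$map$grid$index
  designs <- scan_designs(crosses, positions)
  res <- scan_core(Y, designs, n)
  structure(list(lod = res$lod,
                 grid = crosses$map$grid[positions, , drop = FALSE],
                 df1 = res$df1, n = n,
                 transcripts = colnames(Y)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result:", nrow(x$lod), "positions x", ncol(x$lod),
      "phenotypes; max LOD", round(max(x$lod), 2), "\n")
  invisible(x)
}

# orthonormal bases of the genotype design at each position
scan_designs <- function(crosses, positions) {
  lapply(positions, function(p) {
    X <- cbind(1, cross_dosage(crosses, p))
    qr_x <- qr(X, LAPACK = FALSE)
    r <- qr_x$rank
    list(Q = qr.Q(qr_x)[, seq_len(r), drop = FALSE], rank = r)
  })
}

# LOD matrix for raw phenotypes Y (n x T) over precomputed designs
scan_core <- function(Y, designs, n) {
  yty <- colSums(Y^2)
  rss0 <- pmax(yty - n * colMeans(Y)^2, 0)
  lod <- matrix(0, length(designs), ncol(Y))
  df1 <- integer(length(designs))
  for (j in seq_along(designs)) {
    d <- designs[[j]]
    rss1 <- pmax(yty - colSums(crossprod(d$Q, Y)^2), 0)
    ok <- rss0 > 0 & rss1 > 0
    lod[j, ok] <- (n / 2) * log10(rss0[ok] / rss1[ok])
    # rss1 == 0 with rss0 > 0: perfect fit; cap by machine floor
    pf0 <- rss0 > 0 & rss1 == 0
    lod[j, pf0] <- (n / 2) * log10(rss0[pf0] / (.Machine$double.eps * yty[pf0] + 1e-300))
    df1[j] <- d$rank - 1L
  }
  list(lod = lod, df1 = df1)
}

#' Experiment-wise significance thresholds by permutation
#'
#' The full expression matrix is permuted together: one shuffle of cross
#' labels per permutation is applied to all transcripts, preserving the
#' transcript correlation structure.  The statistic is the maximum LOD over
#' all transcripts and positions; the genome-wide threshold is its
#' `1 - level` quantile.  A cis-specific threshold is computed from the same
#' permutations restricting each transcript to positions within
#' `cis_window_cM` of its transcription start site.
#'
#' @param expr expression matrix, transcripts x crosses.
#' @param crosses a `cross_genotypes`.
#' @param positions grid indices to scan (default whole grid).
#' @param n_perm number of permutations (>= 100).
#' @param level experiment-wise error rate.
#' @param cis_window_cM half-width of the cis window in cM; set `NULL` to
#'   skip the cis threshold.
#' @param tss data.frame `transcript_id, chrom, tss_cM` (required for the
#'   cis threshold), rows matching `rownames(expr)`.
#' @param rng_seed seed for the permutation draws.
#' @return An object of class `thresholds`: `genome_wide`, `cis_only`,
#'   `n_perm`, `level`, and the permutation maxima.
#' @export
permutation_threshold <- function(expr, crosses, positions = NULL,
                                  n_perm = 1000L, level = 0.05,
                                  cis_window_cM = 1.5, tss = NULL,
                                  rng_seed = 1L) {
  stopifnot(is.matrix(expr), inherits(crosses, "cross_genotypes"))
  if (n_perm < 100L) stop("n_perm must be >= 100 for quantile stability")
  n <- crosses$n
  if (ncol(expr) != n) stop("expr must be transcripts x crosses")
  if (is.null(positions)) positions <- crosses$map$grid$index
  Y <- t(expr)
  designs <- scan_designs(crosses, positions)
  grid <- crosses$map$grid[positions, , drop = FALSE]
  cis_idx <- NULL
  if (!is.null(cis_window_cM)) {
    if (is.null(tss)) stop("cis threshold requested but no TSS annotation given")
    tss <- tss[match(rownames(expr), tss$transcript_id), ]
    if (anyNA(tss$tss_cM)) stop("TSS annotation missing for some transcripts")
    cis_idx <- lapply(seq_len(nrow(tss)), function(t)
      which(grid$chrom == tss$chrom[t] &
            abs(grid$pos_cM - tss$tss_cM[t]) <= cis_window_cM))
  }
  set.seed(rng_seed)
  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  max_all <- numeric(n_perm)
  max_cis <- if (is.null(cis_idx)) NULL else numeric(n_perm)
  for (b in seq_len(n_perm)) {
    lod <- scan_core(Y[perms[[b]], , drop = FALSE], designs, n)$lod
    max_all[b] <- max(lod)
    if (!is.null(cis_idx)) {
      mx <- 0
      for (t in seq_along(cis_idx))
        if (length(cis_idx[[t]]))
          mx <- max(mx, lod[cis_idx[[t]], t])
      max_cis[b] <- mx
    }
  }
  gw <- as.numeric(quantile(max_all, 1 - level, type = 7))
  cis <- if (is.null(max_cis)) NA_real_ else
    as.numeric(quantile(max_cis, 1 - level, type = 7))
  if (!is.na(cis) && cis > gw)
    warning("cis-only threshold exceeds the genome-wide threshold")
  structure(list(genome_wide = gw, cis_only = cis, n_perm = n_perm,
                 level = level, perm_max = max_all, perm_max_cis = max_cis),
            class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat("thresholds (", x$n_perm, " permutations, level ", x$level, "): ",
      "genome-wide LOD ", round(x$genome_wide, 2),
      ", cis-only LOD ", round(x$cis_only, 2), "\n", sep = "")
  invisible(x)
}
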