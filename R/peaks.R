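#' Call eQTL peaks from a scan
#'
#' Local maxima exceeding the significance threshold are found per
#' chromosome.  Positions within `cis_window_cM` of the transcript's TSS are
#' compared against the cis-specific threshold, all others against the
#' genome-wide threshold.  When nearby peaks have overlapping 3-LOD-drop
#' intervals, only the peak with the highest LOD is kept; merging iterates
#' to a fixed point.
#'
#' @param scan a `scan_result` for one transcript (single column).
#' @param thresholds a `thresholds` object (or a list with `genome_wide` and
#'   optionally `cis_only`).
#' @param tss optional list/row with `chrom` and `tss_cM` for the transcript,
#'   enabling the cis threshold and cis/trans labelling.
#' @param transcript column of `scan` to use (default 1).
#' @param drop LOD drop defining merge intervals.
#' @param cis_window_cM cis window half-width.
#' @return data.frame of peaks (possibly 0 rows): grid coordinates, LOD,
#'   CI bounds by LOD drop and Bayes credible interval in both coordinate
#'   systems, cis flag, and interval flags.
#' @export
call_peaks <- function(scan, thresholds, tss = NULL, transcript = 1L,
                       drop = 3, cis_window_cM = 1.5) {
  stopifnot(inherits(scan, "scan_result"))
  lod <- scan$lod[, transcript]
  grid <- scan$grid
  out <- list()
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    l <- lod[idx]
    cand <- local_maxima(l)
    thr <- rep(thresholds$genome_wide, length(cand))
    is_cis <- rep(FALSE, length(cand))
    if (!is.null(tss) && identical(as.character(tss$chrom), ch)) {
      is_cis <- abs(grid$pos_cM[idx[cand]] - tss$tss_cM) <= cis_window_cM
      if (!is.null(thresholds$cis_only) && !is.na(thresholds$cis_only))
        thr[is_cis] <- thresholds$cis_only
    }
    cand <- cand[l[cand] > thr]
    if (length(cand) == 0L) next
    # merge peaks with overlapping LOD-drop intervals, keep highest
    repeat {
      ivs <- lapply(cand, function(p) lod_drop_ci(l, p, drop))
      keep <- rep(TRUE, length(cand))
      merged <- FALSE
      if (length(cand) > 1L) {
        for (i in seq_along(cand)[-1L]) {
          for (j in seq_len(i - 1L)) {
            if (!keep[i] || !keep[j]) next
            if (ivs[[i]]$lo_idx <= ivs[[j]]$hi_idx &&
                ivs[[j]]$lo_idx <= ivs[[i]]$hi_idx) {
              loser <- if (l[cand[i]] >= l[cand[j]]) j else i
              keep[loser] <- FALSE
              merged <- TRUE
            }
          }
        }
      }
      cand <- cand[keep]
      if (!merged) break
    }
    for (p in cand) {
      li <- lod_drop_ci(l, p, drop)
      bi <- bayes_credible_interval(l, p)
      g <- grid[idx, ]
      pk_cM <- g$pos_cM[p]
      cis <- if (is.null(tss)) NA else
        identical(as.character(tss$chrom), ch) &&
          abs(pk_cM - tss$tss_cM) <= cis_window_cM
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, peak_idx = idx[p],
        pos_bp = g$pos_bp[p], pos_cM = pk_cM, lod = l[p],
        ci_lo_bp = g$pos_bp[li$lo_idx], ci_hi_bp = g$pos_bp[li$hi_idx],
        ci_lo_cM = g$pos_cM[li$lo_idx], ci_hi_cM = g$pos_cM[li$hi_idx],
        bci_lo_bp = g$pos_bp[bi$lo_idx], bci_hi_bp = g$pos_bp[bi$hi_idx],
        bci_lo_cM = g$pos_cM[bi$lo_idx], bci_hi_cM = g$pos_cM[bi$hi_idx],
        ci_flag = li$flag, bci_flag = bi$flag, cis = cis,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame())
  do.call(rbind, out)
}

# indices of strict-or-plateau local maxima of a vector
local_maxima <- function(l) {
  n <- length(l)
  if (n == 1L) return(1L)
  left <- c(-Inf, l[-n])
  right <- c(l[-1L], -Inf)
  which(l >= left & l > right | (l > left & l >= right))
}

#' LOD-drop support interval
#'
#' The contiguous run of positions around the peak with LOD at least
#' `peak - drop`, extended one grid point beyond each end.  Three-LOD drops
#' are treated as a conservative 95% interval for this cross design.
#'
#' @param lod LOD vector over one chromosome's grid.
#' @param peak index of a local maximum within `lod`.
#' @param drop LOD units to descend.
#' @return List `lo_idx`, `hi_idx` (indices into `lod`) and `flag`
#'   (`"ok"`, `"left_end"`, `"right_end"`, or `"both_ends"`).
#' @export
lod_drop_ci <- function(lod, peak, drop = 3) {
  thr <- lod[peak] - drop
  lo <- peak
  while (lo > 1L && lod[lo - 1L] >= thr) lo <- lo - 1L
  hi <- peak
  n <- length(lod)
  while (hi < n && lod[hi + 1L] >= thr) hi <- hi + 1L
  flag_l <- lo == 1L
  flag_r <- hi == n
  # extend to the flanking grid points
  if (!flag_l) lo <- lo - 1L
  if (!flag_r) hi <- hi + 1L
  flag <- if (flag_l && flag_r) "both_ends"
          else if (flag_l) "left_end"
          else if (flag_r) "right_end" else "ok"
  list(lo_idx = lo, hi_idx = hi, flag = flag)
}

#' Bayes credible interval from a LOD curve
#'
#' `10^LOD` is normalized over the peak's chromosome as a posterior for the
#' QTL location; the interval grows outward from the peak, adding the
#' flanking grid point with the larger posterior, until it holds at least
#' `coverage` of the mass.
#'
#' @inheritParams lod_drop_ci
#' @param coverage posterior mass required.
#' @return List `lo_idx`, `hi_idx`, `flag` as in [lod_drop_ci()].
#' @export
bayes_credible_interval <- function(lod, peak, coverage = 0.95) {
  w <- 10^(lod - max(lod))
  w <- w / sum(w)
  lo <- hi <- peak
  mass <- w[peak]
  n <- length(lod)
  while (mass < coverage && (lo > 1L || hi < n)) {
    left <- if (lo > 1L) w[lo - 1L] else -Inf
    right <- if (hi < n) w[hi + 1L] else -Inf
    if (left >= right) {
      lo <- lo - 1L; mass <- mass + w[lo]
    } else {
      hi <- hi + 1L; mass <- mass + w[hi]
    }
  }
  flag <- if (mass < coverage) "chromosome" else "ok"
  list(lo_idx = lo, hi_idx = hi, flag = flag)
}

#' Attribute a peak to one or both mapping panels
#'
#' Compares by AIC three least-squares models at the peak: maternal pA
#' probability columns only, paternal pB only, and both.  The lowest AIC
#' wins; an exact tie prefers the full pA+pB model (flagged).
#'
#' @param y phenotype vector.
#' @param crosses a `cross_genotypes`.
#' @param peak_pos grid index of the peak.
#' @return List `model` in `{"pA+pB", "pA only", "pB only"}`, `aic` (named
#'   vector), `flag`.
#' @export
classify_population <- function(y, crosses, peak_pos) {
  X <- cross_dosage(crosses, peak_pos)
  aic <- c("pA+pB" = aic_ls(y, X),
           "pA only" = aic_ls(y, X[, 1:8, drop = FALSE]),
           "pB only" = aic_ls(y, X[, 9:16, drop = FALSE]))
  best <- which(aic == min(aic))
  flag <- "none"
  if (length(best) > 1L) {
    best <- 1L  # tie: keep the full model, conservatively
    flag <- "aic_tie"
  }
  list(model = names(aic)[best], aic = aic, flag = flag)
}

# AIC of least squares y ~ 1 + X with rank-based parameter count
aic_ls <- function(y, X) {
  n <- length(y)
  W <- cbind(1, X)
  qr_w <- qr(W)
  rss <- sum(qr.resid(qr_w, y)^2)
  n * log(max(rss, 1e-300) / n) + 2 * (qr_w$rank + 1)
}

#' Variance and heritability accounting for a peak
#'
#' Percent phenotypic variance explained at the peak,
#' `100 * (1 - RSS_full / RSS_null)`, and the percentage of the transcript's
#' heritability that the peak accounts for.  The latter can exceed 100 when
#' heritability is underestimated or the peak effect is overestimated; it is
#' flagged, never clipped.
#'
#' @param y phenotype vector.
#' @param crosses a `cross_genotypes`.
#' @param peak_pos grid index of the peak.
#' @param h2 heritability estimate for the transcript (from
#'   [heritability()]).
#' @return List `pct_variance`, `pct_heritability`, `flag`.
#' @export
effect_accounting <- function(y, crosses, peak_pos, h2) {
  X <- cbind(1, cross_dosage(crosses, peak_pos))
  rss1 <- sum(qr.resid(qr(X), y)^2)
  rss0 <- sum((y - mean(y))^2)
  pv <- 100 * (1 - rss1 / rss0)
  if (is.na(h2) || h2 <= 0) {
    return(list(pct_variance = pv, pct_heritability = NA_real_,
                flag = "h2_zero"))
  }
  ph <- pv / h2
  list(pct_variance = pv, pct_heritability = ph,
       flag = if (ph > 100) "exceeds_100" else "none")
}

#' Label a peak cis or trans
#'
#' A peak is cis when it lies on the transcript's chromosome within
#' `window_cM` (inclusive) of the transcription start site.
#'
#' @param peak list/row with `chrom` and `pos_cM`.
#' @param tss list/row with `chrom` and `tss_cM`; `NULL` or `NA` entries
#'   yield trans with a flag.
#' @param window_cM cis window half-width.
#' @return List `cis` (logical), `distance_cM` (NA across chromosomes),
#'   `flag`.
#' @export
cis_trans_label <- function(peak, tss, window_cM = 1.5) {
  if (is.null(tss) || is.na(tss$chrom) || is.na(tss$tss_cM))
    return(list(cis = FALSE, distance_cM = NA_real_, flag = "missing_tss"))
  if (!identical(as.character(peak$chrom), as.character(tss$chrom)))
    return(list(cis = FALSE, distance_cM = NA_real_, flag = "none"))
  d <- abs(peak$pos_cM - tss$tss_cM)
  list(cis = d <= window_cM, distance_cM = d, flag = "none")
}
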