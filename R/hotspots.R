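#' Trans-eQTL density in sliding windows
#'
#' Number of distinct genes (not transcripts) whose trans-eQTL peak falls in
#' each half-open window `[start, start + window_bp)`, windows advancing by
#' `step_bp` along each chromosome.
#'
#' @param trans_peaks data.frame with columns `chrom`, `pos_bp`, `gene_id`.
#' @param map a `genetic_map` (supplies chromosome lengths).
#' @param window_bp window size in bp.
#' @param step_bp step between window starts.
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `count` of class
#'   `hotspot_windows` with the window parameters attached.
#' @export
trans_density <- function(trans_peaks, map, window_bp = 5e5, step_bp = 1e3) {
  stopifnot(inherits(map, "genetic_map"))
  out <- lapply(seq_len(nrow(map$chromosomes)), function(i) {
    ch <- map$chromosomes$chrom[i]
    len <- map$chromosomes$length_bp[i]
    starts <- seq(1, max(1, len - window_bp + 1), by = step_bp)
    pk <- trans_peaks[trans_peaks$chrom == ch, , drop = FALSE]
    counts <- integer(length(starts))
    if (nrow(pk)) {
      o <- order(pk$pos_bp)
      pos <- pk$pos_bp[o]
      gene <- as.character(pk$gene_id[o])
      # peaks with start <= pos < start + window
      first <- findInterval(starts - 1, pos) + 1L      # first pos >= start
      last <- findInterval(starts + window_bp - 1e-9, pos)  # last pos < end
      for (w in seq_along(starts)) {
        if (first[w] <= last[w])
          counts[w] <- length(unique(gene[first[w]:last[w]]))
      }
    }
    data.frame(chrom = ch, start_bp = starts,
               end_bp = starts + window_bp, count = counts,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "window_bp") <- window_bp
  attr(res, "step_bp") <- step_bp
  class(res) <- c("hotspot_windows", "data.frame")
  res
}

#' Poisson-Bonferroni density threshold for trans hotspots
#'
#' Under a homogeneous Poisson model, a window of `window_bp` contains on
#' average `lambda = n_trans * window_bp / genome_bp` trans-eQTL genes.  The
#' threshold is the smallest integer `d` with
#' `P(X > d) < level / n_tests`; windows are called hotspots when their
#' count strictly exceeds `d`.
#'
#' @param n_trans total number of trans-eQTL (unique genes).
#' @param window_bp window size.
#' @param genome_bp total genome size tested.
#' @param n_tests number of windows tested (Bonferroni denominator).
#' @param level family-wise error level.
#' @return Integer threshold `d` (with `lambda` and the corrected alpha as
#'   attributes).
#' @export
poisson_threshold <- function(n_trans, window_bp, genome_bp, n_tests,
                              level = 0.05) {
  lambda <- n_trans * window_bp / genome_bp
  alpha <- level / n_tests
  if (lambda == 0) {
    d <- 0L
  } else {
    d <- 0L
    while (ppois(d, lambda, lower.tail = FALSE) >= alpha) d <- d + 1L
  }
  structure(d, lambda = lambda, alpha = alpha)
}

#' Delineate hotspot intervals from flagged windows
#'
#' Runs of contiguous over-threshold windows are merged; each hotspot
#' interval spans from the lowermost to the uppermost confidence-interval
#' bound of any trans-eQTL peak falling in a member window.
#'
#' @param windows a `hotspot_windows` data.frame.
#' @param threshold integer density threshold (count must exceed it).
#' @param trans_peaks data.frame with `chrom`, `pos_bp`, `gene_id`,
#'   `ci_lo_bp`, `ci_hi_bp`.
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `n_eqtl`, `n_genes`
#'   (0 rows when nothing exceeds the threshold).
#' @export
delineate_hotspots <- function(windows, threshold, trans_peaks) {
  flagged <- windows[windows$count > threshold, , drop = FALSE]
  if (nrow(flagged) == 0L) return(data.frame())
  step <- attr(windows, "step_bp")
  win <- attr(windows, "window_bp")
  out <- list()
  for (ch in unique(flagged$chrom)) {
    fw <- flagged[flagged$chrom == ch, , drop = FALSE]
    fw <- fw[order(fw$start_bp), ]
    run_id <- cumsum(c(1, diff(fw$start_bp) > step))
    for (r in unique(run_id)) {
      rw <- fw[run_id == r, ]
      span_lo <- min(rw$start_bp)
      span_hi <- max(rw$start_bp) + win
      pk <- trans_peaks[trans_peaks$chrom == ch &
                        trans_peaks$pos_bp >= span_lo &
                        trans_peaks$pos_bp < span_hi, , drop = FALSE]
      if (nrow(pk) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start_bp = min(pk$ci_lo_bp), end_bp = max(pk$ci_hi_bp),
        n_eqtl = nrow(pk), n_genes = length(unique(pk$gene_id)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(data.frame())
  do.call(rbind, out)
}

#' Composite-variable candidate-gene analysis for a hotspot
#'
#' The first principal component of the transcripts regulated by a hotspot
#' serves as a composite expression variable.  Genes located inside the
#' hotspot interval are then ranked by the absolute correlation of their
#' expression with the composite; the per-regulated-transcript
#' best-correlated interval gene is reported, and optionally the correlation
#' between a candidate's cis haplotype effects and each trans-eQTL's
#' haplotype effects.
#'
#' @param regulated expression matrix (regulated transcripts x crosses).
#' @param interval_genes expression matrix (interval genes x crosses).
#' @param hap_effects optional list with `candidate` (named effect vector)
#'   and `trans` (list of named effect vectors per regulated transcript) for
#'   the effect-correlation report.
#' @return List: `composite` (scores per cross), `loadings`,
#'   `candidate_cor` (named, sorted by absolute correlation), `top_candidate`,
#'   `per_transcript_best` (best interval gene per regulated transcript),
#'   `effect_cor` (or NULL), `dropped` (constant transcripts).
#' @export
composite_candidate_analysis <- function(regulated, interval_genes,
                                         hap_effects = NULL) {
  stopifnot(is.matrix(regulated), is.matrix(interval_genes))
  sds <- apply(regulated, 1, sd)
  dropped <- rownames(regulated)[sds < 1e-12]
  regulated <- regulated[sds >= 1e-12, , drop = FALSE]
  if (nrow(regulated) == 0L) stop("no non-constant regulated transcripts")
  if (nrow(regulated) == 1L) {
    composite <- drop(scale(regulated[1L, ]))
    loadings <- setNames(1, rownames(regulated))
  } else {
    pc <- prcomp(t(regulated), center = TRUE, scale. = FALSE)
    composite <- pc$x[, 1L]
    loadings <- setNames(pc$rotation[, 1L], rownames(regulated))
  }
  cand <- apply(interval_genes, 1, function(g) cor(g, composite))
  ord <- order(-abs(cand))
  per_best <- apply(regulated, 1, function(tr) {
    cc <- apply(interval_genes, 1, function(g) cor(g, tr))
    rownames(interval_genes)[which.max(abs(cc))]
  })
  eff <- NULL
  if (!is.null(hap_effects)) {
    eff <- vapply(hap_effects$trans, function(e)
      cor(hap_effects$candidate[names(e)], e), numeric(1))
  }
  list(composite = composite, loadings = loadings,
       candidate_cor = cand[ord],
       top_candidate = rownames(interval_genes)[ord[1L]],
       per_transcript_best = per_best,
       effect_cor = eff, dropped = dropped)
}
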