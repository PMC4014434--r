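#' Map array probes to transcripts by exact sequence match
#'
#' A probe is kept if and only if its full 60-base sequence has an exact
#' match in at least one transcript CDS, on either strand.  Probes matching
#' several transcripts (common for transcripts of one gene) are mapped to
#' all of them.
#'
#' @param probes data.frame with `probe_id` and `seq` (60-base, ACGT only).
#' @param cds named character vector or `Biostrings::DNAStringSet` of
#'   transcript CDS sequences.
#' @return data.frame `probe_id`, `seq`, `transcript_ids` (comma-separated),
#'   `n_targets`, restricted to mapped probes.
#' @export
map_probes <- function(probes, cds) {
  stopifnot(is.data.frame(probes), all(c("probe_id", "seq") %in% names(probes)))
  if (any(grepl("[^ACGT]", probes$seq)))
    stop("probe sequences must contain only A, C, G, T")
  if (any(nchar(probes$seq) != 60L))
    stop("probe sequences must be exactly 60 bases")
  cds_set <- if (inherits(cds, "DNAStringSet")) cds
             else Biostrings::DNAStringSet(cds)
  if (is.null(names(cds_set))) stop("CDS sequences must be named")
  hits <- lapply(probes$seq, function(s) {
    p <- Biostrings::DNAString(s)
    fwd <- Biostrings::vcountPattern(p, cds_set, fixed = TRUE) > 0
    rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(p),
                                     cds_set, fixed = TRUE) > 0
    names(cds_set)[fwd | rev]
  })
  keep <- lengths(hits) > 0L
  data.frame(probe_id = probes$probe_id[keep],
             seq = probes$seq[keep],
             transcript_ids = vapply(hits[keep], paste, "", collapse = ","),
             n_targets = lengths(hits[keep]),
             stringsAsFactors = FALSE)
}

#' Filter probes whose measurements respond to a SNP under the probe
#'
#' Probes with more than one SNP are discarded outright.  For single-SNP
#' probes, the per-cross minor-allele dosage `M` (maternal plus paternal
#' minor-allele probability, 0..2) is regressed together with the
#' subpopulation factor against the intensity,
#' `intensity ~ intercept + S + M`, and the probe is removed when the
#' two-sided P value of the dosage coefficient falls below `alpha`.
#' SNP-free probes pass untouched; a probe whose dosage does not vary passes
#' with a warning.
#'
#' @param probe_info data.frame with `probe_id` and `snp_count`.
#' @param intensity matrix probes x crosses (rows matching `probe_info`).
#' @param M matrix of minor-allele dosages, same shape (rows for snp-free
#'   probes are ignored).
#' @param S subpopulation factor, one per cross.
#' @param alpha removal threshold for the dosage P value.
#' @return List `keep` (logical per probe), `p_value` (NA where untested),
#'   `log` (counts removed per rule).
#' @export
snp_probe_filter <- function(probe_info, intensity, M, S, alpha = 0.05) {
  stopifnot(nrow(probe_info) == nrow(intensity))
  n_probe <- nrow(probe_info)
  keep <- rep(TRUE, n_probe)
  p_value <- rep(NA_real_, n_probe)
  multi <- probe_info$snp_count > 1L
  keep[multi] <- FALSE
  single <- which(probe_info$snp_count == 1L)
  n_const <- 0L
  for (i in single) {
    m <- M[i, ]
    if (var(m) < 1e-12) {
      n_const <- n_const + 1L
      next
    }
    fit <- lm(intensity[i, ] ~ S + m)
    p <- summary(fit)$coefficients["m", "Pr(>|t|)"]
    p_value[i] <- p
    if (p < alpha) keep[i] <- FALSE
  }
  if (n_const > 0L)
    warning(n_const, " single-SNP probe(s) without dosage variation passed unfiltered")
  list(keep = keep, p_value = p_value,
       log = list(multi_snp_removed = sum(multi),
                  snp_effect_removed = sum(!keep) - sum(multi),
                  constant_dosage = n_const))
}

#' Summarize probe intensities into per-transcript expression
#'
#' Probes are grouped by target transcript (a probe mapping to several
#' transcripts contributes to each); transcripts with fewer than
#' `min_probes` contributing probes are dropped.  The per-transcript summary
#' is a median polish over the log2 probe intensities: the fitted overall
#' plus column (cross) effects, robust to single outlying probes.
#'
#' @param mapped data.frame from [map_probes()] (columns `probe_id`,
#'   `transcript_ids`), restricted to probes that passed filtering.
#' @param intensity matrix probes x crosses on the raw scale, rows matching
#'   `mapped`.
#' @param min_probes minimum probes per transcript.
#' @return List `expr` (matrix transcripts x crosses, log2 scale),
#'   `n_probes` (named), `dropped` (transcript ids with too few probes).
#' @export
summarize_transcripts <- function(mapped, intensity, min_probes = 4L) {
  stopifnot(nrow(mapped) == nrow(intensity))
  target <- strsplit(mapped$transcript_ids, ",", fixed = TRUE)
  by_tx <- split(rep(seq_len(nrow(mapped)), lengths(target)),
                 unlist(target))
  n_probes <- lengths(by_tx)
  dropped <- names(by_tx)[n_probes < min_probes]
  by_tx <- by_tx[n_probes >= min_probes]
  expr <- t(vapply(by_tx, function(rows) {
    mp <- medpolish(log2(intensity[rows, , drop = FALSE]),
                    trace.iter = FALSE, maxiter = 20L)
    mp$overall + mp$col
  }, numeric(ncol(intensity))))
  list(expr = expr, n_probes = n_probes[n_probes >= min_probes],
       dropped = dropped)
}

#' Collapse transcripts of a gene when they agree
#'
#' Within each gene, if all pairwise Pearson correlations between its
#' transcripts are at least `r_min` (inclusive), the transcripts are
#' replaced by their average expression under the gene's id; otherwise they
#' are kept separate.  Single-transcript genes pass through.
#'
#' @param expr matrix transcripts x crosses.
#' @param annotation data.frame `transcript_id`, `gene_id` covering the rows.
#' @param r_min correlation bound.
#' @return List `expr` (collapsed matrix), `collapsed` (logical per output
#'   row), `gene_id` per output row.
#' @export
collapse_gene_transcripts <- function(expr, annotation, r_min = 0.95) {
  ann <- annotation[match(rownames(expr), annotation$transcript_id), ]
  if (anyNA(ann$gene_id)) stop("annotation missing for some transcripts")
  rows <- list(); collapsed <- logical(); gene <- character()
  for (g in unique(ann$gene_id)) {
    idx <- which(ann$gene_id == g)
    if (length(idx) == 1L) {
      rows[[length(rows) + 1L]] <- expr[idx, ]
      names(rows)[length(rows)] <- rownames(expr)[idx]
      collapsed <- c(collapsed, FALSE); gene <- c(gene, g)
    } else {
      cc <- cor(t(expr[idx, , drop = FALSE]))
      if (all(cc[upper.tri(cc)] >= r_min)) {
        rows[[length(rows) + 1L]] <- colMeans(expr[idx, , drop = FALSE])
        names(rows)[length(rows)] <- g
        collapsed <- c(collapsed, TRUE); gene <- c(gene, g)
      } else {
        for (i in idx) {
          rows[[length(rows) + 1L]] <- expr[i, ]
          names(rows)[length(rows)] <- rownames(expr)[i]
          collapsed <- c(collapsed, FALSE); gene <- c(gene, g)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  list(expr = out, collapsed = collapsed, gene_id = gene)
}

# rank-based inverse-normal transform, ties by average rank
quantile_normalize_rows <- function(expr) {
  t(apply(expr, 1, function(y)
    qnorm((rank(y, ties.method = "average") - 0.5) / length(y))))
}

#' Quantile normalization and principal-component correction
#'
#' Each transcript is quantile-normalized to a standard normal (ranks with
#' average ties), principal components are computed across the full
#' transcript set, and each transcript is residualized on the subpopulation
#' factor plus the first `n_pcs` components to strip batch-like structure.
#' The residuals (exactly uncorrelated with every removed component) are
#' then re-quantile-normalized to restore per-transcript normality, which
#' perturbs those correlations only marginally.
#'
#' @param expr matrix transcripts x crosses.
#' @param S subpopulation factor per cross (optional).
#' @param n_pcs number of leading components to remove.
#' @param requantile re-normalize the residuals (default TRUE; FALSE leaves
#'   raw residuals, exactly orthogonal to the removed components).
#' @return List `expr` (corrected matrix), `pcs` (crosses x n_pcs scores),
#'   `var_explained` (per component).
#' @export
normalize_and_correct <- function(expr, S = NULL, n_pcs = 10L,
                                  requantile = TRUE) {
  n <- ncol(expr)
  if (n_pcs >= n) stop("n_pcs must be smaller than the number of crosses")
  if (n < n_pcs + 2L) stop("too few crosses for the requested correction")
  qn <- quantile_normalize_rows(expr)
  pc <- prcomp(t(qn), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  design <- if (is.null(S)) cbind(1, pc$x[, seq_len(k)])
            else model.matrix(~ S + pc$x[, seq_len(k)])
  qr_d <- qr(design)
  resid <- t(qr.resid(qr_d, t(qn)))
  out <- if (requantile) quantile_normalize_rows(resid) else resid
  dimnames(out) <- dimnames(expr)
  list(expr = out, pcs = pc$x[, seq_len(k), drop = FALSE],
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Remove transcripts expressed below the repeatability floor
#'
#' Replicated samples locate the expression level below which measurements
#' stop being repeatable.  Transcripts are binned by mean expression into
#' `n_bins` quantile bins; per bin the mean absolute replicate difference is
#' computed (averaged over replicate pairs).  Starting from the lowest bin,
#' the contiguous run of bins whose replicate discrepancy exceeds
#' `fold` times the median discrepancy of the upper half of bins is removed.
#'
#' @param expr matrix transcripts x crosses.
#' @param replicate_pairs list of length-2 integer vectors of column indices
#'   that are technical replicates of the same cross.
#' @param n_bins number of quantile bins.
#' @param fold multiple of the reference discrepancy that marks a bin
#'   unreliable.
#' @return List `expr` (filtered), `removed` (ids), `fraction_removed`,
#'   `floor` (mean-expression cutoff, -Inf when nothing removed).
#' @export
expression_floor <- function(expr, replicate_pairs, n_bins = 20L,
                             fold = 1.5) {
  if (length(replicate_pairs) == 0L) {
    warning("no replicate pairs: expression floor not applied")
    return(list(expr = expr, removed = character(), fraction_removed = 0,
                floor = -Inf))
  }
  m <- rowMeans(expr)
  d <- rowMeans(vapply(replicate_pairs,
                       function(pr) abs(expr[, pr[1L]] - expr[, pr[2L]]),
                       numeric(nrow(expr))))
  bins <- cut(rank(m, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  bin_d <- tapply(d, bins, mean)
  ref <- median(bin_d[(n_bins %/% 2 + 1L):n_bins])
  bad <- bin_d > fold * ref
  run <- 0L
  while (run < n_bins && bad[run + 1L]) run <- run + 1L
  if (run == 0L)
    return(list(expr = expr, removed = character(), fraction_removed = 0,
                floor = -Inf))
  rm_rows <- bins <= run
  list(expr = expr[!rm_rows, , drop = FALSE],
       removed = rownames(expr)[rm_rows],
       fraction_removed = mean(rm_rows),
       floor = max(m[rm_rows]))
}
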