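#' Simulate a transcript-abundance study over a set of crosses
#'
#' Builds an expression matrix with the statistical structure the mapping
#' pipeline assumes: per-transcript phenotypes composed of planted QTL
#' genetic values, a shared batch component, a polygenic component from a
#' genome-wide random founder-effect model, and Gaussian noise.  The
#' non-QTL part of every transcript has unit variance, split between the
#' polygenic share `polygenic_h2` and noise; a planted QTL is scaled so it
#' explains its specified fraction `z` of the transcript's phenotypic
#' variance in expectation.
#'
#' @param crosses a `cross_genotypes`.
#' @param n_transcripts number of transcripts.
#' @param qtl_catalog named list: transcript id -> [qtl_spec()] (or a list
#'   of them).  Ids must exist among the generated transcripts.
#' @param batch_effect_sd standard deviation of per-transcript batch
#'   loadings (0 disables batches); crosses are batched in groups of 12,
#'   emulating a 12-plex array.
#' @param polygenic_h2 fraction of non-QTL variance from the polygenic
#'   component.
#' @param n_polygenic_loci loci in the random founder-effect model.
#' @param gene_map optional function(transcript index) -> gene id, for
#'   multi-transcript genes; defaults to one gene per transcript.
#' @param annotation optional precomputed transcript annotation
#'   (`transcript_id, gene_id, chrom, tss_bp, tss_cM`); when given it
#'   overrides `n_transcripts` and `gene_map` and TSS positions are not
#'   redrawn (needed to plant cis QTL at known TSSs).
#' @param rng_seed integer seed.
#' @return Object of class `expression_study`: `expr` (transcripts x
#'   crosses), `annotation` (`transcript_id, gene_id, chrom, tss_bp,
#'   tss_cM`), `batch` (factor), `truth` (data.frame of planted QTL),
#'   `crosses`.
#' @export
simulate_expression_study <- function(crosses, n_transcripts,
                                      qtl_catalog = list(),
                                      batch_effect_sd = 0,
                                      polygenic_h2 = 0,
                                      n_polygenic_loci = 30L,
                                      gene_map = NULL,
                                      annotation = NULL,
                                      rng_seed = 1L) {
  stopifnot(inherits(crosses, "cross_genotypes"))
  map <- crosses$map
  n <- crosses$n
  set.seed(rng_seed)
  if (is.null(annotation)) {
    tx_id <- sprintf("tx_%04d", seq_len(n_transcripts))
    gene_id <- if (is.null(gene_map)) tx_id
               else vapply(seq_len(n_transcripts), gene_map, "")
    # TSS positions uniform over the genome, length-weighted
    ch_i <- sample.int(nrow(map$chromosomes), n_transcripts, replace = TRUE,
                       prob = map$chromosomes$length_bp)
    tss_bp <- floor(runif(n_transcripts) * map$chromosomes$length_bp[ch_i]) + 1
    annotation <- data.frame(
      transcript_id = tx_id, gene_id = gene_id,
      chrom = map$chromosomes$chrom[ch_i],
      tss_bp = tss_bp,
      tss_cM = tss_bp / map$chromosomes$length_bp[ch_i] *
        map$chromosomes$length_cM[ch_i],
      stringsAsFactors = FALSE)
  } else {
    n_transcripts <- nrow(annotation)
    tx_id <- annotation$transcript_id
    gene_id <- annotation$gene_id
  }
  if (length(qtl_catalog) &&
      !all(names(qtl_catalog) %in% tx_id))
    stop("qtl_catalog targets unknown transcripts: ",
         paste(setdiff(names(qtl_catalog), tx_id), collapse = ", "))
  batch <- factor(rep(seq_len(ceiling(n / 12)), each = 12)[seq_len(n)])
  batch_z <- as.numeric(scale(rnorm(nlevels(batch))[as.integer(batch)]))
  # polygenic random founder-effect model at shared loci
  poly_hap <- list()
  if (polygenic_h2 > 0) {
    poly_pos <- sample(map$grid$index,
                       min(n_polygenic_loci, nrow(map$grid)))
    poly_hap <- lapply(poly_pos, function(p) true_haplotypes(crosses, p))
  }
  expr <- matrix(0, n_transcripts, n, dimnames = list(tx_id, crosses$cross_id))
  truth <- list()
  for (t in seq_len(n_transcripts)) {
    base <- sqrt(1 - polygenic_h2) * rnorm(n)
    if (polygenic_h2 > 0) {
      gp <- rowSums(vapply(poly_hap, function(h) {
        effA <- rnorm(8); effB <- rnorm(8)
        effA[h[, "mat"]] + effB[h[, "pat"]]
      }, numeric(n)))
      base <- base + sqrt(polygenic_h2) * as.numeric(scale(gp))
    }
    if (batch_effect_sd > 0)
      base <- base + rnorm(1, 0, batch_effect_sd) * batch_z
    y <- base
    qs <- qtl_catalog[[tx_id[t]]]
    if (!is.null(qs)) {
      if (inherits(qs, "qtl_spec")) qs <- list(qs)
      for (q in qs) {
        pos <- find_grid_index(map, q$chrom, q$pos_cM)
        hap <- true_haplotypes(crosses, pos)
        effA <- q$allele_effects[q$allele_map[c(paste0("A", 1:7), "AB8_A")]]
        effB <- q$allele_effects[q$allele_map[c(paste0("B", 1:7), "AB8_B")]]
        g <- effA[hap[, "mat"]] + effB[hap[, "pat"]]
        if (var(g) < .Machine$double.eps)
          stop("degenerate QTL for transcript ", tx_id[t])
        s <- sqrt(var(base) * q$z / (1 - q$z) / var(g))
        y <- y + s * (g - mean(g))
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = tx_id[t], gene_id = gene_id[t],
          chrom = q$chrom, pos_cM = q$pos_cM,
          pos_bp = map$grid$pos_bp[pos], grid_index = pos,
          k = q$k, z = q$z, stringsAsFactors = FALSE)
      }
    }
    expr[t, ] <- y
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(transcript_id = character(), gene_id = character(),
               chrom = character(), pos_cM = numeric(), pos_bp = numeric(),
               grid_index = integer(), k = integer(), z = numeric())
  structure(list(expr = expr, annotation = annotation, batch = batch,
                 truth = truth, crosses = crosses),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$expr), "transcripts x", ncol(x$expr),
      "crosses;", nrow(x$truth), "planted QTL\n")
  invisible(x)
}

#' Simulate probe-level array intensities with SNP-in-probe artifacts
#'
#' Expands transcript-level expression into per-probe intensities on the
#' raw (anti-log) scale: probe affinity offsets, probe noise, and for a
#' fraction of probes a SNP whose minor-allele dosage shifts the measured
#' intensity, emulating hybridization artifacts.  A further fraction of
#' probes carries multiple SNPs (flagged, no model fitted for them).
#'
#' @param study an `expression_study`.
#' @param probes_per_transcript probes per transcript.
#' @param snp_probe_frac fraction of probes carrying exactly one SNP.
#' @param multi_snp_frac fraction carrying more than one SNP.
#' @param snp_effect_sd standard deviation of per-probe SNP effects on the
#'   log2 scale (effects drawn centred away from zero are not assumed:
#'   a zero-effect SNP probe is legitimate and should usually survive the
#'   filter).
#' @param noise_sd probe-level log2 noise.
#' @param rng_seed integer seed.
#' @return List `probe_info` (`probe_id, transcript_ids, snp_count`),
#'   `intensity` (probes x crosses, raw scale), `M` (minor-allele dosage,
#'   probes x crosses; zero rows for SNP-free probes), `S` (subpopulation
#'   factor), `snp_effect` (true per-probe log2 effect).
#' @export
simulate_probe_intensities <- function(study, probes_per_transcript = 8L,
                                       snp_probe_frac = 0.3,
                                       multi_snp_frac = 0.1,
                                       snp_effect_sd = 0.5,
                                       noise_sd = 0.1,
                                       rng_seed = 1L) {
  stopifnot(inherits(study, "expression_study"))
  crosses <- study$crosses
  set.seed(rng_seed)
  n_tx <- nrow(study$expr)
  n <- ncol(study$expr)
  n_probe <- n_tx * probes_per_transcript
  tx_of <- rep(seq_len(n_tx), each = probes_per_transcript)
  u <- runif(n_probe)
  snp_count <- ifelse(u < multi_snp_frac, 2L,
                      ifelse(u < multi_snp_frac + snp_probe_frac, 1L, 0L))
  M <- matrix(0, n_probe, n)
  snp_effect <- numeric(n_probe)
  log2_int <- matrix(0, n_probe, n)
  for (i in seq_len(n_probe)) {
    base <- study$expr[tx_of[i], ] + rnorm(1, 8, 1)  # probe affinity
    if (snp_count[i] == 1L) {
      pos <- sample(crosses$map$grid$index, 1L)
      X <- cross_dosage(crosses, pos)
      carA <- sample.int(8L, sample(1:4, 1L))
      carB <- sample.int(8L, sample(1:4, 1L))
      M[i, ] <- rowSums(X[, carA, drop = FALSE]) +
        rowSums(X[, 8L + carB, drop = FALSE])
      snp_effect[i] <- rnorm(1, 0, snp_effect_sd)
    }
    log2_int[i, ] <- base + snp_effect[i] * M[i, ] + rnorm(n, 0, noise_sd)
  }
  list(probe_info = data.frame(
         probe_id = sprintf("probe_%05d", seq_len(n_probe)),
         transcript_ids = rownames(study$expr)[tx_of],
         snp_count = snp_count, stringsAsFactors = FALSE),
       intensity = 2^log2_int, M = M, S = study$crosses$S,
       snp_effect = snp_effect)
}

#' Simulate a replicated study with an unreliable low-expression stratum
#'
#' Fixture generator for the expression-floor step: transcripts span a
#' range of mean expression; a low-expression stratum (default 23% of
#' transcripts) carries replicate-incoherent noise inflated by
#' `low_noise_fold`, emulating measurements below the array's reliable
#' range.  Two replicate column pairs are appended.
#'
#' @param n_transcripts,n_crosses matrix dimensions (replicate columns are
#'   added on top of `n_crosses`).
#' @param low_frac fraction of transcripts in the unreliable stratum.
#' @param low_noise_fold noise inflation for that stratum.
#' @param noise_sd baseline measurement noise.
#' @param rng_seed integer seed.
#' @return List `expr`, `replicate_pairs` (list of column pairs),
#'   `low_stratum` (logical per transcript).
#' @export
simulate_floor_study <- function(n_transcripts = 1000L, n_crosses = 100L,
                                 low_frac = 0.23, low_noise_fold = 2,
                                 noise_sd = 0.25, rng_seed = 1L) {
  set.seed(rng_seed)
  n_low <- round(low_frac * n_transcripts)
  mu <- sort(runif(n_transcripts, 4, 14))  # mean log2 expression
  low <- seq_len(n_transcripts) <= n_low   # lowest-expressed stratum
  sd_t <- ifelse(low, noise_sd * low_noise_fold, noise_sd)
  ncol_tot <- n_crosses + 2L
  # biological signal shared between replicates of a cross; drowned out
  # (absent) for the unreliable stratum
  signal <- matrix(rnorm(n_transcripts * n_crosses, 0, noise_sd),
                   n_transcripts, n_crosses) * as.numeric(!low)
  expr <- mu + cbind(signal, signal[, 1:2]) +
    matrix(rnorm(n_transcripts * ncol_tot, 0, sd_t), n_transcripts, ncol_tot)
  rownames(expr) <- sprintf("tx_%04d", seq_len(n_transcripts))
  list(expr = expr,
       replicate_pairs = list(c(1L, n_crosses + 1L), c(2L, n_crosses + 2L)),
       low_stratum = low)
}
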