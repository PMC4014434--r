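# Pipeline orchestration: synth -> scan -> peaks -> alleles -> hotspots,
# each stage writing versioned outputs and a JSON provenance record under
# the configured output directory.  Completed stages are reused on rerun
# unless force = TRUE.

# allowed configuration schema: key -> validator
pipeline_schema <- function() {
  num1 <- function(x) is.numeric(x) && length(x) == 1L
  pos1 <- function(x) num1(x) && x > 0
  list(
    out_dir = is.character,
    master_seed = num1,
    synth = list(
      n_crosses = pos1, n_transcripts = pos1, grid_step_bp = pos1,
      pool_size = pos1, certainty = function(x) num1(x) && x >= 1/8 && x <= 1,
      breakpoint_rate = pos1, cis_fraction = num1,
      hotspot_targets = function(x) num1(x) && x >= 0,
      batch_effect_sd = num1, polygenic_h2 = num1),
    scan = list(
      n_perm = pos1, level = pos1, cis_window_cM = pos1),
    peaks = list(drop = pos1, bci_coverage = pos1),
    alleles = list(
      k_set = is.numeric, min_count = pos1, min_prob = pos1,
      criterion = function(x) x %in% c("min_p", "aic"),
      within_panel_only = is.logical),
    hotspots = list(window_bp = pos1, step_bp = pos1, level = pos1))
}

pipeline_defaults <- function() {
  list(out_dir = "results/pipeline", master_seed = 1,
       synth = list(n_crosses = 200, n_transcripts = 50,
                    grid_step_bp = 2e5, pool_size = 120, certainty = 0.98,
                    breakpoint_rate = 0.25, cis_fraction = 0.5,
                    hotspot_targets = 0, batch_effect_sd = 0,
                    polygenic_h2 = 0.2),
       scan = list(n_perm = 200, level = 0.05, cis_window_cM = 1.5),
       peaks = list(drop = 3, bci_coverage = 0.95),
       alleles = list(k_set = 2:8, min_count = 5, min_prob = 0.95,
                      criterion = "min_p", within_panel_only = FALSE),
       hotspots = list(window_bp = 5e5, step_bp = 1e4, level = 0.05))
}

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected; known keys are checked against simple type
#' and range predicates, and defaults fill the rest.
#'
#' @param config named list (e.g. from [yaml::read_yaml()]).
#' @return The completed configuration.
#' @export
validate_pipeline_config <- function(config) {
  schema <- pipeline_schema()
  defaults <- pipeline_defaults()
  check <- function(cfg, sch, def, path) {
    unknown <- setdiff(names(cfg), names(sch))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste(paste0(path, unknown), collapse = ", "))
    for (k in names(sch)) {
      if (is.list(sch[[k]]) && !is.function(sch[[k]])) {
        cfg[[k]] <- check(if (is.null(cfg[[k]])) list() else cfg[[k]],
                          sch[[k]], def[[k]], paste0(path, k, "."))
      } else if (is.null(cfg[[k]])) {
        cfg[[k]] <- def[[k]]
      } else if (!isTRUE(sch[[k]](cfg[[k]]))) {
        stop("invalid value for configuration key ", path, k)
      }
    }
    cfg
  }
  check(config, schema, defaults, "")
}

#' Read and validate a YAML pipeline configuration
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

stage_done <- function(dir, stage) {
  file.exists(file.path(dir, stage, "provenance.json"))
}

write_provenance <- function(dir, stage, config, seed, counts = list()) {
  d <- file.path(dir, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(stage = stage, seed = seed, config_hash = config_hash(config),
         counts = counts, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(d, "provenance.json"), auto_unbox = TRUE, digits = NA)
}

#' Run the full mapping pipeline on a synthetic study
#'
#' Stages run in order (synth, scan, peaks, alleles, hotspots); each stage
#' writes its outputs plus a provenance JSON under `out_dir` and is skipped
#' on rerun when its provenance record already exists (`force = TRUE`
#' recomputes everything).
#'
#' @param config configuration list or YAML path (see
#'   [validate_pipeline_config()]).
#' @param force recompute completed stages.
#' @return Invisible list with the main in-memory artifacts (`study`,
#'   `thresholds`, `eqtl` table, `alleles` table, `hotspots`).
#' @export
run_pipeline <- function(config = list(), force = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  else config <- validate_pipeline_config(config)
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- fan_seeds(config$master_seed, 10L)
  # fingerprint over the scientific configuration, not the output location
  hash_cfg <- config[setdiff(names(config), "out_dir")]
  meta <- list(config_hash = config_hash(hash_cfg), seed = config$master_seed)

  ## stage: synth ------------------------------------------------------
  sy <- config$synth
  map <- dspr_map(sy$grid_step_bp)
  pA <- attach_uncertainty(
    simulate_ril_pool(map, founder_panel("A"), 2L * sy$pool_size,
                      sy$breakpoint_rate, rng_seed = seeds[1]), sy$certainty)
  pB <- attach_uncertainty(
    simulate_ril_pool(map, founder_panel("B"), 2L * sy$pool_size,
                      sy$breakpoint_rate, rng_seed = seeds[2]), sy$certainty)
  set.seed(seeds[3])
  nh <- sy$n_crosses %/% 2L
  idxA <- c(sample(which(pA$pool$subpop == "A1"), nh),
            sample(which(pA$pool$subpop == "A2"), nh))
  idxB <- c(sample(which(pB$pool$subpop == "B2"), nh),
            sample(which(pB$pool$subpop == "B1"), nh))
  crosses <- make_crosses(pA, pB, idxA, idxB)
  catalog <- demo_qtl_catalog(map, sy, seeds[4])
  study <- simulate_expression_study(
    crosses, sy$n_transcripts, catalog$by_transcript,
    batch_effect_sd = sy$batch_effect_sd, polygenic_h2 = sy$polygenic_h2,
    annotation = catalog$annotation, rng_seed = seeds[5])
  if (force || !stage_done(dir, "synth")) {
    write_expression_study(study, file.path(dir, "synth"), meta)
    write_provenance(dir, "synth", hash_cfg, seeds[5],
                     list(transcripts = nrow(study$expr),
                          crosses = ncol(study$expr),
                          planted_qtl = nrow(study$truth)))
  }

  ## stage: scan -------------------------------------------------------
  sc <- config$scan
  thr <- permutation_threshold(study$expr, crosses, n_perm = sc$n_perm,
                               level = sc$level,
                               cis_window_cM = sc$cis_window_cM,
                               tss = study$annotation, rng_seed = seeds[6])
  scan <- lod_scan(study$expr, crosses)
  if (force || !stage_done(dir, "scan")) {
    d <- file.path(dir, "scan")
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    write_thresholds(thr, file.path(d, "thresholds.json"))
    lod_df <- data.frame(scan$grid[, c("chrom", "pos_bp", "pos_cM")],
                         scan$lod, check.names = FALSE)
    colnames(lod_df)[-(1:3)] <- rownames(study$expr)
    write_tsv(lod_df, file.path(d, "lod.tsv"), meta)
    write_provenance(dir, "scan", hash_cfg, seeds[6],
                     list(n_perm = sc$n_perm,
                          genome_wide = thr$genome_wide,
                          cis_only = thr$cis_only))
  }

  ## stage: peaks ------------------------------------------------------
  h2_cache <- NULL
  eqtl <- list(); peak_meta <- list()
  K <- kinship(crosses, grid_step_cM = 0.5)
  eK <- eigen(unclass(K), symmetric = TRUE)
  for (t in seq_len(nrow(study$expr))) {
    tss <- study$annotation[t, ]
    pk <- call_peaks(scan, thr, tss = list(chrom = tss$chrom,
                                           tss_cM = tss$tss_cM),
                     transcript = t, drop = config$peaks$drop,
                     cis_window_cM = sc$cis_window_cM)
    if (nrow(pk) == 0L) next
    y <- study$expr[t, ]
    h2 <- heritability(y, eK)$h2
    for (r in seq_len(nrow(pk))) {
      acct <- effect_accounting(y, crosses, pk$peak_idx[r], h2)
      pop <- classify_population(y, crosses, pk$peak_idx[r])
      tab <- peak_table(pk[r, , drop = FALSE], tss$transcript_id,
                        tss$gene_id, tss, acct$pct_variance, h2)
      tab$population <- pop$model
      eqtl[[length(eqtl) + 1L]] <- tab
      peak_meta[[length(peak_meta) + 1L]] <-
        list(transcript = t, peak_idx = pk$peak_idx[r], row = tab)
    }
  }
  eqtl <- if (length(eqtl)) do.call(rbind, eqtl) else data.frame()
  if (force || !stage_done(dir, "peaks")) {
    d <- file.path(dir, "peaks")
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    write_tsv(eqtl, file.path(d, "eqtl.tsv"), meta)
    if (nrow(eqtl)) {
      bed <- data.frame(chrom = eqtl$chr, ci_lo_bp = eqtl$peaklpL,
                        ci_hi_bp = eqtl$peakupL, name = eqtl$Name)
      write_peaks_bed(bed, file.path(d, "eqtl_ci.bed"))
    }
    write_provenance(dir, "peaks", hash_cfg, seeds[7],
                     list(n_eqtl = nrow(eqtl)))
  }

  ## stage: alleles ----------------------------------------------------
  al <- config$alleles
  allele_rows <- list()
  for (pm in peak_meta) {
    y <- study$expr[pm$transcript, ]
    rh <- try(retained_haplotypes(y, crosses, pm$peak_idx,
                                  al$min_count, al$min_prob), silent = TRUE)
    if (inherits(rh, "try-error")) next
    fit <- estimate_allele_number(y, rh, al$criterion, al$k_set,
                                  al$within_panel_only)
    allele_rows[[length(allele_rows) + 1L]] <- data.frame(
      eqtl_id = pm$row$Name, criterion = al$criterion,
      k_hat = fit$k_hat, p_best = fit$best$p, aic_best = fit$best$aic,
      r2_best = fit$best$r2,
      extra_var_vs_2allele = extra_variance_vs_two_allele(fit),
      stringsAsFactors = FALSE)
  }
  alleles <- if (length(allele_rows)) do.call(rbind, allele_rows)
             else data.frame()
  if (force || !stage_done(dir, "alleles")) {
    d <- file.path(dir, "alleles")
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    write_tsv(alleles, file.path(d, "alleles.tsv"), meta)
    write_provenance(dir, "alleles", hash_cfg, seeds[8],
                     list(n_eqtl = nrow(alleles)))
  }

  ## stage: hotspots ---------------------------------------------------
  ho <- config$hotspots
  hotspots <- data.frame(); windows <- NULL
  if (nrow(eqtl)) {
    trans <- eqtl[!eqtl$cis, , drop = FALSE]
    windows <- trans_density(
      data.frame(chrom = trans$chr, pos_bp = trans$peakp,
                 gene_id = trans$GID),
      map, ho$window_bp, ho$step_bp)
    thr_d <- poisson_threshold(length(unique(trans$GID[!is.na(trans$GID)])),
                               ho$window_bp, sum(map$chromosomes$length_bp),
                               nrow(windows), ho$level)
    hotspots <- delineate_hotspots(
      windows, thr_d,
      data.frame(chrom = trans$chr, pos_bp = trans$peakp,
                 gene_id = trans$GID, ci_lo_bp = trans$peaklpL,
                 ci_hi_bp = trans$peakupL))
  }
  if (force || !stage_done(dir, "hotspots")) {
    d <- file.path(dir, "hotspots")
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(windows))
      write_density_bedgraph(windows, file.path(d, "density.bedGraph"))
    write_tsv(hotspots, file.path(d, "hotspots.tsv"), meta)
    write_provenance(dir, "hotspots", hash_cfg, seeds[9],
                     list(n_hotspots = nrow(hotspots)))
  }

  invisible(list(study = study, crosses = crosses, thresholds = thr,
                 scan = scan, eqtl = eqtl, alleles = alleles,
                 windows = windows, hotspots = hotspots))
}

# catalog of planted QTL for the demo study: TSS annotation drawn first,
# cis QTL planted at their target transcript's TSS on a fraction of
# transcripts, plus an optional trans regulator driving several targets
demo_qtl_catalog <- function(map, sy, seed) {
  set.seed(seed)
  n_tx <- sy$n_transcripts
  tx_ids <- sprintf("tx_%04d", seq_len(n_tx))
  ch_i <- sample.int(nrow(map$chromosomes), n_tx, replace = TRUE,
                     prob = map$chromosomes$length_bp)
  tss_bp <- floor(runif(n_tx) * map$chromosomes$length_bp[ch_i]) + 1
  annotation <- data.frame(
    transcript_id = tx_ids, gene_id = tx_ids,
    chrom = map$chromosomes$chrom[ch_i], tss_bp = tss_bp,
    tss_cM = tss_bp / map$chromosomes$length_bp[ch_i] *
      map$chromosomes$length_cM[ch_i],
    stringsAsFactors = FALSE)
  n_cis <- round(sy$cis_fraction * n_tx)
  by_tx <- list()
  cis_targets <- sample(tx_ids, n_cis)
  for (id in cis_targets) {
    t <- match(id, tx_ids)
    z <- min(0.95, max(0.1, rbeta(1, 1.5, 3.5) + 0.1))
    by_tx[[id]] <- random_qtl_spec(annotation$chrom[t], annotation$tss_cM[t],
                                   k = sample(2:4, 1L), z = z)
  }
  if (sy$hotspot_targets > 0) {
    ci <- sample.int(nrow(map$chromosomes), 1L)
    pos <- runif(1, 5, map$chromosomes$length_cM[ci] - 5)
    reg <- random_qtl_spec(map$chromosomes$chrom[ci], pos, k = 2L, z = 0.4)
    free <- setdiff(tx_ids, cis_targets)
    # one transcript becomes the regulator gene itself: relocated to the
    # regulator locus with a cis-QTL of the same allelic architecture
    reg_id <- free[1L]
    t <- match(reg_id, tx_ids)
    annotation$chrom[t] <- map$chromosomes$chrom[ci]
    annotation$tss_cM[t] <- pos
    annotation$tss_bp[t] <- round(pos / map$chromosomes$length_cM[ci] *
                                    map$chromosomes$length_bp[ci])
    by_tx[[reg_id]] <- reg
    targets <- sample(free[-1L], min(sy$hotspot_targets,
                                     length(free) - 1L))
    for (id in targets) {   # targets are disjoint from the cis set
      q <- reg
      q$z <- min(0.9, max(0.15, rbeta(1, 2, 3)))
      by_tx[[id]] <- q
    }
  }
  list(by_transcript = by_tx, annotation = annotation)
}
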