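# Readers and writers for the interchange formats.  Internal coordinates are
# 1-based closed bp plus cM; BED/bedGraph exports are 0-based half-open (the
# conversion is delegated to rtracklayer).  Every output file carries header
# comment lines with the config hash and seed.

# '# hapqtl key=value' header lines
format_meta <- function(meta) {
  vapply(names(meta), function(k)
    sprintf("# hapqtl %s=%s", k, as.character(meta[[k]])), "")
}

parse_meta <- function(lines) {
  hdr <- grep("^# hapqtl ", lines, value = TRUE)
  kv <- sub("^# hapqtl ", "", hdr)
  eq <- regexpr("=", kv, fixed = TRUE)
  setNames(as.list(substring(kv, eq + 1L)), substring(kv, 1L, eq - 1L))
}

#' Write a table as TSV with a provenance header
#'
#' @param df data.frame.
#' @param path output path.
#' @param meta named list written as `# hapqtl key=value` comment lines
#'   (config hash, seed, ...).
#' @export
write_tsv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(format_meta(meta), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-headed TSV
#'
#' @param path input path.
#' @return data.frame with attribute `meta`.
#' @export
read_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "meta") <- parse_meta(readLines(path, n = 50L))
  df
}

# short config fingerprint for provenance headers
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %%
            .Machine$integer.max)
}

#' Write haplotype probabilities, one TSV per chromosome
#'
#' Columns: `cross_id, pos_bp, pos_cM`, then the 16 probability columns
#' `pA_A1..pA_AB8, pB_B1..pB_AB8` (one row per cross per grid position).
#'
#' @param crosses a `cross_genotypes`.
#' @param dir output directory.
#' @param meta provenance header entries.
#' @return Paths written.
#' @export
write_hap_probs <- function(crosses, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- crosses$map$grid
  paths <- character()
  for (ch in unique(grid$chrom)) {
    idx <- chrom_grid_idx(crosses$map, ch)
    blocks <- lapply(idx, function(p) {
      X <- cross_dosage(crosses, p)
      data.frame(cross_id = crosses$cross_id,
                 pos_bp = grid$pos_bp[p], pos_cM = grid$pos_cM[p],
                 X, check.names = FALSE)
    })
    path <- file.path(dir, paste0("happrob_", ch, ".tsv"))
    ch_meta <- c(meta, list(chrom = ch,
                            length_bp = crosses$map$chromosomes$length_bp[
                              crosses$map$chromosomes$chrom == ch],
                            length_cM = crosses$map$chromosomes$length_cM[
                              crosses$map$chromosomes$chrom == ch]))
    write_tsv(do.call(rbind, blocks), path, ch_meta)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read haplotype probabilities written by [write_hap_probs()]
#'
#' Probability rows are validated: each panel's eight probabilities must sum
#' to 1 within `tol`.
#'
#' @param paths TSV paths (one per chromosome).
#' @param tol tolerance on probability sums.
#' @return A `cross_genotypes` with materialized probabilities (true
#'   mosaics unavailable).
#' @export
read_hap_probs <- function(paths, tol = 1e-6) {
  cols <- founder_column_labels()
  chrom_tab <- list(); per_chrom <- list()
  for (path in paths) {
    df <- read_tsv(path)
    meta <- attr(df, "meta")
    if (is.null(meta$chrom)) stop("missing chromosome metadata in ", path)
    sums_a <- rowSums(df[, cols[1:8]])
    sums_b <- rowSums(df[, cols[9:16]])
    bad <- which(abs(sums_a - 1) > tol | abs(sums_b - 1) > tol)
    if (length(bad))
      stop("probabilities do not sum to 1 within ", tol, " at line(s) ",
           paste(head(bad, 3L), collapse = ", "), " of ", path)
    chrom_tab[[meta$chrom]] <- data.frame(
      chrom = meta$chrom, length_bp = as.numeric(meta$length_bp),
      length_cM = as.numeric(meta$length_cM))
    per_chrom[[meta$chrom]] <- df
  }
  chromosomes <- do.call(rbind, unname(chrom_tab))
  cross_id <- unique(per_chrom[[1L]]$cross_id)
  n <- length(cross_id)
  grid <- do.call(rbind, lapply(per_chrom, function(df)
    unique(df[, c("pos_bp", "pos_cM")])))
  grid <- data.frame(chrom = rep(names(per_chrom),
                                 vapply(per_chrom, function(df)
                                   length(unique(df$pos_bp)), 1L)),
                     grid, stringsAsFactors = FALSE)
  grid$index <- seq_len(nrow(grid))
  map <- structure(list(chromosomes = chromosomes, grid = grid,
                        grid_step_bp = NA), class = "genetic_map")
  P <- array(NA_real_, c(n, 16L, nrow(grid)),
             dimnames = list(cross_id, cols, NULL))
  off <- 0L
  for (ch in names(per_chrom)) {
    df <- per_chrom[[ch]]
    pos <- unique(df$pos_bp)
    for (j in seq_along(pos)) {
      rows <- df[df$pos_bp == pos[j], ]
      P[match(rows$cross_id, cross_id), , off + j] <-
        as.matrix(rows[, cols])
    }
    off <- off + length(pos)
  }
  structure(list(P = P, map = map, n = n, cross_id = cross_id,
                 S = NULL, backend = "probs"),
            class = "cross_genotypes")
}

#' Write an expression study: TSV matrix, GFF3 TSS sidecar, truth JSON
#'
#' @param study an `expression_study`.
#' @param dir output directory.
#' @param meta provenance entries.
#' @return Directory path.
#' @export
write_expression_study <- function(study, dir, meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_df <- data.frame(transcript_id = rownames(study$expr),
                        study$expr, check.names = FALSE)
  write_tsv(expr_df, file.path(dir, "expression.tsv"), meta)
  gr <- GenomicRanges::GRanges(
    seqnames = study$annotation$chrom,
    ranges = IRanges::IRanges(start = study$annotation$tss_bp, width = 1L),
    ID = study$annotation$transcript_id,
    gene_id = study$annotation$gene_id,
    type = "transcription_start_site")
  rtracklayer::export.gff3(gr, file.path(dir, "tss.gff3"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read an expression study directory
#'
#' @param dir directory written by [write_expression_study()].
#' @param map the `genetic_map` of the study (to recover cM coordinates).
#' @return List `expr`, `annotation`, `truth` (NULL when absent).
#' @export
read_expression_study <- function(dir, map) {
  df <- read_tsv(file.path(dir, "expression.tsv"))
  expr <- as.matrix(df[, -1L, drop = FALSE])
  rownames(expr) <- df$transcript_id
  gr <- rtracklayer::import(file.path(dir, "tss.gff3"))
  annotation <- data.frame(
    transcript_id = gr$ID, gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss_bp = GenomicRanges::start(gr), stringsAsFactors = FALSE)
  ci <- match(annotation$chrom, map$chromosomes$chrom)
  annotation$tss_cM <- annotation$tss_bp / map$chromosomes$length_bp[ci] *
    map$chromosomes$length_cM[ci]
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::fromJSON(truth_path) else NULL
  list(expr = expr, annotation = annotation, truth = truth)
}

#' Export peak confidence intervals as BED
#'
#' BED uses 0-based half-open coordinates; the conversion from the internal
#' 1-based closed bounds is handled by rtracklayer.
#'
#' @param peaks peak data.frame from [call_peaks()] (needs `chrom`,
#'   `ci_lo_bp`, `ci_hi_bp`) with optional `name` column.
#' @param path output `.bed` path.
#' @param which `"lod_drop"` or `"bayes"` interval columns.
#' @export
write_peaks_bed <- function(peaks, path, which = c("lod_drop", "bayes")) {
  which <- match.arg(which)
  lo <- if (which == "lod_drop") peaks$ci_lo_bp else peaks$bci_lo_bp
  hi <- if (which == "lod_drop") peaks$ci_hi_bp else peaks$bci_hi_bp
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = lo, end = hi),
    name = if (!is.null(peaks$name)) peaks$name
           else sprintf("peak_%03d", seq_len(nrow(peaks))))
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Export a window density track as bedGraph
#'
#' @param windows `hotspot_windows` data.frame from [trans_density()].
#' @param path output `.bedGraph` path.
#' @export
write_density_bedgraph <- function(windows, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = windows$chrom,
    ranges = IRanges::IRanges(start = windows$start_bp,
                              end = windows$end_bp - 1L),
    score = windows$count)
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Assemble the per-eQTL results table
#'
#' One row per called peak in the canonical column layout: identifiers,
#' peak and confidence-interval coordinates in both systems, LOD, percent
#' variance, heritability, distances to the transcription start site, the
#' cis flag, and the transcript location.
#'
#' @param peaks data.frame from [call_peaks()] (one transcript's peaks).
#' @param transcript_id,gene_id identifiers.
#' @param tss row with `chrom`, `tss_bp`, `tss_cM`.
#' @param pct_variance,h2 effect accounting values (scalars, recycled).
#' @return data.frame with columns `Name, TID, GID, chr, peakp, peaklpL,
#'   peakupL, peaklpB, peakupB, peakg, peaklgL, peakugL, peaklgB, peakugB,
#'   LOD, Pvar, h2, psdist, gsdist, cis, GlocC, GlocP, GlocG`.
#' @export
peak_table <- function(peaks, transcript_id, gene_id, tss,
                       pct_variance = NA, h2 = NA) {
  if (nrow(peaks) == 0L) return(data.frame())
  same_chr <- peaks$chrom == tss$chrom
  data.frame(
    Name = sprintf("%s_eqtl%d", transcript_id, seq_len(nrow(peaks))),
    TID = transcript_id, GID = gene_id, chr = peaks$chrom,
    peakp = peaks$pos_bp,
    peaklpL = peaks$ci_lo_bp, peakupL = peaks$ci_hi_bp,
    peaklpB = peaks$bci_lo_bp, peakupB = peaks$bci_hi_bp,
    peakg = peaks$pos_cM,
    peaklgL = peaks$ci_lo_cM, peakugL = peaks$ci_hi_cM,
    peaklgB = peaks$bci_lo_cM, peakugB = peaks$bci_hi_cM,
    LOD = peaks$lod, Pvar = pct_variance, h2 = h2,
    psdist = ifelse(same_chr, peaks$pos_bp - tss$tss_bp, NA),
    gsdist = ifelse(same_chr, peaks$pos_cM - tss$tss_cM, NA),
    cis = peaks$cis,
    GlocC = tss$chrom, GlocP = tss$tss_bp, GlocG = tss$tss_cM,
    stringsAsFactors = FALSE)
}

#' Write thresholds as JSON
#' @param thresholds a `thresholds` object.
#' @param path output path.
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(
    list(genome_wide = thresholds$genome_wide,
         cis_only = thresholds$cis_only,
         n_perm = thresholds$n_perm, level = thresholds$level),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
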