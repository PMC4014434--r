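#!/usr/bin/env Rscript
# Trans-eQTL hotspot detection on the demo study: sliding-window density of
# unique genes with trans peaks, the Poisson-Bonferroni density threshold,
# hotspot delineation from member confidence intervals, and the
# composite-variable candidate-gene analysis against the planted regulator.

source("analysis/00_common.R")

res <- build_demo()
eqtl <- res$eqtl
map <- res$crosses$map

trans <- eqtl[!eqtl$cis, , drop = FALSE]
message(sprintf("%d trans-eQTL (%d unique genes) enter the density scan",
                nrow(trans), length(unique(trans$GID))))

peaks <- data.frame(chrom = trans$chr, pos_bp = trans$peakp,
                    gene_id = trans$GID,
                    ci_lo_bp = trans$peaklpL, ci_hi_bp = trans$peakupL)
w <- trans_density(peaks, map, window_bp = 5e5, step_bp = 1e4)
d <- poisson_threshold(length(unique(peaks$gene_id)), 5e5,
                       sum(map$chromosomes$length_bp), nrow(w))
message(sprintf("Poisson density threshold: > %d genes per 500 kb (lambda %.3f, %d windows)",
                as.integer(d), attr(d, "lambda"), nrow(w)))

hs <- delineate_hotspots(w, d, peaks)
if (nrow(hs)) {
  message("hotspots:")
  print(hs)
} else message("no window exceeded the threshold")
write_tsv(hs, file.path(RESULTS, "hotspots.tsv"),
          meta = list(seed = MASTER_SEED))
write_density_bedgraph(w, file.path(SCRATCH, "trans_density.bedGraph"))

# composite candidate analysis inside the first hotspot
if (nrow(hs)) {
  study <- res$study
  reg_tx <- unique(peaks$gene_id[peaks$chrom == hs$chrom[1] &
                                   peaks$pos_bp >= hs$start_bp[1] &
                                   peaks$pos_bp <= hs$end_bp[1]])
  regulated <- study$expr[rownames(study$expr) %in% reg_tx, , drop = FALSE]
  in_interval <- study$annotation$chrom == hs$chrom[1] &
    study$annotation$tss_bp >= hs$start_bp[1] &
    study$annotation$tss_bp <= hs$end_bp[1]
  interval_genes <- study$expr[in_interval, , drop = FALSE]
  if (nrow(interval_genes) == 0L) {
    message("no assayed transcript lies inside the hotspot interval")
  } else {
    cca <- composite_candidate_analysis(regulated, interval_genes)
    message(sprintf("composite loadings span |%.2f-%.2f|; top candidate: %s (r = %.2f)",
                    min(abs(cca$loadings)), max(abs(cca$loadings)),
                    cca$top_candidate, cca$candidate_cor[1]))
    write_tsv(data.frame(gene = names(cca$candidate_cor),
                         cor_with_composite = as.numeric(cca$candidate_cor)),
              file.path(RESULTS, "hotspot_candidates.tsv"),
              meta = list(seed = MASTER_SEED))
  }
}
message("wrote ", RESULTS, "/hotspots.tsv")
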