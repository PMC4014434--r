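#!/usr/bin/env Rscript
# Generate the synthetic mapping study every later stage consumes:
# two 8-founder RIL panels, 200 pA x pB F1 crosses, and a 60-transcript
# expression matrix with planted cis-QTL, one trans-regulator hotspot,
# batch structure, and a polygenic background.  Writes the ground-truth
# ledger and a summary; the full study files land in the scratch pipeline
# directory for the downstream scripts.

source("analysis/00_common.R")

res <- build_demo()
study <- res$study

message(sprintf("study: %d transcripts x %d crosses, %d planted QTL",
                nrow(study$expr), ncol(study$expr), nrow(study$truth)))
message(sprintf("  cis-planted transcripts: %d; trans-regulator targets: %d",
                sum(study$truth$pos_cM %in%
                      study$annotation$tss_cM[match(study$truth$transcript_id,
                                                    study$annotation$transcript_id)]),
                sum(duplicated(study$truth$pos_bp))))

write_tsv(study$truth, file.path(RESULTS, "planted_qtl.tsv"),
          meta = list(seed = MASTER_SEED))
jsonlite::write_json(
  list(n_transcripts = nrow(study$expr), n_crosses = ncol(study$expr),
       n_planted = nrow(study$truth),
       mean_z = mean(study$truth$z)),
  file.path(RESULTS, "study_summary.json"), auto_unbox = TRUE, digits = NA)
message("wrote ", RESULTS, "/planted_qtl.tsv and study_summary.json")
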