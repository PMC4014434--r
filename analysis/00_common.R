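# Shared builders for the analysis scripts.  Everything is deterministic
# given the master seed, so each script can rebuild the study instead of
# serializing R objects.

library(hapqtl)

MASTER_SEED <- 20140508

RESULTS <- "results"
SCRATCH <- "scratch/analysis"
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)
dir.create(SCRATCH, showWarnings = FALSE, recursive = TRUE)

# demo study: 200 F1 crosses on a five-arm genome (200 kb scan grid),
# 60 transcripts -- half with a cis-QTL at their own TSS (2-4 alleles,
# large effects), 16 driven in trans by one planted regulator locus --
# plus batch structure and a polygenic background
demo_config <- function() {
  validate_pipeline_config(list(
    out_dir = file.path(SCRATCH, "pipeline"),
    master_seed = MASTER_SEED,
    synth = list(n_crosses = 200, n_transcripts = 60, grid_step_bp = 2e5,
                 pool_size = 150, certainty = 0.98, cis_fraction = 0.5,
                 hotspot_targets = 16, batch_effect_sd = 0.3,
                 polygenic_h2 = 0.2),
    scan = list(n_perm = 200)))
}

build_demo <- function() {
  run_pipeline(demo_config())
}
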