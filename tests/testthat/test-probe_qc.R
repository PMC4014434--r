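make_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("probes map by exact 60-mer match only, on either strand, possibly to several transcripts", {
  shared <- make_seq(60, 1)
  tx1 <- paste0(make_seq(40, 2), shared, make_seq(40, 3))
  tx2 <- paste0(make_seq(20, 4), shared, make_seq(70, 5))
  tx3 <- make_seq(150, 6)
  cds <- c(tx1A = tx1, tx1B = tx2, tx3 = tx3)
  exact <- substr(tx3, 31, 90)
  mism <- exact
  substr(mism, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                  substr(exact, 30, 30))[1]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(exact)))
  probes <- data.frame(
    probe_id = c("p_shared", "p_exact", "p_mismatch", "p_rc"),
    seq = c(shared, exact, mism, rc))
  res <- map_probes(probes, cds)
  expect_setequal(res$probe_id, c("p_shared", "p_exact", "p_rc"))
  expect_equal(res$transcript_ids[res$probe_id == "p_shared"], "tx1A,tx1B")
  expect_equal(res$n_targets[res$probe_id == "p_shared"], 2L)
  expect_equal(res$transcript_ids[res$probe_id == "p_rc"], "tx3")
  expect_error(map_probes(data.frame(probe_id = "x",
                                     seq = paste(rep("N", 60), collapse = "")),
                          cds), "A, C, G, T")
})

test_that("SNP-in-probe filter removes multi-SNP probes, keeps neutral probes, and has power", {
  n <- 500
  set.seed(42)
  S <- factor(rep(c("A1xB2", "A2xB1"), each = n / 2))
  n_probe <- 300
  M <- matrix(rbinom(n_probe * n, 2, 0.3), n_probe, n)
  info <- data.frame(probe_id = sprintf("p%03d", 1:n_probe),
                     snp_count = rep(1L, n_probe))
  # neutral probes: intensity independent of dosage
  intensity <- matrix(rnorm(n_probe * n, 10, 1), n_probe, n)
  res <- snp_probe_filter(info, intensity, M, S, alpha = 0.05)
  frac_kept <- mean(res$keep)
  ci <- qbinom(c(0.0005, 0.9995), n_probe, 0.95) / n_probe
  expect_gte(frac_kept, ci[1])
  expect_lte(frac_kept, ci[2])
  # multi-SNP probes removed regardless of any fit
  info2 <- info; info2$snp_count[1:50] <- 2L
  res2 <- snp_probe_filter(info2, intensity, M, S)
  expect_false(any(res2$keep[1:50]))
  expect_equal(res2$log$multi_snp_removed, 50L)
  # affected probes removed: intensity = 0.5 M + noise
  aff <- 0.5 * M + matrix(rnorm(n_probe * n, 0, 0.1), n_probe, n)
  res3 <- snp_probe_filter(info, aff, M, S)
  expect_false(any(res3$keep))
  # relaxing alpha keeps a superset (monotone filtering)
  res4 <- snp_probe_filter(info, intensity, M, S, alpha = 0.01)
  expect_true(all(res4$keep[res$keep]))
  # constant dosage passes with a warning
  M0 <- M; M0[3, ] <- 1
  expect_warning(r5 <- snp_probe_filter(info, intensity, M0, S),
                 "without dosage variation")
  expect_true(r5$keep[3])
})

test_that("median-polish summarization enforces the four-probe rule and resists outliers", {
  n <- 20
  mk <- function(ids, k) data.frame(probe_id = sprintf("%s_%d", ids, 1:k),
                                    transcript_ids = ids)
  # 3 probes: dropped
  mapped <- rbind(mk("tx_few", 3), mk("tx_flat", 8), mk("tx_out", 8))
  inten <- rbind(matrix(2^8, 3, n),
                 matrix(2^6, 8, n),
                 matrix(2^6, 8, n))
  inten[12, ] <- 2^13    # one wildly outlying probe for tx_out
  rs <- summarize_transcripts(mapped, inten)
  expect_setequal(rownames(rs$expr), c("tx_flat", "tx_out"))
  expect_equal(rs$dropped, "tx_few")
  # identical probes: summary equals the common value
  expect_equal(unname(rs$expr["tx_flat", ]), rep(6, n))
  # summary closer to the probe median than to the probe mean
  med <- 6; mn <- mean(c(rep(6, 7), 13))
  expect_true(all(abs(rs$expr["tx_out", ] - med) < abs(rs$expr["tx_out", ] - mn)))
})

test_that("transcripts collapse to their gene only when all pairwise correlations reach the bound", {
  set.seed(9)
  n <- 60
  x <- rnorm(n)
  orth <- residuals(lm(rnorm(n) ~ x))
  mix <- function(r) {
    v <- r * scale(x)[, 1] + sqrt(1 - r^2) * scale(orth)[, 1]
    as.numeric(v)
  }
  expr <- rbind(tA1 = as.numeric(scale(x)), tA2 = as.numeric(scale(x)),
                tB1 = as.numeric(scale(x)), tB2 = mix(0.99), tB3 = mix(0.60),
                tC1 = as.numeric(scale(x)), tC2 = mix(0.95),
                tD1 = rnorm(n))
  ann <- data.frame(transcript_id = rownames(expr),
                    gene_id = c("gA", "gA", "gB", "gB", "gB",
                                "gC", "gC", "gD"))
  res <- collapse_gene_transcripts(expr, ann, r_min = 0.95)
  # gA: r = 1 -> averaged under the gene id
  expect_true("gA" %in% rownames(res$expr))
  # gB: one poor pair breaks the ALL rule -> kept separate
  expect_true(all(c("tB1", "tB2", "tB3") %in% rownames(res$expr)))
  # gC: r exactly at the bound (inclusive) -> averaged
  expect_equal(cor(expr["tC1", ], expr["tC2", ]), 0.95, tolerance = 1e-12)
  expect_true("gC" %in% rownames(res$expr))
  # single-transcript gene passes through
  expect_true("tD1" %in% rownames(res$expr))
})

test_that("PC correction leaves residuals orthogonal to removed components and strips planted batches", {
  set.seed(31)
  n_tx <- 120; n <- 80
  S <- factor(rep(c("A1xB2", "A2xB1"), each = n / 2))
  batch <- rep(1:4, each = n / 4)
  batch_z <- as.numeric(scale(rnorm(4)[batch]))
  expr <- matrix(rnorm(n_tx * n), n_tx, n)
  affected <- 1:36   # 30% of transcripts load on the batch factor
  expr[affected, ] <- expr[affected, ] + 2 * outer(rep(1, 36), batch_z)
  rownames(expr) <- sprintf("tx%03d", 1:n_tx)
  res_raw <- normalize_and_correct(expr, S, n_pcs = 10, requantile = FALSE)
  for (j in 1:10)
    expect_lt(max(abs(cor(t(res_raw$expr), res_raw$pcs[, j]))), 1e-8)
  res <- normalize_and_correct(expr, S, n_pcs = 10)
  cors <- abs(apply(res$expr[affected, ], 1, function(y) cor(y, batch_z)))
  expect_lt(median(cors), 0.1)
  expect_error(normalize_and_correct(expr[, 1:8], n_pcs = 10), "n_pcs")
})

test_that("normalization output stays normal and the step is stable under reapplication", {
  set.seed(77)
  expr <- matrix(rnorm(200 * 60), 200, 60)
  rownames(expr) <- sprintf("tx%03d", 1:200)
  res <- normalize_and_correct(expr, n_pcs = 10)
  pvals <- apply(res$expr, 1, function(y) shapiro.test(y)$p.value)
  expect_gte(mean(pvals > 0.001), 0.99)
  # the two halves of the step are individually idempotent: the rank-based
  # normal transform is invariant on already-transformed rows, and
  # residualizing twice on the same components equals residualizing once
  qn <- hapqtl:::quantile_normalize_rows(expr)
  expect_equal(hapqtl:::quantile_normalize_rows(qn), qn, tolerance = 1e-12)
  design <- cbind(1, res$pcs)
  r1 <- t(qr.resid(qr(design), t(qn)))
  r2 <- t(qr.resid(qr(design), t(r1)))
  expect_equal(r2, r1, tolerance = 1e-10)
})

test_that("expression floor removes the planted unreliable stratum and only that", {
  fs <- simulate_floor_study(1000, 100, low_frac = 0.23, rng_seed = 5)
  res <- expression_floor(fs$expr, fs$replicate_pairs)
  expect_gt(res$fraction_removed, 0.15)
  expect_lt(res$fraction_removed, 0.31)
  removed <- rownames(fs$expr) %in% res$removed
  expect_gt(mean(fs$low_stratum[removed]), 0.9)   # removals are low-stratum
  expect_gt(mean(removed[fs$low_stratum]), 0.7)   # most of the stratum goes
  # identical replicates: nothing removed
  expr2 <- fs$expr
  expr2[, 101] <- expr2[, 1]; expr2[, 102] <- expr2[, 2]
  res2 <- expression_floor(expr2, fs$replicate_pairs)
  expect_equal(res2$fraction_removed, 0)
  expect_warning(res3 <- expression_floor(fs$expr, list()), "no replicate")
  expect_identical(res3$expr, fs$expr)
})
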