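test_that("LOD is zero for uninformative genotypes and invariant to affine phenotype changes", {
  map <- toy_map(5e5)
  # certainty 1/8: uniform probability vectors carry no information
  pA <- attach_uncertainty(
    simulate_ril_pool(map, founder_panel("A"), 60, rng_seed = 1), 1 / 8)
  pB <- attach_uncertainty(
    simulate_ril_pool(map, founder_panel("B"), 60, rng_seed = 2), 1 / 8)
  cr <- make_crosses(pA, pB)
  set.seed(3)
  y <- rnorm(60)
  sc <- lod_scan(y, cr)
  expect_true(all(sc$lod == 0))
  expect_true(all(sc$df1 == 0L))
  # affine invariance on informative genotypes
  cr2 <- toy_crosses()
  y2 <- rnorm(cr2$n)
  l1 <- lod_scan(y2, cr2, positions = 1:30)$lod
  l2 <- lod_scan(5.5 * y2 - 3, cr2, positions = 1:30)$lod
  expect_equal(l1, l2, tolerance = 1e-8)
  expect_true(all(l1 >= 0))
  expect_error(lod_scan(rnorm(10), cr2), "length")
})

# helper exercised above only for its error; a 19-cross set is invalid
make_crosses_n19 <- function() {
  map <- toy_map(5e5)
  pA <- attach_uncertainty(
    simulate_ril_pool(map, founder_panel("A"), 19, rng_seed = 5), 1)
  pB <- attach_uncertainty(
    simulate_ril_pool(map, founder_panel("B"), 19, rng_seed = 6), 1)
  suppressWarnings(make_crosses(pA, pB))
}

test_that("the scan rejects undersized or incomplete inputs", {
  cr19 <- make_crosses_n19()
  expect_lt(cr19$n, 20L)
  expect_error(lod_scan(rnorm(cr19$n), cr19), "20 crosses")
  cr <- toy_crosses()
  y <- rnorm(cr$n); y[4] <- NA
  expect_error(lod_scan(y, cr), "missing")
})

test_that("a planted QTL is localized within 1.5 cM in at least 95% of replicates", {
  crosses <- big_crosses()
  am <- setNames(rep(1:2, length.out = 15), hapqtl:::founder_truth_labels())
  qtl <- qtl_spec("c1", 30, am, c(0, 1), z = 0.4)
  n_rep <- 200
  Y <- t(vapply(1:n_rep,
                function(s) as.numeric(simulate_phenotype(crosses, qtl, s)),
                numeric(crosses$n)))
  rownames(Y) <- sprintf("rep%03d", 1:n_rep)
  pos <- chrom_positions(crosses$map, "c1")
  sc <- lod_scan(Y, crosses, positions = pos)
  true_cM <- 30
  est_cM <- sc$grid$pos_cM[apply(sc$lod, 2, which.max)]
  expect_gte(mean(abs(est_cM - true_cM) <= 1.5), 0.95)
})

test_that("permutation thresholds behave like maxima: cis below genome-wide, degenerate at zero", {
  crosses <- toy_crosses()
  set.seed(11)
  n_tx <- 40
  expr <- matrix(rnorm(n_tx * crosses$n), n_tx, crosses$n,
                 dimnames = list(sprintf("tx%02d", 1:n_tx), NULL))
  tss <- data.frame(transcript_id = rownames(expr),
                    chrom = sample(c("c1", "c2"), n_tx, TRUE),
                    tss_cM = runif(n_tx, 0, 60))
  thr <- permutation_threshold(expr, crosses, n_perm = 120,
                               tss = tss, rng_seed = 4)
  expect_lte(thr$cis_only, thr$genome_wide)
  expect_true(all(thr$perm_max_cis <= thr$perm_max))
  # all-constant transcripts: nothing to exceed, threshold collapses to 0
  const <- matrix(1, 5, crosses$n,
                  dimnames = list(paste0("c", 1:5), NULL))
  thr0 <- permutation_threshold(const, crosses, n_perm = 100,
                                cis_window_cM = NULL, rng_seed = 1)
  expect_equal(thr0$genome_wide, 0)
  expect_error(permutation_threshold(expr, crosses, n_perm = 50),
               "n_perm")
  expect_error(permutation_threshold(expr, crosses, n_perm = 120,
                                     cis_window_cM = 1.5, tss = NULL),
               "TSS")
})

test_that("observed null scan maxima are exchangeable with permutation maxima", {
  crosses <- toy_crosses()
  set.seed(21)
  n_tx <- 60
  expr <- matrix(rnorm(n_tx * crosses$n), n_tx, crosses$n,
                 dimnames = list(sprintf("tx%02d", 1:n_tx), NULL))
  pos <- seq(1, nrow(crosses$map$grid), by = 2)
  thr <- permutation_threshold(expr, crosses, positions = pos, n_perm = 100,
                               cis_window_cM = NULL, rng_seed = 9)
  sc <- lod_scan(expr, crosses, positions = pos)
  # the observed experiment-wise maximum sits inside the permutation null
  expect_lt(max(sc$lod), max(thr$perm_max) + 1.5)
  expect_gt(max(sc$lod), min(thr$perm_max) - 1.5)
})

test_that("the threshold grows with the number of transcripts scanned", {
  crosses <- toy_crosses()
  set.seed(5)
  expr_big <- matrix(rnorm(100 * crosses$n), 100, crosses$n,
                     dimnames = list(sprintf("t%03d", 1:100), NULL))
  pos <- seq(1, nrow(crosses$map$grid), by = 4)
  thr10 <- permutation_threshold(expr_big[1:10, ], crosses, positions = pos,
                                 n_perm = 100, cis_window_cM = NULL,
                                 rng_seed = 2)
  thr100 <- permutation_threshold(expr_big, crosses, positions = pos,
                                  n_perm = 100, cis_window_cM = NULL,
                                  rng_seed = 2)
  expect_gt(thr100$genome_wide, thr10$genome_wide)
})

test_that("kinship matches closed forms for crafted genotype structures", {
  # identical one-hot crosses: K_ii = 1; disjoint founders: K_ij = 0;
  # shared maternal RIL with disjoint paternal: K_ij = 1/2
  P <- rbind(one_hot_row(1, 1),
             one_hot_row(1, 2),
             one_hot_row(2, 3))
  cr <- probs_crosses(P)
  K <- kinship(cr, grid_step_cM = 0.5)
  expect_equal(diag(unclass(K)), rep(1, 3), ignore_attr = TRUE)
  expect_equal(unclass(K)[1, 3], 0)
  expect_equal(unclass(K)[1, 2], 0.5)
  expect_true(isSymmetric(unclass(K)))
})

test_that("REML heritability recovers planted polygenic signal and flags degenerate designs", {
  crosses <- toy_crosses()
  K <- unclass(kinship(crosses, grid_step_cM = 1))
  eK <- eigen(K, symmetric = TRUE)
  n <- crosses$n
  L <- eK$vectors %*% diag(sqrt(pmax(eK$values, 0)))
  h2_target <- 0.5
  est <- vapply(1:100, function(s) {
    set.seed(s)
    g <- L %*% rnorm(n)
    y <- sqrt(h2_target) * g / sd(g) + sqrt(1 - h2_target) * rnorm(n)
    heritability(as.numeric(y), eK)$h2
  }, numeric(1))
  expect_lt(abs(mean(est) - h2_target), 0.05)
  # pure noise: h2 near zero
  null_est <- vapply(101:200, function(s) {
    set.seed(s)
    heritability(rnorm(n), eK)$h2
  }, numeric(1))
  expect_lt(median(null_est), 0.05)
  # identity kinship: unidentifiable, flagged
  res <- heritability(rnorm(50), diag(50))
  expect_true(is.na(res$h2))
  expect_equal(res$flag, "unidentifiable")
})

test_that("adding the true grouped genotype predictor never increases the residual sum of squares", {
  crosses <- toy_crosses()
  am <- setNames(rep(1:2, length.out = 15), hapqtl:::founder_truth_labels())
  qtl <- qtl_spec("c1", 30, am, c(0, 1), z = 0.3)
  y <- simulate_phenotype(crosses, qtl, rng_seed = 12)
  pos <- attr(y, "truth")$pos_index
  X <- cross_dosage(crosses, pos)
  rss_full <- sum(qr.resid(qr(cbind(1, X)), y)^2)
  g_true <- attr(y, "truth")$g
  rss_aug <- sum(qr.resid(qr(cbind(1, X, g_true)), y)^2)
  expect_lte(rss_aug, rss_full + 1e-10)
})
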