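test_that("mosaic simulation is deterministic and honors the no-recombination limit", {
  map <- toy_map()
  panel <- founder_panel("A")
  m1 <- simulate_ril_mosaic(map, panel, breakpoint_rate = 0.25, rng_seed = 7)
  m2 <- simulate_ril_mosaic(map, panel, breakpoint_rate = 0.25, rng_seed = 7)
  expect_identical(m1, m2)
  # vanishing rate: a single founder along each chromosome
  m0 <- simulate_ril_mosaic(map, panel, breakpoint_rate = 1e-9, rng_seed = 3)
  for (ch in unique(map$grid$chrom))
    expect_length(unique(m0[map$grid$chrom == ch]), 1L)
  expect_error(simulate_ril_pool(map, panel, 0), "n_ril")
  expect_error(simulate_ril_pool(map, panel, 5, breakpoint_rate = 0), ">")
})

test_that("breakpoint counts match the Poisson expectation of the recombination model", {
  # 50 cM chromosome on a fine grid; expected breakpoints = rate * length
  map <- genetic_map(data.frame(chrom = "c", length_bp = 5e6,
                                length_cM = 50), grid_step_bp = 2500)
  pool <- simulate_ril_pool(map, founder_panel("A"), 10000,
                            breakpoint_rate = 0.25, rng_seed = 11)
  n_bp <- rowSums(pool$founder[, -1L, drop = FALSE] !=
                    pool$founder[, -ncol(pool$founder), drop = FALSE])
  delta <- diff(map$grid$pos_cM)[1]
  expected <- (ncol(pool$founder) - 1L) * (1 - exp(-0.25 * delta))
  expect_lt(abs(expected - 12.5), 0.12)  # discretization bias is small
  se <- sd(n_bp) / sqrt(length(n_bp))
  expect_lt(abs(mean(n_bp) - 12.5), 3 * se + 0.12)
})

test_that("mosaic block lengths are approximately exponential", {
  map <- genetic_map(data.frame(chrom = "c", length_bp = 5e6,
                                length_cM = 100), grid_step_bp = 2500)
  pool <- simulate_ril_pool(map, founder_panel("A"), 800,
                            breakpoint_rate = 0.25, rng_seed = 13)
  delta <- diff(map$grid$pos_cM)[1]
  lengths_cM <- unlist(apply(pool$founder, 1, function(f) {
    r <- rle(f)$lengths
    if (length(r) < 3L) return(numeric())
    r[2:(length(r) - 1L)] * delta   # interior blocks only (uncensored)
  }))
  set.seed(1)
  lengths_cM <- lengths_cM + runif(length(lengths_cM), 0, delta)
  lengths_cM <- sample(lengths_cM, 10000)
  ks <- suppressWarnings(stats::ks.test(lengths_cM, "pexp", rate = 0.25))
  expect_gt(ks$p.value, 0.001)
})

test_that("attach_uncertainty spreads mass as specified and validates its range", {
  pool <- simulate_ril_pool(toy_map(), founder_panel("A"), 10, rng_seed = 5)
  hp1 <- attach_uncertainty(pool, 1)
  P1 <- hapqtl:::hap_prob_matrix(hp1, 4L)
  expect_true(all(P1 %in% c(0, 1)))
  expect_equal(rowSums(P1), rep(1, 10))
  hp <- attach_uncertainty(pool, 0.95)
  P <- hapqtl:::hap_prob_matrix(hp, 4L)
  expect_true(all(abs(P - 0.95) < 1e-12 | abs(P - 0.05 / 7) < 1e-12))
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-12)
  expect_error(attach_uncertainty(pool, 0.1), "certainty")
  expect_error(attach_uncertainty(pool, 1.01), "certainty")
})

test_that("probability vectors sum to one per panel at every position", {
  crosses <- toy_crosses()
  for (p in c(1L, 50L, 150L, nrow(crosses$map$grid))) {
    X <- cross_dosage(crosses, p)
    expect_lt(max(abs(rowSums(X[, 1:8]) - 1)), 1e-9)
    expect_lt(max(abs(rowSums(X[, 9:16]) - 1)), 1e-9)
  }
})

test_that("make_crosses pairs panels correctly and passes probabilities through", {
  map <- toy_map()
  pA <- attach_uncertainty(
    simulate_ril_pool(map, founder_panel("A"), 40, rng_seed = 1), 0.9)
  pB <- attach_uncertainty(
    simulate_ril_pool(map, founder_panel("B"), 40, rng_seed = 2), 0.9)
  cr <- make_crosses(pA, pB)
  expect_equal(cr$n, 40L)
  expect_setequal(levels(cr$S), c("A1xB2", "A2xB1"))
  # probability vectors preserved bit-exact
  X <- cross_dosage(cr, 10L)
  A <- hapqtl:::hap_prob_matrix(pA, 10L)[cr$idx_A, ]
  expect_identical(unname(X[, 1:8]), unname(A))
  expect_error(make_crosses(pB, pA), "panel")
  expect_error(make_crosses(pA, pB, integer(), integer()), "no RILs")
  expect_error(make_crosses(pA, pB, 1:3, 1:5), "equal numbers")
})

test_that("simulate_phenotype realizes the requested variance fraction", {
  crosses <- big_crosses()
  am <- setNames(rep(1:3, length.out = 15), hapqtl:::founder_truth_labels())
  for (z in c(0.1, 0.3, 0.6)) {
    qtl <- qtl_spec("c1", 30, am, c(0, 1, 2), z = z)
    frac <- vapply(1:100, function(s) {
      y <- simulate_phenotype(crosses, qtl, rng_seed = s)
      tr <- attr(y, "truth")
      var(tr$g) / var(y)
    }, numeric(1))
    expect_lt(abs(mean(frac) - z), 0.05)
  }
  expect_error(qtl_spec("c1", 30, am, c(0, 1, 2), z = 1.2), "z must")
  mono <- setNames(rep(1L, 15), hapqtl:::founder_truth_labels())
  qtl0 <- qtl_spec("c1", 30, mono, c(1, 2), z = 0.5)
  expect_error(simulate_phenotype(crosses, qtl0), "degenerate")
})

test_that("a strong biallelic QTL is nearly perfectly explained by its true genotype", {
  crosses <- toy_crosses_certain()
  am <- setNames(rep(1:2, length.out = 15), hapqtl:::founder_truth_labels())
  qtl <- qtl_spec("c1", 30, am, c(0, 1), z = 0.999)
  y <- simulate_phenotype(crosses, qtl, rng_seed = 8)
  g <- attr(y, "truth")$g
  expect_gt(summary(lm(y ~ g))$r.squared, 0.99)
})

test_that("expression study generator emits a complete ground-truth ledger", {
  crosses <- toy_crosses()
  q1 <- random_qtl_spec("c1", 10, 2, 0.4)
  q2 <- random_qtl_spec("c2", 40, 3, 0.3)
  st <- simulate_expression_study(
    crosses, 5, qtl_catalog = list(tx_0001 = q1, tx_0004 = q2),
    rng_seed = 5)
  expect_equal(nrow(st$truth), 2L)
  expect_equal(dim(st$expr), c(5L, crosses$n))
  expect_false(anyNA(st$expr))
  expect_equal(nrow(st$annotation), 5L)
  expect_error(
    simulate_expression_study(crosses, 5,
                              qtl_catalog = list(tx_9999 = q1)),
    "unknown transcript")
})
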