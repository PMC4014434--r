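#' Configuration for the allele-number estimator simulation study
#'
#' Defaults are the desk-scale study: 200 iterations per true allele number
#' in {2..8, 15}, 600 RILs sampled per panel from pre-generated pools of 800
#' per replicate subpopulation, equal-spaced allele effects, and the QTL
#' variance fraction drawn from a Beta(1.5, 3.5) distribution truncated to
#' [0.05, 0.95] standing in for the observed distribution of variance
#' explained by cis-eQTL (large effects, median near 25%).  The full-scale
#' study uses `iterations = 1000`.
#'
#' @param k_values true allele numbers (subset of 2..8, 15; 15 means the
#'   full set of founder genomes with AB8 shared between panels).
#' @param iterations iterations per k.
#' @param n_per_panel RILs sampled per panel per iteration.
#' @param effect_scheme `"equal_spaced"` (effects 1..k) or `"normal"`
#'   (effects drawn N(0,1)).
#' @param z_source `"distribution"` (truncated Beta) or `"fixed"`.
#' @param z_params list: `shape1`, `shape2`, `min`, `max` for
#'   `"distribution"`; `z` for `"fixed"`.
#' @param certainty haplotype probability mass on the true founder seen by
#'   the estimator.
#' @param pool_size RILs per replicate subpopulation in the panel pools.
#' @param grid_step_bp scan-grid spacing of the synthetic genome.
#' @param breakpoint_rate mosaic breakpoints per cM.
#' @param k_set allele numbers swept by the estimator (full model added).
#' @param master_seed master seed fanned out to all random draws.
#' @return List of class `sim_study_config`.
#' @export
sim_study_config <- function(k_values = c(2:8, 15L),
                             iterations = 200L,
                             n_per_panel = 600L,
                             effect_scheme = c("equal_spaced", "normal"),
                             z_source = c("distribution", "fixed"),
                             z_params = list(shape1 = 1.5, shape2 = 3.5,
                                             min = 0.05, max = 0.95),
                             certainty = 0.98,
                             pool_size = 800L,
                             grid_step_bp = 1e5,
                             breakpoint_rate = 0.25,
                             k_set = 2:8,
                             master_seed = 1L) {
  effect_scheme <- match.arg(effect_scheme)
  z_source <- match.arg(z_source)
  stopifnot(iterations >= 1L, all(k_values %in% c(2:8, 15L)))
  if (any(k_values > 15L)) stop("more alleles than founder genomes")
  structure(list(k_values = as.integer(k_values),
                 iterations = as.integer(iterations),
                 n_per_panel = as.integer(n_per_panel),
                 effect_scheme = effect_scheme,
                 z_source = z_source, z_params = z_params,
                 certainty = certainty, pool_size = as.integer(pool_size),
                 grid_step_bp = grid_step_bp,
                 breakpoint_rate = breakpoint_rate,
                 k_set = k_set, master_seed = master_seed),
            class = "sim_study_config")
}

# draw one z value
draw_z <- function(config) {
  if (config$z_source == "fixed") return(config$z_params$z)
  repeat {
    z <- rbeta(1, config$z_params$shape1, config$z_params$shape2)
    if (z >= config$z_params$min && z <= config$z_params$max) return(z)
  }
}

# allele assignment over the 15 founder genomes, every allele represented
draw_allele_map <- function(k) {
  if (k == 15L) {
    am <- sample.int(15L)
  } else {
    repeat {
      am <- sample.int(k, 15L, replace = TRUE)
      if (length(unique(am)) == k) break
    }
  }
  names(am) <- founder_truth_labels()
  am
}

#' Run the allele-number estimator simulation study
#'
#' Per iteration: sample crosses from the panel pools, plant a QTL of known
#' allele number at a uniform-random grid position (AB8 carries one shared
#' allele across panels), draw the variance fraction z, simulate the
#' phenotype from the true haplotypes, and run the ordered-partition
#' estimator on the haplotype probabilities.  Both selection criteria
#' (lowest P, lowest AIC) are recorded from the same model sweep, so
#' criterion comparisons share datasets exactly.
#'
#' @param config a [sim_study_config()].
#' @param pools optional precomputed list `pA`, `pB` of `hap_probs` pools
#'   (for sharing across study variants); must match the config's map,
#'   certainty and pool size.
#' @return Object of class `sim_study_result`: `records` (one row per
#'   iteration), `config`, plus [sim_confusion()] / [sim_rates()] summaries.
#' @export
run_allele_sim <- function(config, pools = NULL) {
  stopifnot(inherits(config, "sim_study_config"))
  seeds <- fan_seeds(config$master_seed,
                     2L + length(config$k_values) * config$iterations)
  if (is.null(pools)) pools <- sim_panel_pools(config, seeds[1:2])
  map <- pools$pA$pool$map
  grid_n <- nrow(map$grid)
  n_half <- config$n_per_panel %/% 2L
  a1 <- which(pools$pA$pool$subpop == "A1")
  a2 <- which(pools$pA$pool$subpop == "A2")
  b1 <- which(pools$pB$pool$subpop == "B1")
  b2 <- which(pools$pB$pool$subpop == "B2")
  recs <- vector("list", length(config$k_values) * config$iterations)
  ctr <- 0L
  for (k_true in config$k_values) {
    for (it in seq_len(config$iterations)) {
      ctr <- ctr + 1L
      set.seed(seeds[2L + ctr])
      idxA <- c(sample(a1, n_half), sample(a2, n_half))
      idxB <- c(sample(b2, n_half), sample(b1, n_half))
      crosses <- make_crosses(pools$pA, pools$pB, idxA, idxB)
      pos <- sample.int(grid_n, 1L)
      am <- draw_allele_map(k_true)
      effects <- if (config$effect_scheme == "equal_spaced") seq_len(k_true)
                 else rnorm(k_true)
      z <- draw_z(config)
      hap <- true_haplotypes(crosses, pos)
      effA <- effects[am[c(paste0("A", 1:7), "AB8")]]
      effB <- effects[am[c(paste0("B", 1:7), "AB8")]]
      g <- effA[hap[, "mat"]] + effB[hap[, "pat"]]
      if (var(g) < .Machine$double.eps) {
        # all sampled crosses monoallelic at the locus; record NA row
        recs[[ctr]] <- data.frame(k_true = k_true, iteration = it,
                                  k_minp = NA, k_aic = NA, m = NA,
                                  p_best = NA, r2_best = NA, z = z,
                                  extra_var = NA)
        next
      }
      y <- g + rnorm(length(g), 0, sqrt(var(g) * (1 - z) / z))
      rh <- retained_haplotypes(y, crosses, pos)
      gr <- enumerate_groupings(rh, config$k_set)
      sw <- sweep_groupings(y, rh, gr)
      pick_p <- select_grouping(sw, "min_p")
      pick_a <- select_grouping(sw, "aic")
      two <- sw[sw$k == 2L, , drop = FALSE]
      extra <- if (nrow(two)) 100 * (sw$r2[pick_p] - max(two$r2)) else NA
      recs[[ctr]] <- data.frame(k_true = k_true, iteration = it,
                                k_minp = sw$k[pick_p], k_aic = sw$k[pick_a],
                                m = gr$m, p_best = sw$p[pick_p],
                                r2_best = sw$r2[pick_p], z = z,
                                extra_var = extra)
    }
  }
  structure(list(records = do.call(rbind, recs), config = config),
            class = "sim_study_result")
}

# generate the two panel pools for a config
sim_panel_pools <- function(config, seeds = fan_seeds(config$master_seed, 2)) {
  map <- dspr_map(config$grid_step_bp)
  mk <- function(panel_id, seed) {
    pool <- simulate_ril_pool(map, founder_panel(panel_id),
                              n_ril = 2L * config$pool_size,
                              breakpoint_rate = config$breakpoint_rate,
                              rng_seed = seed)
    attach_uncertainty(pool, config$certainty)
  }
  list(pA = mk("A", seeds[1]), pB = mk("B", seeds[2]))
}

#' @export
print.sim_study_result <- function(x, ...) {
  r <- sim_rates(x)
  cat("sim_study_result:", nrow(x$records), "iterations;",
      sprintf("min-P under/correct/over = %.1f/%.1f/%.1f%%\n",
              r["under"], r["correct"], r["over"]))
  invisible(x)
}

#' Confusion matrix of true versus estimated allele numbers
#'
#' @param result a `sim_study_result`.
#' @param criterion `"min_p"` or `"aic"`.
#' @return Matrix of row percentages (rows: true k, columns: estimated k).
#' @export
sim_confusion <- function(result, criterion = c("min_p", "aic")) {
  criterion <- match.arg(criterion)
  rec <- result$records
  k_hat <- if (criterion == "min_p") rec$k_minp else rec$k_aic
  ok <- !is.na(k_hat)
  tab <- table(true = rec$k_true[ok], estimated = k_hat[ok])
  100 * prop.table(tab, margin = 1)
}

#' Marginal under/correct/over rates of the estimator
#'
#' @inheritParams sim_confusion
#' @param by_k return a per-true-k matrix instead of the marginal rates.
#' @return Named vector `under`, `correct`, `over` in percent (or a matrix
#'   with one row per true k).
#' @export
sim_rates <- function(result, criterion = c("min_p", "aic"), by_k = FALSE) {
  criterion <- match.arg(criterion)
  rec <- result$records
  k_hat <- if (criterion == "min_p") rec$k_minp else rec$k_aic
  ok <- !is.na(k_hat)
  rate <- function(sel) {
    c(under = 100 * mean(k_hat[sel] < rec$k_true[sel]),
      correct = 100 * mean(k_hat[sel] == rec$k_true[sel]),
      over = 100 * mean(k_hat[sel] > rec$k_true[sel]))
  }
  if (!by_k) return(rate(ok))
  t(vapply(sort(unique(rec$k_true)),
           function(k) rate(ok & rec$k_true == k), numeric(3)))
}

#' Compare the two model-selection criteria on shared datasets
#'
#' Both criteria were applied to the identical simulated datasets (one model
#' sweep per iteration), so the comparison is exactly paired.
#'
#' @param result a `sim_study_result`.
#' @return List: `accuracy` (named, percent), `aic_over2_rate` (percent of
#'   k_true = 2 datasets where AIC picks more than two alleles),
#'   `minp_over2_rate`, `n`.
#' @export
compare_criteria <- function(result) {
  rec <- result$records[!is.na(result$records$k_minp), ]
  acc <- c(min_p = 100 * mean(rec$k_minp == rec$k_true),
           aic = 100 * mean(rec$k_aic == rec$k_true))
  two <- rec[rec$k_true == 2L, ]
  list(accuracy = acc,
       aic_over2_rate = if (nrow(two)) 100 * mean(two$k_aic > 2L) else NA,
       minp_over2_rate = if (nrow(two)) 100 * mean(two$k_minp > 2L) else NA,
       n = nrow(rec))
}

#' Check that underestimation worsens with the true allele number
#'
#' @param result a `sim_study_result` (at least 3 true-k values).
#' @param criterion selection criterion to summarize.
#' @return List: `under_by_k` (named percent), `monotone` (TRUE when the
#'   underestimation rate is non-decreasing in true k, allowing one adjacent
#'   inversion).
#' @export
bias_gradient_check <- function(result, criterion = "min_p") {
  rates <- sim_rates(result, criterion, by_k = TRUE)
  ks <- sort(unique(result$records$k_true))
  if (length(ks) < 3L) stop("need at least 3 true allele numbers")
  under <- setNames(rates[, "under"], ks)
  inversions <- sum(diff(under) < 0)
  list(under_by_k = under, monotone = inversions <= 1L)
}
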