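#' Simulate a pool of recombinant inbred line (RIL) mosaic genomes
#'
#' Each RIL genome is a mosaic of the eight panel founders.  Along the scan
#' grid the founder state follows a Markov chain: between adjacent positions
#' separated by `delta` cM the state switches with probability
#' `1 - exp(-breakpoint_rate * delta)`, and on a switch the new founder is
#' drawn uniformly from the other seven.  The default rate of 0.25 per cM
#' reflects the ~25-fold map expansion of a 50-generation free-recombination
#' intercross followed by inbreeding.
#'
#' @param map a [genetic_map()].
#' @param panel a [founder_panel()].
#' @param n_ril number of RILs to simulate.
#' @param breakpoint_rate expected breakpoints per cM (> 0).
#' @param subpop optional character vector of length `n_ril` of replicate
#'   subpopulation labels (e.g. "A1"/"A2"); defaults to an even split.
#' @param rng_seed integer seed.
#' @return An object of class `ril_pool`: integer matrix `founder`
#'   (`n_ril` x grid positions, entries 1..8) plus `map`, `panel`, `subpop`.
#' @export
simulate_ril_pool <- function(map, panel, n_ril, breakpoint_rate = 0.25,
                              subpop = NULL, rng_seed = 1L) {
  stopifnot(inherits(map, "genetic_map"), inherits(panel, "founder_panel"))
  if (nrow(map$grid) == 0L) stop("empty map")
  if (n_ril < 1L) stop("n_ril must be >= 1")
  if (breakpoint_rate <= 0) stop("breakpoint_rate must be > 0")
  if (is.null(subpop)) {
    subpop <- paste0(panel$panel_id, rep_len(1:2, n_ril))
  }
  stopifnot(length(subpop) == n_ril)
  set.seed(rng_seed)
  founder <- matrix(0L, n_ril, nrow(map$grid))
  for (ch in unique(map$grid$chrom)) {
    idx <- chrom_grid_idx(map, ch)
    p_switch <- 1 - exp(-breakpoint_rate * diff(map$grid$pos_cM[idx]))
    cur <- sample.int(8L, n_ril, replace = TRUE)
    founder[, idx[1L]] <- cur
    for (j in seq_along(p_switch)) {
      sw <- runif(n_ril) < p_switch[j]
      if (any(sw)) {
        # uniform over the other 7 founders
        jump <- sample.int(7L, sum(sw), replace = TRUE)
        cur[sw] <- ((cur[sw] - 1L + jump) %% 8L) + 1L
      }
      founder[, idx[j + 1L]] <- cur
    }
  }
  structure(list(founder = founder, map = map, panel = panel,
                 subpop = subpop, breakpoint_rate = breakpoint_rate),
            class = "ril_pool")
}

#' Simulate a single RIL mosaic haplotype
#'
#' Convenience wrapper around [simulate_ril_pool()] for one genome.
#'
#' @inheritParams simulate_ril_pool
#' @return Integer vector of founder indices (1..8) along the grid, with the
#'   map attached as attribute `map`.
#' @export
simulate_ril_mosaic <- function(map, panel, breakpoint_rate = 0.25,
                                rng_seed = 1L) {
  pool <- simulate_ril_pool(map, panel, n_ril = 1L,
                            breakpoint_rate = breakpoint_rate,
                            rng_seed = rng_seed)
  structure(drop(pool$founder), map = map)
}

#' @export
print.ril_pool <- function(x, ...) {
  cat("ril_pool: panel", x$panel$panel_id, "-", nrow(x$founder), "RILs x",
      ncol(x$founder), "grid positions\n")
  invisible(x)
}

#' Attach genotype uncertainty to RIL mosaics
#'
#' Emulates the output of a haplotype-inference HMM: at every position the
#' true founder receives probability mass `certainty` and the remaining
#' `1 - certainty` is spread uniformly over the other seven founders.  The
#' true mosaic is kept alongside so that phenotypes can be generated from
#' true haplotypes while the mapper sees only probabilities.
#'
#' @param pool a `ril_pool`.
#' @param certainty probability mass on the true founder, in `[1/8, 1]`.
#' @return An object of class `hap_probs` wrapping the pool.
#' @export
attach_uncertainty <- function(pool, certainty = 1) {
  stopifnot(inherits(pool, "ril_pool"))
  if (certainty < 1 / 8 || certainty > 1)
    stop("certainty must be in [1/8, 1]")
  structure(list(pool = pool, certainty = certainty), class = "hap_probs")
}

# n x 8 founder probability matrix at one grid position
hap_prob_matrix <- function(hp, pos_index) {
  stopifnot(inherits(hp, "hap_probs"))
  f <- hp$pool$founder[, pos_index]
  n <- length(f)
  off <- (1 - hp$certainty) / 7
  P <- matrix(off, n, 8L)
  P[cbind(seq_len(n), f)] <- hp$certainty
  P
}
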