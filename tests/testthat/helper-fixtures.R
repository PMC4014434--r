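# Shared fixtures, built once per test run and memoized.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# two-chromosome toy map, coarse grid
toy_map <- function(step = 2.5e5) {
  genetic_map(data.frame(chrom = c("c1", "c2"),
                         length_bp = c(25e6, 25e6),
                         length_cM = c(60, 60)), step)
}

# standard mid-size cross set: 300 crosses, certainty 0.98
toy_crosses <- function() {
  fixture("toy_crosses", function() {
    map <- toy_map()
    pA <- attach_uncertainty(
      simulate_ril_pool(map, founder_panel("A"), 300, rng_seed = 101), 0.98)
    pB <- attach_uncertainty(
      simulate_ril_pool(map, founder_panel("B"), 300, rng_seed = 102), 0.98)
    make_crosses(pA, pB)
  })
}

# fully certain genotypes for closed-form checks
toy_crosses_certain <- function() {
  fixture("toy_crosses_certain", function() {
    map <- toy_map()
    pA <- attach_uncertainty(
      simulate_ril_pool(map, founder_panel("A"), 200, rng_seed = 201), 1)
    pB <- attach_uncertainty(
      simulate_ril_pool(map, founder_panel("B"), 200, rng_seed = 202), 1)
    make_crosses(pA, pB)
  })
}

# large cross set for recovery studies (n = 600)
big_crosses <- function() {
  fixture("big_crosses", function() {
    map <- toy_map(step = 1e5)
    pA <- attach_uncertainty(
      simulate_ril_pool(map, founder_panel("A"), 600, rng_seed = 301), 0.98)
    pB <- attach_uncertainty(
      simulate_ril_pool(map, founder_panel("B"), 600, rng_seed = 302), 0.98)
    make_crosses(pA, pB)
  })
}

# hand-built probability-backed cross set (n crosses, one position repeated)
probs_crosses <- function(P, map = NULL) {
  n <- dim(P)[1L]
  if (is.null(map))
    map <- genetic_map(data.frame(chrom = "c1", length_bp = 1e6,
                                  length_cM = 2), 5e5)
  npos <- nrow(map$grid)
  arr <- array(rep(P, npos), c(dim(P), npos),
               dimnames = list(NULL, founder_column_labels(), NULL))
  structure(list(P = arr, map = map, n = n,
                 cross_id = sprintf("cross_%04d", seq_len(n)),
                 S = factor(rep(c("A1xB2", "A2xB1"), length.out = n)),
                 backend = "probs"),
            class = "cross_genotypes")
}

# one-hot 16-column dosage row for maternal founder a, paternal founder b
one_hot_row <- function(a, b) {
  x <- numeric(16)
  x[a] <- 1
  x[8 + b] <- 1
  x
}

chrom_positions <- function(map, ch) which(map$grid$chrom == ch)

# reduced-diversity panel: only founders 1..4 segregate on each side, so
# eight haplotypes are retained at any locus (an "m = 8" toy panel)
toy_crosses_m8 <- function(n_ril = 1200, seed = 61) {
  fixture(paste0("m8_", n_ril, "_", seed), function() {
    map <- toy_map(1e5)
    pA <- simulate_ril_pool(map, founder_panel("A"), n_ril, rng_seed = seed)
    pB <- simulate_ril_pool(map, founder_panel("B"), n_ril,
                            rng_seed = seed + 1)
    pA$founder <- ((pA$founder - 1L) %% 4L) + 1L
    pB$founder <- ((pB$founder - 1L) %% 4L) + 1L
    make_crosses(attach_uncertainty(pA, 1), attach_uncertainty(pB, 1))
  })
}

# brute-force enumeration oracle: every subset of the m-1 cut points,
# keeping partitions whose block count is in k_set (full model included)
brute_force_groupings <- function(m, k_set) {
  ks <- sort(unique(c(k_set[k_set <= m], m)))
  total <- 0L
  for (bits in 0:(2^(m - 1L) - 1L)) {
    k <- sum(bitwAnd(bits, 2^(0:(m - 2L))) > 0) + 1L
    if (k %in% ks) total <- total + 1L
  }
  total
}
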