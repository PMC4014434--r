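#' Haplotypes retained for allele-number estimation at a peak
#'
#' A founder haplotype is retained if it occurs at least `min_count` times at
#' probability greater than `min_prob` among the crosses (maternal
#' occurrences for pA founders, paternal for pB).  Rarer haplotypes give
#' unstable mean estimates and are excluded from the grouping search.
#' Haplotype means come from the minimum-norm least-squares fit of the
#' phenotype on all 16 probability columns, centered within each panel so
#' that the per-panel location indeterminacy does not affect their order.
#'
#' @param y phenotype vector.
#' @param crosses a `cross_genotypes`.
#' @param peak_pos grid index of the peak.
#' @param min_count minimum number of high-confidence occurrences.
#' @param min_prob probability needed to count an occurrence (strict `>`).
#' @return Object of class `retained_haplotypes`: `labels`, `means`,
#'   `counts`, `retained` (logical over the 16 columns), `X` (n x m retained
#'   dosage columns, sorted by mean), `order` (sorted labels), `y`, `n`.
#' @export
retained_haplotypes <- function(y, crosses, peak_pos, min_count = 5,
                                min_prob = 0.95) {
  stopifnot(inherits(crosses, "cross_genotypes"))
  X <- cross_dosage(crosses, peak_pos)
  counts <- colSums(X > min_prob)
  retained <- counts >= min_count
  if (sum(retained) < 2L)
    stop("fewer than 2 haplotypes retained at the peak")
  means <- haplotype_means(y, X)
  ord <- order(means[retained],
               match(names(means[retained]), founder_column_labels()))
  lab_sorted <- colnames(X)[retained][ord]
  structure(list(labels = colnames(X), means = means, counts = counts,
                 retained = retained,
                 X = X[, lab_sorted, drop = FALSE],
                 order = lab_sorted,
                 means_sorted = means[lab_sorted],
                 y = y, n = nrow(X), peak_pos = peak_pos),
            class = "retained_haplotypes")
}

# per-panel-centered minimum-norm haplotype effects from the 16-column fit
haplotype_means <- function(y, X) {
  fit <- MASS::ginv(cbind(1, X)) %*% y
  eff <- drop(fit)[-1]
  names(eff) <- colnames(X)
  pa <- seq_len(8); pb <- 9:16
  eff[pa] <- eff[pa] - mean(eff[pa])
  eff[pb] <- eff[pb] - mean(eff[pb])
  eff
}

#' @export
print.retained_haplotypes <- function(x, ...) {
  cat("retained_haplotypes:", sum(x$retained), "of", length(x$labels),
      "haplotypes retained at grid index", x$peak_pos, "\n")
  invisible(x)
}

# cache of contiguous-composition label matrices, keyed by "m:k"
.composition_cache <- new.env(parent = emptyenv())

# all contiguous assignments of m sorted items into k ordered blocks,
# as an C(m-1, k-1) x m integer label matrix
contiguous_compositions <- function(m, k) {
  key <- paste(m, k, sep = ":")
  hit <- .composition_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (k == 1L) {
    lab <- matrix(1L, 1L, m)
  } else if (k == m) {
    lab <- matrix(seq_len(m), 1L, m, byrow = TRUE)
  } else {
    cuts <- utils::combn(m - 1L, k - 1L)
    lab <- t(apply(cuts, 2L, function(cc) {
      lab_i <- integer(m)
      start <- 1L
      for (b in seq_len(k)) {
        end <- if (b < k) cc[b] else m
        lab_i[start:end] <- b
        start <- end + 1L
      }
      lab_i
    }))
    if (m == 1L) lab <- matrix(lab, ncol = 1L)
  }
  .composition_cache[[key]] <- lab
  lab
}

#' Enumerate ordered allele groupings
#'
#' All partitions of the retained haplotypes, sorted by estimated mean, into
#' `k` contiguous blocks for each `k` in `k_set`, plus the full model in
#' which every retained haplotype is its own allele (AB8 in pA and AB8 in pB
#' counted separately).  For `m` retained haplotypes there are
#' `choose(m-1, k-1)` groupings per `k`.  Blocks may span the two panels:
#' haplotypes from pA and pB may share one effect.  Setting
#' `within_panel_only = TRUE` restricts blocks to single-panel membership.
#'
#' @param retained a [retained_haplotypes()].
#' @param k_set allele numbers to enumerate (values > m are skipped); the
#'   full model (k = m) is always added.
#' @param within_panel_only disallow blocks mixing pA and pB haplotypes.
#' @return Object of class `allele_groupings`: integer label matrix
#'   `labels` (models x m, blocks numbered along the sorted order), vector
#'   `k`, and the sorted haplotype labels.
#' @export
enumerate_groupings <- function(retained, k_set = 2:8,
                                within_panel_only = FALSE) {
  stopifnot(inherits(retained, "retained_haplotypes"))
  m <- length(retained$order)
  ks <- sort(unique(k_set[k_set <= m & k_set >= 1]))
  mats <- lapply(ks, function(k) contiguous_compositions(m, k))
  if (!(m %in% ks)) {
    mats <- c(mats, list(contiguous_compositions(m, m)))
    ks <- c(ks, m)
  }
  labels <- do.call(rbind, mats)
  k <- rep(ks, vapply(mats, nrow, 1L))
  if (within_panel_only) {
    panel <- substr(retained$order, 1, 2)  # "pA" / "pB"
    keep <- vapply(seq_len(nrow(labels)), function(r) {
      !any(tapply(panel, labels[r, ], function(p) length(unique(p))) > 1L)
    }, logical(1))
    labels <- labels[keep, , drop = FALSE]
    k <- k[keep]
  }
  structure(list(labels = labels, k = k, haplotypes = retained$order,
                 m = m), class = "allele_groupings")
}

#' @export
print.allele_groupings <- function(x, ...) {
  cat("allele_groupings:", nrow(x$labels), "models over", x$m,
      "retained haplotypes (k:", paste(sort(unique(x$k)), collapse = ","),
      ")\n")
  invisible(x)
}

#' Allele-group dosages for one grouping
#'
#' The probability a cross carries each allele group: founder haplotype
#' probabilities of the block members are summed within each panel
#' (maternal probabilities for pA members, paternal for pB members).  Under
#' the default `"per_panel"` coding a block containing haplotypes from both
#' panels yields two dosage columns - its pA portion and its pB portion -
#' each receiving its own effect estimate in the grouped model; under
#' `"shared"` the two portions are summed into one column with a single
#' effect.  Summed over all columns, the dosages of a fully retained cross
#' always add to 2.
#'
#' @param grouping integer block labels along the sorted haplotype order
#'   (one row of an `allele_groupings` label matrix).
#' @param retained the [retained_haplotypes()] the grouping refers to.
#' @param effects `"per_panel"` (separate pA/pB effect columns) or
#'   `"shared"` (one column per block).
#' @return Numeric matrix n x (number of effect columns).
#' @export
group_dosages <- function(grouping, retained,
                          effects = c("per_panel", "shared")) {
  effects <- match.arg(effects)
  stopifnot(inherits(retained, "retained_haplotypes"),
            length(grouping) == length(retained$order))
  panel <- if (effects == "shared") rep(1L, length(grouping))
           else ifelse(startsWith(retained$order, "pA_"), 1L, 2L)
  key <- paste(grouping, panel)
  cols <- unique(key)            # first-occurrence order
  D <- vapply(cols, function(kk)
    rowSums(retained$X[, key == kk, drop = FALSE]), numeric(retained$n))
  first <- match(cols, key)
  colnames(D) <- paste0("allele", grouping[first],
                        if (effects == "per_panel")
                          c("_pA", "_pB")[panel[first]] else "")
  D
}

#' Fit one allele grouping
#'
#' Least squares of the phenotype on the block dosages plus intercept (via
#' the shared pseudo-inverse machinery), with the overall F test against the
#' intercept-only null, AIC from the Gaussian log-likelihood with rank-based
#' parameter count, and R^2.
#'
#' @param y phenotype vector.
#' @param dosages block dosage matrix from [group_dosages()].
#' @return List `p`, `aic`, `r2`, `rss`, `rank`, `k`, `df1`, `df2`, `flag`.
#' @export
fit_grouping <- function(y, dosages) {
  n <- length(y)
  X <- cbind(1, dosages)
  G <- crossprod(X)
  xty <- crossprod(X, y)
  flag <- if (any(apply(dosages, 2, var) < 1e-12)) "zero-variance dosage"
          else "none"
  lab <- matrix(seq_len(ncol(dosages)), 1L)
  res <- fit_groupings_gram(G, drop(xty), sum(y^2), lab,
                            rep(1L, ncol(dosages)))
  stats <- grouping_stats(res, sum((y - mean(y))^2), n)
  c(as.list(stats[1L, ]), list(flag = flag))
}

# rss/rank/k matrix -> data.frame of p, aic, r2 etc.; k may be overridden
# (the kernel's k counts effect columns, the caller knows the block count)
grouping_stats <- function(res, rss0, n, k = NULL) {
  rss <- res[, 1L]; rank <- res[, 2L]
  if (is.null(k)) k <- res[, 3L]
  df1 <- pmax(rank - 1, 1)
  df2 <- n - rank
  Fst <- ((rss0 - rss) / df1) / (rss / df2)
  p <- pf(Fst, df1, df2, lower.tail = FALSE)
  # Gaussian log-likelihood AIC; +1 parameter for the error variance
  aic <- n * log(pmax(rss, 1e-300) / n) + 2 * (rank + 1)
  data.frame(k = k, rss = rss, rank = rank, df1 = df1, df2 = df2,
             F = Fst, p = p, aic = aic, r2 = 1 - rss / rss0)
}

#' Estimate the number of functional alleles at a QTL
#'
#' Sweeps every ordered grouping from [enumerate_groupings()] with the shared
#' Gram-matrix least-squares kernel and selects the best model by the chosen
#' criterion: lowest overall-model P value (`"min_p"`) or lowest AIC
#' (`"aic"`).  Criterion ties break toward fewer alleles.  Each block's pA
#' and pB portions receive separate effect estimates by default (the two
#' panels' probabilities are independent); `effects = "shared"` forces one
#' effect per block.
#'
#' @param y phenotype vector.
#' @param retained a [retained_haplotypes()].
#' @param criterion `"min_p"` or `"aic"`.
#' @param k_set allele counts to consider (the full model is always added).
#' @param within_panel_only see [enumerate_groupings()].
#' @param effects see [group_dosages()].
#' @param groupings optionally a precomputed `allele_groupings` (must match
#'   `retained`).
#' @return Object of class `allele_fit`: `k_hat`, `best` (row of `fits`),
#'   `fits` (all models), `criterion`, `groupings`.
#' @export
estimate_allele_number <- function(y, retained, criterion = c("min_p", "aic"),
                                   k_set = 2:8, within_panel_only = FALSE,
                                   effects = c("per_panel", "shared"),
                                   groupings = NULL) {
  criterion <- match.arg(criterion)
  effects <- match.arg(effects)
  stopifnot(inherits(retained, "retained_haplotypes"))
  if (is.null(groupings))
    groupings <- enumerate_groupings(retained, k_set, within_panel_only)
  sw <- sweep_groupings(y, retained, groupings, effects)
  pick <- select_grouping(sw, criterion)
  structure(list(k_hat = sw$k[pick],
                 best = sw[pick, ],
                 best_index = pick,
                 fits = sw,
                 criterion = criterion,
                 groupings = groupings),
            class = "allele_fit")
}

# fit every grouping; returns grouping_stats() data.frame
sweep_groupings <- function(y, retained, groupings,
                            effects = c("per_panel", "shared")) {
  effects <- match.arg(effects)
  X <- cbind(1, retained$X)
  G <- crossprod(X)
  xty <- drop(crossprod(X, y))
  panel <- if (effects == "shared") rep(1L, groupings$m)
           else ifelse(startsWith(retained$order, "pA_"), 1L, 2L)
  res <- fit_groupings_gram(G, xty, sum(y^2), groupings$labels,
                            as.integer(panel))
  grouping_stats(res, sum((y - mean(y))^2), length(y), k = groupings$k)
}

# index of the best model under a criterion, ties toward smaller k
select_grouping <- function(fits, criterion) {
  score <- if (criterion == "min_p") fits$p else fits$aic
  ord <- order(score, fits$k)
  ord[1L]
}

#' @export
print.allele_fit <- function(x, ...) {
  cat("allele_fit: k_hat =", x$k_hat, "by", x$criterion,
      "(best p =", format(x$best$p, digits = 3),
      ", R2 =", round(x$best$r2, 3), ")\n")
  invisible(x)
}

#' Hard-coded founder genotype assignments at a position
#'
#' Each cross is coded as a two-digit label: the most likely maternal pA
#' founder (1-8) followed by the most likely paternal pB founder, each digit
#' replaced by 9 when the highest probability does not exceed `min_prob`.
#' E.g. "24" is an A2/B4 trans-heterozygote; "94" has an uncertain maternal
#' assignment.
#'
#' @param crosses a `cross_genotypes`.
#' @param pos_index grid position.
#' @param min_prob certainty needed for a hard assignment (strict `>`).
#' @return Character vector of two-digit codes, named by cross id.
#' @export
hard_genotype_codes <- function(crosses, pos_index, min_prob = 0.95) {
  X <- cross_dosage(crosses, pos_index)
  code_side <- function(P) {
    best <- max.col(P)
    ifelse(P[cbind(seq_len(nrow(P)), best)] > min_prob, best, 9L)
  }
  a <- code_side(X[, 1:8, drop = FALSE])
  b <- code_side(X[, 9:16, drop = FALSE])
  setNames(paste0(a, b), crosses$cross_id)
}

#' Added variance of the best model over the best two-allele model
#'
#' @param fit an `allele_fit` (its `fits` table must include k = 2 models).
#' @return Percentage points of phenotypic variance:
#'   `100 * (R2_best - R2_best_two_allele)`; 0 when a two-allele model is
#'   best, `NA` if no two-allele model was fitted.
#' @export
extra_variance_vs_two_allele <- function(fit) {
  stopifnot(inherits(fit, "allele_fit"))
  two <- fit$fits[fit$fits$k == 2L, , drop = FALSE]
  if (nrow(two) == 0L) return(NA_real_)
  best2 <- two[select_grouping(two, fit$criterion), ]
  100 * (fit$best$r2 - best2$r2)
}
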