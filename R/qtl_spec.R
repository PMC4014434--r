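#' Specify a simulated QTL
#'
#' A QTL is placed at a map position and assigns each founder genome to one
#' of `k` functional alleles with an additive effect.  By default the shared
#' founder AB8 carries the same allele in both panels (15 distinct founder
#' genomes); pass `AB8_B` explicitly in `allele_map` to split it.
#'
#' @param chrom chromosome name.
#' @param pos_cM genetic position.
#' @param allele_map named integer vector founder label -> allele index.
#'   Names must cover `A1..A7`, `B1..B7` and `AB8` (or `AB8_A`/`AB8_B`).
#' @param allele_effects numeric vector, effect of each allele index.
#' @param z fraction of phenotypic variance explained by the QTL, in (0, 1).
#' @return An object of class `qtl_spec`.
#' @export
qtl_spec <- function(chrom, pos_cM, allele_map, allele_effects, z) {
  if (!(z > 0 && z < 1)) stop("z must be in (0, 1)")
  am <- allele_map
  if ("AB8" %in% names(am) && !all(c("AB8_A", "AB8_B") %in% names(am))) {
    am <- c(am, AB8_A = unname(am[["AB8"]]), AB8_B = unname(am[["AB8"]]))
    am <- am[names(am) != "AB8"]
  }
  need <- c(paste0("A", 1:7), paste0("B", 1:7), "AB8_A", "AB8_B")
  if (!all(need %in% names(am)))
    stop("allele_map must assign every founder; missing: ",
         paste(setdiff(need, names(am)), collapse = ", "))
  am <- am[need]
  if (any(!am %in% seq_along(allele_effects)))
    stop("allele_map refers to alleles without effects")
  structure(list(chrom = chrom, pos_cM = pos_cM, allele_map = am,
                 allele_effects = allele_effects,
                 k = length(unique(am)), z = z),
            class = "qtl_spec")
}

# per-founder effect in dosage-column order (16 columns)
qtl_column_effects <- function(qtl) {
  lab <- c(paste0("A", 1:7), "AB8_A", paste0("B", 1:7), "AB8_B")
  qtl$allele_effects[qtl$allele_map[lab]]
}

#' Draw a random QTL specification
#'
#' Assigns `k` alleles with effects `1..k` uniformly at random to the 15
#' founder genomes (AB8 shared, every allele represented), using the current
#' RNG stream.
#'
#' @inheritParams qtl_spec
#' @param k number of alleles.
#' @return A [qtl_spec()].
#' @export
random_qtl_spec <- function(chrom, pos_cM, k, z) {
  qtl_spec(chrom, pos_cM, draw_allele_map(k), seq_len(k), z)
}

#' Simulate a phenotype from a planted QTL
#'
#' The genetic value of a cross is the sum of the allele effects of its two
#' true haplotypes at the QTL (pure additivity).  Environmental noise is
#' normal with variance `sigma_g^2 * (1 - z) / z`, where `sigma_g^2` is the
#' empirical variance of the genetic values, so the QTL explains a fraction
#' `z` of the phenotypic variance in expectation.  Phenotypes are generated
#' from the true mosaic haplotypes; genotype uncertainty affects only what
#' the mapper sees.
#'
#' @param crosses a `cross_genotypes`.
#' @param qtl a [qtl_spec()].
#' @param rng_seed integer seed for the noise draw.
#' @return Numeric phenotype vector with attribute `truth` (genetic values,
#'   grid index, sigma_g2).
#' @export
simulate_phenotype <- function(crosses, qtl, rng_seed = 1L) {
  stopifnot(inherits(crosses, "cross_genotypes"), inherits(qtl, "qtl_spec"))
  pos <- find_grid_index(crosses$map, qtl$chrom, qtl$pos_cM)
  hap <- true_haplotypes(crosses, pos)
  effA <- qtl$allele_effects[qtl$allele_map[c(paste0("A", 1:7), "AB8_A")]]
  effB <- qtl$allele_effects[qtl$allele_map[c(paste0("B", 1:7), "AB8_B")]]
  g <- effA[hap[, "mat"]] + effB[hap[, "pat"]]
  sigma_g2 <- var(g)
  if (sigma_g2 < .Machine$double.eps)
    stop("degenerate QTL: no genetic variance among crosses")
  set.seed(rng_seed)
  e <- rnorm(length(g), 0, sqrt(sigma_g2 * (1 - qtl$z) / qtl$z))
  y <- as.numeric(g + e)
  attr(y, "truth") <- list(g = g, pos_index = pos, sigma_g2 = sigma_g2,
                           z = qtl$z)
  y
}
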