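#' Cross pA RILs to pB RILs
#'
#' F1 trans-heterozygote crosses between a maternal panel-A RIL and a paternal
#' panel-B RIL.  Pairing follows the line-number convention: RIL i of pA is
#' crossed to RIL i of pB, respecting the replicate subpopulation structure
#' (A1 x B2 and A2 x B1).  Each cross carries its maternal pA and paternal pB
#' founder-probability vectors unchanged.
#'
#' @param pA,pB `hap_probs` objects (see [attach_uncertainty()]) for the two
#'   panels, same map, equal RIL counts.
#' @param ril_idx_A,ril_idx_B optional integer vectors selecting (and
#'   ordering) the RILs used from each pool; defaults to all.
#' @return An object of class `cross_genotypes` with `n` crosses, cross IDs,
#'   a subpopulation factor `S`, and accessors over grid positions.
#' @export
make_crosses <- function(pA, pB, ril_idx_A = NULL, ril_idx_B = NULL) {
  stopifnot(inherits(pA, "hap_probs"), inherits(pB, "hap_probs"))
  if (pA$pool$panel$panel_id != "A" || pB$pool$panel$panel_id != "B")
    stop("make_crosses expects a panel-A pool and a panel-B pool")
  if (!identical(pA$pool$map$grid$pos_bp, pB$pool$map$grid$pos_bp))
    stop("the two pools must share one genetic map")
  if (is.null(ril_idx_A) && is.null(ril_idx_B)) {
    # line-number pairing respecting the subpopulation rule:
    # A1 females to B2 males, A2 females to B1 males
    a1 <- which(pA$pool$subpop == "A1"); a2 <- which(pA$pool$subpop == "A2")
    b2 <- which(pB$pool$subpop == "B2"); b1 <- which(pB$pool$subpop == "B1")
    n1 <- min(length(a1), length(b2)); n2 <- min(length(a2), length(b1))
    ril_idx_A <- c(a1[seq_len(n1)], a2[seq_len(n2)])
    ril_idx_B <- c(b2[seq_len(n1)], b1[seq_len(n2)])
  }
  if (is.null(ril_idx_A)) ril_idx_A <- seq_len(nrow(pA$pool$founder))
  if (is.null(ril_idx_B)) ril_idx_B <- seq_len(nrow(pB$pool$founder))
  nA <- length(ril_idx_A); nB <- length(ril_idx_B)
  if (nA == 0L || nB == 0L) stop("no RILs to cross")
  if (nA != nB) stop("equal numbers of pA and pB RILs are required")
  subA <- pA$pool$subpop[ril_idx_A]
  subB <- pB$pool$subpop[ril_idx_B]
  S <- paste0(subA, "x", subB)
  ok <- S %in% c("A1xB2", "A2xB1")
  if (!all(ok))
    stop("crosses must pair subpopulations A1xB2 or A2xB1; offending: ",
         paste(unique(S[!ok]), collapse = ", "))
  structure(list(pA = pA, pB = pB,
                 idx_A = ril_idx_A, idx_B = ril_idx_B,
                 n = nA,
                 cross_id = sprintf("cross_%04d", seq_len(nA)),
                 S = factor(S),
                 map = pA$pool$map,
                 backend = "mosaic"),
            class = "cross_genotypes")
}

#' @export
print.cross_genotypes <- function(x, ...) {
  cat("cross_genotypes:", x$n, "pA x pB crosses on",
      nrow(x$map$grid), "grid positions\n")
  invisible(x)
}

#' Founder dosage matrix of all crosses at one grid position
#'
#' Returns the 16 regressors of the scan model: the maternal probability
#' vector over the eight pA founders followed by the paternal vector over the
#' eight pB founders.  Each half sums to 1 per cross.
#'
#' @param crosses a `cross_genotypes`.
#' @param pos_index grid position index.
#' @return Numeric matrix `n x 16` with columns `pA_A1..pA_AB8, pB_B1..pB_AB8`.
#' @export
cross_dosage <- function(crosses, pos_index) {
  stopifnot(inherits(crosses, "cross_genotypes"), length(pos_index) == 1L)
  if (identical(crosses$backend, "probs"))
    return(crosses$P[, , pos_index])
  A <- hap_prob_matrix(crosses$pA, pos_index)[crosses$idx_A, , drop = FALSE]
  B <- hap_prob_matrix(crosses$pB, pos_index)[crosses$idx_B, , drop = FALSE]
  X <- cbind(A, B)
  colnames(X) <- founder_column_labels()
  X
}

# true (mosaic) maternal/paternal founder indices at one position
true_haplotypes <- function(crosses, pos_index) {
  if (identical(crosses$backend, "probs"))
    stop("true haplotypes are unavailable for probability-backed crosses")
  cbind(mat = crosses$pA$pool$founder[crosses$idx_A, pos_index],
        pat = crosses$pB$pool$founder[crosses$idx_B, pos_index])
}
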