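#' Derive a stream of independent sub-seeds from a master seed
#'
#' One master seed fans out to per-task seeds via a counter so that modules
#' (panel generation, per-iteration simulation, permutations) are
#' independently reproducible.  Seeds stay within the 32-bit integer range.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @export
fan_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
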