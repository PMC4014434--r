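#' Build a genetic map with a regular physical scan grid
#'
#' A map holds a chromosome table (physical and genetic lengths) and an ordered
#' grid of scan positions carrying both coordinates.  The cM position of a grid
#' point is obtained by linear interpolation of the chromosome-wide
#' recombination rate, so the cM/bp relation is monotone within each
#' chromosome.
#'
#' @param chromosomes data.frame with columns `chrom`, `length_bp`, `length_cM`.
#' @param grid_step_bp spacing of scan-grid positions in base pairs.
#' @return An object of class `genetic_map` with elements `chromosomes` and
#'   `grid` (data.frame `chrom`, `pos_bp`, `pos_cM`, `index`).
#' @examples
#' map <- genetic_map(data.frame(chrom = "2L", length_bp = 2e6, length_cM = 5),
#'                    grid_step_bp = 1e5)
#' nrow(map$grid)
#' @export
genetic_map <- function(chromosomes, grid_step_bp = 1e4) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length_bp", "length_cM") %in% names(chromosomes)))
  if (nrow(chromosomes) == 0L) stop("empty chromosome table")
  if (any(chromosomes$length_bp <= 0) || any(chromosomes$length_cM <= 0))
    stop("chromosome lengths must be positive")
  chromosomes$chrom <- as.character(chromosomes$chrom)
  grid <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
    ch <- chromosomes[i, ]
    pos_bp <- seq(grid_step_bp, ch$length_bp, by = grid_step_bp)
    data.frame(chrom = ch$chrom,
               pos_bp = pos_bp,
               pos_cM = pos_bp / ch$length_bp * ch$length_cM,
               stringsAsFactors = FALSE)
  }))
  grid$index <- seq_len(nrow(grid))
  structure(list(chromosomes = chromosomes, grid = grid,
                 grid_step_bp = grid_step_bp),
            class = "genetic_map")
}

#' Default synthetic genome emulating a five-arm fly genome
#'
#' Five chromosome arms totalling ~118.8 Mb and ~281 cM, the scale of the
#' euchromatic genome interrogated by the scan grid.
#'
#' @inheritParams genetic_map
#' @return A `genetic_map`.
#' @export
dspr_map <- function(grid_step_bp = 1e5) {
  genetic_map(data.frame(
    chrom = c("X", "2L", "2R", "3L", "3R"),
    length_bp = c(22.4e6, 23.0e6, 21.1e6, 24.4e6, 27.9e6),
    length_cM = c(66, 55, 52, 47, 61)), grid_step_bp)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$grid), "grid positions (step", x$grid_step_bp, "bp)\n")
  invisible(x)
}

# grid indices of one chromosome
chrom_grid_idx <- function(map, chrom) {
  which(map$grid$chrom == chrom)
}

#' Nearest scan-grid index to a genetic position
#' @param map a `genetic_map`.
#' @param chrom chromosome name.
#' @param pos_cM genetic position.
#' @return Integer grid index.
#' @export
find_grid_index <- function(map, chrom, pos_cM) {
  idx <- chrom_grid_idx(map, chrom)
  if (length(idx) == 0L) stop("unknown chromosome: ", chrom)
  idx[which.min(abs(map$grid$pos_cM[idx] - pos_cM))]
}

# thin the grid to approximately a fixed cM step (at least one position kept
# per chromosome); used by the kinship computation
resample_grid_idx <- function(map, step_cM) {
  unlist(lapply(unique(map$grid$chrom), function(ch) {
    idx <- chrom_grid_idx(map, ch)
    cm <- map$grid$pos_cM[idx]
    keep <- !duplicated(floor(cm / step_cM))
    idx[keep]
  }), use.names = FALSE)
}

# cM distance between adjacent grid points, per chromosome list
grid_cm_deltas <- function(map, chrom) {
  cm <- map$grid$pos_cM[chrom_grid_idx(map, chrom)]
  diff(c(0, cm))
}
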