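#' Extreme-mean block search on an en-face map
#'
#' Exhaustive sliding-window search (stride one map cell) for the contiguous
#' square block of a given area whose mean is extreme (largest or smallest)
#' among all blocks having at least `min_valid_frac` valid (non-`NA`) cells.
#' Ties are broken by first occurrence in row-major order. This implements
#' the "best 1 mm^2 area" selection used to localize the most fibrotic
#' region of a sample (highest retardance / lowest entropy).
#'
#' @param map Numeric matrix (`NA` = invalid cell).
#' @param pitch_um Length-2 (or scalar) cell pitch in um.
#' @param block_um Block side length in um (default 1000, i.e. 1 mm^2).
#' @param mode `"max"` or `"min"`.
#' @param min_valid_frac Minimum fraction of valid cells per block
#'   (default 0.8).
#' @return List with `row`, `col` (top-left cell), `side` (cells per side),
#'   `mean`, `mode`, `n_valid`.
#' @export
best_block <- function(map, pitch_um, block_um = 1000,
                       mode = c("max", "min"), min_valid_frac = 0.8) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(map), all(pitch_um > 0))
  if (length(pitch_um) == 1) pitch_um <- rep(pitch_um, 2)
  sr <- round(block_um / pitch_um[1])
  sc <- round(block_um / pitch_um[2])
  if (sr < 1 || sc < 1) stop("block smaller than one map cell")
  if (sr > nrow(map) || sc > ncol(map))
    stop("map is smaller than the requested block")
  ok <- is.finite(map)
  m0 <- ifelse(ok, map, 0)
  # integral images for O(1) block sums
  csum <- function(m) {
    m <- apply(m, 2, cumsum)
    t(apply(m, 1, cumsum))
  }
  Sm <- rbind(0, cbind(0, csum(m0)))
  Sv <- rbind(0, cbind(0, csum(ok * 1)))
  rows <- seq_len(nrow(map) - sr + 1L)
  cols <- seq_len(ncol(map) - sc + 1L)
  blk <- function(S, i, j) S[cbind(i + sr, j + sc)] - S[cbind(i, j + sc)] -
    S[cbind(i + sr, j)] + S[cbind(i, j)]
  sums <- outer(rows, cols, function(i, j) blk(Sm, i, j))
  nval <- outer(rows, cols, function(i, j) blk(Sv, i, j))
  means <- sums / nval
  means[nval < min_valid_frac * sr * sc] <- NA_real_
  if (all(is.na(means))) stop("no block meets the validity fraction")
  ext <- if (mode == "max") max(means, na.rm = TRUE)
         else min(means, na.rm = TRUE)
  hit <- which(means == ext, arr.ind = TRUE)
  # first occurrence in row-major order
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  list(row = unname(hit[1]), col = unname(hit[2]), side = c(sr, sc),
       mean = ext, mode = mode,
       n_valid = nval[hit[1], hit[2]])
}
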