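#' Build a genome analysis grid of non-overlapping intervals
#'
#' Tiles each chromosome with half-open, 0-based `[start, end)` intervals of a
#' fixed physical size (1 Mb by default). All recombination rates produced by
#' the package are expressed per grid interval. Only the last interval of a
#' chromosome may be shorter than `interval_size`.
#'
#' @param chrom_lengths Data frame with columns `chrom` (character) and
#'   `length` (base pairs, positive).
#' @param interval_size Interval width in base pairs (default 1e6).
#'
#' @return A tibble of class `genome_grid` with columns `chrom`, `start`,
#'   `end`, `interval` (a genome-wide 1-based interval index) and an attribute
#'   `chrom_lengths` holding the input table.
#' @examples
#' grid <- genome_grid(data.frame(chrom = "1", length = 5e6))
#' grid
#' @export
genome_grid <- function(chrom_lengths, interval_size = 1e6) {
  chrom_lengths <- tibble::as_tibble(chrom_lengths)
  stopifnot(all(c("chrom", "length") %in% names(chrom_lengths)))
  if (any(chrom_lengths$length <= 0)) {
    stop("all chromosome lengths must be > 0", call. = FALSE)
  }
  if (anyDuplicated(chrom_lengths$chrom) > 0) {
    stop("duplicated chromosome ids", call. = FALSE)
  }
  if (interval_size <= 0) stop("interval_size must be > 0", call. = FALSE)
  grid <- purrr::pmap_dfr(chrom_lengths, function(chrom, length, ...) {
    starts <- seq(0, length - 1, by = interval_size)
    tibble::tibble(
      chrom = as.character(chrom),
      start = starts,
      end = pmin(starts + interval_size, length)
    )
  })
  grid$interval <- seq_len(nrow(grid))
  structure(grid,
    chrom_lengths = chrom_lengths,
    interval_size = interval_size,
    class = c("genome_grid", class(tibble::tibble()))
  )
}

#' Chromosome lengths of a grid
#' @param grid A [genome_grid()].
#' @return Tibble with `chrom`, `length`.
#' @export
chrom_lengths <- function(grid) {
  attr(grid, "chrom_lengths")
}

#' Locate positions on a grid
#'
#' Maps base-pair positions to the genome-wide interval index of the grid
#' interval containing them.
#'
#' @param grid A [genome_grid()].
#' @param chrom Character vector of chromosome ids.
#' @param pos Numeric vector of base-pair positions (0-based).
#' @return Integer vector of `interval` indices (NA when off-grid).
#' @export
grid_locate <- function(grid, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    g <- grid[grid$chrom == ch, ]
    if (nrow(g) == 0) next
    sel <- which(chrom == ch)
    idx <- findInterval(pos[sel], g$start)
    ok <- idx >= 1 & pos[sel] < max(g$end)
    out[sel[ok]] <- g$interval[idx[ok]]
  }
  out
}

interval_len_mb <- function(grid) (grid$end - grid$start) / 1e6
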