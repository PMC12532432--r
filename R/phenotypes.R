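#' Genome-wide recombination rate of a meiosis
#'
#' The autosomal crossover count divided by the informative genome length in
#' Mb, scaled by 100 to cM/Mb so it is comparable across meioses with
#' different informativity.
#'
#' @param acc Autosomal crossover count (non-negative).
#' @param informative_mb Informative genome length in Mb (> 0).
#' @return GRR in cM/Mb, vectorised.
#' @export
grr <- function(acc, informative_mb) {
  stopifnot(all(acc >= 0))
  if (any(informative_mb <= 0)) {
    stop("informative length must be > 0 (exclude uninformative meioses)",
      call. = FALSE)
  }
  100 * acc / informative_mb
}

#' Intra-chromosomal shuffling statistic
#'
#' The probability that two loci drawn at random on the autosomal genome land
#' on the same chromosome and uncouple (inherit from different grandparents)
#' in a given meiosis: `sum over chromosomes of 2 p (1 - p) L^2`, where `p`
#' is the proportion of markers inherited from one grandparent and `L` the
#' chromosome's proportion of the autosomal genome. Symmetric in `p` vs
#' `1 - p`, so the grandparental labelling polarity is irrelevant; bounded by
#' `0.5 * sum(L^2)`.
#'
#' @param p Per-chromosome proportions in `[0, 1]`.
#' @param L Per-chromosome genome proportions (must sum to 1).
#' @return The shuffling probability (scalar).
#' @export
r_intra <- function(p, L) {
  stopifnot(length(p) == length(L), all(p >= 0 & p <= 1), all(L >= 0))
  if (abs(sum(L) - 1) > 1e-6) {
    stop("chromosome proportions L must sum to 1", call. = FALSE)
  }
  sum(2 * p * (1 - p) * L^2)
}

#' Per-meiosis recombination phenotypes
#'
#' Computes, for every meiosis of a crossover scan, the autosomal crossover
#' count (ACC), the informative genome length, the genome-wide recombination
#' rate (GRR) and the intra-chromosomal shuffling statistic. The grandparental
#' proportion `p` of each chromosome is computed over informative markers
#' (origin is unobservable elsewhere); chromosomes with no informative marker
#' contribute `p = 0`. Chromosome weights use physical bp proportions by
#' default, or informative-marker-count proportions with
#' `weights = "snp"`.
#'
#' @param scan A `crossover_set` with filtered events.
#' @param grid A [genome_grid()] providing chromosome lengths.
#' @param weights `"physical"` (default) or `"snp"`.
#' @return Tibble of class `meiosis_phenotypes`: `meiosis`, `parent`,
#'   `parent_sex`, `acc`, `informative_mb`, `grr`, `r_intra`. Meioses with
#'   zero informative length are dropped with a warning.
#' @export
meiosis_phenotypes <- function(scan, grid, weights = c("physical", "snp")) {
  weights <- match.arg(weights)
  cl <- chrom_lengths(grid)
  acc <- table(factor(scan$events$meiosis,
    levels = scan$meioses$meiosis))
  ci <- scan$chrom_info
  info <- ci |>
    dplyr::group_by(.data$meiosis) |>
    dplyr::summarise(
      informative_mb = sum((.data$mask_end - .data$mask_start) / 1e6,
        na.rm = TRUE),
      .groups = "drop"
    )
  shuf <- ci |>
    dplyr::group_by(.data$meiosis) |>
    dplyr::summarise(r_intra = {
      p <- ifelse(.data$n_informative > 0,
        .data$n_origin1 / .data$n_informative, 0)
      L <- if (weights == "physical") {
        len <- cl$length[match(.data$chrom, cl$chrom)]
        len / sum(len)
      } else {
        if (sum(.data$n_informative) == 0) rep(NA_real_, length(p)) else {
          .data$n_informative / sum(.data$n_informative)
        }
      }
      sum(2 * p * (1 - p) * L^2)
    }, .groups = "drop")
  out <- scan$meioses |>
    dplyr::select("meiosis", "parent", "parent_sex") |>
    dplyr::mutate(acc = as.integer(acc[.data$meiosis])) |>
    dplyr::left_join(info, by = "meiosis") |>
    dplyr::left_join(shuf, by = "meiosis")
  bad <- is.na(out$informative_mb) | out$informative_mb <= 0
  if (any(bad)) {
    warning(sprintf("%d meioses with zero informative length excluded",
      sum(bad)), call. = FALSE)
    out <- out[!bad, ]
  }
  out$grr <- grr(out$acc, out$informative_mb)
  structure(
    dplyr::select(out, "meiosis", "parent", "parent_sex", "acc",
      "informative_mb", "grr", "r_intra"),
    class = c("meiosis_phenotypes", class(tibble::tibble()))
  )
}

#' @export
glance.meiosis_phenotypes <- function(x, ...) {
  tibble::tibble(
    n_meioses = nrow(x),
    mean_acc = mean(x$acc),
    mean_grr = mean(x$grr),
    mean_r_intra = mean(x$r_intra),
    cor_grr_r_intra = stats::cor(x$grr, x$r_intra)
  )
}
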