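#' Longest increasing subsequence
#'
#' Returns the indices of one maximal strictly increasing subsequence of a
#' vector of distinct values. Among all subsequences of maximal length, the one
#' whose value sequence is lexicographically smallest is returned, which makes
#' the result deterministic.
#'
#' Used for marker-order quality control: markers ordered by assembly position
#' whose ranks on an independent physical map do not belong to the LIS are
#' inconsistently ordered between the two maps.
#'
#' @param ranks Numeric vector of distinct values.
#' @return Integer vector of indices, strictly increasing, with
#'   `ranks[result]` strictly increasing and of maximal length.
#' @examples
#' longest_increasing_subsequence(c(3, 1, 2, 5, 4))
#' @export
longest_increasing_subsequence <- function(ranks) {
  n <- length(ranks)
  if (n == 0) return(integer(0))
  if (anyDuplicated(ranks) > 0) {
    stop("ranks must be distinct", call. = FALSE)
  }
  v <- rank(ranks) # distinct integers, order-isomorphic to input
  # len_from[i]: length of the longest strictly increasing run starting at i.
  # Patience sorting on the reversed, negated sequence.
  w <- rev(-v)
  tails <- numeric(0)
  len_from <- integer(n)
  for (j in seq_len(n)) {
    pos <- findInterval(w[j] - 0.5, tails) + 1L
    tails[pos] <- w[j]
    len_from[n - j + 1L] <- pos
  }
  L <- max(len_from)
  # Greedy reconstruction, smallest value first. Within a len_from class,
  # values are strictly decreasing with position, so the smallest admissible
  # value is the last candidate passing both the position and value bounds.
  out <- integer(L)
  classes <- split(seq_len(n), len_from)
  prev_idx <- 0L
  prev_val <- -Inf
  for (l in seq(L, 1)) {
    cand <- classes[[as.character(l)]]
    cand <- cand[cand > prev_idx & v[cand] > prev_val]
    pick <- cand[length(cand)]
    out[L - l + 1L] <- pick
    prev_idx <- pick
    prev_val <- v[pick]
  }
  out
}

#' Project SNP positions onto an independent physical map
#'
#' Assigns each marker a position on an external map (e.g. a radiation hybrid
#' map) by linear interpolation between the two flanking external markers in
#' assembly coordinates. Markers outside the external span of their chromosome
#' cannot be projected and receive the terminal flag; their assembly order is
#' taken at face value downstream.
#'
#' @param markers Tibble with `marker`, `chrom`, `pos` (assembly bp).
#' @param externals Tibble with `chrom`, `pos` (assembly bp), `rh_pos`
#'   (external map units), sorted by `pos` within chromosome.
#' @return `markers` with added `rh_pos` (NA where terminal) and `terminal`
#'   (logical) columns.
#' @export
project_onto_rh <- function(markers, externals) {
  markers <- tibble::as_tibble(markers)
  out <- markers |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(mk, key) {
      ext <- externals[externals$chrom == key$chrom, ]
      ext <- ext[order(ext$pos), ]
      if (nrow(ext) < 2) {
        warning(sprintf(
          "chromosome %s has < 2 external markers; all markers flagged terminal",
          key$chrom), call. = FALSE)
        mk$rh_pos <- NA_real_
      } else {
        mk$rh_pos <- stats::approx(ext$pos, ext$rh_pos, xout = mk$pos,
          rule = 1, ties = "ordered")$y
      }
      mk$terminal <- is.na(mk$rh_pos)
      mk
    }) |>
    dplyr::ungroup()
  out[match(markers$marker, out$marker), c(names(markers), "rh_pos", "terminal")]
}

#' Keep markers consistently ordered on both physical maps
#'
#' Per chromosome, markers are sorted by assembly position and the longest
#' increasing subsequence of their external-map order is kept; projected
#' markers outside the LIS are removed (reason `order_inconsistent`).
#' Terminal markers (no external projection) are always kept.
#'
#' @param markers Output of [project_onto_rh()].
#' @return List with `markers` (kept rows) and `report` (tibble `item`,
#'   `type`, `reason`).
#' @export
consistent_marker_set <- function(markers) {
  drop <- character(0)
  for (ch in unique(markers$chrom)) {
    mk <- markers[markers$chrom == ch & !markers$terminal, ]
    if (nrow(mk) < 2) next
    mk <- mk[order(mk$pos), ]
    keep <- longest_increasing_subsequence(mk$rh_pos)
    drop <- c(drop, mk$marker[-keep])
  }
  list(
    markers = markers[!markers$marker %in% drop, ],
    report = tibble::tibble(item = drop, type = "marker",
      reason = "order_inconsistent")
  )
}

panel_subset <- function(panel, marker_keep = NULL, sample_keep = NULL) {
  mi <- if (is.null(marker_keep)) seq_len(nrow(panel$markers)) else marker_keep
  si <- if (is.null(sample_keep)) seq_len(nrow(panel$samples)) else sample_keep
  panel$markers <- panel$markers[mi, ]
  panel$samples <- panel$samples[si, ]
  panel$hap_pat <- panel$hap_pat[mi, si, drop = FALSE]
  panel$hap_mat <- panel$hap_mat[mi, si, drop = FALSE]
  panel$missing <- panel$missing[mi, si, drop = FALSE]
  panel
}

#' Call-rate and monomorphism genotype filters
#'
#' Applies, in this fixed order: (1) removal of markers with call rate below
#' `marker_call_rate_min`; (2) removal of samples with call rate below
#' `sample_call_rate_min` over the remaining markers; (3) removal of markers
#' monomorphic among the remaining samples. No minor-allele-frequency filter is
#' applied: even rare alleles are informative for crossover detection in
#' families segregating for them.
#'
#' @param panel A `genotype_panel`.
#' @param marker_call_rate_min,sample_call_rate_min Minimum call rates
#'   (default 0.99 each).
#' @return List with `panel` (filtered) and `report` (tibble `item`, `type`,
#'   `reason`). An empty panel after filtering is returned as such (zero-row
#'   markers/samples), not an error.
#' @export
basic_genotype_filters <- function(panel, marker_call_rate_min = 0.99,
                                   sample_call_rate_min = 0.99) {
  stopifnot(nrow(panel$markers) > 0, nrow(panel$samples) > 0)
  d <- panel_dosage(panel)
  rep1 <- tibble::tibble(
    item = panel$markers$marker[rowMeans(!is.na(d)) < marker_call_rate_min],
    type = "marker", reason = "low_call_rate"
  )
  keep_m <- which(!panel$markers$marker %in% rep1$item)
  d <- d[keep_m, , drop = FALSE]
  rep2 <- tibble::tibble(
    item = panel$samples$id[colMeans(!is.na(d)) < sample_call_rate_min],
    type = "sample", reason = "low_call_rate"
  )
  keep_s <- which(!panel$samples$id %in% rep2$item)
  d <- d[, keep_s, drop = FALSE]
  freq <- rowMeans(d, na.rm = TRUE) / 2
  mono <- is.nan(freq) | freq == 0 | freq == 1
  rep3 <- tibble::tibble(
    item = panel$markers$marker[keep_m][mono],
    type = "marker", reason = "monomorphic"
  )
  out <- panel_subset(panel, keep_m[!mono], keep_s)
  list(panel = out, report = dplyr::bind_rows(rep1, rep2, rep3))
}

# Chi-square (1 df, no continuity correction) or exact p-value for departure
# from Hardy-Weinberg genotype proportions given counts of the three classes.
hwe_p <- function(n0, n1, n2, exact = FALSE) {
  n <- n0 + n1 + n2
  if (n == 0) return(NA_real_)
  if (sum(c(n0, n1, n2) > 0) < 2) return(NA_real_) # cannot depart
  if (!exact) {
    p <- (2 * n0 + n1) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((c(n0, n1, n2) - e)^2 / e)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  # exact test: sum of probabilities of heterozygote counts no more likely
  # than the observed one, conditional on the allele counts
  na_ <- 2 * n0 + n1
  nb_ <- 2 * n2 + n1
  h_vals <- seq(na_ %% 2, min(na_, nb_), by = 2)
  logp <- lgamma(n + 1) - lgamma((na_ - h_vals) / 2 + 1) -
    lgamma(h_vals + 1) - lgamma((nb_ - h_vals) / 2 + 1) +
    h_vals * log(2) + lgamma(na_ + 1) + lgamma(nb_ + 1) -
    lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n1, h_vals)] * (1 + 1e-12)])
}

#' Hardy-Weinberg equilibrium filter
#'
#' Tests each marker for departure from Hardy-Weinberg genotype proportions
#' and removes markers with p below `p_threshold`. Offspring of sires with
#' more than `big_sire_offspring` genotyped offspring are excluded from the
#' genotype counts, since a sire carrying a rare allele in a large half-sib
#' family distorts the test. When a `population` factor is supplied the test
#' is computed within each population and a marker failing in any population
#' is removed. Markers with fewer than two observed genotype classes cannot
#' depart from equilibrium and are retained.
#'
#' @param panel A `genotype_panel`.
#' @param pedigree Pedigree tibble linking panel samples.
#' @param p_threshold Removal threshold (default 1e-7).
#' @param big_sire_offspring Offspring count above which a sire's family is
#'   excluded from the test (default 50).
#' @param population Optional character vector of population labels, named by
#'   sample id.
#' @param exact Use the exact test instead of the 1-df chi-square
#'   (default FALSE).
#' @return List with `panel` and `report` (reason `hwe_fail`).
#' @export
hwe_filter <- function(panel, pedigree, p_threshold = 1e-7,
                       big_sire_offspring = 50, population = NULL,
                       exact = FALSE) {
  ids <- panel$samples$id
  off <- pedigree[!is.na(pedigree$sire) & pedigree$id %in% ids, ]
  n_off <- table(off$sire)
  big <- names(n_off)[n_off > big_sire_offspring]
  excluded <- off$id[off$sire %in% big]
  use <- !(ids %in% excluded)
  pop <- if (is.null(population)) rep("all", length(ids)) else {
    unname(population[ids])
  }
  d <- panel_dosage(panel)
  fail <- rep(FALSE, nrow(d))
  for (pp in unique(pop)) {
    dd <- d[, use & pop == pp, drop = FALSE]
    n0 <- rowSums(dd == 0, na.rm = TRUE)
    n1 <- rowSums(dd == 1, na.rm = TRUE)
    n2 <- rowSums(dd == 2, na.rm = TRUE)
    p <- vapply(seq_along(n0), function(i) hwe_p(n0[i], n1[i], n2[i], exact),
      numeric(1))
    fail <- fail | (!is.na(p) & p < p_threshold)
  }
  list(
    panel = panel_subset(panel, which(!fail)),
    report = tibble::tibble(item = panel$markers$marker[fail],
      type = "marker", reason = "hwe_fail")
  )
}

#' Count Mendelian incompatibilities per parent-offspring pair
#'
#' A marker is incompatible when parent and offspring are opposite
#' homozygotes. Markers missing in either member are excluded from the
#' denominator. Pairs whose incompatibility rate exceeds `rate_threshold` are
#' flagged for pedigree-link review (no automatic correction is attempted).
#'
#' @param panel A `genotype_panel`.
#' @param pedigree Pedigree tibble.
#' @param rate_threshold Flagging threshold on the incompatibility rate
#'   (default 0.01).
#' @return Tibble with `parent`, `offspring`, `relation` (sire/dam),
#'   `n_markers`, `n_incompatible`, `rate`, `flagged`.
#' @export
mendel_check <- function(panel, pedigree, rate_threshold = 0.01) {
  d <- panel_dosage(panel)
  ids <- panel$samples$id
  pairs <- pedigree_meioses(pedigree)
  pairs <- pairs[pairs$parent %in% ids & pairs$offspring %in% ids, ]
  res <- purrr::pmap_dfr(pairs, function(meiosis, parent, offspring,
                                         parent_sex) {
    dp <- d[, parent]
    do_ <- d[, offspring]
    ok <- !is.na(dp) & !is.na(do_)
    inc <- sum((dp == 0 & do_ == 2) | (dp == 2 & do_ == 0), na.rm = TRUE)
    tibble::tibble(
      parent = parent, offspring = offspring,
      relation = ifelse(parent_sex == "M", "sire", "dam"),
      n_markers = sum(ok), n_incompatible = inc,
      rate = ifelse(sum(ok) > 0, inc / sum(ok), NA_real_)
    )
  })
  res$flagged <- !is.na(res$rate) & res$rate > rate_threshold
  res
}

#' Flag regions of extreme recombination rate
#'
#' Screens interval maximum-likelihood rates for runs exceeding a fold
#' threshold over the genome-wide median; adjacent flagged intervals merge
#' into regions. Such regions typically betray assembly errors rather than
#' genuine hotspots; removal of the markers they contain is left to the user.
#'
#' @param rates Tibble with `chrom`, `start`, `end`, `rate` (cM/Mb), one row
#'   per grid interval, in genome order.
#' @param fold_threshold Fold over the genome-wide median (default 10).
#' @param markers Optional marker tibble (`marker`, `chrom`, `pos`); when
#'   given, markers inside flagged regions are listed.
#' @return List with `regions` (tibble `chrom`, `start`, `end`,
#'   `n_intervals`, `max_rate`) and `markers` (character vector).
#' @export
flag_excess_recombination <- function(rates, fold_threshold = 10,
                                      markers = NULL) {
  med <- stats::median(rates$rate, na.rm = TRUE)
  hot <- !is.na(rates$rate) & rates$rate > fold_threshold * med & rates$rate > 0
  if (!any(hot)) {
    return(list(
      regions = tibble::tibble(chrom = character(0), start = numeric(0),
        end = numeric(0), n_intervals = integer(0), max_rate = numeric(0)),
      markers = character(0)
    ))
  }
  run <- cumsum(c(TRUE, diff(hot) != 0 |
    rates$chrom[-1] != rates$chrom[-nrow(rates)]))
  regions <- rates[hot, ] |>
    dplyr::mutate(run = run[hot]) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom), start = min(.data$start),
      end = max(.data$end), n_intervals = dplyr::n(),
      max_rate = max(.data$rate), .groups = "drop"
    ) |>
    dplyr::select(-"run")
  flagged_markers <- character(0)
  if (!is.null(markers) && nrow(regions) > 0) {
    for (k in seq_len(nrow(regions))) {
      inside <- markers$chrom == regions$chrom[k] &
        markers$pos >= regions$start[k] & markers$pos < regions$end[k]
      flagged_markers <- c(flagged_markers, markers$marker[inside])
    }
  }
  list(regions = regions, markers = unique(flagged_markers))
}
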