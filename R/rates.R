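# Interval x meiosis sufficient-statistic matrices.
# L[i, m]: informative length (Mb) of grid interval i in meiosis m, the
# overlap of the interval with the meiosis' informativity mask.
# Y[i, m]: crossover count assigned to interval i, either wholly to the
# interval containing the detection-interval midpoint, or split across
# intervals proportionally to overlap ("fractional", the deterministic
# expected assignment under uniform placement).
obs_matrices <- function(scan, grid,
                         assignment = c("fractional", "midpoint")) {
  assignment <- match.arg(assignment)
  mei <- scan$meioses
  n_m <- nrow(mei)
  n_i <- nrow(grid)
  m_of <- stats::setNames(seq_len(n_m), mei$meiosis)
  L <- matrix(0, n_i, n_m)
  ci <- scan$chrom_info[!is.na(scan$chrom_info$mask_start), ]
  for (r in seq_len(nrow(ci))) {
    g <- which(grid$chrom == ci$chrom[r] &
      grid$start < ci$mask_end[r] & grid$end > ci$mask_start[r])
    L[g, m_of[[ci$meiosis[r]]]] <-
      (pmin(grid$end[g], ci$mask_end[r]) -
       pmax(grid$start[g], ci$mask_start[r])) / 1e6
  }
  Y <- matrix(0, n_i, n_m)
  ev <- scan$events
  if (nrow(ev) > 0) {
    mcol <- m_of[ev$meiosis]
    i_left <- grid_locate(grid, ev$chrom, ev$left)
    i_right <- grid_locate(grid, ev$chrom, pmax(ev$left, ev$right - 1e-9))
    if (anyNA(i_left) || anyNA(i_right)) {
      stop("crossover event outside the genome grid", call. = FALSE)
    }
    if (assignment == "midpoint") {
      mid <- grid_locate(grid, ev$chrom, (ev$left + ev$right) / 2)
      for (k in seq_along(mid)) Y[mid[k], mcol[k]] <- Y[mid[k], mcol[k]] + 1
    } else {
      simple <- i_left == i_right
      for (k in which(simple)) {
        Y[i_left[k], mcol[k]] <- Y[i_left[k], mcol[k]] + 1
      }
      for (k in which(!simple)) {
        ii <- i_left[k]:i_right[k]
        w <- pmin(grid$end[ii], ev$right[k]) - pmax(grid$start[ii], ev$left[k])
        Y[ii, mcol[k]] <- Y[ii, mcol[k]] + w / sum(w)
      }
    }
  }
  list(Y = Y, L = L, meioses = mei)
}

#' Assemble per-meiosis, per-interval crossover observations
#'
#' Builds the sufficient statistics of the Gamma-Poisson model: for every
#' meiosis and grid interval, the informative length `l` (Mb, the overlap of
#' the interval with the meiosis' informativity mask) and the crossover count
#' `y` assigned to the interval. Under `"midpoint"` assignment each event
#' counts wholly in the interval containing its detection-interval midpoint;
#' under `"fractional"` (the deterministic default) it is split across
#' intervals proportionally to overlap.
#'
#' @param scan A `crossover_set` (events already filtered as desired).
#' @param grid A [genome_grid()].
#' @param assignment `"fractional"` or `"midpoint"`.
#' @return Tibble with `meiosis`, `interval`, `y`, `l`; rows with `l = 0` and
#'   `y = 0` are omitted.
#' @export
assemble_observations <- function(scan, grid,
                                  assignment = c("fractional", "midpoint")) {
  m <- obs_matrices(scan, grid, assignment)
  keep <- which(m$L > 0 | m$Y > 0, arr.ind = TRUE)
  tibble::tibble(
    meiosis = m$meioses$meiosis[keep[, 2]],
    interval = grid$interval[keep[, 1]],
    y = m$Y[keep],
    l = m$L[keep]
  ) |> dplyr::arrange(.data$interval, .data$meiosis)
}

#' Per-interval maximum-likelihood recombination rates
#'
#' The Poisson MLE of the rate in interval `i` is
#' `sum(y) / (0.01 * sum(l))` cM/Mb over all meioses; it is undefined
#' (returned NA) where no informative length was observed.
#'
#' @param observations Output of [assemble_observations()].
#' @param grid Optional [genome_grid()]; when given, all grid intervals are
#'   reported (missing ones with zero totals).
#' @return Tibble with `interval`, `sum_y`, `sum_l` (Mb), `rate` (cM/Mb).
#' @export
mle_rates <- function(observations, grid = NULL) {
  out <- observations |>
    dplyr::group_by(.data$interval) |>
    dplyr::summarise(sum_y = sum(.data$y), sum_l = sum(.data$l),
      .groups = "drop")
  if (!is.null(grid)) {
    out <- dplyr::left_join(tibble::tibble(interval = grid$interval), out,
      by = "interval") |>
      dplyr::mutate(sum_y = dplyr::coalesce(.data$sum_y, 0),
                    sum_l = dplyr::coalesce(.data$sum_l, 0))
  }
  out$rate <- ifelse(out$sum_l > 0, out$sum_y / (0.01 * out$sum_l), NA_real_)
  out
}

#' Fit the empirical-Bayes gamma prior on recombination rates
#'
#' Fits a gamma distribution (shape `alpha`, rate `beta`, in cM/Mb) by maximum
#' likelihood to the genome-wide distribution of interval MLE rates. Only
#' strictly positive, finite MLEs from well-observed intervals contribute:
#' when the input carries `sum_l`, intervals with less than `l_fraction` of
#' the maximum total informative length are excluded, which stabilises the
#' fit against intervals seen in few meioses.
#'
#' @param mles Either the tibble returned by [mle_rates()] or a bare numeric
#'   vector of rates.
#' @param l_fraction Minimum `sum_l` as a fraction of the maximum (default
#'   0.5); ignored for bare vectors.
#' @param min_n Minimum number of usable MLEs (default 30).
#' @return Object of class `gamma_prior`: list with `alpha`, `beta`, their
#'   standard errors, `n`, and `loglik`.
#' @export
fit_gamma_prior <- function(mles, l_fraction = 0.5, min_n = 30) {
  x <- if (is.data.frame(mles)) {
    ok <- mles$sum_l >= l_fraction * max(mles$sum_l)
    mles$rate[ok]
  } else {
    as.numeric(mles)
  }
  x <- x[is.finite(x) & x > 0]
  if (length(x) < min_n) {
    stop(sprintf("need at least %d positive finite MLEs, got %d", min_n,
      length(x)), call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate input: rates have zero variance", call. = FALSE)
  }
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(x, "gamma")),
    error = function(e) stop("gamma prior fit failed: ", conditionMessage(e),
      call. = FALSE)
  )
  structure(
    list(alpha = unname(fit$estimate["shape"]),
         beta = unname(fit$estimate["rate"]),
         se_alpha = unname(fit$sd["shape"]),
         se_beta = unname(fit$sd["rate"]),
         n = length(x), loglik = fit$loglik),
    class = "gamma_prior"
  )
}

#' Construct a gamma prior from known parameters
#' @param alpha,beta Shape and rate (> 0).
#' @return A `gamma_prior`.
#' @export
gamma_prior <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta, se_alpha = NA_real_,
    se_beta = NA_real_, n = NA_integer_, loglik = NA_real_),
    class = "gamma_prior")
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat(sprintf("<gamma_prior> alpha = %.3f, beta = %.3f (mean %.3f cM/Mb)\n",
    x$alpha, x$beta, x$alpha / x$beta))
  invisible(x)
}

#' @export
tidy.gamma_prior <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    std.error = c(x$se_alpha, x$se_beta)
  )
}

#' @export
glance.gamma_prior <- function(x, ...) {
  tibble::tibble(mean = x$alpha / x$beta, nobs = x$n, logLik = x$loglik)
}

#' Conjugate posterior of interval recombination rates
#'
#' Given the gamma prior and the interval totals, the posterior of the rate
#' is Gamma(alpha + sum(y), beta + 0.01 * sum(l)) in closed form; the mean,
#' variance and a central credible interval are reported.
#'
#' @param prior A `gamma_prior`.
#' @param sum_y,sum_l Numeric vectors of per-interval crossover totals and
#'   informative lengths (Mb); recycled against each other.
#' @param interval Optional interval ids to carry through.
#' @param level Credible level (default 0.99).
#' @return Tibble with `interval`, `shape`, `rate_param`, `mean`, `var`,
#'   `lower`, `upper` (all rates in cM/Mb).
#' @export
posterior_rate <- function(prior, sum_y, sum_l, interval = NULL,
                           level = 0.99) {
  shape <- prior$alpha + sum_y
  rate <- prior$beta + 0.01 * sum_l
  a <- (1 - level) / 2
  tibble::tibble(
    interval = interval %||% seq_along(shape),
    shape = shape, rate_param = rate,
    mean = shape / rate, var = shape / rate^2,
    lower = stats::qgamma(a, shape, rate),
    upper = stats::qgamma(1 - a, shape, rate)
  )
}

#' Chromosome-wide recombination rate
#'
#' Posterior-mean rate of each chromosome from observations aggregated over
#' all of its intervals: `(alpha + sum(y)) / (beta + 0.01 * sum(l))`. The
#' 0.01 factor keeps the units (cM/Mb against Mb) consistent with the
#' interval-level posterior.
#'
#' @param prior A `gamma_prior`.
#' @param observations Output of [assemble_observations()].
#' @param grid A [genome_grid()] (maps intervals to chromosomes).
#' @return Tibble with `chrom`, `sum_y`, `sum_l`, `rate` (cM/Mb).
#' @export
chromosome_rate <- function(prior, observations, grid) {
  observations |>
    dplyr::mutate(chrom = grid$chrom[match(.data$interval, grid$interval)]) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(sum_y = sum(.data$y), sum_l = sum(.data$l),
      .groups = "drop") |>
    dplyr::mutate(
      rate = (prior$alpha + .data$sum_y) / (prior$beta + 0.01 * .data$sum_l)
    )
}

# Central credible interval of an equal-weight mixture of gamma posteriors,
# by root-finding on the mixture CDF.
mixture_ci <- function(shapes, rate, level = 0.99) {
  a <- (1 - level) / 2
  f <- function(x, p) mean(stats::pgamma(x, shapes, rate)) - p
  hi <- stats::qgamma(1 - a / 2, max(shapes), rate)
  c(
    stats::uniroot(f, c(0, hi), p = a, tol = 1e-8)$root,
    stats::uniroot(f, c(0, hi), p = 1 - a, tol = 1e-8)$root
  )
}

#' Monte-Carlo recombination-rate estimates under placement uncertainty
#'
#' Crossovers are only localised to detection intervals. For each of `K`
#' replicates, every event's position is drawn uniformly in its detection
#' interval and assigned to the containing grid interval; the conjugate
#' posterior is computed per replicate, and the reported estimate is the mean
#' of the `K` posterior means. The combined variance follows the
#' total-variance decomposition: the mean within-replicate posterior variance
#' plus the between-replicate variance of the posterior means (the
#' between-replicate component is also reported separately). Credible bounds
#' come from the equal-weight mixture of the `K` gamma posteriors.
#'
#' @param prior A `gamma_prior`.
#' @param scan A `crossover_set` (filtered events).
#' @param grid A [genome_grid()].
#' @param K Number of placement replicates (default 100, >= 2).
#' @param seed Integer seed for the placement draws (required, logged in the
#'   result's attributes).
#' @param level Credible level (default 0.99).
#' @return A tibble of class `recomb_map`: per interval `chrom`, `start`,
#'   `end`, `sum_l` (Mb), `mean` (cM/Mb), `var_within`, `var_between`,
#'   `var`, `lower`, `upper`.
#' @export
mc_rate_estimate <- function(prior, scan, grid, K = 100, seed, level = 0.99) {
  stopifnot(K >= 2)
  set.seed(seed)
  m <- obs_matrices(scan, grid, "midpoint") # only L is used from here
  sum_l <- rowSums(m$L)
  rate <- prior$beta + 0.01 * sum_l
  ev <- scan$events
  n_i <- nrow(grid)
  Yk <- matrix(0, n_i, K)
  if (nrow(ev) > 0) {
    for (k in seq_len(K)) {
      pos <- stats::runif(nrow(ev), ev$left, ev$right)
      idx <- grid_locate(grid, ev$chrom, pos)
      Yk[, k] <- tabulate(idx, nbins = n_i)
    }
  }
  shapes <- prior$alpha + Yk
  b <- shapes / rate
  est <- rowMeans(b)
  var_within <- rowMeans(shapes) / rate^2
  var_between <- apply(b, 1, stats::var)
  ci <- t(vapply(seq_len(n_i), function(i) {
    if (stats::var(shapes[i, ]) == 0) {
      a <- (1 - level) / 2
      stats::qgamma(c(a, 1 - a), shapes[i, 1], rate[i])
    } else {
      mixture_ci(shapes[i, ], rate[i], level)
    }
  }, numeric(2)))
  out <- tibble::tibble(
    interval = grid$interval, chrom = grid$chrom, start = grid$start,
    end = grid$end, sum_l = sum_l, mean = est,
    var_within = var_within, var_between = var_between,
    var = var_within + var_between, lower = ci[, 1], upper = ci[, 2]
  )
  structure(out, K = K, seed = seed, prior = prior,
    class = c("recomb_map", class(tibble::tibble())))
}

subset_scan <- function(scan, meiosis_ids) {
  scan$meioses <- scan$meioses[scan$meioses$meiosis %in% meiosis_ids, ]
  scan$events <- scan$events[scan$events$meiosis %in% meiosis_ids, ]
  scan$chrom_info <- scan$chrom_info[
    scan$chrom_info$meiosis %in% meiosis_ids, ]
  scan
}

#' Build sex-specific recombination maps
#'
#' End-to-end map construction: fits the empirical-Bayes gamma prior on the
#' pooled (both-sex) interval MLE rates with fractional crossover assignment,
#' then runs the Monte-Carlo placement machinery separately within each sex.
#'
#' @param scan A `crossover_set` with filtered events.
#' @param grid A [genome_grid()].
#' @param K Monte-Carlo placement replicates (default 100).
#' @param seed Integer seed.
#' @param prior Optional `gamma_prior`; fitted from the data when NULL.
#' @param level Credible level (default 0.99).
#' @return A `recomb_map` tibble with a `sex` column (attribute `prior` holds
#'   the prior used).
#' @export
build_recomb_map <- function(scan, grid, K = 100, seed = 1, prior = NULL,
                             level = 0.99) {
  if (is.null(prior)) {
    obs <- assemble_observations(scan, grid, "fractional")
    prior <- fit_gamma_prior(mle_rates(obs, grid))
  }
  sexes <- sort(unique(scan$meioses$parent_sex))
  maps <- purrr::map_dfr(sexes, function(s) {
    sub <- subset_scan(scan, scan$meioses$meiosis[scan$meioses$parent_sex == s])
    m <- mc_rate_estimate(prior, sub, grid, K = K,
      seed = seed + match(s, sexes), level = level)
    m$sex <- s
    m
  })
  structure(maps, prior = prior, K = K, seed = seed,
    class = c("recomb_map", class(tibble::tibble())))
}

#' Total genetic map length of an estimated map
#' @param map A `recomb_map` (with or without a `sex` column).
#' @return Tibble with `sex` (if present) and `morgans`.
#' @export
map_length <- function(map) {
  g <- if ("sex" %in% names(map)) dplyr::group_by(map, .data$sex) else map
  dplyr::summarise(g,
    morgans = sum(.data$mean * (.data$end - .data$start) / 1e6) / 100,
    .groups = "drop")
}

#' Recombination landscape relative to the centromere
#'
#' Maps every interval to its relative position along the chromosome
#' (0 = centromeric tip, 1 = telomeric tip; all chromosomes are treated as
#' acrocentric with the centromere at coordinate 0) and averages rates within
#' equal-width relative-position bins, weighted by informative length.
#'
#' @param estimates A `recomb_map` (per-sex rows supported via the `sex`
#'   column).
#' @param grid The [genome_grid()] used.
#' @param n_bins Number of relative-position bins (default 50).
#' @return Tibble of class `centromere_profile`: `sex` (when present),
#'   `bin`, `rel_pos` (bin midpoint), `rate`, `n_intervals`.
#' @export
centromere_landscape <- function(estimates, grid, n_bins = 50) {
  cl <- chrom_lengths(grid)
  x <- tibble::as_tibble(estimates)
  x$rel <- ((x$start + x$end) / 2) / cl$length[match(x$chrom, cl$chrom)]
  x$bin <- pmin(floor(x$rel * n_bins) + 1L, n_bins)
  if (!"sex" %in% names(x)) x$sex <- NA_character_
  out <- x |>
    dplyr::group_by(.data$sex, .data$bin) |>
    dplyr::summarise(
      rel_pos = (dplyr::first(.data$bin) - 0.5) / n_bins,
      rate = stats::weighted.mean(.data$mean, .data$sum_l + 1e-12),
      n_intervals = dplyr::n(), .groups = "drop"
    )
  structure(out, class = c("centromere_profile", class(tibble::tibble())))
}

#' Regression of chromosome rate on log chromosome size
#'
#' Ordinary least squares of the chromosome-wide recombination rate on the
#' natural log of physical chromosome size, with additive indicator effects
#' for `sex` and `breed` when those columns are present. Small chromosomes
#' recombining more than large ones shows up as a negative log-size slope.
#'
#' @param chrom_rates Tibble with columns `rate` (cM/Mb), `size` (bp), and
#'   optionally `sex` and/or `breed`.
#' @return An `lm` fit (coefficients `log(size)` etc.).
#' @export
chromosome_size_model <- function(chrom_rates) {
  if (length(unique(chrom_rates$size)) < 3) {
    stop("need at least 3 chromosomes", call. = FALSE)
  }
  terms <- "log(size)"
  for (v in c("sex", "breed")) {
    if (v %in% names(chrom_rates) && length(unique(chrom_rates[[v]])) > 1) {
      terms <- c(terms, v)
    }
  }
  stats::lm(stats::reformulate(terms, response = "rate"),
    data = chrom_rates)
}
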