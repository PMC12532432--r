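#' Log2 male/female rate ratio
#'
#' The per-interval heterochiasmy statistic: positive when males recombine
#' more, one unit per two-fold difference.
#'
#' @param c_male,c_female Rates in cM/Mb (> 0; posterior means from a gamma
#'   prior are always positive).
#' @return `log2(c_male) - log2(c_female)`, vectorised.
#' @export
d_statistic <- function(c_male, c_female) {
  stopifnot(all(c_male > 0), all(c_female > 0))
  log2(c_male) - log2(c_female)
}

# Posterior-mean rates per interval for a given male-parent indicator over
# meioses, from the fixed sufficient-statistic matrices. Columns of z are
# alternative male assignments; totals are fixed, so female sums are
# complements.
d_from_assignment <- function(Y, L, z, prior) {
  tot_y <- rowSums(Y)
  tot_l <- rowSums(L)
  ym <- Y %*% z
  lm_ <- L %*% z
  cm <- (prior$alpha + ym) / (prior$beta + 0.01 * lm_)
  cf <- (prior$alpha + (tot_y - ym)) / (prior$beta + 0.01 * (tot_l - lm_))
  log2(cm) - log2(cf)
}

#' Permutation null for sex differences in local recombination
#'
#' Permutes the sex labels over meioses (each meiosis keeps its crossovers
#' and informativity mask), so every permutation has exactly the observed
#' number of male and female meioses and the informativity imbalance between
#' the sexes is preserved under the null. The deterministic
#' fractional-assignment Bayesian rate estimates are recomputed for both
#' label groups in each permutation and the log2 ratio recorded per interval;
#' the observed statistic is computed with the identical estimator, so
#' observed and null values are exchangeable when the sexes share one map.
#'
#' @param scan A `crossover_set` with filtered events.
#' @param grid A [genome_grid()].
#' @param prior A `gamma_prior`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `d_obs` (numeric per interval), `d_null` (matrix
#'   intervals x `n_perm`), and `intervals` (the grid rows).
#' @export
permutation_null <- function(scan, grid, prior, n_perm = 1000, seed = 1) {
  mei <- scan$meioses
  if (length(unique(mei$parent_sex)) < 2) {
    stop("cannot permute two groups: all parents have the same sex",
      call. = FALSE)
  }
  set.seed(seed)
  m <- obs_matrices(scan, grid, "fractional")
  z_obs <- as.numeric(mei$parent_sex == "M")
  zp <- vapply(seq_len(n_perm), function(k) sample(z_obs),
    numeric(length(z_obs)))
  d_obs <- drop(d_from_assignment(m$Y, m$L, z_obs, prior))
  d_null <- d_from_assignment(m$Y, m$L, zp, prior)
  list(d_obs = d_obs, d_null = d_null,
    intervals = tibble::as_tibble(grid))
}

#' Normal-approximation p-values from a permutation null
#'
#' The permutation distribution of the log-ratio statistic is close to normal
#' in each interval, so a two-sided tail probability under
#' Normal(null mean, null sd) is reported; the raw empirical permutation
#' p-value is emitted alongside as a diagnostic.
#'
#' @param d_observed Numeric vector of observed statistics.
#' @param null_samples Matrix (intervals x permutations) of null statistics.
#' @return Tibble with `null_mean`, `null_sd`, `p` (normal approximation) and
#'   `p_perm` (empirical).
#' @export
interval_pvalues <- function(d_observed, null_samples) {
  stopifnot(length(d_observed) == nrow(null_samples))
  mu <- rowMeans(null_samples)
  sd_ <- apply(null_samples, 1, stats::sd)
  n_perm <- ncol(null_samples)
  p_perm <- (1 + rowSums(abs(null_samples - mu) >=
    abs(d_observed - mu) - 1e-12)) / (n_perm + 1)
  # a degenerate null (all permutations identical) can only arise when the
  # observed statistic is the same value; report p = 1 there
  z <- ifelse(sd_ > 0, (d_observed - mu) / sd_, 0)
  p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  tibble::tibble(null_mean = mu, null_sd = sd_, p = p, p_perm = p_perm)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05 to 0.95 (step
#' 0.05) with a cubic smoothing spline evaluated at the largest lambda,
#' clipped to (0, 1], then applies the step-up so q is monotone
#' non-decreasing in p. With fewer than 100 p-values pi0 falls back to 1
#' (Benjamini-Hochberg behaviour).
#'
#' @param pvals Numeric vector of p-values.
#' @return Numeric vector of q-values, same order as `pvals`.
#' @export
qvalues <- function(pvals) {
  stopifnot(length(pvals) >= 1, all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  m <- length(pvals)
  if (m < 100) {
    pi0 <- 1
  } else {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  ord <- order(pvals, decreasing = TRUE)
  q <- numeric(m)
  q[ord] <- cummin(pi0 * m * pvals[ord] / rank(pvals)[ord])
  pmin(q, 1)
}

#' Test for heterochiasmy in local recombination rates
#'
#' Full sex-difference scan: the observed log2 male/female rate ratio per
#' interval, its permutation null preserving the informativity imbalance
#' between the sexes, a
#' normal-approximation p-value, and Storey q-values with a significance call
#' at `fdr`.
#'
#' @param scan A `crossover_set` with filtered events.
#' @param grid A [genome_grid()].
#' @param prior A `gamma_prior` (fitted on the pooled data when NULL).
#' @param n_perm Permutations (default 1000).
#' @param seed Integer seed.
#' @param fdr Significance threshold on q (default 0.05).
#' @return Tibble of class `heterochiasmy_result`: `interval`, `chrom`,
#'   `start`, `end`, `d`, `null_mean`, `null_sd`, `p`, `p_perm`, `q`,
#'   `significant`, `direction` (`"male_biased"` / `"female_biased"`).
#' @export
heterochiasmy_test <- function(scan, grid, prior = NULL, n_perm = 1000,
                               seed = 1, fdr = 0.05) {
  if (is.null(prior)) {
    obs <- assemble_observations(scan, grid, "fractional")
    prior <- fit_gamma_prior(mle_rates(obs, grid))
  }
  null <- permutation_null(scan, grid, prior, n_perm = n_perm, seed = seed)
  pv <- interval_pvalues(null$d_obs, null$d_null)
  out <- dplyr::bind_cols(
    null$intervals[, c("interval", "chrom", "start", "end")],
    tibble::tibble(d = null$d_obs), pv
  )
  out$q <- qvalues(out$p)
  out$significant <- out$q < fdr
  out$direction <- ifelse(out$d >= out$null_mean, "male_biased",
    "female_biased")
  structure(out, prior = prior, n_perm = n_perm, fdr = fdr,
    class = c("heterochiasmy_result", class(tibble::tibble())))
}

#' @export
glance.heterochiasmy_result <- function(x, ...) {
  tibble::tibble(
    n_intervals = nrow(x),
    n_significant = sum(x$significant),
    n_male_biased = sum(x$significant & x$direction == "male_biased"),
    n_female_biased = sum(x$significant & x$direction == "female_biased"),
    fdr = attr(x, "fdr"), n_perm = attr(x, "n_perm")
  )
}
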