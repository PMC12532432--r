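test_that("observation assembly computes informative lengths and splits counts", {
  grid <- small_grid(1, 5e6)
  ci <- tibble::tibble(meiosis = "m", chrom = "1", n_informative = 10L,
    n_origin1 = 5L, mask_start = 0, mask_end = 5e6)
  ev <- tibble::tibble(meiosis = "m", chrom = "1", left = 1.5e6,
    right = 2.5e6) # straddles intervals 2 and 3 half-and-half
  mei <- tibble::tibble(meiosis = "m", parent = "p", offspring = "o",
    parent_sex = "M")
  scan <- structure(list(meioses = mei, events = ev, chrom_info = ci),
    grid = grid, class = "crossover_set")
  obs <- assemble_observations(scan, grid, "fractional")
  expect_equal(obs$l, rep(1, 5)) # full informativity: 1 Mb everywhere
  expect_equal(obs$y[obs$interval %in% 2:3], c(0.5, 0.5))
  expect_equal(sum(obs$y), 1)
  mid <- assemble_observations(scan, grid, "midpoint")
  # the detection-interval midpoint (2.0 Mb) falls in [2, 3) Mb = interval 3
  expect_equal(mid$y[mid$interval == 3], 1)
  expect_equal(sum(mid$y), 1)
})

test_that("total assigned counts equal retained events in both modes", {
  grid <- small_grid(2, 2e7)
  ped <- simulate_pedigree(2, 6, 6, 2, 1, seed = 51)
  maps <- simulate_true_maps(grid, 3, 3, end_fold = 2)
  sc <- truth_scan(ped, maps, grid, seed = 52)
  # widen detection intervals artificially so fractional splitting happens
  set.seed(53)
  w <- runif(nrow(sc$events), 0, 3e6)
  sc$events$left <- pmax(0, sc$events$left - w)
  sc$events$right <- pmin(2e7 - 1, sc$events$right + w)
  for (mode in c("fractional", "midpoint")) {
    obs <- assemble_observations(sc, grid, mode)
    per_mei <- tapply(obs$y, obs$meiosis, sum)
    n_ev <- table(sc$events$meiosis)
    expect_equal(as.numeric(per_mei[names(n_ev)]), as.numeric(n_ev),
      tolerance = 1e-10)
  }
})

test_that("interval MLE agrees with numerical likelihood maximisation", {
  obs <- tibble::tibble(meiosis = c("a", "b", "a", "b"),
    interval = c(1L, 1L, 2L, 2L), y = c(1, 1, 0, 0), l = c(50, 50, 30, 0))
  ml <- mle_rates(obs)
  expect_equal(ml$rate[1], 2 / (0.01 * 100)) # 2 crossovers over 100 Mb
  expect_equal(ml$rate[2], 0)
  # numerical oracle: maximise the Poisson log likelihood in one dimension
  nll <- function(c) -sum(stats::dpois(c(1, 1), 0.01 * c * 50, log = TRUE))
  opt <- stats::optimize(nll, c(0.01, 50))
  expect_equal(ml$rate[1], opt$minimum, tolerance = 1e-4)
  # undefined when nothing informative
  obs0 <- tibble::tibble(meiosis = "a", interval = 3L, y = 0, l = 0)
  expect_true(is.na(mle_rates(obs0)$rate))
})

test_that("gamma prior fit recovers known parameters and rejects degenerate input", {
  set.seed(501)
  x <- stats::rgamma(1e5, shape = 3.0, rate = 2.3)
  fit <- fit_gamma_prior(x)
  expect_gt(fit$alpha, 2.9); expect_lt(fit$alpha, 3.1)
  expect_gt(fit$beta, 2.2); expect_lt(fit$beta, 2.4)
  expect_error(fit_gamma_prior(rep(1.5, 100)), "zero variance")
  expect_error(fit_gamma_prior(stats::rgamma(10, 3, 2)), "at least 30")
  # the published goat prior has mean about 1.30 cM/Mb
  prior <- gamma_prior(3.02, 2.32)
  expect_equal(prior$alpha / prior$beta, 1.3017, tolerance = 1e-4)
  # well-observed-interval restriction drops sparse intervals
  set.seed(505)
  tbl <- tibble::tibble(interval = 1:100,
    sum_y = c(stats::rpois(60, 300), rep(1, 40)),
    sum_l = c(rep(100, 60), rep(1, 40)))
  tbl$rate <- tbl$sum_y / (0.01 * tbl$sum_l)
  fit2 <- fit_gamma_prior(tbl)
  expect_equal(fit2$n, 60)
})

test_that("conjugate posterior matches closed form and quadrature", {
  prior <- gamma_prior(3.02, 2.32)
  # no data: posterior equals prior
  p0 <- posterior_rate(prior, 0, 0)
  expect_equal(p0$mean, 3.02 / 2.32)
  expect_equal(p0$var, 3.02 / 2.32^2)
  # arithmetic example: 5 crossovers over 300 Mb
  p1 <- posterior_rate(prior, 5, 300)
  expect_equal(p1$shape, 8.02)
  expect_equal(p1$rate_param, 5.32)
  expect_equal(p1$mean, 8.02 / 5.32, tolerance = 1e-12)
  set.seed(502)
  for (k in 1:10) {
    a <- runif(1, 0.5, 5); b <- runif(1, 0.5, 5)
    sy <- sample(0:10, 1); sl <- runif(1, 0, 400)
    post <- posterior_rate(gamma_prior(a, b), sy, sl)
    quad <- posterior_quadrature(a, b, sy, sl)
    expect_equal(post$mean, unname(quad["mean"]), tolerance = 1e-7)
    expect_equal(post$var, unname(quad["var"]), tolerance = 1e-7)
  }
})

test_that("chromosome rate is the posterior of aggregated observations", {
  prior <- gamma_prior(3.02, 2.32)
  grid <- small_grid(1, 5e6)
  obs <- tibble::tibble(meiosis = rep(c("a", "b"), each = 5),
    interval = rep(1:5, 2), y = c(2, 1, 0, 0, 0, 1, 0, 1, 0, 0),
    l = rep(1, 10))
  cr <- chromosome_rate(prior, obs, grid)
  expect_equal(cr$rate, (3.02 + 5) / (2.32 + 0.1))
  expect_equal(cr$rate,
    posterior_rate(prior, sum(obs$y), sum(obs$l))$mean)
  # headline arithmetic: 120 crossovers over 10,000 informative Mb
  expect_equal((3.02 + 120) / (2.32 + 0.01 * 10000), 1.2023, tolerance = 1e-4)
  # no data: prior mean
  obs0 <- tibble::tibble(meiosis = "a", interval = 1L, y = 0, l = 0)
  expect_equal(chromosome_rate(prior, obs0, grid)$rate, 3.02 / 2.32)
})

test_that("posterior mean shrinks between prior mean and MLE, monotonically in counts", {
  prior <- gamma_prior(3, 2)
  set.seed(503)
  for (k in 1:20) {
    sy <- sample(1:30, 1); sl <- runif(1, 20, 400)
    mle <- sy / (0.01 * sl)
    post <- posterior_rate(prior, sy, sl)$mean
    lo <- min(prior$alpha / prior$beta, mle)
    hi <- max(prior$alpha / prior$beta, mle)
    expect_gt(post, lo); expect_lt(post, hi)
    # adding a crossover never decreases the posterior mean
    expect_gt(posterior_rate(prior, sy + 1, sl)$mean, post)
  }
})

test_that("MC placement replicates converge and collapse when degenerate", {
  grid <- small_grid(1, 2e7)
  ped <- simulate_pedigree(2, 10, 10, 2, 1, seed = 54)
  maps <- simulate_true_maps(grid, 2, 2, end_fold = 1)
  sc <- truth_scan(ped, maps, grid, seed = 55)
  prior <- gamma_prior(3.02, 2.32)
  # zero-width detection intervals: every replicate identical, MC equals
  # the single-pass posterior exactly and between-replicate variance is 0
  mc <- mc_rate_estimate(prior, sc, grid, K = 20, seed = 56)
  obs <- assemble_observations(sc, grid, "midpoint")
  single <- posterior_rate(prior,
    mle_rates(obs, grid)$sum_y, mle_rates(obs, grid)$sum_l)
  expect_identical(mc$mean, single$mean)
  expect_true(all(mc$var_between == 0))
  # widen detection intervals: K=100 vs K=1500 agree within MC error
  set.seed(57)
  w <- runif(nrow(sc$events), 1e5, 4e6)
  sc$events$left <- pmax(0, sc$events$left - w)
  sc$events$right <- pmin(2e7 - 1, sc$events$right + w)
  m1 <- mc_rate_estimate(prior, sc, grid, K = 100, seed = 58)
  m2 <- mc_rate_estimate(prior, sc, grid, K = 1500, seed = 59)
  mc_se <- sqrt(m1$var_between / 100 + m2$var_between / 1500)
  expect_true(all(abs(m1$mean - m2$mean) <= 3.5 * mc_se + 1e-12))
})

test_that("map length is conserved against mean crossover count per meiosis", {
  grid <- genome_grid(data.frame(chrom = as.character(1:3), length = 1e8))
  ped <- simulate_pedigree(5, 250, 50, 1, 1, seed = 60,
    prop_dams_genotyped = 0)
  maps <- simulate_true_maps(grid, 1.5, 1.5, end_fold = 2,
    end_fraction = 0.1)
  sc <- truth_scan(ped, maps, grid, seed = 61)
  sc <- observable_scan(sc, ped)
  expect_equal(unique(sc$meioses$parent_sex), "M")
  obs <- assemble_observations(sc, grid, "fractional")
  prior <- fit_gamma_prior(mle_rates(obs, grid))
  mc <- mc_rate_estimate(prior, sc, grid, K = 50, seed = 62)
  # sum of rate (cM/Mb) x length (Mb) / 100 is the map length in Morgans,
  # which equals the expected crossover count per meiosis
  est_morgans <- sum(mc$mean * (mc$end - mc$start) / 1e6) / 100
  mean_acc <- nrow(sc$events) / nrow(sc$meioses)
  expect_lt(abs(est_morgans - mean_acc) / mean_acc, 0.02)
})

test_that("centromere landscape bins intervals by relative position", {
  grid <- small_grid(2, 5e7)
  map <- tibble::as_tibble(grid)
  map$sum_l <- 100
  map$mean <- 1 + (map$start >= 4.5e7) # elevated telomeric tip
  prof <- centromere_landscape(structure(map,
    class = c("recomb_map", class(tibble::tibble()))), grid, n_bins = 10)
  expect_equal(nrow(prof), 10)
  expect_equal(prof$rate[prof$bin == 10], 2)
  expect_equal(prof$rate[prof$bin == 1], 1)
  # first interval lands in the first bin, last in the last
  expect_equal(min(prof$bin), 1); expect_equal(max(prof$bin), 10)
})

test_that("chromosome size regression recovers an exact log-linear law", {
  sizes <- c(4e7, 6e7, 9e7, 1.2e8, 1.6e8)
  rates <- 5 - 0.2 * log(sizes)
  fit <- chromosome_size_model(tibble::tibble(rate = rates, size = sizes))
  expect_equal(unname(stats::coef(fit)), c(5, -0.2), tolerance = 1e-10)
  expect_error(chromosome_size_model(
    tibble::tibble(rate = 1, size = 1e8)), "at least 3")
  # noisy small-chromosome elevation is detected as a negative slope
  set.seed(504)
  sz <- rep(c(4e7, 8e7, 1.2e8, 1.6e8), each = 4)
  rt <- 6 - 0.25 * log(sz) + stats::rnorm(16, 0, 0.02)
  fit2 <- chromosome_size_model(tibble::tibble(rate = rt, size = sz))
  sm <- summary(fit2)$coefficients
  expect_lt(sm["log(size)", "Estimate"], 0)
  expect_lt(sm["log(size)", "Pr(>|t|)"], 0.05)
})
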