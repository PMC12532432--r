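test_that("pedigree design arithmetic and errors", {
  ped <- simulate_pedigree(1, 1, 10, 10, 1, seed = 1)
  expect_equal(sum(ped$generation == 1), 10)
  expect_equal(nrow(pedigree_meioses(ped)), 20)
  expect_equal(table(pedigree_meioses(ped)$parent_sex)[["M"]], 10)
  expect_error(simulate_pedigree(0, 1, 10, 10, 1, seed = 1), "positive")
  expect_error(simulate_pedigree(2, 3, 5, 5, 1, seed = 1), "must equal")
})

test_that("per-sex meiosis counts match an independent edge traversal", {
  ped <- simulate_pedigree(5, 50, 40, 4, 2, seed = 7)
  mei <- pedigree_meioses(ped)
  # oracle: walk the pedigree rows and count parent edges by parent sex
  counts <- c(M = 0L, F = 0L)
  for (r in seq_len(nrow(ped))) {
    if (!ped$genotyped[r] || is.na(ped$sire[r])) next
    sx <- ped$sex[match(ped$sire[r], ped$id)]
    counts[sx] <- counts[sx] + 1L
    dx <- ped$sex[match(ped$dam[r], ped$id)]
    counts[dx] <- counts[dx] + 1L
  }
  expect_equal(sum(mei$parent_sex == "M"), counts[["M"]])
  expect_equal(sum(mei$parent_sex == "F"), counts[["F"]])
  # acyclic, parents before offspring, sires male and dams female
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  expect_true(all(is.na(ped$sire) | idx[ped$sire] < seq_len(nrow(ped))))
  expect_true(all(ped$sex[match(stats::na.omit(ped$sire), ped$id)] == "M"))
  expect_true(all(ped$sex[match(stats::na.omit(ped$dam), ped$id)] == "F"))
  expect_false(anyDuplicated(ped$id) > 0)
})

test_that("true maps place terminal elevation and conserve Morgans", {
  grid <- genome_grid(data.frame(chrom = "1", length = 1e8))
  flat <- simulate_true_maps(grid, 1.2, 1.0, end_fold = 1)
  expect_true(all(flat$rate[flat$sex == "M"] == 1.2))
  maps <- simulate_true_maps(grid, 1.2, 1.0, end_fold = 3,
    end_fraction = 0.1)
  m <- maps[maps$sex == "M", ]
  expect_equal(m$rate[m$start < 1e7], rep(3.6, 10))
  expect_equal(m$rate[m$start >= 9e7], rep(3.6, 10))
  expect_equal(m$rate[m$start >= 1e7 & m$start < 9e7], rep(1.2, 80))
  # total Morgans equals an independent summation
  expect_equal(
    true_map_length(maps)$morgans[true_map_length(maps)$sex == "M"],
    sum(m$rate * (m$end - m$start) / 1e6) / 100
  )
  expect_error(simulate_true_maps(grid, 1, 1, end_fraction = 0.7),
    "end_fraction")
})

test_that("meioses draw Poisson crossover counts from the sex map", {
  grid <- genome_grid(data.frame(chrom = as.character(1:5), length = 5e8))
  ped <- simulate_pedigree(2, 500, 250, 1, 1, seed = 2,
    prop_dams_genotyped = 0)
  zero <- simulate_meioses(ped, simulate_true_maps(grid, 0, 0), seed = 3)
  expect_equal(nrow(zero$crossovers), 0)

  maps <- simulate_true_maps(grid, 1.2, 1.2, end_fold = 1)
  truth <- simulate_meioses(ped, maps, seed = 4)
  male <- truth$meioses$meiosis[truth$meioses$parent_sex == "M"]
  expect_length(male, 500)
  acc <- table(factor(truth$crossovers$meiosis, levels = male))
  # flat 1.2 cM/Mb over 2500 Mb: mean count 30, check within 3 SE
  se <- sqrt(30 / length(male))
  expect_lt(abs(mean(acc) - 30), 3 * se)
  # dispersion: variance/mean ~ 1 for Poisson counts
  disp <- stats::var(acc) / mean(acc) * (length(acc) - 1)
  expect_gt(stats::pchisq(disp, length(acc) - 1, lower.tail = FALSE), 0.005)
  # conservation: one meiosis per (parent, genotyped offspring) pair
  expect_equal(nrow(truth$meioses), nrow(pedigree_meioses(ped)))
  # positions strictly increasing within meiosis/chromosome
  expect_true(all(tapply(truth$crossovers$pos,
    paste(truth$crossovers$meiosis, truth$crossovers$chrom),
    function(x) all(diff(x) > 0))))
})

test_that("interval counts pass a goodness-of-fit against the Poisson law", {
  grid <- genome_grid(data.frame(chrom = "1", length = 2e6))
  ped <- simulate_pedigree(2, 1000, 500, 1, 1, seed = 5,
    prop_dams_genotyped = 0)
  maps <- simulate_true_maps(grid, 40, 40, end_fold = 1) # high rate for counts
  truth <- simulate_meioses(ped, maps, seed = 6)
  male <- truth$meioses$meiosis[truth$meioses$parent_sex == "M"]
  xo <- truth$crossovers[truth$crossovers$meiosis %in% male &
    truth$crossovers$pos < 1e6, ]
  counts <- table(factor(xo$meiosis, levels = male))
  lambda <- 0.01 * 40 * 1
  obs <- table(factor(pmin(counts, 3), levels = 0:3))
  expected <- length(male) *
    c(stats::dpois(0:2, lambda), stats::ppois(2, lambda, lower.tail = FALSE))
  stat <- sum((obs - expected)^2 / expected)
  expect_gt(stats::pchisq(stat, df = 3, lower.tail = FALSE), 0.01)
})

test_that("gamete construction follows truth and founder frequencies", {
  grid <- small_grid(1, 2e7)
  ped <- simulate_pedigree(1, 1, 2, 2, 1, seed = 8)
  zero_maps <- simulate_true_maps(grid, 0, 0)
  truth <- simulate_meioses(ped, zero_maps, seed = 9)
  panel <- simulate_genotypes(ped, truth, grid, n_markers = 200,
    missing_rate = 0, seed = 10)
  # zero crossovers: offspring haplotype identical to one parental haplotype
  sire <- ped$id[ped$sex == "M" & is.na(ped$sire)]
  off <- ped$id[!is.na(ped$sire)][1]
  expect_true(
    identical(panel$hap_pat[, off], panel$hap_pat[, sire]) ||
    identical(panel$hap_pat[, off], panel$hap_mat[, sire])
  )

  # with crossovers, the transmitted haplotype switches source exactly at
  # the true positions
  maps <- simulate_true_maps(grid, 8, 8, end_fold = 1)
  truth2 <- simulate_meioses(ped, maps, seed = 11)
  panel2 <- simulate_genotypes(ped, truth2, grid, n_markers = 500,
    missing_rate = 0, seed = 12)
  mei_id <- paste0(sire, "->", off)
  xo <- truth2$crossovers$pos[truth2$crossovers$meiosis == mei_id]
  init <- truth2$origins$init_origin[truth2$origins$meiosis == mei_id]
  n_left <- findInterval(panel2$markers$pos, sort(xo))
  origin <- 1L + (init - 1L + n_left) %% 2L
  expected <- ifelse(origin == 1L, panel2$hap_pat[, sire],
    panel2$hap_mat[, sire])
  expect_equal(unname(panel2$hap_pat[, off]), unname(expected))
})

test_that("founder heterozygosity matches 2p(1-p) and missingness its rate", {
  grid <- small_grid(1, 1e7)
  ped <- simulate_pedigree(100, 100, 1, 1, 1, seed = 13)
  truth <- simulate_meioses(ped, simulate_true_maps(grid, 0, 0), seed = 14)
  panel <- simulate_genotypes(ped, truth, grid, n_markers = 400,
    maf_range = c(0.1, 0.5), missing_rate = 0.05, seed = 15)
  founders <- ped$id[is.na(ped$sire)]
  het <- rowMeans(panel$hap_pat[, founders] != panel$hap_mat[, founders])
  exp_het <- 2 * panel$markers$freq * (1 - panel$markers$freq)
  diff <- mean(het - exp_het)
  se <- stats::sd(het - exp_het) / sqrt(length(het))
  expect_lt(abs(diff), 4 * se + 1e-3)
  expect_lt(abs(mean(panel$missing) - 0.05), 0.01)
  expect_error(simulate_genotypes(ped, truth, grid, n_markers = 1,
    missing_rate = 0, seed = 1), "fewer than 2")
})

test_that("simulation is deterministic given the seed", {
  grid <- small_grid(1, 1e7)
  ped1 <- simulate_pedigree(2, 4, 4, 2, 2, seed = 99)
  ped2 <- simulate_pedigree(2, 4, 4, 2, 2, seed = 99)
  expect_identical(ped1, ped2)
  maps <- simulate_true_maps(grid, 2, 2, end_fold = 2, sd_log = 0.1,
    seed = 3)
  maps2 <- simulate_true_maps(grid, 2, 2, end_fold = 2, sd_log = 0.1,
    seed = 3)
  expect_identical(maps, maps2)
  t1 <- simulate_meioses(ped1, maps, seed = 5)
  t2 <- simulate_meioses(ped2, maps2, seed = 5)
  expect_identical(t1$crossovers, t2$crossovers)
  p1 <- simulate_genotypes(ped1, t1, grid, 100, missing_rate = 0.1, seed = 6)
  p2 <- simulate_genotypes(ped2, t2, grid, 100, missing_rate = 0.1, seed = 6)
  expect_identical(p1$hap_pat, p2$hap_pat)
  expect_identical(p1$missing, p2$missing)
})

test_that("association fixtures honour significance counts and causal genes", {
  grid <- small_grid(1, 1e7)
  ped <- simulate_pedigree(5, 5, 2, 2, 1, seed = 20)
  truth <- simulate_meioses(ped, simulate_true_maps(grid, 1, 1), seed = 21)
  panel <- simulate_genotypes(ped, truth, grid, n_markers = 60,
    missing_rate = 0, seed = 22)
  none <- simulate_assoc_summary(grid, panel,
    causal = data.frame(snp = character(0), effect = numeric(0)),
    n_significant = 0, seed = 23)
  expect_equal(sum(none$assoc$s < 0.01), 0)
  d <- t(panel_dosage(panel))
  expect_equal(nrow(define_peaks(none$assoc, d)), 0)

  causal <- data.frame(snp = panel$markers$marker[30], effect = 0.5)
  fx <- simulate_assoc_summary(grid, panel, causal, n_significant = 4,
    seed = 24)
  expect_equal(sum(fx$assoc$s < 0.01), 4)
  expect_true(fx$assoc$s[30] < 0.01)
  focal <- fx$genes[grepl("focal", fx$genes$gene_id), ]
  expect_true(focal$start <= panel$markers$pos[30] &
    focal$end >= panel$markers$pos[30])
  expect_error(simulate_assoc_summary(grid, panel, causal,
    n_significant = 1e5, seed = 1), "exceeds")
})
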