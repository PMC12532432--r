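# Shared fixtures and independent oracles, all built in code at test time.

small_grid <- function(n_chrom = 2, len = 5e7, interval_size = 1e6) {
  genome_grid(
    data.frame(chrom = as.character(seq_len(n_chrom)), length = len),
    interval_size = interval_size
  )
}

# A crossover_set built directly from simulated truth: full-genome
# informativity masks and zero-width detection intervals at the true
# crossover positions. Exercises the estimation machinery without the
# genotype layer.
truth_scan <- function(ped, maps, grid, seed, n_info = 1000L) {
  truth <- simulate_meioses(ped, maps, seed = seed)
  cl <- chrom_lengths(grid)
  ci <- tidyr::expand_grid(meiosis = truth$meioses$meiosis, chrom = cl$chrom)
  ci$n_informative <- n_info
  ci$n_origin1 <- n_info %/% 2L
  ci$mask_start <- 0
  ci$mask_end <- cl$length[match(ci$chrom, cl$chrom)]
  ev <- tibble::tibble(
    meiosis = truth$crossovers$meiosis, chrom = truth$crossovers$chrom,
    left = truth$crossovers$pos, right = truth$crossovers$pos
  )
  sc <- structure(list(meioses = truth$meioses, events = ev, chrom_info = ci),
    grid = grid, class = "crossover_set")
  attr(sc, "truth") <- truth
  sc
}

# Restrict a scan to meioses whose parent carries the genotyped flag
observable_scan <- function(sc, ped) {
  ok <- ped$genotyped[match(sc$meioses$parent, ped$id)]
  keep <- sc$meioses$meiosis[ok]
  sc$meioses <- sc$meioses[sc$meioses$meiosis %in% keep, ]
  sc$events <- sc$events[sc$events$meiosis %in% keep, ]
  sc$chrom_info <- sc$chrom_info[sc$chrom_info$meiosis %in% keep, ]
  sc
}

# Hand-built genotype panel from explicit haplotype matrices
make_panel <- function(chrom, pos, hap_pat, hap_mat, sex = NULL,
                       missing = NULL, chrom_len = NULL) {
  n_mk <- length(pos)
  n_s <- ncol(hap_pat)
  ids <- colnames(hap_pat) %||% sprintf("id%02d", seq_len(n_s))
  colnames(hap_pat) <- colnames(hap_mat) <- ids
  if (is.null(missing)) {
    missing <- matrix(FALSE, n_mk, n_s, dimnames = list(NULL, ids))
  }
  if (is.null(chrom_len)) {
    chrom_len <- tapply(pos, chrom, max) + 1e6
  }
  grid <- genome_grid(data.frame(chrom = names(chrom_len),
    length = as.numeric(chrom_len)))
  structure(
    list(
      markers = tibble::tibble(
        marker = sprintf("snp_%s_%d", chrom, pos),
        chrom = as.character(chrom), pos = pos),
      samples = tibble::tibble(id = ids,
        sex = sex %||% rep("M", n_s)),
      hap_pat = hap_pat, hap_mat = hap_mat, missing = missing,
      pedigree = NULL),
    grid = grid, class = "genotype_panel"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- independent oracles -------------------------------------------------

# exhaustive LIS: longest strictly increasing subsequence by recursion
lis_brute <- function(v) {
  n <- length(v)
  best <- list(len = 0L, vals = NULL)
  recurse <- function(i, last, picked) {
    if (best$len < length(picked)) {
      best <<- list(len = length(picked), vals = v[picked])
    } else if (best$len == length(picked) && length(picked) > 0) {
      cur <- v[picked]
      for (k in seq_along(cur)) {
        if (cur[k] < best$vals[k]) {
          best <<- list(len = length(picked), vals = cur)
          break
        } else if (cur[k] > best$vals[k]) break
      }
    }
    if (i > n) return()
    if (v[i] > last) recurse(i + 1L, v[i], c(picked, i))
    recurse(i + 1L, last, picked)
  }
  recurse(1L, -Inf, integer(0))
  best
}

# brute-force marking pass of the close double-crossover rule on one
# meiosis/chromosome: every pair of ADJACENT events (by left boundary) with
# boundary gap < min_gap marks both members
double_co_brute <- function(left, right, min_gap = 5e6) {
  ord <- order(left, right)
  left <- left[ord]; right <- right[ord]
  n <- length(left)
  marked <- logical(n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      gap <- max(0, left[i + 1] - right[i])
      if (gap < min_gap) marked[c(i, i + 1)] <- TRUE
    }
  }
  list(left = left[!marked], right = right[!marked])
}

# union-find connected components over an adjacency matrix
unionfind_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && isTRUE(adj[i, j])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# posterior mean/variance of the rate by numerical integration of the
# Poisson likelihood times the gamma prior density
posterior_quadrature <- function(alpha, beta, sum_y, sum_l) {
  f <- function(c, k) {
    lam <- 0.01 * c * sum_l
    lik <- if (sum_y == 0) exp(-lam) else {
      exp(sum_y * log(lam) - lam - lgamma(sum_y + 1))
    }
    c^k * stats::dgamma(c, alpha, beta) * lik
  }
  m0 <- stats::integrate(f, 0, Inf, k = 0, rel.tol = 1e-12)$value
  m1 <- stats::integrate(f, 0, Inf, k = 1, rel.tol = 1e-12)$value
  m2 <- stats::integrate(f, 0, Inf, k = 2, rel.tol = 1e-12)$value
  c(mean = m1 / m0, var = m2 / m0 - (m1 / m0)^2)
}
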