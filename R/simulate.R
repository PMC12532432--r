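#' Simulate a male-biased multi-generation breeding pedigree
#'
#' Emulates the structure of a dairy breeding program: few, heavily used sires
#' and many dams, over one or more discrete generations. Each generation
#' produces `n_sires * offspring_per_sire` offspring (which must equal
#' `n_dams * offspring_per_dam`); sires and dams of later generations are drawn
#' from the previous generation's offspring where possible and supplemented
#' with new founders otherwise.
#'
#' Because informative maternal meioses are typically scarce in such programs
#' (most dams are not genotyped), `prop_dams_genotyped` controls the fraction
#' of founder dams carrying the genotyped flag; all sires and all offspring are
#' genotyped.
#'
#' @param n_sires,n_dams Number of sires and dams per generation (>= 1).
#' @param offspring_per_sire,offspring_per_dam Offspring per sire and per dam;
#'   `n_sires * offspring_per_sire` must equal `n_dams * offspring_per_dam`.
#' @param generations Number of generations (>= 1).
#' @param seed Integer seed; identical seeds give identical pedigrees.
#' @param prop_dams_genotyped Fraction of dams flagged genotyped (default 1).
#'
#' @return A tibble with columns `id`, `sire` (NA for founders), `dam`, `sex`
#'   (`"M"`/`"F"`), `generation`, `genotyped`. Rows are in topological order
#'   (parents before offspring).
#' @examples
#' ped <- simulate_pedigree(2, 10, 5, 1, generations = 1, seed = 1)
#' table(ped$sex, is.na(ped$sire))
#' @export
simulate_pedigree <- function(n_sires, n_dams, offspring_per_sire,
                              offspring_per_dam, generations, seed,
                              prop_dams_genotyped = 1) {
  for (v in c(n_sires, n_dams, offspring_per_sire, offspring_per_dam,
              generations)) {
    if (length(v) != 1 || is.na(v) || v < 1 || v != round(v)) {
      stop("pedigree design counts must be positive integers", call. = FALSE)
    }
  }
  if (n_sires * offspring_per_sire != n_dams * offspring_per_dam) {
    stop("n_sires * offspring_per_sire must equal n_dams * offspring_per_dam",
      call. = FALSE)
  }
  if (prop_dams_genotyped < 0 || prop_dams_genotyped > 1) {
    stop("prop_dams_genotyped must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  n_off <- n_sires * offspring_per_sire
  rows <- list()
  founder_k <- 0L
  new_founder <- function(sex, gen, genotyped) {
    founder_k <<- founder_k + 1L
    tibble::tibble(
      id = sprintf("F%04d", founder_k), sire = NA_character_,
      dam = NA_character_, sex = sex, generation = gen, genotyped = genotyped
    )
  }
  prev_off <- NULL
  for (g in seq_len(generations)) {
    # recruit parents: previous offspring first, founders for the remainder
    pick <- function(sex, n) {
      pool <- if (is.null(prev_off)) character(0) else {
        prev_off$id[prev_off$sex == sex]
      }
      avail <- utils::head(pool, n)
      need <- n - length(avail)
      if (need > 0) {
        geno <- if (sex == "M") rep(TRUE, need) else {
          seq_len(need) <= round(prop_dams_genotyped * need)
        }
        fnd <- purrr::map2_dfr(rep(sex, need), geno,
          function(s, gt) new_founder(s, g - 1L, gt))
        rows[[length(rows) + 1L]] <<- fnd
        avail <- c(avail, fnd$id)
      }
      avail
    }
    sires <- pick("M", n_sires)
    dams <- pick("F", n_dams)
    off <- tibble::tibble(
      id = sprintf("G%dI%04d", g, seq_len(n_off)),
      sire = rep(sires, each = offspring_per_sire),
      dam = rep(dams, each = offspring_per_dam)[sample.int(n_off)],
      sex = sample(c("M", "F"), n_off, replace = TRUE),
      generation = g,
      genotyped = TRUE
    )
    rows[[length(rows) + 1L]] <- off
    prev_off <- off
  }
  ped <- dplyr::bind_rows(rows)
  # keep topological order but place all founders first within generation 0
  ped <- dplyr::arrange(ped, .data$generation, is.na(.data$sire) == FALSE)
  class(ped) <- c("pedigree_tbl", class(ped))
  ped
}

#' Parent-offspring transmissions of a pedigree
#'
#' One row per gamete transmitted to a genotyped offspring, i.e. the meioses
#' observable in principle from genotype data.
#'
#' @param pedigree A pedigree tibble (see [simulate_pedigree()]).
#' @return Tibble with `meiosis`, `parent`, `offspring`, `parent_sex`.
#' @export
pedigree_meioses <- function(pedigree) {
  off <- pedigree[pedigree$genotyped & !is.na(pedigree$sire), ]
  long <- dplyr::bind_rows(
    tibble::tibble(parent = off$sire, offspring = off$id, parent_sex = "M"),
    tibble::tibble(parent = off$dam, offspring = off$id, parent_sex = "F")
  )
  long$meiosis <- paste(long$parent, long$offspring, sep = "->")
  dplyr::select(long, "meiosis", "parent", "offspring", "parent_sex")
}

#' Simulate sex-specific true recombination maps
#'
#' The male map is elevated by a factor `end_fold` inside the first and last
#' `end_fraction` of each chromosome (acrocentric chromosomes recombine more at
#' both physical ends in males), and flat at `base_rate_male` elsewhere; the
#' female map is flat at `base_rate_female`. Optional multiplicative lognormal
#' noise (`sd_log`, default off) perturbs every (sex, interval) rate.
#'
#' @param grid A [genome_grid()].
#' @param base_rate_male,base_rate_female Baseline rates in cM/Mb (>= 0).
#' @param end_fold Fold elevation of the male rate at chromosome ends (>= 0);
#'   `end_fold = 1` gives a flat male map.
#' @param end_fraction Fraction (0 to 0.5) of each chromosome length treated as
#'   a terminal region at each end.
#' @param seed Integer seed (used only when `sd_log > 0`).
#' @param sd_log Standard deviation of lognormal rate noise (default 0).
#' @return A tibble of class `true_map`: grid columns plus `sex` and
#'   `rate` (cM/Mb), two rows per interval.
#' @export
simulate_true_maps <- function(grid, base_rate_male, base_rate_female,
                               end_fold = 1, end_fraction = 0.1, seed = 1,
                               sd_log = 0) {
  stopifnot(base_rate_male >= 0, base_rate_female >= 0, end_fold >= 0)
  if (end_fraction < 0 || end_fraction > 0.5) {
    stop("end_fraction must be in [0, 0.5]", call. = FALSE)
  }
  cl <- chrom_lengths(grid)
  len <- cl$length[match(grid$chrom, cl$chrom)]
  terminal <- grid$end <= end_fraction * len | grid$start >= (1 - end_fraction) * len
  male <- tibble::as_tibble(grid)
  male$sex <- "M"
  male$rate <- ifelse(terminal, base_rate_male * end_fold, base_rate_male)
  female <- tibble::as_tibble(grid)
  female$sex <- "F"
  female$rate <- base_rate_female
  maps <- dplyr::bind_rows(male, female)
  if (sd_log > 0) {
    set.seed(seed)
    maps$rate <- maps$rate * stats::rlnorm(nrow(maps), -sd_log^2 / 2, sd_log)
  }
  structure(maps, chrom_lengths = cl,
    class = c("true_map", class(tibble::tibble())))
}

#' Total genetic map length of a true map
#' @param maps A `true_map` tibble.
#' @return Tibble with `sex` and `morgans` (sum of rate x length / 100).
#' @export
true_map_length <- function(maps) {
  maps |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(
      morgans = sum(.data$rate * (.data$end - .data$start) / 1e6) / 100,
      .groups = "drop"
    )
}

#' Simulate meioses with Poisson crossover counts
#'
#' For every transmission to a genotyped offspring, the number of crossovers in
#' each grid interval is drawn Poisson(0.01 x rate x interval length in Mb)
#' from the parent-sex map, positions uniform within the interval, with no
#' crossover interference and no obligate crossover. The grandparental origin
#' of the transmitted chromatid starts from an independent fair coin per
#' chromosome and alternates at each crossover.
#'
#' @param pedigree A pedigree tibble.
#' @param maps A `true_map` (see [simulate_true_maps()]).
#' @param seed Integer seed.
#' @return An object of class `meiosis_truth`: a list with tibbles `meioses`
#'   (`meiosis`, `parent`, `offspring`, `parent_sex`), `crossovers`
#'   (`meiosis`, `chrom`, `pos`, sorted by position within meiosis/chromosome)
#'   and `origins` (`meiosis`, `chrom`, `init_origin` in 1:2, where 1 is the
#'   parent's own paternal haplotype).
#' @export
simulate_meioses <- function(pedigree, maps, seed) {
  grid_cols <- c("chrom", "start", "end", "interval")
  grid <- dplyr::distinct(tibble::as_tibble(maps)[, grid_cols])
  set.seed(seed)
  mei <- pedigree_meioses(pedigree)
  n_m <- nrow(mei)
  n_i <- nrow(grid)
  len_mb <- (grid$end - grid$start) / 1e6
  rate_sex <- function(s) {
    m <- maps[maps$sex == s, ]
    m$rate[match(grid$interval, m$interval)]
  }
  lam <- cbind(M = 0.01 * rate_sex("M") * len_mb,
               F = 0.01 * rate_sex("F") * len_mb)
  counts <- vapply(seq_len(n_m), function(m) {
    stats::rpois(n_i, lam[, mei$parent_sex[m]])
  }, integer(n_i))                              # n_i x n_m
  tot <- colSums(counts)
  idx <- which(counts > 0, arr.ind = TRUE)
  xo <- tibble::tibble(
    interval_row = rep(idx[, 1], counts[idx]),
    meiosis_row = rep(idx[, 2], counts[idx])
  )
  xo$pos <- grid$start[xo$interval_row] +
    stats::runif(nrow(xo)) * (grid$end[xo$interval_row] - grid$start[xo$interval_row])
  crossovers <- tibble::tibble(
    meiosis = mei$meiosis[xo$meiosis_row],
    chrom = grid$chrom[xo$interval_row],
    pos = xo$pos
  ) |>
    dplyr::arrange(match(.data$meiosis, mei$meiosis), .data$chrom, .data$pos)
  chroms <- unique(grid$chrom)
  origins <- tidyr::expand_grid(meiosis = mei$meiosis, chrom = chroms)
  origins$init_origin <- sample(1:2, nrow(origins), replace = TRUE)
  structure(
    list(meioses = mei, crossovers = crossovers, origins = origins),
    grid = grid, class = "meiosis_truth"
  )
}

#' @export
print.meiosis_truth <- function(x, ...) {
  cat("<meiosis_truth>", nrow(x$meioses), "meioses,",
      nrow(x$crossovers), "crossovers\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy crossover truth table
#' @param x A `meiosis_truth` object.
#' @param ... Unused.
#' @return Tibble of crossovers with parent and sex columns joined in.
#' @export
tidy.meiosis_truth <- function(x, ...) {
  dplyr::left_join(x$crossovers, x$meioses, by = "meiosis") |>
    dplyr::select("meiosis", "parent", "offspring", "parent_sex",
                  "chrom", "pos")
}

# Grandparental origin (1/2) of a transmitted chromatid at given positions,
# from the initial coin flip and the parity of crossovers to the left.
origin_at <- function(init_origin, xo_pos, pos) {
  n_left <- findInterval(pos, sort(xo_pos))
  1L + (init_origin - 1L + n_left) %% 2L
}

#' Simulate a phased SNP genotype panel along a pedigree
#'
#' Founder haplotypes carry independent alleles with frequencies uniform in
#' `maf_range`; each non-founder gamete copies one parental haplotype,
#' switching source at the true crossover positions of the corresponding
#' meiosis. Genotypes of genotyped individuals are masked missing independently
#' at `missing_rate`; the true phases are retained alongside so parameter
#' recovery can be assessed.
#'
#' @param pedigree A pedigree tibble.
#' @param truth A `meiosis_truth` from [simulate_meioses()].
#' @param grid The [genome_grid()] used for the simulation.
#' @param n_markers Total marker count, allocated to chromosomes
#'   proportionally to physical length (>= 2 per chromosome).
#' @param maf_range Length-2 numeric, founder allele frequency range in
#'   (0, 0.5].
#' @param missing_rate Per-genotype missingness probability in [0, 1).
#' @param seed Integer seed.
#' @return An object of class `genotype_panel`: list with `markers` tibble
#'   (`marker`, `chrom`, `pos`, `freq`), `samples` tibble (genotyped
#'   individuals, with `id`, `sex`), integer matrices `hap_pat` and `hap_mat`
#'   (markers x samples, true phased alleles 0/1), logical matrix `missing`,
#'   and the `pedigree`.
#' @export
simulate_genotypes <- function(pedigree, truth, grid, n_markers,
                               maf_range = c(0.05, 0.5), missing_rate = 0,
                               seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must satisfy 0 < low <= high <= 0.5", call. = FALSE)
  }
  set.seed(seed)
  cl <- chrom_lengths(grid)
  n_per <- round(n_markers * cl$length / sum(cl$length))
  if (any(n_per < 2)) {
    stop("n_markers allocates fewer than 2 markers to a chromosome",
      call. = FALSE)
  }
  markers <- purrr::pmap_dfr(
    list(cl$chrom, cl$length, n_per),
    function(ch, L, n) {
      tibble::tibble(chrom = as.character(ch),
                     pos = sort(sample.int(L, n)))
    }
  )
  markers$marker <- sprintf("snp_%s_%d", markers$chrom, markers$pos)
  markers$freq <- stats::runif(nrow(markers), maf_range[1], maf_range[2])
  n_mk <- nrow(markers)

  ids <- pedigree$id
  hap_pat <- matrix(NA_integer_, n_mk, length(ids), dimnames = list(NULL, ids))
  hap_mat <- hap_pat
  xo_by <- split(truth$crossovers, truth$crossovers$meiosis)
  or_key <- paste(truth$origins$meiosis, truth$origins$chrom)
  init_or <- stats::setNames(truth$origins$init_origin, or_key)
  chrom_of <- markers$chrom

  gamete <- function(parent_id, meiosis_id) {
    h1 <- hap_pat[, parent_id]
    h2 <- hap_mat[, parent_id]
    xo <- xo_by[[meiosis_id]]
    out <- integer(n_mk)
    for (ch in unique(chrom_of)) {
      sel <- chrom_of == ch
      io <- init_or[[paste(meiosis_id, ch)]]
      org <- origin_at(io, xo$pos[xo$chrom == ch], markers$pos[sel])
      out[sel] <- ifelse(org == 1L, h1[sel], h2[sel])
    }
    out
  }
  for (k in seq_along(ids)) {
    if (is.na(pedigree$sire[k])) {
      hap_pat[, k] <- stats::rbinom(n_mk, 1, markers$freq)
      hap_mat[, k] <- stats::rbinom(n_mk, 1, markers$freq)
    } else {
      hap_pat[, k] <- gamete(pedigree$sire[k],
        paste(pedigree$sire[k], ids[k], sep = "->"))
      hap_mat[, k] <- gamete(pedigree$dam[k],
        paste(pedigree$dam[k], ids[k], sep = "->"))
    }
  }
  keep <- pedigree$genotyped
  hap_pat <- hap_pat[, keep, drop = FALSE]
  hap_mat <- hap_mat[, keep, drop = FALSE]
  missing <- matrix(
    stats::runif(n_mk * sum(keep)) < missing_rate, n_mk, sum(keep),
    dimnames = dimnames(hap_pat)
  )
  samples <- tibble::tibble(id = ids[keep], sex = pedigree$sex[keep])
  structure(
    list(markers = dplyr::select(markers, "marker", "chrom", "pos", "freq"),
         samples = samples, hap_pat = hap_pat, hap_mat = hap_mat,
         missing = missing, pedigree = pedigree),
    grid = grid, class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel>", nrow(x$markers), "markers x",
      nrow(x$samples), "samples;",
      sprintf("%.2f%% missing\n", 100 * mean(x$missing)))
  invisible(x)
}

#' Genotype dosage matrix of a panel
#'
#' @param panel A `genotype_panel`.
#' @return Integer matrix (markers x samples) of alternate-allele counts
#'   0/1/2, NA where masked missing.
#' @export
panel_dosage <- function(panel) {
  d <- panel$hap_pat + panel$hap_mat
  d[panel$missing] <- NA_integer_
  d
}

#' Simulate association summary statistics and a gene annotation fixture
#'
#' Produces per-SNP effect estimates (`beta`, `se`) and s-values in which a
#' designated set of SNPs around the causal positions is flagged significant
#' (s-value < 0.01), plus a small gene annotation: one focal gene spanning each
#' causal SNP and neighbour genes at fixed offsets, so downstream peak
#' definition and candidate-gene scoring can be exercised against a known
#' layout.
#'
#' @param grid A [genome_grid()] (used only for validation).
#' @param panel A `genotype_panel` whose markers are scored.
#' @param causal Tibble/data frame with columns `snp` and `effect`; must be
#'   markers of the panel. May have zero rows.
#' @param n_significant Number of SNPs flagged significant (the causal SNPs
#'   and their nearest neighbours in bp).
#' @param seed Integer seed.
#' @param gene_width Width (bp) of each synthetic gene (default 2e5).
#' @param neighbour_offsets Offsets (bp) of neighbour gene starts relative to
#'   each causal SNP (default +/- 3 Mb).
#' @return List with `assoc` (tibble `snp`, `chrom`, `pos`, `beta`, `se`,
#'   `s`) and `genes` (tibble `gene_id`, `chrom`, `start`, `end`, `strand`).
#' @export
simulate_assoc_summary <- function(grid, panel, causal, n_significant, seed,
                                   gene_width = 2e5,
                                   neighbour_offsets = c(-3e6, 3e6)) {
  set.seed(seed)
  mk <- panel$markers
  causal <- tibble::as_tibble(causal)
  if (nrow(causal) > 0 && !all(causal$snp %in% mk$marker)) {
    stop("causal SNPs must exist in the panel", call. = FALSE)
  }
  if (n_significant > nrow(mk)) {
    stop("n_significant exceeds the panel SNP count", call. = FALSE)
  }
  assoc <- tibble::tibble(
    snp = mk$marker, chrom = mk$chrom, pos = mk$pos,
    beta = stats::rnorm(nrow(mk), 0, 0.01),
    se = stats::runif(nrow(mk), 0.01, 0.05),
    s = stats::runif(nrow(mk), 0.05, 1)
  )
  if (nrow(causal) > 0) {
    j <- match(causal$snp, assoc$snp)
    assoc$beta[j] <- assoc$beta[j] + causal$effect
  }
  if (n_significant > 0) {
    if (nrow(causal) == 0) {
      sig <- seq_len(n_significant)
    } else {
      # nearest panel SNPs to any causal SNP, same chromosome, causal first
      j <- match(causal$snp, assoc$snp)
      dmin <- rep(Inf, nrow(assoc))
      for (k in j) {
        same <- assoc$chrom == assoc$chrom[k]
        dmin[same] <- pmin(dmin[same], abs(assoc$pos[same] - assoc$pos[k]))
      }
      sig <- order(dmin)[seq_len(n_significant)]
    }
    assoc$s[sig] <- stats::runif(length(sig), 1e-4, 0.009)
    assoc$s[match(causal$snp, assoc$snp)] <- 1e-4
  }
  genes <- purrr::pmap_dfr(causal, function(snp, effect, ...) {
    k <- match(snp, assoc$snp)
    lead_pos <- assoc$pos[k]
    ch <- assoc$chrom[k]
    focal <- tibble::tibble(
      gene_id = sprintf("GENE_%s_focal", snp), chrom = ch,
      start = max(1, lead_pos - gene_width %/% 2),
      end = lead_pos + gene_width %/% 2, strand = "+"
    )
    nb <- tibble::tibble(
      gene_id = sprintf("GENE_%s_nb%d", snp, seq_along(neighbour_offsets)),
      chrom = ch,
      start = pmax(1, lead_pos + neighbour_offsets),
      end = pmax(1, lead_pos + neighbour_offsets) + gene_width,
      strand = "+"
    )
    dplyr::bind_rows(focal, nb)
  })
  list(assoc = assoc, genes = genes)
}

#' Simulate a single clean association peak with a causal gene
#'
#' Builds a worked-example locus for the candidate-gene scoring machinery:
#' one lead SNP and three further significant SNPs in strong mutual LD, all
#' lying inside one focal gene; background SNPs in linkage equilibrium; and
#' neighbour genes more than 2 Mb away on either side. By construction the
#' focal gene contains the lead and every other member SNP of the peak,
#' overlaps the high-LD area, and is the closest gene on both sides of the
#' lead, so it satisfies all five candidate criteria.
#'
#' @param n_samples Number of genotyped samples (default 400).
#' @param seed Integer seed.
#' @return List with `assoc` (association tibble), `dosages` (samples x SNPs
#'   matrix) and `genes` (gene tibble with the focal gene first).
#' @export
simulate_peak_fixture <- function(n_samples = 400, seed = 1) {
  set.seed(seed)
  lead <- stats::rbinom(n_samples, 1, 0.49) + stats::rbinom(n_samples, 1, 0.49)
  in_ld <- function(x, flip = 0.05) {
    j <- stats::runif(n_samples) < flip
    x[j] <- stats::rbinom(sum(j), 2, 0.49)
    x
  }
  member <- replicate(3, in_ld(lead))
  n_bg <- 16
  bg <- replicate(n_bg, stats::rbinom(n_samples, 1, 0.4) +
    stats::rbinom(n_samples, 1, 0.4))
  pos <- c(7.00e6, 6.96e6, 7.03e6, 7.06e6,
    sort(sample(c(5e5:6.5e6, 7.5e6:1.4e7), n_bg)))
  snp <- sprintf("snp_1_%d", pos)
  dosages <- cbind(lead, member, bg)
  colnames(dosages) <- snp
  assoc <- tibble::tibble(
    snp = snp, chrom = "1", pos = pos,
    beta = c(0.52, 0.48, 0.45, 0.44, stats::rnorm(n_bg, 0, 0.02)),
    se = stats::runif(4 + n_bg, 0.05, 0.12),
    s = c(0.0005, 0.002, 0.004, 0.005, stats::runif(n_bg, 0.2, 1))
  )
  genes <- tibble::tibble(
    gene_id = c("GENE_FOCAL", "GENE_LEFT", "GENE_RIGHT"),
    chrom = "1",
    start = c(6.90e6, 3.9e6, 10.1e6),
    end = c(7.10e6, 4.0e6, 10.2e6),
    strand = "+"
  )
  list(assoc = assoc, dosages = dosages, genes = genes)
}
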