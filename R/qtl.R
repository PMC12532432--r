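#' Linkage disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of unphased allele dosages (0/1/2) over
#' pairwise-complete samples — the composite measure reported by standard
#' genotype tools.
#'
#' @param dosages_a,dosages_b Integer vectors of allele counts over the same
#'   samples (NA allowed).
#' @return r-squared, or NA (with a warning) when fewer than two complete
#'   pairs remain or either SNP is monomorphic among them.
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  stopifnot(length(dosages_a) == length(dosages_b))
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("r2 undefined: monomorphic SNP or too few complete samples",
      call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

# r2 of one SNP against the columns of a dosage matrix (samples x snps)
r2_vs <- function(lead, mat) {
  apply(mat, 2, function(x) {
    ok <- !is.na(lead) & !is.na(x)
    if (sum(ok) < 2 || stats::sd(lead[ok]) == 0 || stats::sd(x[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(lead[ok], x[ok])^2
  })
}

#' Define association peaks by LD clustering of significant SNPs
#'
#' Per chromosome, significant SNPs (s-value below `s_significant`) form a
#' graph with an edge wherever pairwise r-squared reaches `r2_min`; each
#' connected component is one peak. The lead variant is the member with the
#' smallest s-value (ties broken by larger absolute effect, then smaller
#' position).
#'
#' @param assoc Association tibble (`snp`, `chrom`, `pos`, `beta`, `se`,
#'   `s`).
#' @param dosages Matrix of allele dosages, samples x SNPs, with column names
#'   matching `assoc$snp`.
#' @param r2_min Peak-membership LD threshold (default 0.2).
#' @param s_significant Significance threshold on s-values (default 0.01).
#' @return Tibble of class `qtl_peaks`: one row per member SNP with `peak`,
#'   `snp`, `chrom`, `pos`, `beta`, `s`, `is_lead`.
#' @export
define_peaks <- function(assoc, dosages, r2_min = 0.2, s_significant = 0.01) {
  sig <- assoc[assoc$s < s_significant, ]
  if (nrow(sig) == 0) {
    out <- tibble::tibble(peak = character(0), snp = character(0),
      chrom = character(0), pos = numeric(0), beta = numeric(0),
      s = numeric(0), is_lead = logical(0))
    return(structure(out, class = c("qtl_peaks", class(tibble::tibble()))))
  }
  if (!all(sig$snp %in% colnames(dosages))) {
    stop("significant SNPs missing from the dosage panel", call. = FALSE)
  }
  res <- list()
  peak_n <- 0L
  for (ch in unique(sig$chrom)) {
    ss <- sig[sig$chrom == ch, ]
    n <- nrow(ss)
    if (n == 1) {
      comp <- 1L
    } else {
      r2 <- suppressWarnings(
        stats::cor(dosages[, ss$snp, drop = FALSE],
          use = "pairwise.complete.obs")^2)
      adj <- !is.na(r2) & r2 >= r2_min
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
        diag = FALSE)
      comp <- igraph::components(g)$membership
    }
    for (k in sort(unique(comp))) {
      peak_n <- peak_n + 1L
      members <- ss[comp == k, ]
      lead <- order(members$s, -abs(members$beta), members$pos)[1]
      members$peak <- sprintf("peak_%02d", peak_n)
      members$is_lead <- seq_len(nrow(members)) == lead
      res[[peak_n]] <- members
    }
  }
  out <- dplyr::bind_rows(res) |>
    dplyr::select("peak", "snp", "chrom", "pos", "beta", "s", "is_lead")
  structure(out, class = c("qtl_peaks", class(tibble::tibble())))
}

#' High-LD area around a peak's lead variant
#'
#' The area spans from the furthest SNP in r-squared above `r2_area` with the
#' lead on the left to the furthest on the right, over all panel SNPs of the
#' chromosome (not only significant ones). A side with no qualifying SNP
#' collapses to the lead position.
#'
#' @param peak One peak's member rows (a `qtl_peaks` subset containing the
#'   lead).
#' @param assoc Association tibble covering the panel SNPs of the chromosome
#'   (for positions).
#' @param dosages Dosage matrix, samples x SNPs.
#' @param r2_area LD threshold (default 0.6; strict inequality).
#' @return Named numeric `c(left, right)` in bp.
#' @export
high_ld_area <- function(peak, assoc, dosages, r2_area = 0.6) {
  lead <- peak[peak$is_lead, ]
  stopifnot(nrow(lead) == 1)
  cand <- assoc[assoc$chrom == lead$chrom & assoc$snp %in% colnames(dosages), ]
  r2 <- r2_vs(dosages[, lead$snp], dosages[, cand$snp, drop = FALSE])
  qual <- cand$pos[!is.na(r2) & r2 > r2_area]
  c(left = min(qual, lead$pos), right = max(qual, lead$pos))
}

gene_snp_distance <- function(gene_start, gene_end, snp_pos) {
  # 0 when the SNP lies within the gene body, else gap to the nearer edge
  ifelse(snp_pos >= gene_start & snp_pos <= gene_end, 0,
    pmin(abs(snp_pos - gene_start), abs(snp_pos - gene_end)))
}

#' Score candidate genes at an association peak
#'
#' Five boolean criteria are evaluated for every gene on the peak's
#' chromosome: within `window` of the lead variant; closest gene to the right
#' of the lead; closest gene to the left; closest gene to at least one other
#' significant member SNP of the peak; overlapping the high-LD
#' (r-squared > 0.6) area. The candidate score is their count (0-5). A gene
#' containing the lead is the closest on both sides; ties for "closest" award
#' the criterion to all tied genes. Distances are to the gene body
#' (containment counts as zero).
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`.
#' @param peak One peak's member rows (with its lead).
#' @param area Length-2 numeric `c(left, right)` from [high_ld_area()].
#' @param window Lead-proximity window in bp (default 2e6).
#' @return Tibble ranked by score (desc), distance to lead (asc), gene id:
#'   `gene_id`, `score`, the five criterion flags, `dist_lead`.
#' @export
score_genes <- function(genes, peak, area, window = 2e6) {
  lead <- peak[peak$is_lead, ]
  stopifnot(nrow(lead) == 1)
  g <- genes[genes$chrom == lead$chrom, ]
  if (nrow(g) == 0) {
    return(tibble::tibble(gene_id = character(0), score = integer(0),
      within_window = logical(0), closest_right = logical(0),
      closest_left = logical(0), closest_other = logical(0),
      in_area = logical(0), dist_lead = numeric(0)))
  }
  dist_lead <- gene_snp_distance(g$start, g$end, lead$pos)
  within_window <- dist_lead <= window
  contains <- g$start <= lead$pos & g$end >= lead$pos
  on_right <- g$start > lead$pos
  on_left <- g$end < lead$pos
  closest_side <- function(side) {
    cand <- side | contains
    if (!any(cand)) return(rep(FALSE, nrow(g)))
    dmin <- min(dist_lead[cand])
    cand & dist_lead == dmin
  }
  closest_right <- closest_side(on_right)
  closest_left <- closest_side(on_left)
  others <- peak[!peak$is_lead, ]
  closest_other <- rep(FALSE, nrow(g))
  for (j in seq_len(nrow(others))) {
    dd <- gene_snp_distance(g$start, g$end, others$pos[j])
    closest_other <- closest_other | dd == min(dd)
  }
  in_area <- g$start <= area[["right"]] & g$end >= area[["left"]]
  score <- within_window + closest_right + closest_left + closest_other +
    in_area
  tibble::tibble(
    gene_id = g$gene_id, score = as.integer(score),
    within_window = within_window, closest_right = closest_right,
    closest_left = closest_left, closest_other = closest_other,
    in_area = in_area, dist_lead = dist_lead
  ) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$dist_lead, .data$gene_id)
}

#' Annotate all peaks of an association scan
#'
#' Convenience wrapper: defines peaks, delimits each peak's high-LD area and
#' scores every gene, returning one ranked gene table per peak.
#'
#' @inheritParams define_peaks
#' @param genes Gene tibble (see [read_gff3_genes()]).
#' @param r2_area High-LD area threshold (default 0.6).
#' @param window Lead-proximity window (default 2e6).
#' @return Tibble: peak summary columns (`peak`, `chrom`, `lead_snp`,
#'   `lead_pos`, `n_members`, `area_left`, `area_right`) joined to the gene
#'   scores.
#' @export
annotate_peaks <- function(assoc, dosages, genes, r2_min = 0.2,
                           s_significant = 0.01, r2_area = 0.6,
                           window = 2e6) {
  peaks <- define_peaks(assoc, dosages, r2_min, s_significant)
  if (nrow(peaks) == 0) return(tibble::tibble())
  purrr::map_dfr(unique(peaks$peak), function(pk) {
    p <- peaks[peaks$peak == pk, ]
    area <- high_ld_area(p, assoc, dosages, r2_area)
    scores <- score_genes(genes, p, area, window)
    lead <- p[p$is_lead, ]
    dplyr::bind_cols(
      tibble::tibble(peak = pk, chrom = lead$chrom, lead_snp = lead$snp,
        lead_pos = lead$pos, n_members = nrow(p),
        area_left = area[["left"]], area_right = area[["right"]])[
          rep(1, nrow(scores)), ],
      scores
    )
  })
}

#' Standard-error-weighted correlation of SNP effects between groups
#'
#' Weighted Pearson correlation of effect estimates from two analyses (e.g.
#' two breeds) over a selected SNP set, with weights
#' `1 / (se_a^2 + se_b^2)` so imprecisely estimated effects in either group
#' count less.
#'
#' @param betas_a,betas_b Effect estimates over the same SNPs.
#' @param ses_a,ses_b Their standard errors (> 0).
#' @param selection Logical mask of SNPs to use (e.g. significant in at least
#'   one group); default all.
#' @return The weighted correlation (scalar in `[-1, 1]`).
#' @export
weighted_effect_correlation <- function(betas_a, ses_a, betas_b, ses_b,
                                        selection = NULL) {
  if (is.null(selection)) selection <- rep(TRUE, length(betas_a))
  a <- betas_a[selection]; b <- betas_b[selection]
  w <- 1 / (ses_a[selection]^2 + ses_b[selection]^2)
  if (length(a) < 3) stop("need at least 3 selected SNPs", call. = FALSE)
  w <- w / sum(w)
  ma <- sum(w * a); mb <- sum(w * b)
  cov_ab <- sum(w * (a - ma) * (b - mb))
  cov_ab / sqrt(sum(w * (a - ma)^2) * sum(w * (b - mb)^2))
}
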