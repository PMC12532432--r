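#' Informativity mask of one meiosis
#'
#' A marker is informative for crossover detection when the parent is
#' heterozygous with resolved phase and the offspring's inherited allele is
#' resolved. Crossovers can only be observed between the first and the last
#' informative marker of a chromosome, so the mask is the half-open span
#' between them; chromosomes with fewer than two informative markers carry an
#' empty mask.
#'
#' @param parent_pat,parent_mat Integer vectors (0/1, NA when unresolved):
#'   the parent's phased haplotypes over all markers.
#' @param gamete Integer vector: the allele the offspring inherited from this
#'   parent (NA when unresolved).
#' @param positions Marker base-pair positions.
#' @param chrom Character vector of marker chromosomes.
#' @return List with `informative` (integer marker indices) and `mask`
#'   (tibble `chrom`, `start`, `end`, `n_informative`; one row per chromosome
#'   with >= 2 informative markers).
#' @export
informative_mask <- function(parent_pat, parent_mat, gamete, positions,
                             chrom) {
  n <- length(positions)
  if (length(parent_pat) != n || length(parent_mat) != n ||
      length(gamete) != n || length(chrom) != n) {
    stop("all marker vectors must have identical length", call. = FALSE)
  }
  info <- which(!is.na(parent_pat) & !is.na(parent_mat) &
    parent_pat != parent_mat & !is.na(gamete))
  mask <- tibble::tibble(chrom = character(0), start = numeric(0),
    end = numeric(0), n_informative = integer(0))
  if (length(info) > 0) {
    mask <- tibble::tibble(chrom = chrom[info], pos = positions[info]) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(start = min(.data$pos), end = max(.data$pos),
        n_informative = dplyr::n(), .groups = "drop") |>
      dplyr::filter(.data$n_informative >= 2)
  }
  list(informative = info, mask = mask)
}

#' Detect crossovers as grandparental-origin switches
#'
#' Emits one crossover event per adjacent pair of informative markers with
#' differing grandparental origin; the detection interval runs from the left
#' flanking marker to the right flanking marker. A chromosome with a single
#' informative marker yields no events.
#'
#' @param origin Integer vector (1/2) of grandparental origin at the
#'   informative markers, in position order.
#' @param positions Base-pair positions of those markers.
#' @param chrom Chromosome of each marker.
#' @param meiosis Meiosis id recorded on the events (default NA).
#' @return Tibble with `meiosis`, `chrom`, `left`, `right`.
#' @export
detect_crossovers <- function(origin, positions, chrom,
                              meiosis = NA_character_) {
  stopifnot(length(origin) == length(positions),
    length(chrom) == length(positions))
  keep <- !is.na(origin)
  origin <- origin[keep]; positions <- positions[keep]; chrom <- chrom[keep]
  n <- length(origin)
  if (n < 2) {
    return(tibble::tibble(meiosis = character(0), chrom = character(0),
      left = numeric(0), right = numeric(0)))
  }
  adj <- which(origin[-1] != origin[-n] & chrom[-1] == chrom[-n])
  tibble::tibble(
    meiosis = meiosis, chrom = chrom[adj],
    left = positions[adj], right = positions[adj + 1]
  )
}

#' Scan a phased panel for crossovers in every observable meiosis
#'
#' For each genotyped parent-offspring pair, resolves the transmitted
#' haplotype's grandparental origin at informative markers, records the
#' informativity mask and per-chromosome origin counts, and detects crossover
#' events as origin switches. Phasing is consumed, not inferred: the panel's
#' haplotypes are taken as given, and masked genotypes are treated as
#' unresolved in both parent and offspring.
#'
#' @param panel A `genotype_panel` (phased; see [simulate_genotypes()] or
#'   [read_phased_vcf()]).
#' @param pedigree Pedigree tibble (defaults to the panel's).
#' @return Object of class `crossover_set`: list with tibbles
#'   \describe{
#'     \item{meioses}{`meiosis`, `parent`, `offspring`, `parent_sex`,
#'       `parent_phased`, `offspring_phased` (fractions of markers resolved).}
#'     \item{events}{`meiosis`, `chrom`, `left`, `right` detection intervals.}
#'     \item{chrom_info}{per meiosis and chromosome: `n_informative`,
#'       `n_origin1` (markers on the parent's own paternal haplotype),
#'       `mask_start`, `mask_end` (NA when < 2 informative markers).}
#'   }
#' @export
crossover_scan <- function(panel, pedigree = panel$pedigree) {
  if (is.null(pedigree)) stop("a pedigree is required", call. = FALSE)
  ids <- panel$samples$id
  mei <- pedigree_meioses(pedigree)
  mei <- mei[mei$parent %in% ids & mei$offspring %in% ids, ]
  n_mk <- nrow(panel$markers)
  chrom <- panel$markers$chrom
  pos <- panel$markers$pos
  chrom_split <- split(seq_len(n_mk), chrom)
  phased_frac <- 1 - colMeans(panel$missing)
  obs <- function(h, id) {
    x <- h[, id]
    x[panel$missing[, id]] <- NA_integer_
    x
  }
  events <- vector("list", nrow(mei))
  infos <- vector("list", nrow(mei))
  for (k in seq_len(nrow(mei))) {
    p <- mei$parent[k]; o <- mei$offspring[k]
    pp <- obs(panel$hap_pat, p)
    pm <- obs(panel$hap_mat, p)
    gam <- obs(if (mei$parent_sex[k] == "M") panel$hap_pat else panel$hap_mat,
      o)
    info <- !is.na(pp) & !is.na(pm) & pp != pm & !is.na(gam)
    origin <- ifelse(gam == pp, 1L, 2L)
    ik <- purrr::imap_dfr(chrom_split, function(sel, ch) {
      s <- sel[info[sel]]
      tibble::tibble(
        meiosis = mei$meiosis[k], chrom = ch,
        n_informative = length(s),
        n_origin1 = sum(origin[s] == 1L),
        mask_start = if (length(s) >= 2) pos[s[1]] else NA_real_,
        mask_end = if (length(s) >= 2) pos[s[length(s)]] else NA_real_
      )
    })
    infos[[k]] <- ik
    w <- which(info)
    events[[k]] <- detect_crossovers(origin[w], pos[w], chrom[w],
      meiosis = mei$meiosis[k])
  }
  mei$parent_phased <- phased_frac[mei$parent]
  mei$offspring_phased <- phased_frac[mei$offspring]
  structure(
    list(meioses = mei, events = dplyr::bind_rows(events),
         chrom_info = dplyr::bind_rows(infos)),
    grid = attr(panel, "grid"), class = "crossover_set"
  )
}

#' @export
print.crossover_set <- function(x, ...) {
  cat("<crossover_set>", nrow(x$meioses), "meioses,",
      nrow(x$events), "events\n")
  invisible(x)
}

#' Meiosis-level quality control
#'
#' Removes meioses with a parent or offspring phased at less than `phased_min`
#' of markers, and meioses whose parent has none of its own parents genotyped
#' and only one genotyped offspring (crossovers are undetectable in that
#' setting: the parent's phase cannot be anchored).
#'
#' @param scan A `crossover_set` from [crossover_scan()].
#' @param pedigree Pedigree tibble.
#' @param phased_min Minimum phased fraction (default 0.90).
#' @return List with `scan` (filtered `crossover_set`) and `report` (tibble
#'   `meiosis`, `reason`).
#' @export
meiosis_qc <- function(scan, pedigree, phased_min = 0.90) {
  mei <- scan$meioses
  low <- mei$parent_phased < phased_min | mei$offspring_phased < phased_min
  ped <- pedigree
  parent_rows <- match(mei$parent, ped$id)
  parents_genotyped <- vapply(parent_rows, function(r) {
    pr <- c(ped$sire[r], ped$dam[r])
    pr <- pr[!is.na(pr)]
    any(ped$genotyped[match(pr, ped$id)])
  }, logical(1))
  off_geno <- ped[ped$genotyped & !is.na(ped$sire), ]
  n_off <- table(c(off_geno$sire, off_geno$dam))
  single <- !parents_genotyped &
    as.integer(n_off[mei$parent]) <= 1
  reason <- dplyr::case_when(
    low ~ "low_phasing",
    single ~ "unconnected_single_offspring",
    TRUE ~ NA_character_
  )
  drop <- !is.na(reason)
  out <- scan
  out$meioses <- mei[!drop, ]
  out$events <- scan$events[scan$events$meiosis %in% out$meioses$meiosis, ]
  out$chrom_info <- scan$chrom_info[
    scan$chrom_info$meiosis %in% out$meioses$meiosis, ]
  list(scan = out,
    report = tibble::tibble(meiosis = mei$meiosis[drop],
      reason = reason[drop]))
}

#' Remove close double crossovers
#'
#' Pairs of adjacent crossover events on the same chromosome of the same
#' meiosis whose closest detection-interval boundaries lie less than `min_gap`
#' apart are treated as phasing-error artefacts and both members are removed.
#' Marking happens in a single pass, so a chain of mutually close events is
#' removed entirely; isolated events are never touched.
#'
#' @param events Tibble of crossover events (`meiosis`, `chrom`, `left`,
#'   `right`).
#' @param min_gap Minimum boundary gap in bp (default 5e6).
#' @return The filtered events tibble; after filtering every surviving
#'   adjacent pair has a boundary gap of at least `min_gap`.
#' @export
filter_double_crossovers <- function(events, min_gap = 5e6) {
  if (nrow(events) == 0) return(events)
  ord <- order(events$meiosis, events$chrom, events$left, events$right)
  ev <- events[ord, ]
  n <- nrow(ev)
  same <- ev$meiosis[-1] == ev$meiosis[-n] & ev$chrom[-1] == ev$chrom[-n]
  gap <- pmax(0, ev$left[-1] - ev$right[-n])
  bad_pair <- same & gap < min_gap
  marked <- logical(n)
  marked[which(bad_pair)] <- TRUE
  marked[which(bad_pair) + 1L] <- TRUE
  ev[!marked, ]
}
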