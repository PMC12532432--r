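#' Write a phased VCF for a genotype panel
#'
#' Emits a minimal VCF 4.2 with phased GT ('|' separated, paternal allele
#' first), one sample column per genotyped individual; masked genotypes are
#' written `.|.`.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  cl <- chrom_lengths(attr(panel, "grid"))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", cl$chrom, cl$length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$id), collapse = "\t")
  )
  gt <- matrix(paste(panel$hap_pat, panel$hap_mat, sep = "|"),
    nrow = nrow(panel$markers))
  gt[panel$missing] <- ".|."
  body <- paste(
    panel$markers$chrom, panel$markers$pos, panel$markers$marker,
    "A", "B", ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into a genotype panel
#'
#' Parses a VCF (via \pkg{vcfR}) with phased GT fields back into the matrix
#' representation used throughout the package. Unphased or missing genotypes
#' become missing entries.
#'
#' @param path VCF file path.
#' @param pedigree Optional pedigree tibble to attach (sample sexes are looked
#'   up there when given).
#' @return A `genotype_panel` (without founder `freq` information).
#' @export
read_phased_vcf <- function(path, pedigree = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
    stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")
  phased <- !is.na(gt) & grepl("^[01]\\|[01]$", gt)
  hap_pat <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  hap_mat <- hap_pat
  hap_pat[phased] <- as.integer(substr(gt[phased], 1, 1))
  hap_mat[phased] <- as.integer(substr(gt[phased], 3, 3))
  markers <- tibble::tibble(
    marker = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS)
  )
  sex <- if (!is.null(pedigree)) {
    pedigree$sex[match(colnames(gt), pedigree$id)]
  } else {
    rep(NA_character_, ncol(gt))
  }
  cl_len <- vapply(split(markers$pos, markers$chrom), max, 1)
  grid <- genome_grid(tibble::tibble(chrom = names(cl_len),
                                     length = as.numeric(cl_len) + 1))
  structure(
    list(markers = markers,
         samples = tibble::tibble(id = colnames(gt), sex = sex),
         hap_pat = hap_pat, hap_mat = hap_mat, missing = !phased,
         pedigree = pedigree),
    grid = grid, class = "genotype_panel"
  )
}

#' Write / read a PLINK-style .fam pedigree
#'
#' Six whitespace-separated columns: family id (constant `FAM`), individual,
#' sire (0 if unknown), dam, sex code (1 = male, 2 = female), phenotype (-9).
#'
#' @param pedigree Pedigree tibble.
#' @param path File path.
#' @return `path` invisibly (writer); pedigree tibble (reader). Genotyped
#'   status is not representable in .fam and is restored as TRUE.
#' @export
write_fam <- function(pedigree, path) {
  out <- data.frame(
    fid = "FAM", id = pedigree$id,
    sire = ifelse(is.na(pedigree$sire), "0", pedigree$sire),
    dam = ifelse(is.na(pedigree$dam), "0", pedigree$dam),
    sex = ifelse(pedigree$sex == "M", 1L, 2L),
    pheno = -9L
  )
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(path)
}

#' @rdname write_fam
#' @export
read_fam <- function(path) {
  x <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
    col.names = c("fid", "id", "sire", "dam", "sexcode", "pheno"))
  ped <- tibble::tibble(
    id = as.character(x$id),
    sire = ifelse(x$sire == "0", NA_character_, as.character(x$sire)),
    dam = ifelse(x$dam == "0", NA_character_, as.character(x$dam)),
    sex = ifelse(x$sexcode == 1, "M", "F"),
    genotyped = TRUE
  )
  class(ped) <- c("pedigree_tbl", class(ped))
  ped
}

#' Write gene records as GFF3
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open starts are converted to 1-based inclusive GFF3).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- sprintf("%s\tcaprimap\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
    genes$chrom, as.integer(genes$start), as.integer(genes$end),
    genes$strand, genes$gene_id, genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Uses \code{ape::read.gff} and keeps `gene`-type features; the gene id is
#' taken from the `ID=` attribute.
#'
#' @param path GFF3 file path.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff3_genes <- function(path) {
  g <- ape::read.gff(path)
  g <- g[g$type == "gene", ]
  id <- sub(";.*$", "", sub("^.*ID=", "", g$attributes))
  tibble::tibble(
    gene_id = id, chrom = as.character(g$seqid),
    start = as.integer(g$start), end = as.integer(g$end),
    strand = as.character(g$strand)
  )
}

#' Write / read an association summary TSV
#' @param assoc Tibble with `snp`, `chrom`, `pos`, `beta`, `se`, `s`.
#' @param path File path.
#' @return `path` invisibly (writer); tibble (reader).
#' @export
write_assoc_tsv <- function(assoc, path) {
  utils::write.table(assoc, path, quote = FALSE, sep = "\t",
    row.names = FALSE)
  invisible(path)
}

#' @rdname write_assoc_tsv
#' @export
read_assoc_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, colClasses = c(snp = "character",
      chrom = "character")))
}
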