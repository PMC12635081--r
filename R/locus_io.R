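#' Read a phased VCF into a HaplotypeMatrix
#'
#' Parses a VCF 4.x file (plain text or bgzipped) with phased GT fields and
#' returns the haplotype-by-site allele matrix. Multiallelic records are split
#' into one biallelic site per ALT allele, all sharing the record position.
#' Unphased genotypes are rejected; the error names the offending record and
#' sample. Missing genotypes are rejected unless `allow_missing_drop_sites`
#' is set, in which case every site touched by a missing call is dropped.
#'
#' @param path VCF file path
#' @param region optional `"chrom:start-end"` restriction (1-based inclusive)
#' @param allow_missing_drop_sites drop sites containing `.` calls instead of
#'   erroring
#' @param build genome build label stored on the result
#' @return a [haplotype_matrix()]
#' @export
read_phased_vcf <- function(path, region = NULL, allow_missing_drop_sites = FALSE,
                            build = "GRCh37") {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alts <- lapply(rr$ALT, as.character)
  ids <- names(rr)
  samples <- colnames(gt)

  unph <- which(matrix(grepl("/", gt, fixed = TRUE), nrow(gt)), arr.ind = TRUE)
  if (nrow(unph) > 0) {
    stop(sprintf("unphased genotype '%s' at %s:%d for sample %s",
                 gt[unph[1, 1], unph[1, 2]], chrom[unph[1, 1]],
                 pos[unph[1, 1]], samples[unph[1, 2]]))
  }
  miss <- matrix(grepl(".", gt, fixed = TRUE), nrow(gt))
  miss_rec <- apply(miss, 1, any)
  if (any(miss_rec) && !allow_missing_drop_sites) {
    i <- which(miss_rec)[1]
    j <- which(miss[i, ])[1]
    stop(sprintf("missing genotype at %s:%d for sample %s (set allow_missing_drop_sites to drop)",
                 chrom[i], pos[i], samples[j]))
  }

  # phased haplotype allele indices per record (possibly multiallelic);
  # records containing "." were either rejected above or are dropped below,
  # so the NA coercion on them is silenced
  h1 <- suppressWarnings(
    apply(gt, c(1, 2), function(g) as.integer(strsplit(g, "|", fixed = TRUE)[[1]][1])))
  h2 <- suppressWarnings(
    apply(gt, c(1, 2), function(g) as.integer(strsplit(g, "|", fixed = TRUE)[[1]][2])))

  out_alleles <- list()
  out_sites <- list()
  k <- 0L
  for (i in seq_along(pos)) {
    if (miss_rec[i]) next
    for (a in seq_along(alts[[i]])) {
      k <- k + 1L
      row1 <- as.integer(h1[i, ] == a)
      row2 <- as.integer(h2[i, ] == a)
      v <- integer(2 * length(samples))
      v[seq(1, length(v), 2)] <- row1
      v[seq(2, length(v), 2)] <- row2
      out_alleles[[k]] <- v
      out_sites[[k]] <- data.frame(
        chrom = chrom[i], pos = pos[i],
        id = if (length(alts[[i]]) > 1) paste0(ids[i], "_alt", a) else ids[i],
        ref = ref[i], alt = alts[[i]][a], stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) stop("no usable sites in ", path)
  al <- do.call(cbind, out_alleles)
  rownames(al) <- paste0(rep(samples, each = 2), "_h", rep(1:2, length(samples)))
  m <- haplotype_matrix(al, do.call(rbind, out_sites), build = build)
  if (!is.null(region)) m <- restrict_region(m, region)
  m
}

#' Write a HaplotypeMatrix as a phased VCF
#'
#' Emits a minimal VCF 4.2 file with `|`-separated GT fields, one record per
#' site, samples recovered by pairing consecutive haplotype rows.
#'
#' @param x a `HaplotypeMatrix`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_phased_vcf <- function(x, path) {
  samples <- sample_ids(x)
  n <- length(samples)
  a <- x$alleles
  gt <- matrix("", nrow = ncol(a), ncol = n)
  for (j in seq_len(n)) {
    gt[, j] <- paste0(a[2 * j - 1, ], "|", a[2 * j, ])
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=haplolocus",
           sprintf("##contig=<ID=%s>", unique(x$sites$chrom)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(x$sites$chrom, x$sites$pos, x$sites$id, x$sites$ref,
                x$sites$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Polarize alleles against an ancestral-allele map
#'
#' Annotates each site with its ancestral/derived orientation. A site whose
#' ancestral base matches neither REF nor ALT, or is missing/ambiguous
#' (e.g. "N"), is flagged unpolarized and excluded from derived-allele
#' statistics downstream. Allele calls are never modified.
#'
#' @param x a `HaplotypeMatrix`
#' @param ancestral_map either a named character vector (names = positions) or
#'   a data.frame with columns `pos` and `ancestral`
#' @return `x` with `ancestral`, `ancestral_index` (0 = ref ancestral,
#'   1 = alt ancestral) and `polarized` filled in on the site table
#' @export
polarize_alleles <- function(x, ancestral_map) {
  if (is.data.frame(ancestral_map)) {
    anc <- stats::setNames(toupper(as.character(ancestral_map$ancestral)),
                           as.character(ancestral_map$pos))
  } else {
    anc <- toupper(as.character(ancestral_map))
    names(anc) <- names(ancestral_map)
  }
  st <- x$sites
  base <- unname(anc[as.character(st$pos)])
  st$ancestral <- base
  idx <- rep(NA_integer_, nrow(st))
  ok <- !is.na(base) & base %in% c("A", "C", "G", "T")
  idx[ok & base == toupper(st$ref)] <- 0L
  idx[ok & base == toupper(st$alt)] <- 1L
  st$ancestral_index <- idx
  st$polarized <- !is.na(idx)
  x$sites <- st
  x
}

#' Read an ancestral-allele map from a TSV file
#' @param path two-column TSV (`pos`, `ancestral`), with or without header
#' @return data.frame with columns `pos`, `ancestral`
#' @export
read_ancestral_map <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!is.numeric(d[[1]])) {  # header line present
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    names(d)[1:2] <- c("pos", "ancestral")
    return(d[, 1:2])
  }
  stats::setNames(d[, 1:2], c("pos", "ancestral"))
}

#' Export block haplotypes as FASTA
#'
#' One record per haplotype; the sequence is the concatenation of the literal
#' allele bases over the block sites (unpolarized sites export their literal
#' base like any other).
#'
#' @param x a `HaplotypeMatrix`
#' @param block optional integer/logical site index restricting the export
#' @param path optional file; when NULL the FASTA text is returned
#' @return character vector of FASTA lines (invisibly when writing to file)
#' @export
export_block_fasta <- function(x, block = NULL, path = NULL) {
  if (!is.null(block)) x <- subset_sites(x, sites = block)
  if (ncol(x$alleles) == 0) stop("empty block: no sites to export")
  bases <- ifelse(x$alleles == 0L,
                  matrix(x$sites$ref, nrow(x$alleles), ncol(x$alleles), byrow = TRUE),
                  matrix(x$sites$alt, nrow(x$alleles), ncol(x$alleles), byrow = TRUE))
  seqs <- apply(bases, 1, paste, collapse = "")
  dss <- Biostrings::BStringSet(seqs)
  names(dss) <- rownames(x$alleles)
  if (is.null(path)) {
    lines <- as.character(rbind(paste0(">", names(dss)), as.character(dss)))
    return(lines)
  }
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}

#' Re-import a block FASTA against a site table
#'
#' Inverse of [export_block_fasta()]: maps each base back to its 0/1 allele
#' index using the site table's ref/alt columns.
#'
#' @param path FASTA file (or character vector of FASTA lines)
#' @param sites the site table of the exported block (same order)
#' @return a `HaplotypeMatrix` over those sites
#' @export
read_block_fasta <- function(path, sites) {
  if (length(path) > 1 || grepl("^>", path[1])) {
    tf <- tempfile(fileext = ".fa")
    writeLines(path, tf)
    path <- tf
  }
  ss <- Biostrings::readBStringSet(path)
  mat <- do.call(rbind, strsplit(as.character(ss), ""))
  if (ncol(mat) != nrow(sites)) stop("sequence length does not match site table")
  al <- matrix(NA_integer_, nrow(mat), ncol(mat))
  for (j in seq_len(ncol(mat))) {
    al[, j] <- ifelse(mat[, j] == sites$ref[j], 0L,
                      ifelse(mat[, j] == sites$alt[j], 1L, NA_integer_))
    if (anyNA(al[, j])) stop("base not matching ref/alt at site ", sites$id[j])
  }
  rownames(al) <- names(ss)
  haplotype_matrix(al, sites)
}

#' Write a sample-metadata table as TSV
#' @param samples data.frame (see package vignette for the column contract)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample-metadata TSV
#' @param path TSV with header (`sample_id`, `population`, ...)
#' @return data.frame
#' @export
read_sample_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_ids in ", path)
  if (!is.null(d$surv_event) && !all(d$surv_event %in% c(0, 1, NA)))
    stop("surv_event must be 0/1")
  d
}
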