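#' Phased haplotype-by-site allele matrix
#'
#' The central container of the package: one row per phased chromosome
#' (haplotype), one column per biallelic site. Allele indices are relative to
#' the site's REF/ALT pair (0 = ref, 1 = alt); ancestral/derived status is an
#' annotation layered on top by [polarize_alleles()] and never changes the
#' calls themselves.
#'
#' @param alleles integer matrix, haplotypes x sites, entries 0/1. Row names
#'   are haplotype identifiers of the form `<sample_id>_h1` / `<sample_id>_h2`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`; optional `ancestral` (base or NA) and `polarized`.
#' @param build genome build label, e.g. `"GRCh37"`.
#' @return an object of class `HaplotypeMatrix`.
#' @export
haplotype_matrix <- function(alleles, sites, build = "GRCh37") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  stopifnot(is.data.frame(sites), ncol(alleles) == nrow(sites))
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(sites)))
    stop("sites must contain columns: ", paste(req, collapse = ", "))
  nsite <- nrow(sites)
  if (is.null(sites$id)) sites$id <- paste0(sites$chrom, ":", sites$pos)
  if (is.null(sites$ancestral)) sites$ancestral <- rep(NA_character_, nsite)
  if (is.null(sites$polarized)) sites$polarized <- rep(FALSE, nsite)
  if (is.null(sites$ancestral_index)) sites$ancestral_index <- rep(NA_integer_, nsite)
  if (nrow(sites) > 1) {
    o <- order(sites$chrom, sites$pos)
    if (is.unsorted(o) || any(o != seq_len(nrow(sites)))) {
      sites <- sites[o, , drop = FALSE]
      alleles <- alleles[, o, drop = FALSE]
    }
    same <- sites$chrom[-1] == sites$chrom[-nrow(sites)]
    if (any(same & diff(sites$pos) < 0))
      stop("site positions must be non-decreasing within a chromosome")
  }
  if (nrow(alleles) %% 2L != 0L)
    stop("haplotype count must be even (phased diploid input)")
  bad <- which(alleles < 0L | alleles > 1L)
  if (length(bad)) stop("allele indices must be 0 or 1 for biallelic sites")
  if (is.null(rownames(alleles)))
    rownames(alleles) <- paste0("S", rep(seq_len(nrow(alleles) / 2), each = 2),
                                "_h", rep(1:2, nrow(alleles) / 2))
  rownames(sites) <- NULL
  structure(list(alleles = alleles, sites = sites, build = build),
            class = "HaplotypeMatrix")
}

#' @export
print.HaplotypeMatrix <- function(x, ...) {
  cat(sprintf("HaplotypeMatrix: %d haplotypes (%d samples) x %d sites [%s]\n",
              nrow(x$alleles), nrow(x$alleles) / 2, ncol(x$alleles), x$build))
  if (ncol(x$alleles) > 0)
    cat(sprintf("  %s:%s-%s; %d polarized sites\n", x$sites$chrom[1],
                format(min(x$sites$pos), big.mark = ","),
                format(max(x$sites$pos), big.mark = ","),
                sum(x$sites$polarized)))
  invisible(x)
}

#' @export
dim.HaplotypeMatrix <- function(x) dim(x$alleles)

#' Haplotype identifiers of a matrix
#' @param x a `HaplotypeMatrix`
#' @return character vector `<sample>_h1`, `<sample>_h2`, ...
#' @export
haplotype_ids <- function(x) rownames(x$alleles)

#' Sample identifiers of a matrix
#' @param x a `HaplotypeMatrix`
#' @return character vector of distinct sample ids, in row order
#' @export
sample_ids <- function(x) unique(sub("_h[12]$", "", rownames(x$alleles)))

#' Subset a HaplotypeMatrix by sites and/or haplotypes
#' @param x a `HaplotypeMatrix`
#' @param sites integer/logical index over sites
#' @param haplotypes integer/logical/character index over haplotype rows
#' @return a `HaplotypeMatrix`
#' @export
subset_sites <- function(x, sites = NULL, haplotypes = NULL) {
  al <- x$alleles
  st <- x$sites
  if (!is.null(sites)) {
    al <- al[, sites, drop = FALSE]
    st <- st[sites, , drop = FALSE]
  }
  if (!is.null(haplotypes)) al <- al[haplotypes, , drop = FALSE]
  out <- x
  out$alleles <- al
  out$sites <- st
  rownames(out$sites) <- NULL
  out
}

# parse "chr11:5,250,168-5,294,120" into list(chrom, start, end), 1-based
# inclusive as printed; internal arithmetic uses 0-based half-open.
parse_region <- function(region) {
  region <- gsub(",", "", region)
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("cannot parse region: ", region)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Restrict a matrix to a genomic region
#'
#' @param x a `HaplotypeMatrix`
#' @param region string `"chrom:start-end"`, 1-based inclusive coordinates as
#'   printed in VCF; commas are tolerated.
#' @return the restricted `HaplotypeMatrix`
#' @export
restrict_region <- function(x, region) {
  r <- parse_region(region)
  keep <- x$sites$chrom == r$chrom & x$sites$pos >= r$start & x$sites$pos <= r$end
  subset_sites(x, sites = keep)
}

#' Diploid genotype dosages from a phased matrix
#'
#' Pairs consecutive haplotype rows back into individuals and returns the
#' count of alt (or derived) alleles per sample per site.
#'
#' @param x a `HaplotypeMatrix`
#' @param allele `"alt"` (default) or `"derived"`; the latter requires
#'   polarized sites and returns NA columns where polarization failed.
#' @return integer matrix samples x sites with values 0/1/2
#' @export
genotype_dosage <- function(x, allele = c("alt", "derived")) {
  allele <- match.arg(allele)
  a <- x$alleles
  n <- nrow(a) / 2
  g <- a[seq(1, 2 * n, 2), , drop = FALSE] + a[seq(2, 2 * n, 2), , drop = FALSE]
  rownames(g) <- sample_ids(x)
  if (allele == "derived") {
    anc <- x$sites$ancestral_index
    flip <- which(!is.na(anc) & anc == 1L)
    g[, flip] <- 2L - g[, flip, drop = FALSE]
    g[, is.na(anc)] <- NA_integer_
  }
  g
}
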