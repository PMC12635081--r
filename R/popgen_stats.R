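#' Weir-Cockerham F_ST
#'
#' Per-site variance components a (among populations), b (among individuals
#' within populations) and c (within individuals), following Weir &
#' Cockerham (1984), with the multi-locus estimate as the ratio of sums
#' theta = sum(a) / sum(a + b + c). Negative per-site components are retained
#' in the sums (standard ratio-of-averages). Sites whose denominator is
#' undefined (monomorphic across all populations) are excluded and counted.
#'
#' @param x a `HaplotypeMatrix`
#' @param pop_labels population label per sample (in sample order)
#' @return list with `per_site` data.frame (`a`, `b`, `c`, `theta`),
#'   `theta_multi`, `n_excluded`, `populations`
#' @export
weir_cockerham_fst <- function(x, pop_labels) {
  g <- genotype_dosage(x)
  pop_labels <- as.character(pop_labels)
  if (length(pop_labels) != nrow(g))
    stop("pop_labels must have one entry per sample")
  pops <- unique(pop_labels)
  r <- length(pops)
  if (r < 2) stop("need at least 2 populations")
  if (any(table(factor(pop_labels, levels = pops)) == 0))
    stop("population with zero samples")
  m <- ncol(g)
  a <- b <- cc <- theta <- rep(NA_real_, m)
  for (jj in seq_len(m)) {
    comp <- wc_site_components(g[, jj], pop_labels, pops)
    a[jj] <- comp[1]; b[jj] <- comp[2]; cc[jj] <- comp[3]
    denom <- sum(comp)
    theta[jj] <- if (is.na(denom) || denom == 0) NA_real_ else comp[1] / denom
  }
  usable <- !is.na(a)
  theta_multi <- sum(a[usable]) / sum(a[usable] + b[usable] + cc[usable])
  list(per_site = data.frame(a = a, b = b, c = cc, theta = theta),
       theta_multi = theta_multi, n_excluded = sum(!usable),
       populations = pops)
}

# WC84 variance components for one biallelic site; g = dosage of the alt
# allele per individual. Returns c(a, b, c) or NAs when undefined.
wc_site_components <- function(g, pop_labels, pops) {
  r <- length(pops)
  ni <- pi <- hi <- numeric(r)
  for (k in seq_len(r)) {
    gk <- g[pop_labels == pops[k]]
    ni[k] <- length(gk)
    pi[k] <- mean(gk) / 2
    hi[k] <- mean(gk == 1L)
  }
  nbar <- mean(ni)
  if (nbar <= 1) return(c(NA_real_, NA_real_, NA_real_))
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi) / (r * nbar)
  if (pbar == 0 || pbar == 1) return(c(NA_real_, NA_real_, NA_real_))
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c(a, b, hbar / 2)
}

#' Pairwise F_ST matrix across populations
#'
#' @param x a `HaplotypeMatrix`
#' @param pop_labels population label per sample
#' @return symmetric matrix of pairwise multi-locus theta
#' @export
pairwise_fst_matrix <- function(x, pop_labels) {
  pops <- unique(as.character(pop_labels))
  r <- length(pops)
  fst <- matrix(0, r, r, dimnames = list(pops, pops))
  sid <- sample_ids(x)
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    keep <- pop_labels %in% pops[c(i, j)]
    rows <- rep(keep, each = 2)
    sub <- subset_sites(x, haplotypes = rows)
    fst[i, j] <- fst[j, i] <-
      weir_cockerham_fst(sub, pop_labels[keep])$theta_multi
  }
  fst
}

#' UPGMA population tree from an F_ST matrix
#'
#' Negative entries (possible under the Weir-Cockerham estimator) are clamped
#' to zero with a warning before clustering.
#'
#' @param fst_matrix symmetric pairwise F_ST matrix with population labels
#' @return a [upgma()] dendrogram over populations
#' @export
fst_upgma_tree <- function(fst_matrix) {
  fst_matrix <- as.matrix(fst_matrix)
  if (nrow(fst_matrix) != ncol(fst_matrix)) stop("F_ST matrix must be square")
  if (any(fst_matrix < 0)) {
    warning("negative F_ST entries clamped to 0 for tree building")
    fst_matrix[fst_matrix < 0] <- 0
  }
  diag(fst_matrix) <- 0
  upgma(fst_matrix)
}

#' Sliding-window nucleotide diversity
#'
#' theta_pi = mean number of pairwise differences between haplotypes per bp,
#' in windows of `window` bp advanced by `step` bp, anchored at the region
#' start; the final partial window is dropped.
#'
#' @param x a `HaplotypeMatrix`
#' @param window window size in bp (default 50,000)
#' @param step step size in bp (default 10,000)
#' @param region_start,region_end region bounds in bp; default to the span of
#'   the site table
#' @return data.frame with `start`, `end` (1-based inclusive), `n_sites`,
#'   `theta_pi` (per bp)
#' @export
theta_pi_windows <- function(x, window = 50000, step = 10000,
                             region_start = NULL, region_end = NULL) {
  pos <- x$sites$pos
  if (is.null(region_start)) region_start <- min(pos)
  if (is.null(region_end)) region_end <- max(pos)
  span <- region_end - region_start + 1
  if (window > span) stop("window exceeds the region length")
  n <- nrow(x$alleles)
  p <- colMeans(x$alleles)
  # per-site mean pairwise difference: 2*p*q * n/(n-1)
  site_pi <- 2 * p * (1 - p) * n / (n - 1)
  starts <- seq(region_start, region_end - window + 1, by = step)
  res <- data.frame(start = starts, end = starts + window - 1,
                    n_sites = NA_integer_, theta_pi = NA_real_)
  for (i in seq_along(starts)) {
    in_w <- pos >= res$start[i] & pos <= res$end[i]
    res$n_sites[i] <- sum(in_w)
    res$theta_pi[i] <- sum(site_pi[in_w]) / window
  }
  res
}

#' Mean pairwise differences among haplotype rows
#'
#' @param alleles 0/1 matrix, haplotypes x sites (or a `HaplotypeMatrix`)
#' @return mean number of differing sites over all haplotype pairs
#' @export
mean_pairwise_diff <- function(alleles) {
  if (inherits(alleles, "HaplotypeMatrix")) alleles <- alleles$alleles
  n <- nrow(alleles)
  if (n < 2) stop("need at least 2 haplotypes")
  cnt <- colSums(alleles)
  sum(cnt * (n - cnt)) / choose(n, 2)
}

#' Extended haplotype homozygosity
#'
#' EHH at a site x for a core allele is the probability that two randomly
#' chosen carrier chromosomes are identical over all sites between the core
#' and x: EHH(x) = sum_h C(n_h, 2) / C(n_c, 2), over the distinct extended
#' haplotypes h among the n_c carriers. Computed separately leftwards and
#' rightwards from the core; EHH(core) = 1 and the curve is non-increasing
#' with distance.
#'
#' @param x a `HaplotypeMatrix`
#' @param core_site site index of the core
#' @param core_allele allele index (0/1) defining the carrier set
#' @return data.frame with `site`, `pos`, `side` ("left"/"right"/"core"),
#'   `ehh`
#' @export
ehh_curve <- function(x, core_site, core_allele) {
  carriers <- which(x$alleles[, core_site] == core_allele)
  nc <- length(carriers)
  if (nc < 2) stop("fewer than 2 chromosomes carry the core allele")
  m <- ncol(x$alleles)
  a <- x$alleles[carriers, , drop = FALSE]
  ehh_at <- function(span) {
    key <- apply(a[, span, drop = FALSE], 1, paste, collapse = "")
    sum(choose(table(key), 2)) / choose(nc, 2)
  }
  res <- data.frame(site = core_site, pos = x$sites$pos[core_site],
                    side = "core", ehh = 1)
  if (core_site < m) for (j in (core_site + 1):m) {
    res <- rbind(res, data.frame(site = j, pos = x$sites$pos[j],
                                 side = "right", ehh = ehh_at(core_site:j)))
  }
  if (core_site > 1) for (j in (core_site - 1):1) {
    res <- rbind(res, data.frame(site = j, pos = x$sites$pos[j],
                                 side = "left", ehh = ehh_at(j:core_site)))
  }
  res[order(res$site), ]
}
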