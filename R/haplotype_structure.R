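#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the allele counts: the p-value is the
#' sum of probabilities of all heterozygote counts no more probable than the
#' observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts
#' @return the exact two-sided p-value
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  het <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  logp <- lfactorial(n) + het * log(2) + lfactorial(nA) + lfactorial(na) -
    lfactorial((nA - het) / 2) - lfactorial(het) - lfactorial((na - het) / 2) -
    lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, het)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

#' Select the block SNP panel
#'
#' Retains sites with minor allele frequency strictly above `maf_min` and
#' Hardy-Weinberg exact p strictly above `hwe_alpha` (computed from diploid
#' genotypes recovered by pairing phases), in genomic order.
#'
#' @param x a `HaplotypeMatrix`
#' @param maf_min minor-allele-frequency threshold (default 0.05, strict)
#' @param hwe_alpha HWE exact-test threshold (default 0.001, strict)
#' @return integer vector of retained site indices (possibly empty, with a
#'   warning)
#' @export
select_block_snps <- function(x, maf_min = 0.05, hwe_alpha = 0.001) {
  g <- genotype_dosage(x)
  n <- nrow(g)
  keep <- logical(ncol(g))
  for (j in seq_len(ncol(g))) {
    nAA <- sum(g[, j] == 0L)
    nAa <- sum(g[, j] == 1L)
    naa <- sum(g[, j] == 2L)
    p_alt <- (2 * naa + nAa) / (2 * n)
    maf <- min(p_alt, 1 - p_alt)
    keep[j] <- maf > maf_min && hwe_exact_test(nAA, nAa, naa) > hwe_alpha
  }
  if (!any(keep)) warning("no sites pass the MAF/HWE filters; empty panel")
  which(keep)
}

#' Catalog the distinct haplotypes over a SNP panel
#'
#' Collapses chromosomes to distinct allele strings over the panel, computes
#' frequencies, and names haplotypes H1, H2, ... in descending frequency for
#' those above the naming threshold. Frequency ties are broken by allele
#' string order with ancestral (or ref) alleles sorting first, so naming is
#' deterministic.
#'
#' @param x a `HaplotypeMatrix`
#' @param panel site indices (default: all sites)
#' @param naming_threshold minimum frequency for an H-name (default 0.002)
#' @return a `HaplotypeCatalog`: list with `panel`, `hap_alleles` (distinct
#'   haplotypes x panel allele matrix), `strings`, `p` (frequencies),
#'   `count`, `names` (H-labels, NA below threshold) and `assignment`
#'   (index into the catalog per chromosome, named by haplotype id)
#' @export
catalog_haplotypes <- function(x, panel = NULL, naming_threshold = 0.002) {
  if (is.null(panel)) panel <- seq_len(ncol(x$alleles))
  if (length(panel) == 0) stop("empty SNP panel")
  a <- x$alleles[, panel, drop = FALSE]
  # code alleles so that 0 = ancestral where polarization is known
  anc <- x$sites$ancestral_index[panel]
  flip <- which(!is.na(anc) & anc == 1L)
  a[, flip] <- 1L - a[, flip, drop = FALSE]
  strings <- apply(a, 1, paste, collapse = "")
  tab <- table(strings)
  uniq <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, uniq)
  uniq <- uniq[ord]
  cnt <- cnt[ord]
  p <- cnt / sum(cnt)
  nm <- rep(NA_character_, length(uniq))
  named <- which(p > naming_threshold)
  nm[named] <- paste0("H", seq_along(named))
  hap_alleles <- do.call(rbind, lapply(strsplit(uniq, ""), as.integer))
  assignment <- match(strings, uniq)
  names(assignment) <- rownames(x$alleles)
  structure(list(panel = panel, site_pos = x$sites$pos[panel],
                 hap_alleles = hap_alleles, strings = uniq, p = p,
                 count = cnt, names = nm, assignment = assignment,
                 naming_threshold = naming_threshold),
            class = "HaplotypeCatalog")
}

#' @export
print.HaplotypeCatalog <- function(x, ...) {
  cat(sprintf("HaplotypeCatalog: %d distinct haplotypes over %d sites (%d named, H1-H%d)\n",
              length(x$p), length(x$panel), sum(!is.na(x$names)),
              max(1, sum(!is.na(x$names)))))
  invisible(x)
}

#' Haplotype diversity
#'
#' H_d = 1 - sum(p_i^2) over the catalog's haplotype frequencies; the
#' uncorrected (no n/(n-1) factor) form.
#'
#' @param catalog a `HaplotypeCatalog`, or a numeric vector of frequencies
#' @return H_d in `[0, 1 - 1/k]`
#' @export
haplotype_diversity <- function(catalog) {
  p <- if (inherits(catalog, "HaplotypeCatalog")) catalog$p else catalog
  if (abs(sum(p) - 1) > 1e-8) stop("frequencies must sum to 1")
  1 - sum(p^2)
}

#' IBS distance matrix between haplotypes
#'
#' Identity-by-state distance = proportion of panel sites at which two
#' haplotypes carry different alleles (Hamming fraction).
#'
#' @param catalog a `HaplotypeCatalog` (or a 0/1 matrix of haplotypes x sites)
#' @return symmetric distance matrix in `[0, 1]`, labelled by H-names where
#'   available
#' @export
ibs_distance_matrix <- function(catalog) {
  a <- if (inherits(catalog, "HaplotypeCatalog")) catalog$hap_alleles else catalog
  if (nrow(a) < 2) stop("need at least 2 haplotypes")
  d <- as.matrix(stats::dist(a, method = "manhattan")) / ncol(a)
  lbl <- if (inherits(catalog, "HaplotypeCatalog")) {
    ifelse(is.na(catalog$names), paste0("hap", seq_len(nrow(a))), catalog$names)
  } else if (!is.null(rownames(a))) rownames(a) else paste0("hap", seq_len(nrow(a)))
  dimnames(d) <- list(lbl, lbl)
  d
}

#' UPGMA clustering
#'
#' Unweighted pair group method with arithmetic mean: repeatedly joins the
#' closest pair of clusters at half their distance, updating distances as the
#' size-weighted average of the merged members. Ties are broken toward the
#' lexicographically first pair for determinism. The result is ultrametric
#' (non-decreasing merge heights) and `hclust`-compatible, so
#' [stats::cutree()] and plotting work.
#'
#' @param d symmetric distance matrix with labels, or a `dist`
#' @return an object of class `c("haplo_dendrogram", "hclust")`
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 labels to cluster")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("L", 1:n)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  size <- rep(1L, n)
  id <- -(1:n)                      # hclust convention: negatives = leaves
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  act <- 1:n
  D <- d
  for (s in seq_len(n - 1)) {
    m <- length(act)
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      v <- D[act[i], act[j]]
      if (v < bd - 1e-15) { bd <- v; best <- c(i, j) }
    }
    i <- act[best[1]]; j <- act[best[2]]
    merge[s, ] <- sort(c(id[i], id[j]))
    height[s] <- bd / 2
    # size-weighted average update
    for (x in setdiff(act, c(i, j))) {
      D[i, x] <- D[x, i] <- (size[i] * D[i, x] + size[j] * D[j, x]) /
        (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    id[i] <- s
    act <- setdiff(act, j)
  }
  hc <- structure(list(merge = merge, height = height,
                       order = integer(n), labels = labels,
                       method = "average", call = match.call(),
                       dist.method = "ibs"),
                  class = c("haplo_dendrogram", "hclust"))
  hc$order <- order_leaves(merge, n)
  hc
}

# leaf ordering for plotting: left-to-right traversal of the merge tree
order_leaves <- function(merge, n) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(n - 1)
}

#' Assign haplogroup labels by cutting the dendrogram
#'
#' Cuts the UPGMA dendrogram into `k` clusters and labels them HG1..HGk in
#' descending order of total chromosome frequency, so the largest clade is
#' always HG1.
#'
#' @param dend a [upgma()] dendrogram over catalog haplotypes
#' @param k number of haplogroups (default 3)
#' @param weights chromosome frequency (or count) per leaf, in leaf-label
#'   order; defaults to equal weights
#' @return named character vector of `HG` labels, one per leaf
#' @export
assign_haplogroups <- function(dend, k = 3, weights = NULL) {
  if (k < 1) stop("k must be >= 1")
  n <- length(dend$labels)
  if (k > n) stop("k exceeds the number of leaves")
  cl <- stats::cutree(dend, k = k)
  if (is.null(weights)) weights <- rep(1, n)
  tot <- tapply(weights, cl, sum)
  ord <- order(-tot, as.integer(names(tot)))
  relabel <- stats::setNames(paste0("HG", seq_len(k)), names(tot)[ord])
  out <- unname(relabel[as.character(cl)])
  names(out) <- dend$labels
  out
}

#' Mutation-by-haplotype cross-tabulation
#'
#' Counts carrier chromosomes per (mutation, haplotype) and per (mutation,
#' haplogroup), and classifies each mutation by the number of distinct
#' haplogroups its carriers occupy (sharing class 1, 2, or 3).
#'
#' @param catalog a `HaplotypeCatalog`
#' @param carriers named list: mutation label -> character vector of carrier
#'   chromosome (haplotype) ids
#' @param haplogroups haplogroup label per catalog haplotype, as returned by
#'   [assign_haplogroups()] (in catalog order)
#' @return list with `by_haplotype` and `by_haplogroup` count tables and a
#'   `sharing_class` vector per mutation
#' @export
mutation_haplotype_crosstab <- function(catalog, carriers, haplogroups) {
  stopifnot(inherits(catalog, "HaplotypeCatalog"))
  hap_of <- function(ids) {
    idx <- catalog$assignment[ids]
    if (anyNA(idx))
      stop("carrier chromosomes absent from catalog: ",
           paste(ids[is.na(idx)], collapse = ", "))
    idx
  }
  hap_lab <- ifelse(is.na(catalog$names),
                    paste0("hap", seq_along(catalog$names)), catalog$names)
  muts <- names(carriers)
  by_hap <- matrix(0L, length(muts), length(hap_lab),
                   dimnames = list(muts, hap_lab))
  for (m in muts) {
    t <- table(hap_of(carriers[[m]]))
    by_hap[m, as.integer(names(t))] <- as.integer(t)
  }
  hg_levels <- sort(unique(haplogroups))
  by_hg <- matrix(0L, length(muts), length(hg_levels),
                  dimnames = list(muts, hg_levels))
  for (m in muts) {
    hg <- haplogroups[hap_of(carriers[[m]])]
    t <- table(hg)
    by_hg[m, names(t)] <- as.integer(t)
  }
  sharing <- apply(by_hg, 1, function(r) sum(r > 0))
  list(by_haplotype = by_hap, by_haplogroup = by_hg,
       sharing_class = sharing)
}
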