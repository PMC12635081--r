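#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Computes the gametic covariance D, its normalization D' = |D| / D_max and
#' the squared correlation r^2 between two biallelic sites, directly from
#' phased gamete counts.
#'
#' @param x a `HaplotypeMatrix`
#' @param site_i,site_j site indices
#' @return list with `D`, `D_prime`, `r2`, `n_chrom`
#' @export
ld_pair <- function(x, site_i, site_j) {
  a <- x$alleles[, site_i]
  b <- x$alleles[, site_j]
  ld_from_gametes(a, b)
}

ld_from_gametes <- function(a, b) {
  pA <- mean(a)
  pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("monomorphic site: LD is undefined")
  pAB <- mean(a == 1L & b == 1L)
  D <- pAB - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else        min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D,
       D_prime = if (Dmax == 0) 0 else abs(D) / Dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       n_chrom = length(a))
}

# D' over all pairs among the given (polymorphic) site columns
dprime_matrix <- function(alleles) {
  m <- ncol(alleles)
  dp <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    dp[i, j] <- dp[j, i] <- ld_from_gametes(alleles[, i], alleles[, j])$D_prime
  }
  diag(dp) <- 1
  dp
}

# bootstrap percentile CI of D' over chromosomes
dprime_ci <- function(a, b, n_boot = 200, conf = 0.95, seed = 0L) {
  n <- length(a)
  set.seed(seed)
  reps <- numeric(n_boot)
  for (r in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    ar <- a[idx]; br <- b[idx]
    reps[r] <- if (mean(ar) %in% c(0, 1) || mean(br) %in% c(0, 1)) NA_real_
               else ld_from_gametes(ar, br)$D_prime
  }
  reps <- reps[!is.na(reps)]
  alpha <- (1 - conf) / 2
  stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
}

#' Detect haplotype blocks
#'
#' Rule-based block detection over the polymorphic sites of the matrix, by
#' one of three methods:
#' \describe{
#'   \item{four_gamete}{maximal intervals in which no marker pair exhibits
#'     all four gametes at frequency >= `fourth_gamete_min` (default 0.01).}
#'   \item{gabriel_ci}{intervals where at least `strong_frac` (default 0.95)
#'     of informative pairs have a bootstrap D' CI with lower bound >= 0.70
#'     and upper bound >= 0.98 (pairs with CI upper < 0.90 count as evidence
#'     of recombination; others are uninformative).}
#'   \item{solid_spine}{intervals whose first and last markers each have
#'     D' >= `spine_dprime` (default 0.8) with every marker between them.}
#' }
#' Blocks contain at least two markers, never overlap, and are reported in
#' genomic order.
#'
#' @param x a `HaplotypeMatrix`
#' @param method one of `"four_gamete"`, `"gabriel_ci"`, `"solid_spine"`
#' @param fourth_gamete_min minimum gamete frequency counting as a real
#'   fourth gamete
#' @param strong_frac Gabriel strong-pair fraction
#' @param ci_lower,ci_upper Gabriel strong-LD CI thresholds
#' @param recomb_upper Gabriel recombination-evidence CI upper bound
#' @param spine_dprime solid-spine D' threshold
#' @param n_boot bootstrap resamples for the Gabriel CI
#' @param seed seed for the bootstrap
#' @return data.frame of blocks: `start_site`, `end_site` (indices into the
#'   matrix, inclusive), `start_pos`, `end_pos`, `span_bp`, `n_sites`,
#'   `method`
#' @export
detect_blocks <- function(x, method = c("four_gamete", "gabriel_ci", "solid_spine"),
                          fourth_gamete_min = 0.01, strong_frac = 0.95,
                          ci_lower = 0.70, ci_upper = 0.98, recomb_upper = 0.90,
                          spine_dprime = 0.8, n_boot = 200, seed = 0L) {
  method <- match.arg(method)
  freq <- colMeans(x$alleles)
  poly <- which(freq > 0 & freq < 1)
  if (length(poly) < 2)
    return(empty_blocks(method))
  al <- x$alleles[, poly, drop = FALSE]
  m <- length(poly)

  # pair compatibility matrix: TRUE when the pair may share a block
  ok <- matrix(TRUE, m, m)
  if (method == "four_gamete") {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      g <- c(mean(al[, i] == 0 & al[, j] == 0), mean(al[, i] == 0 & al[, j] == 1),
             mean(al[, i] == 1 & al[, j] == 0), mean(al[, i] == 1 & al[, j] == 1))
      ok[i, j] <- ok[j, i] <- sum(g >= fourth_gamete_min) < 4
    }
    blocks <- greedy_intervals(ok)
  } else if (method == "solid_spine") {
    dp <- dprime_matrix(al)
    blocks <- spine_intervals(dp, spine_dprime)
  } else {
    cls <- matrix(NA_character_, m, m)   # "strong" / "recomb" / NA
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      ci <- dprime_ci(al[, i], al[, j], n_boot = n_boot,
                      seed = seed + 1000L * i + j)
      cls[i, j] <- cls[j, i] <-
        if (ci[1] >= ci_lower && ci[2] >= ci_upper) "strong"
        else if (ci[2] < recomb_upper) "recomb" else NA_character_
    }
    blocks <- gabriel_intervals(cls, strong_frac)
  }
  if (nrow(blocks) == 0) return(empty_blocks(method))
  data.frame(start_site = poly[blocks$s], end_site = poly[blocks$e],
             start_pos = x$sites$pos[poly[blocks$s]],
             end_pos = x$sites$pos[poly[blocks$e]],
             span_bp = x$sites$pos[poly[blocks$e]] - x$sites$pos[poly[blocks$s]] + 1L,
             n_sites = blocks$e - blocks$s + 1L,
             method = method, stringsAsFactors = FALSE)
}

empty_blocks <- function(method) {
  data.frame(start_site = integer(0), end_site = integer(0),
             start_pos = integer(0), end_pos = integer(0),
             span_bp = integer(0), n_sites = integer(0),
             method = character(0), stringsAsFactors = FALSE)
}

# maximal left-to-right intervals whose internal pairs are all compatible
greedy_intervals <- function(ok) {
  m <- nrow(ok)
  s <- 1L
  res <- list()
  while (s < m) {
    e <- s
    while (e < m && all(ok[s:e, e + 1L])) e <- e + 1L
    if (e > s) res[[length(res) + 1L]] <- c(s = s, e = e)
    s <- e + 1L
  }
  as.data.frame(do.call(rbind, res))
}

spine_intervals <- function(dp, thr) {
  m <- nrow(dp)
  res <- list()
  s <- 1L
  while (s < m) {
    beste <- s
    for (e in (s + 1L):m) {
      inner <- s:e
      if (all(dp[s, inner[-1]] >= thr) && all(dp[inner[-length(inner)], e] >= thr))
        beste <- e
    }
    if (beste > s) {
      res[[length(res) + 1L]] <- c(s = s, e = beste)
      s <- beste + 1L
    } else s <- s + 1L
  }
  as.data.frame(do.call(rbind, res))
}

gabriel_intervals <- function(cls, strong_frac) {
  m <- nrow(cls)
  res <- list()
  s <- 1L
  frac_ok <- function(s, e) {
    v <- cls[s:e, s:e][upper.tri(matrix(0, e - s + 1, e - s + 1))]
    ns <- sum(v == "strong", na.rm = TRUE)
    ni <- sum(!is.na(v))
    ni > 0 && ns / ni >= strong_frac
  }
  while (s < m) {
    beste <- s
    for (e in (s + 1L):m) if (frac_ok(s, e)) beste <- e
    if (beste > s) {
      res[[length(res) + 1L]] <- c(s = s, e = beste)
      s <- beste + 1L
    } else s <- s + 1L
  }
  as.data.frame(do.call(rbind, res))
}

#' Merge adjacent blocks in strong linkage
#'
#' Adjacent blocks are merged when the inter-block linkage -- the mean |D'|
#' over all cross-block marker pairs -- strictly exceeds the threshold,
#' sweeping left to right until no further merge applies.
#'
#' @param blocks block table from [detect_blocks()] (sorted, non-overlapping)
#' @param x the `HaplotypeMatrix` the blocks were detected on
#' @param linkage_threshold merge threshold (default 0.8, strict `>`)
#' @return merged block table
#' @export
merge_blocks <- function(blocks, x, linkage_threshold = 0.8) {
  if (nrow(blocks) < 2) return(blocks)
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(blocks)) {
      s1 <- blocks$start_site[i]:blocks$end_site[i]
      s2 <- blocks$start_site[i + 1]:blocks$end_site[i + 1]
      dps <- outer(s1, s2, Vectorize(function(a, b) ld_pair(x, a, b)$D_prime))
      if (mean(dps) > linkage_threshold) {
        blocks$end_site[i] <- blocks$end_site[i + 1]
        blocks$end_pos[i] <- blocks$end_pos[i + 1]
        blocks$span_bp[i] <- blocks$end_pos[i] - blocks$start_pos[i] + 1L
        blocks$n_sites[i] <- blocks$n_sites[i] + blocks$n_sites[i + 1]
        blocks <- blocks[-(i + 1), , drop = FALSE]
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  rownames(blocks) <- NULL
  blocks
}

#' Write blocks as BED (0-based half-open)
#' @param blocks block table from [detect_blocks()]
#' @param chrom chromosome label
#' @param path output path
#' @return `path`, invisibly
#' @export
write_blocks_bed <- function(blocks, chrom, path) {
  bed <- data.frame(chrom = chrom, start = blocks$start_pos - 1L,
                    end = blocks$end_pos,
                    name = paste0(blocks$method, "_block", seq_len(nrow(blocks))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
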