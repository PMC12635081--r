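# in-code fixtures and independent oracles shared across test files

# small HaplotypeMatrix from an explicit 0/1 matrix; positions 1 bp apart
# unless given
fix_matrix <- function(alleles, pos = NULL, chrom = "chr11", anc_ref = TRUE) {
  alleles <- as.matrix(alleles)
  m <- ncol(alleles)
  if (is.null(pos)) pos <- seq_len(m)
  sites <- data.frame(chrom = chrom, pos = pos,
                      id = paste0("s", seq_len(m)),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  x <- haplotype_matrix(alleles, sites)
  if (anc_ref) x <- polarize_alleles(x, stats::setNames(rep("A", m), pos))
  x
}

# random phased matrix: n diploid samples, m sites, allele freqs drawn
# uniformly; guaranteed polymorphic columns
rand_matrix <- function(n, m, seed) {
  set.seed(seed)
  repeat {
    p <- runif(m, 0.1, 0.9)
    a <- sapply(p, function(q) rbinom(2 * n, 1, q))
    if (all(colMeans(a) > 0 & colMeans(a) < 1)) break
  }
  fix_matrix(a)
}

# --- independent oracles ---------------------------------------------------

# HWE exact p by direct enumeration over heterozygote counts (independent
# arithmetic: products of factorials via prod(), not lgamma recurrences)
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  prob <- function(het) {
    hom1 <- (nA - het) / 2
    hom2 <- (na - het) / 2
    exp(lfactorial(n) - lfactorial(hom1) - lfactorial(het) - lfactorial(hom2) +
          het * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  }
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  ps <- vapply(hets, prob, numeric(1))
  obs <- ps[match(nAa, hets)]
  sum(ps[ps <= obs * (1 + 1e-7)]) / sum(ps)
}

# Weir-Cockerham theta for a single biallelic site, written out long-hand
# from the 1984 definitions (independent of the package's vectorized code)
oracle_wc_theta <- function(geno_by_pop) {
  r <- length(geno_by_pop)
  n_i <- sapply(geno_by_pop, length)
  p_i <- sapply(geno_by_pop, function(g) sum(g) / (2 * length(g)))
  h_i <- sapply(geno_by_pop, function(g) mean(g == 1))
  n_bar <- sum(n_i) / r
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  a <- (n_bar / n_c) * (s2 - 1 / (n_bar - 1) *
                          (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- n_bar / (n_bar - 1) * (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
                                (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# brute-force UPGMA: recompute full average distance between clusters from
# the raw matrix at every step (no incremental update)
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      v <- mean(d[clusters[[i]], clusters[[j]]])
      if (v < bd - 1e-15) { bd <- v; best <- c(i, j) }
    }
    heights <- c(heights, bd / 2)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# union-of-all-MSTs oracle: edge (u,v) belongs to the MSN iff u and v lie in
# different components of the graph using only edges strictly shorter
oracle_msn_edges <- function(d) {
  n <- nrow(d)
  edges <- list()
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    w <- d[u, v]
    # components under edges with weight < w
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (d[i, j] < w && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (comp[u] != comp[v]) edges[[length(edges) + 1]] <- c(u, v)
  }
  edges
}

# single-population coalescent pairwise-difference simulator used as a
# closed-form check (independent of the package engine): returns a 0/1
# matrix of n haplotypes for a panmictic population
sim_panmictic <- function(n, Ne, mu, L, seed) {
  set.seed(seed)
  cfg <- sim_config(n_samples_per_pop = n / 2, pop_labels = "P",
                    pop_latitudes = c(P = 20), clade_split_times = numeric(0),
                    clade_freqs = 1, latitude_slope = 0,
                    effective_size = Ne, mutation_rate = mu,
                    region_length = L, seed = seed)
  simulate_three_clade_locus(cfg)
}
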