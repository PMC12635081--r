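#' Simulation configuration for the synthetic locus cohort
#'
#' Describes the stated world the generator emulates: a single strong-LD
#' block at a disease locus carrying three deeply diverged haplotype clades,
#' sampled across several geographic populations whose clade-2 frequency
#' rises with latitude. Split times default to the block's published clade
#' structure (outer split 606.8 KYA, inner split 306.7 KYA); the per-clade
#' effective size defaults to 3,400 diploids so that the expected within-clade
#' TMRCA (4N_e generations = 340 KY) matches the published within-clade
#' coalescence depth.
#'
#' @param n_samples_per_pop diploid samples per population
#' @param pop_labels population identifiers (defaults to five province codes)
#' @param pop_latitudes named numeric, degrees north, one per population
#' @param clade_split_times years before present, strictly decreasing outer to
#'   inner; `length = n_clades - 1`
#' @param clade_freqs baseline clade frequencies (sum to 1); clade 2 receives
#'   the latitude gradient
#' @param latitude_slope increase in clade-2 frequency per degree latitude
#'   (fraction per degree); other clades are rescaled proportionally
#' @param effective_size diploid N_e per clade (and ancestrally)
#' @param mutation_rate per-base per-generation
#' @param region_length bp
#' @param region_start 1-based genomic start of the block
#' @param chrom chromosome label
#' @param generation_time years
#' @param recombination_rate per-base per-generation; only 0 is supported
#'   (the block is modeled as recombination-free)
#' @param seed integer seed; required, no hidden global randomness
#' @return a `SimConfig` list
#' @export
sim_config <- function(n_samples_per_pop = 50,
                       pop_labels = c("GX", "GD", "YN", "GZ", "HN"),
                       pop_latitudes = c(GX = 23.8, GD = 23.4, YN = 25.0,
                                         GZ = 26.6, HN = 19.2),
                       clade_split_times = c(606800, 306700),
                       clade_freqs = c(0.80, 0.12, 0.08),
                       latitude_slope = 0.00275,
                       effective_size = 3400,
                       mutation_rate = 1.25e-8,
                       region_length = 43950,
                       region_start = 5250168,
                       chrom = "chr11",
                       generation_time = 25,
                       recombination_rate = 0,
                       seed = 1L) {
  if (effective_size <= 0) stop("effective_size must be positive")
  if (region_length <= 0) stop("region_length must be positive")
  if (mutation_rate < 0 || recombination_rate < 0 || generation_time <= 0)
    stop("rates must be non-negative and generation_time positive")
  if (length(clade_split_times) > 1 && any(diff(clade_split_times) >= 0))
    stop("clade_split_times must be strictly decreasing, outer to inner")
  if (recombination_rate != 0)
    stop("recombination within the block is not modeled; recombination_rate must be 0")
  if (abs(sum(clade_freqs) - 1) > 1e-8) stop("clade_freqs must sum to 1")
  if (!all(pop_labels %in% names(pop_latitudes)) && length(clade_split_times) > 0
      && latitude_slope != 0)
    stop("pop_latitudes must cover every population when latitude_slope != 0")
  structure(list(n_samples_per_pop = n_samples_per_pop,
                 pop_labels = pop_labels, pop_latitudes = pop_latitudes,
                 clade_split_times = clade_split_times,
                 clade_freqs = clade_freqs, latitude_slope = latitude_slope,
                 effective_size = effective_size,
                 mutation_rate = mutation_rate,
                 region_length = region_length, region_start = region_start,
                 chrom = chrom, generation_time = generation_time,
                 recombination_rate = recombination_rate,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# Neutral coalescent with deme (clade) splits; time in generations, backwards.
# tip_demes: integer clade label per tip. merge_times: generations, ascending;
# at merge_times[j] deme (j+1 counted from the inner end) folds into its
# neighbor -- with splits s_outer > s_inner the schedule is: at s_inner demes
# 2..k collapse stepwise from the innermost pair. Returns parent/node-time
# arrays of a binary tree with tips 1..n.
coalescent_tree <- function(tip_demes, Ne, merge_times_gen) {
  n <- length(tip_demes)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n)              # node indices of live lineages
  deme <- tip_demes                 # deme of each live lineage
  nxt <- n + 1L
  t <- 0
  # merge schedule: ascending times; at time m[j], the two innermost remaining
  # demes fuse (deme labels above the fuse point relabelled down)
  mt <- sort(merge_times_gen)
  k_demes <- length(unique(tip_demes))
  ev <- 0L
  while (length(active) > 1L) {
    ks <- table(factor(deme, levels = sort(unique(deme))))
    rates <- ks * (ks - 1) / 2 / (2 * Ne)
    tot <- sum(rates)
    wait <- if (tot > 0) stats::rexp(1, tot) else Inf
    if (ev < length(mt) && t + wait > mt[ev + 1L]) {
      t <- mt[ev + 1L]
      ev <- ev + 1L
      # fold the highest-numbered remaining deme into the next one down
      dl <- sort(unique(deme))
      hi <- max(dl)
      lo <- if (length(dl) >= 2) sort(dl)[length(dl) - 1L] else hi
      deme[deme == hi] <- lo
      next
    }
    t <- t + wait
    d_pick <- sample(rep(names(rates), 1), 1, prob = as.numeric(rates))
    idx <- which(deme == as.integer(d_pick))
    pair <- if (length(idx) == 2) idx else sample(idx, 2)
    node_time[nxt] <- t
    parent[active[pair]] <- nxt
    active <- c(active[-pair], nxt)
    deme <- c(deme[-pair], as.integer(d_pick))
    nxt <- nxt + 1L
  }
  list(parent = parent, node_time = node_time, n_tips = n,
       root = active[1])
}

# Drop infinite-sites mutations on a tree; returns list(positions, carriers)
# where carriers[[j]] is the set of tips below mutation j.
drop_mutations <- function(tree, mu, L) {
  n <- tree$n_tips
  n_nodes <- 2L * n - 1L
  # tips below each node
  below <- vector("list", n_nodes)
  for (i in seq_len(n)) below[[i]] <- i
  ord <- order(tree$node_time[(n + 1L):n_nodes])
  for (v in (n + ord)) {
    kids <- which(tree$parent == v)
    below[[v]] <- unlist(below[kids])
  }
  blen <- ifelse(tree$parent > 0,
                 tree$node_time[pmax(tree$parent, 1)] - tree$node_time,
                 0)
  blen[tree$parent == 0] <- 0
  nmut <- stats::rpois(n_nodes, mu * L * blen)
  tot <- sum(nmut)
  if (tot == 0) return(list(positions = integer(0), carriers = list()))
  if (tot > L) stop("more mutations than sites; increase region_length")
  pos <- sort(sample.int(L, tot))
  # assign positions to branches in a fixed order for determinism
  branch_of <- rep(seq_len(n_nodes), nmut)
  perm <- sample.int(tot)           # shuffle so position ~ branch is random
  branch_of <- branch_of[perm]
  carriers <- lapply(branch_of, function(b) below[[b]])
  list(positions = pos, carriers = carriers)
}

#' Simulate a three-clade haplotype block cohort
#'
#' Generates phased haplotypes for a recombination-free block under a neutral
#' coalescent with clade splits, together with a sample table. Each sampled
#' chromosome is assigned a true clade (recorded in the result's provenance)
#' drawn from population-specific clade frequencies; mutations accumulate on
#' the genealogy under the infinite-sites model at `mutation_rate`.
#'
#' @param cfg a [sim_config()]
#' @return list with elements `matrix` (a polarized [haplotype_matrix()]),
#'   `samples` (sample table: sample_id, population, latitude, ethnicity, sex,
#'   mutation), `true_clade` (integer per chromosome, named by haplotype id)
#'   and `provenance` (the config)
#' @export
simulate_three_clade_locus <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  k <- length(cfg$clade_freqs)
  pops <- rep(cfg$pop_labels, each = cfg$n_samples_per_pop)
  n <- length(pops)
  lat <- cfg$pop_latitudes[pops]
  # latitude-adjusted clade frequencies (gradient on clade 2)
  freq_for <- function(l) {
    f <- cfg$clade_freqs
    if (k >= 2 && cfg$latitude_slope != 0 && !is.na(l)) {
      f2 <- max(0.001, min(0.98, f[2] + cfg$latitude_slope * (l - mean(cfg$pop_latitudes))))
      rest <- f[-2] / sum(f[-2]) * (1 - f2)
      f <- append(rest, f2, after = 1)
    }
    f
  }
  chrom_clade <- integer(2 * n)
  for (i in seq_len(n)) {
    f <- freq_for(lat[i])
    chrom_clade[c(2 * i - 1, 2 * i)] <- sample.int(k, 2, replace = TRUE, prob = f)
  }
  gens <- cfg$clade_split_times / cfg$generation_time
  tree <- coalescent_tree(chrom_clade, cfg$effective_size, gens)
  mut <- drop_mutations(tree, cfg$mutation_rate, cfg$region_length)

  sample_id <- sprintf("%s_%04d", pops, stats::ave(seq_len(n), pops, FUN = seq_along))
  hap_ids <- paste0(rep(sample_id, each = 2), "_h", rep(1:2, n))

  m <- length(mut$positions)
  al <- matrix(0L, nrow = 2 * n, ncol = m)
  for (j in seq_len(m)) al[mut$carriers[[j]], j] <- 1L
  rownames(al) <- hap_ids

  bases <- c("A", "C", "G", "T")
  anc_base <- if (m) sample(bases, m, replace = TRUE) else character(0)
  der_base <- vapply(anc_base, function(b) sample(setdiff(bases, b), 1), "")
  # a fraction of sites get REF = derived base to exercise polarization
  swap <- if (m) stats::runif(m) < 0.3 else logical(0)
  ref <- ifelse(swap, der_base, anc_base)
  alt <- ifelse(swap, anc_base, der_base)
  al[, swap] <- 1L - al[, swap, drop = FALSE]
  sites <- data.frame(chrom = rep(cfg$chrom, m),
                      pos = cfg$region_start + mut$positions - 1L,
                      id = sprintf("sim%d", seq_len(m)),
                      ref = as.character(ref), alt = as.character(alt),
                      stringsAsFactors = FALSE)
  mat <- haplotype_matrix(al, sites, build = "GRCh37")
  mat <- polarize_alleles(mat, stats::setNames(anc_base, sites$pos))

  samples <- data.frame(sample_id = sample_id, population = pops,
                        latitude = unname(lat),
                        ethnicity = ifelse(pops == "HN" & stats::runif(n) < 0.2,
                                           "Li", "Han"),
                        sex = sample(c("M", "F"), n, replace = TRUE),
                        mutation = "none", stringsAsFactors = FALSE)
  names(chrom_clade) <- hap_ids
  list(matrix = mat, samples = samples, true_clade = chrom_clade,
       provenance = cfg)
}

#' Plant a disease mutation on a haplotype background
#'
#' Adds one new biallelic site whose derived allele occurs only on copies of
#' a chosen background haplotype, at the requested allele frequency (rounded
#' to the nearest achievable chromosome count). This reproduces the
#' mutation-on-haplotype linkage structure that the downstream cross-tab and
#' dating analyses dissect.
#'
#' @param x a `HaplotypeMatrix`
#' @param catalog a [catalog_haplotypes()] of `x`; defaults to a catalog over
#'   all sites
#' @param background name of the background haplotype (e.g. `"H1"`)
#' @param target_allele_freq desired derived-allele frequency among all
#'   chromosomes; must not exceed the background haplotype's frequency
#' @param label mutation label written to the carrier table (e.g. `"CD41/42"`)
#' @param position 1-based position for the new site; defaults to one past
#'   the rightmost existing site
#' @param seed integer seed for the carrier draw
#' @return list(`matrix` = augmented matrix, `carriers` = haplotype ids
#'   carrying the derived allele, `label` = label)
#' @export
plant_mutation <- function(x, catalog = NULL, background, target_allele_freq,
                           label = "mut", position = NULL, seed = 1L) {
  if (is.null(catalog)) catalog <- catalog_haplotypes(x)
  if (!background %in% catalog$names)
    stop("background haplotype not found in catalog: ", background)
  if (target_allele_freq < 0 || target_allele_freq > 1)
    stop("target_allele_freq must be in [0, 1]")
  bg_freq <- catalog$p[match(background, catalog$names)]
  if (target_allele_freq > bg_freq + 1e-12)
    stop(sprintf("target frequency %.4g exceeds background haplotype frequency %.4g",
                 target_allele_freq, bg_freq))
  n_chrom <- nrow(x$alleles)
  n_want <- round(target_allele_freq * n_chrom)
  bg_chroms <- names(catalog$assignment)[catalog$assignment ==
                                           match(background, catalog$names)]
  n_want <- min(n_want, length(bg_chroms))
  set.seed(seed)
  carriers <- if (n_want > 0) sort(sample(bg_chroms, n_want)) else character(0)
  col <- integer(n_chrom)
  col[match(carriers, rownames(x$alleles))] <- 1L
  if (is.null(position)) {
    used <- x$sites$pos
    position <- max(used, 0) + 1L
  }
  site <- data.frame(chrom = x$sites$chrom[1], pos = position,
                     id = paste0("planted_", gsub("[^A-Za-z0-9]", "_", label)),
                     ref = "C", alt = "T", ancestral = "C",
                     polarized = TRUE, ancestral_index = 0L,
                     stringsAsFactors = FALSE)
  out <- x
  out$alleles <- cbind(x$alleles, col)
  colnames(out$alleles) <- NULL
  out$sites <- rbind(x$sites, site)
  out <- haplotype_matrix(out$alleles, out$sites, build = x$build)
  list(matrix = out, carriers = carriers, label = label)
}

#' Phenotype-effect configuration
#'
#' @param baseline_mean named numeric: trait baselines (`HGB` in g/L, `HbF`
#'   in percent)
#' @param baseline_sd named numeric: trait standard deviations
#' @param haplogroup_effect named numeric: standardized shift (in units of
#'   baseline_sd) applied to homozygotes of the designated haplogroup
#' @param designated_haplogroup label receiving the effect (default `"HG2"`)
#' @param sex_effect named numeric: additive shift for males, per trait
#' @param survival_baseline_hazard events per year
#' @param survival_hazard_ratio hazard multiplier for designated-haplogroup
#'   homozygotes
#' @param censoring_time years of follow-up
#' @param seed integer seed
#' @return a `PhenotypeEffectConfig` list
#' @export
phenotype_config <- function(baseline_mean = c(HGB = 135, HbF = 1.0),
                             baseline_sd = c(HGB = 14, HbF = 0.3),
                             haplogroup_effect = c(HGB = 0.30, HbF = 0.35),
                             designated_haplogroup = "HG2",
                             sex_effect = c(HGB = 12, HbF = 0),
                             survival_baseline_hazard = 0.15,
                             survival_hazard_ratio = 0.5,
                             censoring_time = 10,
                             seed = 1L) {
  if (any(baseline_sd <= 0)) stop("baseline sds must be positive")
  if (survival_baseline_hazard <= 0 || survival_hazard_ratio <= 0)
    stop("hazards must be positive")
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 haplogroup_effect = haplogroup_effect,
                 designated_haplogroup = designated_haplogroup,
                 sex_effect = sex_effect,
                 survival_baseline_hazard = survival_baseline_hazard,
                 survival_hazard_ratio = survival_hazard_ratio,
                 censoring_time = censoring_time, seed = as.integer(seed)),
            class = "PhenotypeEffectConfig")
}

#' Simulate haplogroup-dependent phenotypes
#'
#' Draws HGB and HbF from normal baselines, shifting homozygotes of the
#' designated haplogroup by `haplogroup_effect` standard deviations, and
#' transfusion-free survival from an exponential proportional-hazards model
#' right-censored at `censoring_time`. HbF is floored at 0.
#'
#' @param samples sample table with `sample_id` and `sex`
#' @param haplogroup_calls named character vector: diplotype label per sample,
#'   e.g. `"HG2/HG2"`; every sample must be present
#' @param cfg a [phenotype_config()]
#' @return the sample table with `haplogroup`, `HGB`, `HbF`, `surv_time`,
#'   `surv_event` columns appended
#' @export
simulate_phenotypes <- function(samples, haplogroup_calls, cfg) {
  stopifnot(inherits(cfg, "PhenotypeEffectConfig"))
  miss <- setdiff(samples$sample_id, names(haplogroup_calls))
  if (length(miss))
    stop("missing haplogroup call for samples: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
  set.seed(cfg$seed)
  dip <- unname(haplogroup_calls[samples$sample_id])
  hg <- cfg$designated_haplogroup
  homo <- dip == paste(hg, hg, sep = "/")
  n <- nrow(samples)
  male <- samples$sex == "M"
  draw <- function(trait) {
    mu <- cfg$baseline_mean[[trait]] +
      ifelse(male, cfg$sex_effect[[trait]], 0) +
      ifelse(homo, cfg$haplogroup_effect[[trait]] * cfg$baseline_sd[[trait]], 0)
    stats::rnorm(n, mu, cfg$baseline_sd[[trait]])
  }
  HGB <- draw("HGB")
  HbF <- pmax(0, draw("HbF"))
  hz <- cfg$survival_baseline_hazard *
    ifelse(homo, cfg$survival_hazard_ratio, 1)
  tt <- stats::rexp(n, hz)
  surv_event <- as.integer(tt <= cfg$censoring_time)
  surv_time <- pmin(tt, cfg$censoring_time)
  out <- samples
  out$haplogroup <- dip
  out$HGB <- HGB
  out$HbF <- HbF
  out$surv_time <- surv_time
  out$surv_event <- surv_event
  out
}
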