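#' Minimum-spanning network (epsilon-relaxed)
#'
#' The union of all minimum spanning trees, relaxed by `epsilon`: an edge
#' (u, v) is retained when its Hamming distance is within `epsilon` of the
#' minimax (bottleneck) path weight between u and v. With `epsilon = 0` this
#' is exactly the union of all MSTs.
#'
#' @param d symmetric integer distance matrix
#' @param epsilon relaxation parameter (>= 0)
#' @return logical adjacency matrix
#' @keywords internal
msn_adjacency <- function(d, epsilon = 0) {
  n <- nrow(d)
  mm <- d                          # minimax path weights (Floyd-style)
  for (k in seq_len(n)) {
    mk <- pmax(matrix(mm[, k], n, n), matrix(mm[k, ], n, n, byrow = TRUE))
    mm <- pmin(mm, mk)
  }
  adj <- d <= mm + epsilon
  diag(adj) <- FALSE
  adj
}

hamming_matrix <- function(h) {
  as.matrix(stats::dist(h, method = "manhattan"))
}

#' Median-joining haplotype network
#'
#' Bandelt-style construction: iteratively build the epsilon-relaxed minimum
#' spanning network over the current node set; for each path-connected
#' triplet compute the majority-consensus (median) vector, site-wise ties
#' resolved toward the ancestral allele (0); add the candidate median that
#' most shortens the triplet connection cost; repeat until no median helps;
#' finally prune median vectors whose network degree falls below 3. The
#' construction is deterministic given the input order.
#'
#' @param haplotypes 0/1 matrix of distinct haplotypes x sites (rownames are
#'   node labels; 0 = ancestral where polarized), or a `HaplotypeCatalog`
#' @param epsilon relaxation parameter (default 0)
#' @param freq optional node frequencies (observed haplotypes)
#' @return a `HaplotypeNetwork`: list with `nodes` (matrix incl. medians),
#'   `is_median`, `freq`, `edges` (data.frame from, to, weight), `epsilon`
#' @export
median_joining_network <- function(haplotypes, epsilon = 0, freq = NULL) {
  if (inherits(haplotypes, "HaplotypeCatalog")) {
    if (is.null(freq)) freq <- haplotypes$count
    h <- haplotypes$hap_alleles
    rownames(h) <- ifelse(is.na(haplotypes$names),
                          paste0("hap", seq_len(nrow(h))), haplotypes$names)
    haplotypes <- h
  }
  h <- as.matrix(haplotypes)
  if (nrow(h) < 2) stop("need at least 2 distinct haplotypes")
  if (is.null(rownames(h))) rownames(h) <- paste0("n", seq_len(nrow(h)))
  n_obs <- nrow(h)
  if (is.null(freq)) freq <- rep(1, n_obs)
  is_median <- rep(FALSE, n_obs)
  med_id <- 0L

  repeat {
    d <- hamming_matrix(h)
    adj <- msn_adjacency(d, epsilon)
    best <- NULL; best_gain <- 0
    nn <- nrow(h)
    for (v in seq_len(nn)) {
      nb <- which(adj[v, ])
      if (length(nb) < 2) next
      for (ii in seq_len(length(nb) - 1)) for (jj in (ii + 1):length(nb)) {
        u <- nb[ii]; w <- nb[jj]
        med <- median_vector(h[u, ], h[v, ], h[w, ])
        if (any(apply(h, 1, function(r) all(r == med)))) next
        cur <- d[u, v] + d[v, w]          # current connection through v
        star <- sum(abs(h[u, ] - med)) + sum(abs(h[v, ] - med)) +
          sum(abs(h[w, ] - med))
        gain <- cur - star
        if (gain > best_gain + 1e-9 ||
            (is.null(best) && gain > 0)) {
          best_gain <- gain
          best <- med
        }
      }
    }
    if (is.null(best)) break
    med_id <- med_id + 1L
    h <- rbind(h, best)
    rownames(h)[nrow(h)] <- paste0("mv", med_id)
    freq <- c(freq, 0)
    is_median <- c(is_median, TRUE)
  }

  # prune medians of degree <= 2; repeat since pruning changes the MSN
  repeat {
    d <- hamming_matrix(h)
    adj <- msn_adjacency(d, epsilon)
    deg <- rowSums(adj)
    drop <- which(is_median & deg <= 2)
    if (!length(drop)) break
    h <- h[-drop, , drop = FALSE]
    freq <- freq[-drop]
    is_median <- is_median[-drop]
  }
  d <- hamming_matrix(h)
  adj <- msn_adjacency(d, epsilon)
  idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- data.frame(from = rownames(h)[idx[, 1]],
                      to = rownames(h)[idx[, 2]],
                      weight = d[idx], stringsAsFactors = FALSE)
  structure(list(nodes = h, is_median = is_median, freq = freq,
                 edges = edges, epsilon = epsilon),
            class = "HaplotypeNetwork")
}

# site-wise majority of three haplotypes; ties impossible for 3 binary inputs
median_vector <- function(a, b, c) {
  as.integer((a + b + c) >= 2)
}

#' @export
print.HaplotypeNetwork <- function(x, ...) {
  cat(sprintf("HaplotypeNetwork: %d nodes (%d median vectors), %d edges, epsilon = %g\n",
              nrow(x$nodes), sum(x$is_median), nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Export a haplotype network as GML
#' @param net a `HaplotypeNetwork`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_network_gml <- function(net, path) {
  lab <- rownames(net$nodes)
  lines <- c("graph [", "  directed 0")
  for (i in seq_along(lab)) {
    lines <- c(lines, "  node [", paste0("    id ", i),
               paste0("    label \"", lab[i], "\""),
               paste0("    frequency ", net$freq[i]),
               paste0("    median ", as.integer(net$is_median[i])), "  ]")
  }
  for (e in seq_len(nrow(net$edges))) {
    lines <- c(lines, "  edge [",
               paste0("    source ", match(net$edges$from[e], lab)),
               paste0("    target ", match(net$edges$to[e], lab)),
               paste0("    weight ", net$edges$weight[e]), "  ]")
  }
  lines <- c(lines, "]")
  writeLines(lines, path)
  invisible(path)
}

#' Export network haplotypes as a NEXUS file (PopART-compatible layout)
#' @param net a `HaplotypeNetwork`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_network_nexus <- function(net, path) {
  obs <- !net$is_median
  seqs <- apply(net$nodes[obs, , drop = FALSE], 1, paste, collapse = "")
  # encode 0/1 as A/T so phylogenetics tools accept the matrix
  seqs <- chartr("01", "AT", seqs)
  lab <- rownames(net$nodes)[obs]
  lines <- c("#NEXUS", "BEGIN TAXA;",
             paste0("DIMENSIONS NTAX=", sum(obs), ";"),
             "TAXLABELS", paste0("  ", lab), ";", "END;",
             "BEGIN CHARACTERS;",
             paste0("DIMENSIONS NCHAR=", ncol(net$nodes), ";"),
             "FORMAT DATATYPE=DNA MISSING=? GAP=-;", "MATRIX",
             paste0("  ", format(lab), "  ", seqs), ";", "END;",
             "BEGIN TRAITS;",
             paste0("  Dimensions NTRAITS=1;"),
             "  Format labels=yes missing=? separator=Comma;",
             "  TraitLabels count;",
             "  Matrix",
             paste0("  ", format(lab), " ", net$freq[obs]),
             ";", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Dating configuration
#'
#' @param calibration `"outgroup"` (scale mean pairwise divergence by the
#'   human-chimpanzee split) or `"clock"` (mutation-rate clock)
#' @param outgroup_divergence_years calibration depth (default 6.5e6 years)
#' @param mutation_rate per-base per-generation (default 1.25e-8)
#' @param generation_time years (default 25)
#' @param replicates resampling replicates (default 100)
#' @param subsample_size sequences drawn per group per replicate (default 25)
#' @param seed integer seed
#' @return a `DatingConfig` list
#' @export
dating_config <- function(calibration = c("outgroup", "clock"),
                          outgroup_divergence_years = 6.5e6,
                          mutation_rate = 1.25e-8, generation_time = 25,
                          replicates = 100, subsample_size = 25, seed = 0L) {
  calibration <- match.arg(calibration)
  if (replicates < 1) stop("replicates must be >= 1")
  if (subsample_size < 2) stop("subsample_size must be >= 2")
  structure(list(calibration = calibration,
                 outgroup_divergence_years = outgroup_divergence_years,
                 mutation_rate = mutation_rate,
                 generation_time = generation_time,
                 replicates = replicates, subsample_size = subsample_size,
                 seed = as.integer(seed)),
            class = "DatingConfig")
}

# per-site mean pairwise difference within rows (or across two sets)
pi_per_site <- function(h, L, h2 = NULL) {
  if (is.null(h2)) {
    mean_pairwise_diff(h) / L
  } else {
    n1 <- nrow(h); n2 <- nrow(h2)
    cnt1 <- colSums(h); cnt2 <- colSums(h2)
    # cross-pair differences per site: x(n2 - y) + y(n1 - x)
    sum(cnt1 * (n2 - cnt2) + cnt2 * (n1 - cnt1)) / (n1 * n2) / L
  }
}

pi_to_years <- function(pihat, cfg, outgroup_diff_per_site) {
  if (cfg$calibration == "outgroup") {
    if (is.null(outgroup_diff_per_site) || outgroup_diff_per_site <= 0)
      stop("outgroup_diff_per_site must be > 0 for outgroup calibration")
    cfg$outgroup_divergence_years * pihat / outgroup_diff_per_site
  } else {
    (pihat / (2 * cfg$mutation_rate)) * cfg$generation_time
  }
}

resample_dating <- function(draw_pi, cfg, outgroup_diff_per_site) {
  set.seed(cfg$seed)
  reps <- vapply(seq_len(cfg$replicates), function(r) {
    pi_to_years(draw_pi(), cfg, outgroup_diff_per_site)
  }, numeric(1))
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
  list(estimate = mean(reps), ci = ci, replicates = reps)
}

#' TMRCA of a haplotype group with resampling CIs
#'
#' Per replicate, `subsample_size` sequences are drawn without replacement
#' (all sequences, with a warning, when the group is smaller) and the mean
#' pairwise difference per site is converted to years either by outgroup
#' calibration (T = T_cal * pi / d_outgroup) or by the mutation clock
#' (T = pi / (2 mu) generations). The point estimate is the replicate mean;
#' the CI spans the 2.5th-97.5th percentiles.
#'
#' @param h 0/1 haplotype matrix (rows = sequences) for the group
#' @param L sequence length in bp over which `h`'s sites segregate
#' @param cfg a [dating_config()]
#' @param outgroup_diff_per_site outgroup divergence per site (required for
#'   outgroup calibration)
#' @return list with `estimate` (years), `ci`, `replicates`
#' @export
tmrca_estimate <- function(h, L, cfg = dating_config(),
                           outgroup_diff_per_site = NULL) {
  h <- as.matrix(h)
  if (nrow(h) < 2) stop("group must contain at least 2 sequences")
  if (nrow(h) < cfg$subsample_size)
    warning("group smaller than subsample_size; using all sequences per replicate")
  draw <- function() {
    idx <- if (nrow(h) <= cfg$subsample_size) seq_len(nrow(h))
           else sample.int(nrow(h), cfg$subsample_size)
    pi_per_site(h[idx, , drop = FALSE], L)
  }
  resample_dating(draw, cfg, outgroup_diff_per_site)
}

#' Divergence time between two haplotype groups
#'
#' Identical to [tmrca_estimate()] except that the per-replicate pi-hat is
#' computed over cross-group pairs only.
#'
#' @param hA,hB 0/1 haplotype matrices for the two groups (same sites)
#' @param L sequence length in bp
#' @param cfg a [dating_config()]
#' @param outgroup_diff_per_site outgroup divergence per site
#' @return list with `estimate` (years), `ci`, `replicates`
#' @export
divergence_time <- function(hA, hB, L, cfg = dating_config(),
                            outgroup_diff_per_site = NULL) {
  hA <- as.matrix(hA); hB <- as.matrix(hB)
  if (nrow(hA) < 2 || nrow(hB) < 2) stop("both groups need >= 2 sequences")
  if (nrow(hA) < cfg$subsample_size || nrow(hB) < cfg$subsample_size)
    warning("group smaller than subsample_size; using all sequences")
  draw <- function() {
    ia <- if (nrow(hA) <= cfg$subsample_size) seq_len(nrow(hA))
          else sample.int(nrow(hA), cfg$subsample_size)
    ib <- if (nrow(hB) <= cfg$subsample_size) seq_len(nrow(hB))
          else sample.int(nrow(hB), cfg$subsample_size)
    pi_per_site(hA[ia, , drop = FALSE], L, hB[ib, , drop = FALSE])
  }
  resample_dating(draw, cfg, outgroup_diff_per_site)
}

#' Star-genealogy allele age
#'
#' Genealogy-free age estimate for a mutation from the derived-allele
#' accumulation on its carrier haplotypes: the founder haplotype is the
#' site-wise majority among carriers (ties toward the ancestral allele), and
#' age in generations is the mean per-carrier count of differences from the
#' founder divided by mu * L, converted to years. This is a deliberately
#' simple desk-scale stand-in for genealogy-based dating tools and is exact
#' under a star genealogy.
#'
#' @param carrier_h 0/1 matrix of carrier haplotypes (0 = ancestral; the
#'   panel must be polarized)
#' @param mu mutation rate per base per generation
#' @param L sequence length in bp
#' @param generation_time years per generation (default 25)
#' @return list with `age_years`, `age_generations`, `founder`
#' @export
allele_age_star <- function(carrier_h, mu, L, generation_time = 25) {
  h <- as.matrix(carrier_h)
  if (nrow(h) < 2) stop("need at least 2 carrier haplotypes")
  founder <- as.integer(colSums(h) > nrow(h) / 2)  # ties -> ancestral (0)
  diffs <- rowSums(abs(sweep(h, 2, founder)))
  gens <- mean(diffs) / (mu * L)
  list(age_years = gens * generation_time, age_generations = gens,
       founder = founder)
}
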