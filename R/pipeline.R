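#' Write a dendrogram in Newick format
#' @param dend an `hclust`-compatible dendrogram
#' @param path optional output path; when NULL the Newick string is returned
#' @return Newick string (or `path` invisibly)
#' @export
write_newick <- function(dend, path = NULL) {
  n <- length(dend$labels)
  rec <- function(node, parent_h) {
    if (node < 0) {
      sprintf("%s:%g", dend$labels[-node], parent_h)
    } else {
      h <- dend$height[node]
      sprintf("(%s,%s):%g", rec(dend$merge[node, 1], h),
              rec(dend$merge[node, 2], h), parent_h - h)
    }
  }
  h_root <- dend$height[n - 1]
  nw <- sprintf("(%s,%s);", rec(dend$merge[n - 1, 1], h_root),
                rec(dend$merge[n - 1, 2], h_root))
  if (is.null(path)) return(nw)
  writeLines(nw, path)
  invisible(path)
}

# deterministic per-stage seed derived from the global seed
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(stage))) %% 2147483647L
}

#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()]. The
#' input is either a synthetic scenario (the default [sim_config()]) or a
#' phased VCF plus metadata files.
#'
#' @param out_dir output directory for the report bundle
#' @param seed global seed; per-stage seeds are derived deterministically
#' @param sim a [sim_config()] (used when `vcf` is NULL); its seed is
#'   overridden by the derived stage seed
#' @param vcf,metadata,ancestral optional input file paths (VCF, sample TSV,
#'   ancestral-allele TSV)
#' @param region optional region restriction for VCF input
#' @param stages character vector of enabled stages, a subset of
#'   `c("blocks", "haplotypes", "network", "dating", "selection", "assoc")`
#' @param block_method block detection method (default `"four_gamete"`)
#' @param k_haplogroups number of haplogroups (default 3)
#' @param maf_min,hwe_alpha,naming_threshold panel/catalog parameters
#' @param merge_threshold inter-block linkage merge threshold
#' @param dating_replicates,dating_subsample resampling design for dating
#' @param window,step sliding-window parameters for nucleotide diversity
#' @param plants optional list of mutation-planting specs; each element is a
#'   list(label, backgrounds, freqs). `"auto"` (default for synthetic input)
#'   plants one mutation per sharing pattern (classes 1, 2 and 3)
#' @param phenotypes a [phenotype_config()] or NULL to skip phenotype
#'   simulation on VCF input
#' @return a `PipelineConfig` list
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_config(),
                            vcf = NULL, metadata = NULL, ancestral = NULL,
                            region = NULL,
                            stages = c("blocks", "haplotypes", "network",
                                       "dating", "selection", "assoc"),
                            block_method = "four_gamete",
                            k_haplogroups = 3, maf_min = 0.05,
                            hwe_alpha = 0.001, naming_threshold = 0.002,
                            merge_threshold = 0.8,
                            dating_replicates = 100, dating_subsample = 25,
                            window = 50000, step = 10000,
                            plants = "auto",
                            phenotypes = phenotype_config()) {
  known <- c("blocks", "haplotypes", "network", "dating", "selection", "assoc")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  for (f in c(vcf, metadata, ancestral))
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 vcf = vcf, metadata = metadata, ancestral = ancestral,
                 region = region, stages = stages,
                 block_method = block_method,
                 k_haplogroups = k_haplogroups, maf_min = maf_min,
                 hwe_alpha = hwe_alpha, naming_threshold = naming_threshold,
                 merge_threshold = merge_threshold,
                 dating_replicates = dating_replicates,
                 dating_subsample = dating_subsample,
                 window = window, step = step, plants = plants,
                 phenotypes = phenotypes),
            class = "PipelineConfig")
}

# choose planting specs realizing sharing classes 1, 2 and 3: the most
# frequent named haplotype of each haplogroup serves as background (real
# mutations share backgrounds, so reuse across labels is fine)
default_plants <- function(catalog, hap_hg) {
  hgs <- sort(unique(hap_hg))
  pick <- function(hg) {
    cand <- which(hap_hg == hg & !is.na(catalog$names))
    if (!length(cand)) return(NULL)
    catalog$names[cand[which.max(catalog$p[cand])]]
  }
  top <- lapply(hgs, pick)
  spec_for <- function(label, bgs) {
    bgs <- unlist(bgs)
    list(label = label, backgrounds = bgs,
         freqs = catalog$p[match(bgs, catalog$names)] / 2)
  }
  plants <- list()
  if (!is.null(top[[1]]))
    plants[[length(plants) + 1]] <- spec_for("class1_mut", top[1])
  if (length(hgs) >= 3 && !is.null(top[[1]]) && !is.null(top[[3]]))
    plants[[length(plants) + 1]] <- spec_for("class2_mut", top[c(1, 3)])
  if (length(hgs) >= 3 && all(!vapply(top[1:3], is.null, TRUE)))
    plants[[length(plants) + 1]] <- spec_for("class3_mut", top[1:3])
  plants
}

#' Build a pipeline configuration from a JSON file
#'
#' The JSON object may carry any argument of [pipeline_config()]; `sim` and
#' `phenotypes` sub-objects override the corresponding config defaults.
#'
#' @param path JSON file
#' @return a `PipelineConfig`
#' @export
pipeline_config_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- if (!is.null(j$sim)) j$sim else list()
  phe_args <- if (!is.null(j$phenotypes)) j$phenotypes else list()
  j$sim <- do.call(sim_config, sim_args)
  j$phenotypes <- do.call(phenotype_config, phe_args)
  do.call(pipeline_config, j)
}

#' Run the full locus analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic or VCF input,
#' writing a report bundle (TSV/BED/Newick/GML/JSON files) into
#' `config$out_dir`. All randomness derives from the global seed, so a fixed
#' configuration reproduces its bundle byte for byte.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with the in-memory stage results and the file
#'   manifest
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- character(0)
  logmsg <- function(...) message("[haplolocus] ", sprintf(...))

  # ---- data stage (always on) ----
  if (is.null(config$vcf)) {
    sim <- config$sim
    sim$seed <- stage_seed(config$seed, "simulate")
    logmsg("simulating synthetic cohort (seed %d)", sim$seed)
    simres <- simulate_three_clade_locus(sim)
    mat <- simres$matrix
    samples <- simres$samples
    true_clade <- simres$true_clade
  } else {
    logmsg("reading %s", config$vcf)
    mat <- read_phased_vcf(config$vcf, region = config$region)
    samples <- if (!is.null(config$metadata)) read_sample_table(config$metadata)
               else data.frame(sample_id = sample_ids(mat))
    if (!is.null(config$ancestral))
      mat <- polarize_alleles(mat, read_ancestral_map(config$ancestral))
    true_clade <- NULL
  }
  write_phased_vcf(mat, out("cohort.vcf"))
  manifest <- c(manifest, "cohort.vcf")
  res <- list(matrix = mat, samples = samples)

  enabled <- function(s) s %in% config$stages

  # ---- blocks ----
  if (enabled("blocks")) {
    logmsg("detecting blocks (%s)", config$block_method)
    blocks <- detect_blocks(mat, method = config$block_method,
                            seed = stage_seed(config$seed, "blocks"))
    blocks <- merge_blocks(blocks, mat, config$merge_threshold)
    write_blocks_bed(blocks, mat$sites$chrom[1], out("blocks.bed"))
    manifest <- c(manifest, "blocks.bed")
    res$blocks <- blocks
  }

  # ---- haplotypes ----
  if (enabled("haplotypes")) {
    logmsg("cataloguing haplotypes")
    panel <- select_block_snps(mat, config$maf_min, config$hwe_alpha)
    if (!length(panel)) stop("stage haplotypes failed: empty SNP panel")
    catalog <- catalog_haplotypes(mat, panel, config$naming_threshold)
    dmat <- ibs_distance_matrix(catalog)
    dend <- upgma(dmat)
    hap_hg <- assign_haplogroups(dend, k = config$k_haplogroups,
                                 weights = catalog$count)
    hd <- haplotype_diversity(catalog)
    cat_tsv <- data.frame(name = ifelse(is.na(catalog$names),
                                        paste0("hap", seq_along(catalog$p)),
                                        catalog$names),
                          string = catalog$strings, count = catalog$count,
                          freq = catalog$p,
                          haplogroup = unname(hap_hg))
    utils::write.table(cat_tsv, out("catalog.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(round(dmat, 6), out("ibs_distance.tsv"), sep = "\t",
                       quote = FALSE)
    write_newick(dend, out("dendrogram.nwk"))
    manifest <- c(manifest, "catalog.tsv", "ibs_distance.tsv", "dendrogram.nwk")
    res$panel <- panel
    res$catalog <- catalog
    res$dendrogram <- dend
    res$haplogroups <- hap_hg
    res$haplotype_diversity <- hd

    # planted mutations + crosstab (synthetic input)
    plants <- config$plants
    if (identical(plants, "auto") && is.null(config$vcf))
      plants <- default_plants(catalog, hap_hg)
    if (is.list(plants) && length(plants)) {
      carriers <- list()
      pmat <- mat
      pseed <- stage_seed(config$seed, "plant")
      for (pl in plants) {
        ids <- character(0)
        for (b in seq_along(pl$backgrounds)) {
          pr <- plant_mutation(pmat, catalog, pl$backgrounds[b],
                               pl$freqs[b],
                               label = paste0(pl$label, "_", b),
                               seed = pseed + 17L * b)
          pmat <- pr$matrix
          ids <- c(ids, pr$carriers)
        }
        carriers[[pl$label]] <- ids
        pseed <- pseed + 1000L
      }
      xt <- mutation_haplotype_crosstab(catalog, carriers, hap_hg)
      utils::write.table(cbind(data.frame(mutation = rownames(xt$by_haplogroup)),
                               as.data.frame(xt$by_haplogroup),
                               sharing_class = xt$sharing_class),
                         out("crosstab.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest <- c(manifest, "crosstab.tsv")
      res$planted <- carriers
      res$crosstab <- xt
      res$matrix_with_mutations <- pmat
    }
  }

  # chromosome-level haplogroup labels (used by several stages)
  chrom_hg <- if (!is.null(res$haplogroups))
    stats::setNames(unname(res$haplogroups[res$catalog$assignment]),
                    names(res$catalog$assignment)) else NULL

  # ---- network ----
  if (enabled("network")) {
    if (is.null(res$catalog)) stop("stage network requires stage haplotypes")
    logmsg("median-joining network")
    named <- which(!is.na(res$catalog$names))
    h <- res$catalog$hap_alleles[named, , drop = FALSE]
    rownames(h) <- res$catalog$names[named]
    net <- median_joining_network(h, epsilon = 0,
                                  freq = res$catalog$count[named])
    write_network_gml(net, out("network.gml"))
    write_network_nexus(net, out("network.nex"))
    manifest <- c(manifest, "network.gml", "network.nex")
    res$network <- net
  }

  # ---- dating ----
  if (enabled("dating")) {
    if (is.null(chrom_hg)) stop("stage dating requires stage haplotypes")
    logmsg("TMRCA / divergence dating")
    L <- config$sim$region_length
    cfgd <- dating_config(calibration = "clock",
                          mutation_rate = config$sim$mutation_rate,
                          generation_time = config$sim$generation_time,
                          replicates = config$dating_replicates,
                          subsample_size = config$dating_subsample,
                          seed = stage_seed(config$seed, "dating"))
    a_derived <- derived_alleles(mat)
    rows <- list()
    for (hg in sort(unique(chrom_hg))) {
      hh <- a_derived[chrom_hg == hg, , drop = FALSE]
      if (nrow(hh) < 2) next
      est <- suppressWarnings(tmrca_estimate(hh, L, cfgd))
      rows[[length(rows) + 1]] <-
        data.frame(quantity = paste0("TMRCA_", hg), years = est$estimate,
                   ci_low = est$ci[1], ci_high = est$ci[2])
    }
    hgs <- sort(unique(chrom_hg))
    if (length(hgs) >= 2) {
      for (i in seq_len(length(hgs) - 1)) for (j in (i + 1):length(hgs)) {
        hA <- a_derived[chrom_hg == hgs[i], , drop = FALSE]
        hB <- a_derived[chrom_hg == hgs[j], , drop = FALSE]
        if (nrow(hA) < 2 || nrow(hB) < 2) next
        est <- suppressWarnings(divergence_time(hA, hB, L, cfgd))
        rows[[length(rows) + 1]] <-
          data.frame(quantity = paste0("divergence_", hgs[i], "_", hgs[j]),
                     years = est$estimate, ci_low = est$ci[1],
                     ci_high = est$ci[2])
      }
    }
    dating <- do.call(rbind, rows)
    utils::write.table(dating, out("dating.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- c(manifest, "dating.tsv")
    res$dating <- dating
  }

  # ---- selection ----
  if (enabled("selection")) {
    logmsg("diversity and EHH")
    span <- max(mat$sites$pos) - min(mat$sites$pos) + 1
    win <- min(config$window, max(1000, span))
    stp <- min(config$step, win)
    div <- theta_pi_windows(mat, window = win, step = stp)
    utils::write.table(div, out("diversity.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- c(manifest, "diversity.tsv")
    res$diversity <- div
    freq <- colMeans(mat$alleles)
    core <- which.min(abs(freq - 0.2))
    allele <- if (sum(mat$alleles[, core] == 1L) >= 2) 1L else 0L
    ehh <- tryCatch(ehh_curve(mat, core, core_allele = allele),
                    error = function(e) NULL)
    if (!is.null(ehh)) {
      utils::write.table(ehh, out("ehh.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest <- c(manifest, "ehh.tsv")
      res$ehh <- ehh
    }
  }

  # ---- association ----
  if (enabled("assoc")) {
    if (is.null(chrom_hg)) stop("stage assoc requires stage haplotypes")
    logmsg("haplogroup-phenotype association")
    hap_ids <- names(chrom_hg)
    sid <- sub("_h[12]$", "", hap_ids)
    dip <- tapply(chrom_hg, sid, function(v) paste(sort(v), collapse = "/"))
    pheno_cfg <- config$phenotypes
    pheno_cfg$seed <- stage_seed(config$seed, "phenotypes")
    pheno <- simulate_phenotypes(samples, dip[samples$sample_id], pheno_cfg)
    utils::write.table(pheno, out("phenotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- c(manifest, "phenotypes.tsv")
    hg <- pheno_cfg$designated_haplogroup
    homo <- pheno$haplogroup == paste(hg, hg, sep = "/")
    rows <- list()
    for (trait in c("HGB", "HbF")) for (sx in c("F", "M")) {
      sel <- pheno$sex == sx
      a <- pheno[[trait]][sel & homo]
      b <- pheno[[trait]][sel & !homo]
      if (length(a) >= 2 && length(b) >= 2) {
        w <- welch_t_test(a, b)
        rows[[length(rows) + 1]] <-
          data.frame(trait = trait, sex = sx, t = w$statistic, df = w$df,
                     p = w$p, hedges_g = w$effect,
                     g_lo = w$CI[1], g_hi = w$CI[2])
      }
    }
    assoc <- do.call(rbind, rows)
    if (!is.null(assoc)) {
      assoc$p_adj <- bh_adjust(assoc$p)
      utils::write.table(assoc, out("association.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      manifest <- c(manifest, "association.tsv")
      res$association <- assoc
    }
    if (sum(homo) >= 2 && sum(!homo) >= 2) {
      surv <- kaplan_meier_logrank(pheno$surv_time, pheno$surv_event,
                                   ifelse(homo, hg, "other"))
      sink_df <- data.frame(chisq = surv$test$statistic, df = 1,
                            p = surv$test$p)
      utils::write.table(sink_df, out("survival.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      manifest <- c(manifest, "survival.tsv")
      res$survival <- surv
    }
  }

  prov <- list(seed = config$seed,
               stages = config$stages,
               parameters = config[setdiff(names(config),
                                           c("phenotypes", "sim", "out_dir"))],
               sim = unclass(config$sim),
               phenotypes = unclass(config$phenotypes),
               skipped = setdiff(c("blocks", "haplotypes", "network",
                                   "dating", "selection", "assoc"),
                                 config$stages),
               files = manifest)
  jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  res$manifest <- c(manifest, "provenance.json")
  res$provenance <- prov
  invisible(res)
}

#' Derived-allele matrix
#'
#' Recodes the allele matrix so 0 = ancestral, restricted to polarized sites.
#' @param x a polarized `HaplotypeMatrix`
#' @return 0/1 matrix over polarized sites (0 = ancestral)
#' @export
derived_alleles <- function(x) {
  pol <- which(x$sites$polarized)
  if (!length(pol)) stop("no polarized sites")
  a <- x$alleles[, pol, drop = FALSE]
  anc <- x$sites$ancestral_index[pol]
  flip <- which(anc == 1L)
  a[, flip] <- 1L - a[, flip, drop = FALSE]
  a
}
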