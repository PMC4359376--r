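# Configuration and end-to-end orchestration: synthetic data -> QC ->
# kinship -> scan -> thresholds -> regions -> interactions -> report.

#' Build a run configuration
#'
#' Returns the default configuration for [run_gwas_pipeline()], a nested
#' list with one section per stage; override any entry via `...` using
#' section names (`synth`, `qc`, `scan`, `thresholds`, `regions`,
#' `epistasis`). The whole configuration can also be stored as YAML.
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param ... Named sections overriding defaults (partial lists are
#'   merged).
#' @return List of class `hz_config`.
#' @export
hz_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    synth = list(n_snps = 2000, prop_fixed_diff = 0.4, n_offspring = 185,
                 admix_generations = 8, recomb_rate_per_Mb = 0.005,
                 missing_rate = 0.01, chrom_scale = 1),
    qc = list(maf_min = 0.05, missing_max = 0.15, ld_window_snps = 30,
              ld_step_snps = 5, prune_r2_max = 0.999, prune = TRUE),
    scan = list(reml = TRUE, exact = TRUE),
    thresholds = list(n_perm = 200, percentile = 0.05, fdr_q = 0.1),
    regions = list(r2_flank = 0.9, merge_distance_bp = 10e6),
    epistasis = list(p_cutoff = 0.05, fdr_q = 0.1,
                     parameterization = "additive"))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm,
                                  call. = FALSE)
    if (is.list(dots[[nm]])) cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  validate_config(cfg)
  structure(cfg, class = c("hz_config", "list"))
}

validate_config <- function(cfg) {
  check_fraction(cfg$qc$maf_min, "qc$maf_min")
  check_fraction(cfg$qc$missing_max, "qc$missing_max")
  check_fraction(cfg$qc$prune_r2_max, "qc$prune_r2_max")
  check_fraction(cfg$thresholds$percentile, "thresholds$percentile")
  check_fraction(cfg$thresholds$fdr_q, "thresholds$fdr_q")
  check_fraction(cfg$epistasis$fdr_q, "epistasis$fdr_q")
  check_count(cfg$thresholds$n_perm, "thresholds$n_perm")
  check_count(cfg$synth$n_snps, "synth$n_snps", min = 40)
  if (cfg$qc$ld_window_snps < cfg$qc$ld_step_snps)
    stop("ld_window_snps must be >= ld_step_snps", call. = FALSE)
  invisible(cfg)
}

#' Read/write a run configuration as YAML
#' @param cfg An `hz_config` object.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(hz_config, c(list(seed = raw$seed),
                       raw[setdiff(names(raw), "seed")]))
}

#' Run the full hybrid-zone GWAS pipeline on synthetic or supplied data
#'
#' Generates (or accepts) an admixed mapping population, applies SNP
#' filtering and LD pruning, computes the centered kinship, scans each
#' phenotype with the mixed model, derives permutation and FDR
#' thresholds, builds LD-defined significant regions, tests pairwise
#' interactions among significant SNPs, and writes TSV artifacts plus a
#' markdown report when `out_dir` is given. Fully deterministic under the
#' configured seed.
#'
#' @param config An `hz_config` object.
#' @param data Optional list with `genotypes`, `panels` (skips synthesis).
#' @param phenotypes Optional named list of phenotype vectors; by default
#'   a single synthetic phenotype with a planted two-locus
#'   incompatibility (dom-dom architecture) is generated.
#' @param out_dir Optional output directory for artifacts.
#' @return List of class `hz_pipeline_result`: `config`, `data`, `qc`,
#'   `scans` (per phenotype: scan, thresholds, regions, interactions),
#'   `report` (character vector of markdown lines).
#' @export
run_gwas_pipeline <- function(config = hz_config(), data = NULL,
                              phenotypes = NULL, out_dir = NULL) {
  validate_config(config)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.null(data)) {
    data <- stage("synthetic-data", {
      s <- config$synth
      simulate_mapping_population(
        n_snps = s$n_snps, prop_fixed_diff = s$prop_fixed_diff,
        chrom_scale = s$chrom_scale, n_offspring = s$n_offspring,
        admix_generations = s$admix_generations,
        recomb_rate_per_Mb = s$recomb_rate_per_Mb,
        missing_rate = s$missing_rate, seed = derive_seed(seed, "synth"))
    })
  }
  geno <- data$genotypes
  panels <- data$panels
  qc_res <- stage("qc", {
    f <- filter_snps(geno, panels, maf_min = config$qc$maf_min,
                     missing_max = config$qc$missing_max)
    pruned <- if (isTRUE(config$qc$prune)) {
      ld_prune(f$genotypes, window_snps = config$qc$ld_window_snps,
               step_snps = config$qc$ld_step_snps,
               r2_max = config$qc$prune_r2_max)
    } else f$genotypes
    list(filtered = f, pruned = pruned)
  })
  mapping <- qc_res$pruned
  K <- stage("kinship", centered_kinship(mapping))
  if (is.null(phenotypes)) {
    phenotypes <- stage("phenotype-synthesis", {
      pool <- select_causal_pairs(mapping, panels, 1, "auto-auto",
                                  seed = derive_seed(seed, "causal"))
      model <- build_genotype_mean_table("dom-dom")
      sim <- simulate_phenotype_datasets(pool[1, ], model, mapping, 1,
                                         seed = derive_seed(seed, "pheno"))
      attr(sim$phenotypes, "planted_pair") <- pool[1, ]
      list(sterility_z = sim$phenotypes[, 1])
    })
  }
  scans <- list()
  for (ph in names(phenotypes)) {
    y <- phenotypes[[ph]]
    scan <- stage(paste0("scan-", ph),
                  wald_scan(mapping, y, kinship = K,
                            exact = config$scan$exact,
                            reml = config$scan$reml))
    perm <- stage(paste0("thresholds-", ph),
                  permutation_thresholds(
                    mapping, y, kinship = K,
                    n_perm = config$thresholds$n_perm,
                    percentile = config$thresholds$percentile,
                    seed = derive_seed(seed, paste0("perm_", ph))))
    thr <- threshold_set(perm, scan$p_wald, fdr_q = config$thresholds$fdr_q)
    sig_fdr <- significant_snps(scan, thr, "fdr")
    sig_perm <- significant_snps(scan, thr, "permutation")
    regions <- stage(paste0("regions-", ph),
                     define_regions(scan$snp_id[sig_fdr], geno,
                                    r2_flank = config$regions$r2_flank,
                                    merge_distance_bp =
                                      config$regions$merge_distance_bp,
                                    sig_perm_snps = scan$snp_id[sig_perm]))
    interactions <- NULL
    region_pairs <- NULL
    sig_ids <- scan$snp_id[sig_fdr]
    if (length(sig_ids) >= 2 &&
        length(unique(scan$chrom[sig_fdr])) >= 2) {
      interactions <- stage(paste0("epistasis-", ph),
                            interaction_scan(
                              sig_ids, mapping, y, kinship = K,
                              p_cutoff = config$epistasis$p_cutoff,
                              fdr_q = config$epistasis$fdr_q,
                              parameterization =
                                config$epistasis$parameterization))
      region_pairs <- summarize_region_pairs(interactions, regions)
    }
    scans[[ph]] <- list(phenotype = ph, scan = scan, thresholds = thr,
                        regions = regions, interactions = interactions,
                        region_pairs = region_pairs,
                        n_sig_fdr = sum(sig_fdr),
                        n_sig_perm = sum(sig_perm))
  }
  report <- pipeline_report(config, qc_res, scans)
  result <- structure(list(config = config, data = data, qc = qc_res,
                           kinship = K, scans = scans, report = report),
                      class = "hz_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

pipeline_report <- function(config, qc_res, scans) {
  lines <- c("# Hybrid-zone GWAS pipeline report", "",
             sprintf("- mapping SNPs after QC/pruning: %d",
                     n_snp(qc_res$pruned)),
             sprintf("- individuals: %d", n_ind(qc_res$pruned)), "")
  for (s in scans) {
    lines <- c(lines, sprintf("## Phenotype: %s", s$phenotype),
               sprintf("- significant SNPs: %d (FDR < %g), %d (permutation)",
                       s$n_sig_fdr, config$thresholds$fdr_q, s$n_sig_perm),
               sprintf("- significant regions: %d", nrow(s$regions)))
    if (!is.null(s$interactions)) {
      lines <- c(lines,
                 sprintf("- interaction tests: %d pairs, %d significant",
                         nrow(s$interactions),
                         sum(s$interactions$significant, na.rm = TRUE)),
                 sprintf("- region pairs with interactions: %d (%d auto-auto, %d X-auto)",
                         nrow(s$region_pairs$pairs),
                         s$region_pairs$n_auto_auto,
                         s$region_pairs$n_x_auto))
    }
    lines <- c(lines, "")
  }
  lines
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config_yaml(result$config, file.path(out_dir, "config.yaml"))
  write_kinship_tsv(result$kinship, file.path(out_dir, "kinship.tsv"))
  for (s in result$scans) {
    pref <- file.path(out_dir, s$phenotype)
    utils::write.table(s$scan, paste0(pref, "_scan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(autosome_p_threshold = s$thresholds$autosome_p_threshold,
           x_p_threshold = s$thresholds$x_p_threshold,
           fdr_q = s$thresholds$fdr_q,
           fdr_equivalent_p = s$thresholds$fdr_equivalent_p,
           n_permutations = s$thresholds$n_permutations,
           seed = result$config$seed),
      paste0(pref, "_thresholds.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(s$regions, paste0(pref, "_regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(s$regions))
      write_regions_bed(s$regions, paste0(pref, "_regions.bed"))
    if (!is.null(s$interactions))
      utils::write.table(s$interactions, paste0(pref, "_interactions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(result$report, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.hz_pipeline_result <- function(x, ...) {
  cat(x$report, sep = "\n")
  invisible(x)
}

#' Validate that genotype/region artifacts survive a write-read cycle
#'
#' Writes each supported artifact to a temporary directory, reads it
#' back, and compares: TSV and PLINK genotype dialects, phenotype TSV,
#' pedigree TSV, kinship TSV and BED regions.
#'
#' @param genotypes An `admixed_genotypes` object.
#' @param regions Optional region data frame.
#' @param pheno Optional phenotype data frame.
#' @return Data frame with one row per artifact: `artifact`, `ok`.
#' @export
validate_io_roundtrip <- function(genotypes, regions = NULL, pheno = NULL) {
  td <- tempfile("roundtrip")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  checks <- list()
  f <- file.path(td, "g.tsv")
  write_genotypes_tsv(genotypes, f)
  g2 <- read_genotypes_tsv(f)
  checks$genotypes_tsv <- identical(unname(genotypes$matrix),
                                    unname(g2$matrix)) &&
    identical(genotypes$map$pos, g2$map$pos)
  write_plink(genotypes, file.path(td, "g"))
  g3 <- read_plink(file.path(td, "g"))
  checks$plink_bed <- identical(unname(genotypes$matrix),
                                unname(g3$matrix)) &&
    identical(genotypes$map$chrom, g3$map$chrom)
  K <- centered_kinship(genotypes)
  write_kinship_tsv(K, file.path(td, "k.tsv"))
  K2 <- read_kinship_tsv(file.path(td, "k.tsv"))
  checks$kinship_tsv <- max(abs(K - K2)) < 1e-12
  if (!is.null(regions) && nrow(regions)) {
    write_regions_bed(regions, file.path(td, "r.bed"))
    r2 <- read_regions_bed(file.path(td, "r.bed"))
    checks$regions_bed <- all(r2$start == regions$start) &&
      all(r2$end == regions$end) && all(r2$chrom == regions$chrom)
  }
  if (!is.null(pheno)) {
    write_phenotypes_tsv(pheno, file.path(td, "p.tsv"))
    p2 <- read_phenotypes_tsv(file.path(td, "p.tsv"))
    checks$phenotypes_tsv <- isTRUE(all.equal(pheno, p2,
                                              check.attributes = FALSE))
  }
  data.frame(artifact = names(checks), ok = unlist(checks),
             row.names = NULL, stringsAsFactors = FALSE)
}
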